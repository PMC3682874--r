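#' Mean-plus-half-SD cutoff policy
#'
#' The condensation cutoff used for both degree centrality and citation
#' frequency: the arithmetic mean of the values plus `sd_multiplier` times
#' their population standard deviation (the value set is the whole population
#' of nodes or predications, not a sample).
#'
#' @param values Numeric vector with at least 2 elements.
#' @param sd_multiplier Multiplier on the population SD (default 0.5).
#' @return A `cutoff_policy`: list with `mean`, `sd`, `cutoff`, `n`.
#' @export
compute_cutoff <- function(values, sd_multiplier = 0.5) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("cutoff needs at least 2 values")
  if (anyNA(values)) stop("cutoff values must not contain NA")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  structure(list(mean = m, sd = s, cutoff = m + sd_multiplier * s,
                 n = length(values), sd_multiplier = sd_multiplier),
            class = "cutoff_policy")
}

#' @export
print.cutoff_policy <- function(x, ...) {
  cat(sprintf("Cutoff policy: mean %.6g + %.3g * sd %.6g = %.6g (n = %d)\n",
              x$mean, x$sd_multiplier, x$sd, x$cutoff, x$n))
  invisible(x)
}

filter_report <- function(stage, before, after, cutoff = NA_real_,
                          note = NA_character_) {
  list(stage = stage,
       predications_before = nrow(before$predications),
       predications_after = nrow(after$predications),
       nodes_before = nrow(before$nodes),
       nodes_after = nrow(after$nodes),
       cutoff = cutoff,
       note = note)
}

# Concept ids regarded as generic under a config: the explicit generic set,
# plus (when a hierarchy is supplied) every concept at depth < generic_depth
# from any root of the hierarchy (roots have depth 0).
generic_concept_ids <- function(config, candidate_ids) {
  generic <- intersect(candidate_ids, config$generic_concepts)
  if (!is.null(config$hierarchy)) {
    if (is.null(config$generic_depth)) {
      stop("config supplies a hierarchy but no generic_depth")
    }
    depth <- hierarchy_depths(config$hierarchy)
    shallow <- names(depth)[depth < config$generic_depth]
    generic <- union(generic, intersect(candidate_ids, shallow))
  }
  generic
}

# Minimum depth of every concept in a (child, parent) hierarchy, measured
# from the roots (parents that are never children).
hierarchy_depths <- function(hierarchy) {
  child <- hierarchy[, "child"]
  parent <- hierarchy[, "parent"]
  all_ids <- unique(c(child, parent))
  roots <- setdiff(parent, child)
  depth <- stats::setNames(rep(Inf, length(all_ids)), all_ids)
  depth[roots] <- 0
  frontier <- roots
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(child[parent %in% frontier])
    nxt <- nxt[depth[nxt] > d]
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

#' Novelty filter: drop predications with a generic argument
#'
#' Removes every predication whose subject or object concept is generic
#' (too high in the concept hierarchy to carry summary-worthy information,
#' e.g. "Patients" or "Pharmaceutical Preparations"). Generic concepts are
#' those in the config's `generic_concepts` set, plus, when a hierarchy is
#' supplied, concepts at depth below `generic_depth` from any hierarchy root.
#' Concepts left without any arc are dropped from the graph.
#'
#' @param graph A `predication_graph`.
#' @param config A `group_config`.
#' @return List with the filtered `graph` and a `report`.
#' @export
novelty_filter <- function(graph, config) {
  stopifnot(inherits(graph, "predication_graph"),
            inherits(config, "group_config"))
  generic <- generic_concept_ids(config, graph$nodes$id)
  keep <- !(graph$predications$subject_id %in% generic |
              graph$predications$object_id %in% generic)
  out <- subset_graph(graph, keep)
  list(graph = out, report = filter_report("novelty", graph, out))
}

#' Centrality filter: keep predications between highly connected concepts
#'
#' Keeps exactly the predications whose two arguments both have degree
#' centrality strictly above the mean-plus-half-SD cutoff computed over all
#' node centralities; everything else, and concepts left isolated, is
#' removed. When every node has the same centrality the population carries a
#' single value and the cutoff is degenerate (a strict cut would empty the
#' graph); the filter is skipped with a warning and the graph passes through
#' unchanged. An active filter that removes everything also warns.
#'
#' @param graph A `predication_graph`.
#' @param centrality Named centrality table for `graph`'s nodes; computed
#'   with [degree_centrality()] when not supplied.
#' @param sd_multiplier Multiplier on the population SD (default 0.5).
#' @return List with the filtered `graph` and a `report`.
#' @export
centrality_filter <- function(graph, centrality = NULL, sd_multiplier = 0.5) {
  stopifnot(inherits(graph, "predication_graph"))
  if (nrow(graph$nodes) < 2) {
    warning("centrality filter skipped: fewer than 2 nodes")
    return(list(graph = graph,
                report = filter_report("centrality", graph, graph,
                                       note = "skipped: fewer than 2 nodes")))
  }
  if (is.null(centrality)) centrality <- degree_centrality(graph)
  policy <- compute_cutoff(centrality, sd_multiplier)
  if (policy$sd == 0) {
    warning("centrality filter skipped: all nodes have identical centrality ",
            "(degenerate single-value population)")
    return(list(graph = graph,
                report = filter_report("centrality", graph, graph,
                                       cutoff = policy$cutoff,
                                       note = "skipped: zero variance")))
  }
  above <- names(centrality)[centrality > policy$cutoff]
  keep <- graph$predications$subject_id %in% above &
    graph$predications$object_id %in% above
  out <- subset_graph(graph, keep)
  if (nrow(out$predications) == 0) {
    warning("centrality filter removed every predication")
  }
  list(graph = out,
       report = filter_report("centrality", graph, out, cutoff = policy$cutoff))
}

#' Frequency filter: drop infrequently asserted predications
#'
#' Computes the mean-plus-half-SD cutoff over the citation frequencies of the
#' surviving predications and removes those with frequency strictly below it
#' (frequency equal to the cutoff survives). A single remaining predication
#' passes unfiltered (a cutoff needs at least 2 values). Arcs left without
#' any predication, and isolated concepts, are dropped.
#'
#' @param graph A `predication_graph` whose predications carry frequencies.
#' @param sd_multiplier Multiplier on the population SD (default 0.5).
#' @return List with the filtered `graph` and a `report`.
#' @export
frequency_filter <- function(graph, sd_multiplier = 0.5) {
  stopifnot(inherits(graph, "predication_graph"))
  freq <- graph$predications$frequency
  if (length(freq) < 2) {
    if (length(freq) == 1) {
      warning("frequency filter skipped: single predication")
    }
    return(list(graph = graph,
                report = filter_report("frequency", graph, graph,
                                       note = "skipped: fewer than 2 values")))
  }
  policy <- compute_cutoff(freq, sd_multiplier)
  out <- subset_graph(graph, freq >= policy$cutoff)
  if (nrow(out$predications) == 0) {
    warning("frequency filter removed every predication")
  }
  list(graph = out,
       report = filter_report("frequency", graph, out, cutoff = policy$cutoff))
}

#' Run the three condensation filters in pipeline order
#'
#' Novelty filter first; degree centrality is then recomputed on the
#' post-novelty graph for the centrality filter; the frequency cutoff
#' statistics use only the predications that survived the centrality filter.
#'
#' @param graph A `predication_graph`.
#' @param config A `group_config`.
#' @param sd_multiplier Multiplier on the population SD for both cutoffs.
#' @return List with the condensed `graph` and a list of three `reports`.
#' @export
condense_graph <- function(graph, config, sd_multiplier = 0.5) {
  nov <- novelty_filter(graph, config)
  if (nrow(nov$graph$predications) == 0) {
    return(list(graph = nov$graph, reports = list(nov$report)))
  }
  cen <- centrality_filter(nov$graph, sd_multiplier = sd_multiplier)
  if (nrow(cen$graph$predications) == 0) {
    return(list(graph = cen$graph, reports = list(nov$report, cen$report)))
  }
  frq <- frequency_filter(cen$graph, sd_multiplier = sd_multiplier)
  list(graph = frq$graph,
       reports = list(nov$report, cen$report, frq$report))
}
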