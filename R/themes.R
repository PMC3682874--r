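#' Assign a predication to a metapredication family
#'
#' Maps the predicate to its predicate group and each argument's semantic
#' type to its semantic group, then looks the resulting
#' `<group, predicate group, group>` triple up in the configured
#' metapredication families. When an argument carries several semantic types,
#' types are tried in their stored (file) order — subject types in the outer
#' loop — and the first combination yielding an allowed triple wins.
#'
#' @param predicate Uppercase predicate string.
#' @param subject_semtypes,object_semtypes Character vectors of semantic-type
#'   codes for the two arguments, in file order.
#' @param config A `group_config`.
#' @return A list with `name` (family display name), `triple` and
#'   `predicate_group`, or `NULL` when the predication is unmapped (unknown
#'   predicate or type, or no allowed triple).
#' @export
assign_metapredication <- function(predicate, subject_semtypes,
                                   object_semtypes, config) {
  pgroup <- config$predicate_to_pgroup[toupper(predicate)]
  if (is.na(pgroup)) return(NULL)
  lookup <- metapredication_lookup(config)
  s_groups <- config$semtype_to_group[subject_semtypes]
  o_groups <- config$semtype_to_group[object_semtypes]
  for (sg in s_groups) {
    if (is.na(sg)) next
    for (og in o_groups) {
      if (is.na(og)) next
      key <- paste(sg, pgroup, og, sep = "\r")
      hit <- lookup[[key]]
      if (!is.null(hit)) {
        return(list(name = hit, triple = c(sg, unname(pgroup), og),
                    predicate_group = unname(pgroup)))
      }
    }
  }
  NULL
}

# triple key -> family display name, cached on the config by environment.
metapredication_lookup <- function(config) {
  lookup <- list()
  for (m in config$metapredications) {
    for (tr in m$triples) {
      lookup[[paste(tr, collapse = "\r")]] <- m$name
    }
  }
  lookup
}

# Order of family names in the config (tie-break of last resort).
family_order <- function(config) {
  vapply(config$metapredications, `[[`, character(1), "name")
}

# Metapredication family (or NA) for every distinct predication of a graph.
assign_all_metapredications <- function(graph, config) {
  semtypes <- stats::setNames(graph$nodes$semtypes, graph$nodes$id)
  preds <- graph$predications
  vapply(seq_len(nrow(preds)), function(i) {
    hit <- assign_metapredication(preds$predicate[i],
                                  semtypes[[preds$subject_id[i]]],
                                  semtypes[[preds$object_id[i]]],
                                  config)
    if (is.null(hit)) NA_character_ else hit$name
  }, character(1))
}

# Indices of the distinct predications belonging to a cluster of cliques:
# those whose two arguments are both members of at least one clique in it.
cluster_predications <- function(cluster, cliques, graph) {
  members <- clique_members(cliques)[cluster]
  preds <- graph$predications
  hit <- rep(FALSE, nrow(preds))
  for (mem in members) {
    hit <- hit | (preds$subject_id %in% mem & preds$object_id %in% mem)
  }
  which(hit)
}

#' Label a cluster of cliques with its dominant metapredication
#'
#' The cluster's predication set contains every distinct predication whose
#' two arguments co-occur in at least one of its cliques. Each is assigned to
#' a metapredication family; families are counted over distinct predications
#' (unmapped ones are retained in the set but do not vote) and the most
#' frequent family becomes the theme label. Count ties resolve toward the
#' family with the higher summed citation frequency, then configuration
#' order. A cluster whose predications are all unmapped is unlabeled
#' (label `NA`).
#'
#' @param cluster Integer vector of clique ids.
#' @param cliques The `clique_set` the ids refer to.
#' @param graph The condensed `predication_graph`.
#' @param config A `group_config`.
#' @param assignments Optional precomputed per-predication family vector from
#'   `assign_all_metapredications` (recomputed when `NULL`).
#' @return A `cluster_label`: list with `cluster`, `pred_idx` (row indices
#'   into `graph$predications`), `assignments` (family or `NA` per
#'   predication), `counts`, and `label`.
#' @export
label_cluster <- function(cluster, cliques, graph, config, assignments = NULL) {
  stopifnot(length(cluster) >= 1)
  if (is.null(assignments)) {
    assignments <- assign_all_metapredications(graph, config)
  }
  idx <- cluster_predications(cluster, cliques, graph)
  assigned <- assignments[idx]
  mapped <- !is.na(assigned)
  label <- NA_character_
  counts <- integer(0)
  if (any(mapped)) {
    counts <- table(assigned[mapped])
    top <- max(counts)
    tied <- names(counts)[counts == top]
    if (length(tied) > 1) {
      freq_sum <- vapply(tied, function(fam) {
        sum(graph$predications$frequency[idx][mapped][assigned[mapped] == fam])
      }, numeric(1))
      tied <- tied[freq_sum == max(freq_sum)]
      if (length(tied) > 1) {
        ord <- family_order(config)
        tied <- tied[order(match(tied, ord))][1]
      }
    }
    label <- tied[1]
    counts <- as.integer(counts)
    names(counts) <- names(table(assigned[mapped]))
  }
  structure(list(cluster = sort(as.integer(cluster)), pred_idx = idx,
                 assignments = assigned, counts = counts, label = label),
            class = "cluster_label")
}

#' Label every cluster of every solution
#'
#' @param solutions A `solution_set`.
#' @param cliques,graph,config As for [label_cluster()].
#' @return List with `detail` (per solution, list of `cluster_label`s) and
#'   `labels` (per solution, character vector of labels, `NA` = unlabeled).
#' @export
label_solutions <- function(solutions, cliques, graph, config) {
  assignments <- assign_all_metapredications(graph, config)
  detail <- lapply(solutions$solutions, function(part) {
    lapply(part, label_cluster, cliques = cliques, graph = graph,
           config = config, assignments = assignments)
  })
  labels <- lapply(detail, function(ds) {
    vapply(ds, `[[`, character(1), "label")
  })
  list(detail = detail, labels = labels)
}

#' Select the optimal cluster solution by theme-label agreement
#'
#' Scans the icicle rows from finest to coarsest for the first row with at
#' most `max_singletons` singleton clusters (the all-singleton row is not a
#' candidate; when no row qualifies the coarsest row is used) and then walks
#' downwards: while the step to the next row merges at least one group of
#' clusters and — under the default conservative reading — every merged group
#' shares one common, non-missing theme label, the next row is the better
#' solution. The walk stops at the first step with a label-inconsistent (or
#' absent) merge, and the current row is the optimum.
#'
#' @param solutions A `solution_set`.
#' @param labels Per-solution label vectors, e.g. `label_solutions()$labels`.
#' @param max_singletons Most singleton clusters tolerated in the starting
#'   row (default 3).
#' @param mode `"conservative"` (default: all merge groups in a step must be
#'   label-consistent to advance) or `"permissive"` (one consistent group
#'   suffices).
#' @return The selected row index.
#' @export
select_solution <- function(solutions, labels, max_singletons = 3,
                            mode = c("conservative", "permissive")) {
  mode <- match.arg(mode)
  parts <- solutions$solutions
  n <- length(parts)
  if (n == 1) return(1L)

  start <- NA_integer_
  for (i in seq_len(n)) {
    sizes <- lengths(parts[[i]])
    if (all(sizes == 1) && length(sizes) > 1) next  # all-singleton row
    if (sum(sizes == 1) <= max_singletons) { start <- i; break }
  }
  if (is.na(start)) start <- n

  current <- start
  while (current < n) {
    groups <- merge_groups(parts[[current]], parts[[current + 1]])
    if (length(groups) == 0) break
    consistent <- vapply(groups, function(g) {
      ls <- labels[[current]][g]
      !anyNA(ls) && length(unique(ls)) == 1
    }, logical(1))
    ok <- if (mode == "conservative") all(consistent) else any(consistent)
    if (!ok) break
    current <- current + 1L
  }
  as.integer(current)
}

# Groups of cluster indices of `finer` that fall into one cluster of
# `coarser`; only groups with >= 2 members (true merge events) are returned.
merge_groups <- function(finer, coarser) {
  coarse_of <- vapply(finer, function(cl) {
    hit <- which(vapply(coarser, function(co) all(cl %in% co), logical(1)))
    hit[1]
  }, integer(1))
  groups <- split(seq_along(finer), coarse_of)
  unname(groups[lengths(groups) >= 2])
}

#' Dynamic cut: merge same-theme clusters along the remaining tree
#'
#' Starting from the selected solution, the remaining merge events of the
#' cluster tree are walked in order. An event is applied if and only if every
#' cluster it would merge (mapped into the current partition) carries the
#' same non-missing theme label; inconsistent events are skipped without
#' stopping the walk, which is what lets different branches of the tree be
#' cut at different heights. Labels of merged clusters are recomputed after
#' each applied event. The result need not equal any icicle row.
#'
#' @param solutions A `solution_set`.
#' @param index Selected row index (from [select_solution()]).
#' @param labeller Function mapping an integer vector of clique ids to a
#'   theme label (or `NA`); e.g. a closure over [label_cluster()].
#' @return List with `partition` (list of clique-id vectors) and `labels`.
#' @export
dynamic_merge <- function(solutions, index, labeller) {
  partition <- solutions$solutions[[index]]
  labels <- vapply(partition, labeller, character(1))
  events <- Filter(function(e) e$step >= index, solutions$merge_events)
  for (ev in events) {
    # Current clusters the event's merged node draws from (children that
    # never formed, because an earlier event was skipped, dissolve into the
    # clusters holding their members).
    holders <- which(vapply(partition, function(cl) {
      any(ev$parent %in% cl)
    }, logical(1)))
    if (length(holders) < 2) next
    ls <- labels[holders]
    if (anyNA(ls) || length(unique(ls)) != 1) next
    merged <- sort(unlist(partition[holders]))
    partition <- c(partition[-holders], list(merged))
    labels <- c(labels[-holders], labeller(merged))
  }
  ord <- order(vapply(partition, min, integer(1)))
  list(partition = partition[ord], labels = labels[ord])
}
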