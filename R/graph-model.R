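#' Build a predication graph from occurrence records
#'
#' Concepts become nodes (one per distinct concept id, keeping the name and
#' the ordered set of semantic types seen for it) and each distinct
#' (subject, predicate, object) triple becomes a predication whose frequency
#' is the number of distinct citations it occurs in. Several predications
#' between the same unordered concept pair share a single arc; direction
#' (subject to object) is retained per predication as metadata.
#'
#' @param records Predication occurrence records as returned by
#'   [read_predications()] or [generate_corpus()].
#' @return A `predication_graph`: list with `nodes` (data frame `id`, `name`,
#'   list-column `semtypes`) and `predications` (data frame `subject_id`,
#'   `predicate`, `object_id`, `frequency`, list-column `citations`).
#' @export
build_graph <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("cannot build a graph from zero records")
  self <- records$subject_id == records$object_id
  if (any(self)) {
    warning(sum(self), " self-predication occurrence(s) dropped")
    records <- records[!self, , drop = FALSE]
    if (nrow(records) == 0) stop("cannot build a graph from zero records")
  }

  # Nodes: first-seen name, ordered union of semantic types (file order).
  concept_ids <- c(records$subject_id, records$object_id)
  concept_names <- c(records$subject_name, records$object_name)
  concept_types <- c(records$subject_semtype, records$object_semtype)
  first <- !duplicated(concept_ids)
  nodes <- data.frame(id = concept_ids[first], name = concept_names[first],
                      stringsAsFactors = FALSE)
  type_key <- paste(concept_ids, concept_types, sep = "\r")
  keep_type <- !duplicated(type_key) & nzchar(concept_types) & !is.na(concept_types)
  semtypes <- split(concept_types[keep_type],
                    factor(concept_ids[keep_type], levels = nodes$id))
  nodes$semtypes <- unname(semtypes[nodes$id])
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  key <- paste(records$subject_id, records$predicate, records$object_id,
               sep = "\r")
  citations <- lapply(split(records$citation_id, key), function(x) sort(unique(x)))
  parts <- strsplit(names(citations), "\r", fixed = TRUE)
  preds <- data.frame(
    subject_id = vapply(parts, `[`, character(1), 1),
    predicate = vapply(parts, `[`, character(1), 2),
    object_id = vapply(parts, `[`, character(1), 3),
    frequency = vapply(citations, length, integer(1)),
    stringsAsFactors = FALSE
  )
  preds$citations <- unname(citations)
  preds <- preds[order(preds$subject_id, preds$object_id, preds$predicate), ,
                 drop = FALSE]
  rownames(preds) <- NULL

  new_predication_graph(nodes, preds)
}

new_predication_graph <- function(nodes, predications) {
  structure(list(nodes = nodes, predications = predications),
            class = "predication_graph")
}

#' @export
print.predication_graph <- function(x, ...) {
  cat("Predication graph: ", nrow(x$nodes), " concepts, ",
      nrow(x$predications), " distinct predications, ",
      n_arcs(x), " arcs\n", sep = "")
  invisible(x)
}

# Unordered concept-pair keys of the arcs (one per pair, any predicate).
arc_pairs <- function(graph) {
  p <- graph$predications
  if (nrow(p) == 0) return(character(0))
  unique(paste(pmin(p$subject_id, p$object_id),
               pmax(p$subject_id, p$object_id), sep = "\r"))
}

n_arcs <- function(graph) length(arc_pairs(graph))

#' Count the citation frequency of one distinct predication
#'
#' Frequency is the number of distinct citations a predication appears in:
#' multiple occurrences within one sentence, or in several sentences of the
#' same citation, count once.
#'
#' @param records Occurrence records that all share the same
#'   (subject, predicate, object) triple.
#' @return Integer count of distinct citation ids.
#' @export
count_frequency <- function(records) {
  records <- as.data.frame(records)
  key <- unique(paste(records$subject_id, records$predicate, records$object_id))
  if (length(key) > 1) {
    stop("records span more than one distinct predication")
  }
  length(unique(records$citation_id))
}

#' Degree centrality of every concept in the graph
#'
#' Freeman degree centrality on the undirected simple view of the graph:
#' the number of distinct neighbours of a node divided by (n - 1). Multiple
#' predicates or directions between a concept pair contribute a single arc.
#'
#' @param graph A `predication_graph` with at least 2 nodes.
#' @return Named numeric vector (concept id -> centrality in \[0, 1\]).
#' @export
degree_centrality <- function(graph) {
  stopifnot(inherits(graph, "predication_graph"))
  n <- nrow(graph$nodes)
  if (n < 2) stop("degree centrality needs at least 2 nodes")
  deg <- stats::setNames(numeric(n), graph$nodes$id)
  pairs <- arc_pairs(graph)
  if (length(pairs) > 0) {
    ends <- unlist(strsplit(pairs, "\r", fixed = TRUE))
    tab <- table(ends)
    deg[names(tab)] <- as.numeric(tab)
  }
  deg / (n - 1)
}

# Restrict a graph to a subset of its distinct predications (logical or
# integer index into graph$predications); nodes left without any arc drop out.
subset_graph <- function(graph, keep) {
  preds <- graph$predications[keep, , drop = FALSE]
  rownames(preds) <- NULL
  used <- unique(c(preds$subject_id, preds$object_id))
  nodes <- graph$nodes[graph$nodes$id %in% used, , drop = FALSE]
  rownames(nodes) <- NULL
  new_predication_graph(nodes, preds)
}

#' Convert a predication graph to an igraph object
#'
#' Undirected simple graph over the arcs (one edge per unordered concept
#' pair); optionally weighted by the arc's summed citation frequency.
#'
#' @param graph A `predication_graph`.
#' @param weighted Attach summed citation frequencies as edge weights.
#' @return An igraph graph whose vertex names are concept ids and `label`
#'   attribute the concept names.
#' @export
as_igraph <- function(graph, weighted = FALSE) {
  stopifnot(inherits(graph, "predication_graph"))
  pairs <- arc_pairs(graph)
  ends <- if (length(pairs) > 0) {
    matrix(unlist(strsplit(pairs, "\r", fixed = TRUE)), ncol = 2, byrow = TRUE)
  } else {
    matrix(character(0), ncol = 2)
  }
  ig <- igraph::graph_from_data_frame(
    as.data.frame(ends, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$id, label = graph$nodes$name,
                          stringsAsFactors = FALSE)
  )
  if (weighted && igraph::ecount(ig) > 0) {
    p <- graph$predications
    key <- paste(pmin(p$subject_id, p$object_id),
                 pmax(p$subject_id, p$object_id), sep = "\r")
    w <- tapply(p$frequency, key, sum)
    igraph::E(ig)$weight <- as.numeric(w[pairs])
  }
  ig
}
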