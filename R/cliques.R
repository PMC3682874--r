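#' Enumerate maximal cliques of the condensed graph
#'
#' All maximal cliques (complete subgraphs contained in no larger complete
#' subgraph) of the undirected simple view of the graph, of size at least
#' `min_clique_size`. Cliques may overlap: a concept can be a member of
#' several cliques, which is what lets hub concepts tie the clique clustering
#' together. Output order is deterministic: descending size, then
#' lexicographic on the sorted member id lists; ids are assigned 1..k in that
#' order.
#'
#' @param graph A `predication_graph`.
#' @param min_clique_size Smallest clique size to report (default 3, the
#'   smallest clique in the social-network sense; configurable down to 2).
#' @return A `clique_set`: list of cliques, each a list with `id`, `members`
#'   (sorted concept ids) and `size`. An empty graph yields an empty set.
#' @export
find_maximal_cliques <- function(graph, min_clique_size = 3) {
  stopifnot(inherits(graph, "predication_graph"))
  if (min_clique_size < 2) stop("min_clique_size must be at least 2")
  if (nrow(graph$nodes) == 0 || nrow(graph$predications) == 0) {
    return(structure(list(), class = "clique_set"))
  }
  ig <- as_igraph(graph)
  raw <- igraph::max_cliques(ig, min = min_clique_size)
  members <- lapply(raw, function(v) sort(names(v)))
  members <- members[order_cliques(members)]
  structure(
    lapply(seq_along(members), function(i) {
      list(id = i, members = members[[i]], size = length(members[[i]]))
    }),
    class = "clique_set"
  )
}

# Deterministic clique ordering: descending size, then lexicographic
# comparison of the sorted member vectors.
order_cliques <- function(members) {
  if (length(members) == 0) return(integer(0))
  keys <- vapply(members, paste, character(1), collapse = "\r")
  order(-lengths(members), keys)
}

#' @export
print.clique_set <- function(x, ...) {
  cat("Clique set: ", length(x), " maximal clique(s)",
      if (length(x) > 0) paste0(", sizes ",
                                paste(range(vapply(x, `[[`, 0L, "size")),
                                      collapse = "-")),
      "\n", sep = "")
  invisible(x)
}

clique_members <- function(cliques) lapply(cliques, `[[`, "members")

#' Clique co-membership matrix
#'
#' Square symmetric matrix indexed by clique id whose (i, j) entry is the
#' number of concepts shared by cliques i and j; the diagonal holds the
#' clique sizes.
#'
#' @param cliques A `clique_set` with at least one clique.
#' @return Integer matrix with dimnames the clique ids.
#' @export
co_membership <- function(cliques) {
  if (length(cliques) == 0) stop("co-membership needs at least 1 clique")
  members <- clique_members(cliques)
  k <- length(members)
  # Incidence matrix concepts x cliques; crossprod gives shared-node counts.
  concepts <- sort(unique(unlist(members)))
  inc <- matrix(0L, nrow = length(concepts), ncol = k,
                dimnames = list(concepts, seq_len(k)))
  for (i in seq_len(k)) inc[members[[i]], i] <- 1L
  S <- crossprod(inc)
  storage.mode(S) <- "integer"
  dimnames(S) <- list(seq_len(k), seq_len(k))
  S
}
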