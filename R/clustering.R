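#' Hierarchically cluster cliques on the co-membership matrix
#'
#' Agglomerative clustering on the shared-node similarity matrix, in the
#' Johnson style: at each step the most similar pair of clusters is merged,
#' and all merges tied at that similarity are applied simultaneously (tied
#' pairs that chain through a common cluster collapse into one multi-way
#' merge). A cluster solution (partition of the cliques) is emitted at every
#' distinct merge height, from the all-singleton partition down to the single
#' all-inclusive cluster — the rows of an icicle plot, finest first.
#'
#' @param S Co-membership matrix from [co_membership()].
#' @param linkage How between-cluster similarity aggregates the pairwise
#'   entries of `S`: `"average"` (default, the UCINET-style Johnson default),
#'   `"single"` (max) or `"complete"` (min).
#' @return A `solution_set`: list with `solutions` (list of partitions, each
#'   a list of integer clique-id vectors, finest first), `heights` (the
#'   similarity at which each partition forms; `NA` for the initial
#'   singletons) and `merge_events` (ordered list; each event has `step`,
#'   `height`, `children` — the merged clusters as clique-id vectors — and
#'   `parent`). One clique yields a degenerate single-partition set with a
#'   warning.
#' @export
cluster_cliques <- function(S, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  S <- as.matrix(S)
  k <- nrow(S)
  stopifnot(k == ncol(S), k >= 1)
  if (k == 1) {
    warning("only one clique: degenerate single-partition solution set")
    return(structure(list(solutions = list(list(1L)),
                          heights = NA_real_,
                          merge_events = list()),
                     class = "solution_set"))
  }
  agg <- switch(linkage, average = mean, single = max, complete = min)
  off <- S
  diag(off) <- NA

  clusters <- lapply(seq_len(k), function(i) i)
  solutions <- list(canonical_partition(clusters))
  heights <- NA_real_
  merge_events <- list()
  step <- 0
  tol <- 1e-9

  cluster_sim <- function(a, b) agg(off[a, b, drop = FALSE][!is.na(off[a, b])])

  while (length(clusters) > 1) {
    step <- step + 1
    m <- length(clusters)
    sims <- matrix(-Inf, m, m)
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        sims[i, j] <- sims[j, i] <- cluster_sim(clusters[[i]], clusters[[j]])
      }
    }
    h <- max(sims)
    # Merge the connected components of the "tied at h" graph simultaneously.
    tied <- which(sims >= h - tol, arr.ind = TRUE)
    tied <- tied[tied[, 1] < tied[, 2], , drop = FALSE]
    comp <- seq_len(m)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (r in seq_len(nrow(tied))) {
      a <- find(tied[r, 1]); b <- find(tied[r, 2])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(m), find, integer(1))
    new_clusters <- list()
    for (root in unique(roots)) {
      group <- which(roots == root)
      merged <- sort(unlist(clusters[group]))
      new_clusters <- c(new_clusters, list(merged))
      if (length(group) > 1) {
        merge_events[[length(merge_events) + 1]] <- list(
          step = step, height = h,
          children = clusters[group],
          parent = merged
        )
      }
    }
    clusters <- new_clusters
    solutions <- c(solutions, list(canonical_partition(clusters)))
    heights <- c(heights, h)
  }

  structure(list(solutions = solutions, heights = heights,
                 merge_events = merge_events),
            class = "solution_set")
}

# Order a partition's clusters by smallest member, members sorted.
canonical_partition <- function(clusters) {
  clusters <- lapply(clusters, function(x) sort(as.integer(x)))
  clusters[order(vapply(clusters, min, integer(1)))]
}

#' @export
print.solution_set <- function(x, ...) {
  cat("Solution set: ", length(x$solutions), " cluster solution(s) over ",
      length(unlist(x$solutions[[1]])), " clique(s)\n", sep = "")
  for (i in seq_along(x$solutions)) {
    cat(sprintf("  row %d (height %s): %d cluster(s)\n", i,
                format(x$heights[i]), length(x$solutions[[i]])))
  }
  invisible(x)
}

#' Plain-text icicle plot of a solution set
#'
#' One row per cluster solution, finest first; cliques in the same cluster
#' share a letter within a row.
#'
#' @param solutions A `solution_set`.
#' @return Character vector of lines, invisibly; also printed.
#' @export
icicle_text <- function(solutions) {
  k <- length(unlist(solutions$solutions[[1]]))
  header <- paste(sprintf("%2d", seq_len(k)), collapse = " ")
  lines <- paste0("   ", header)
  for (i in seq_along(solutions$solutions)) {
    part <- solutions$solutions[[i]]
    sym <- character(k)
    for (ci in seq_along(part)) sym[part[[ci]]] <- LETTERS[(ci - 1) %% 26 + 1]
    lines <- c(lines, paste0(sprintf("%2d ", i),
                             paste(sprintf("%2s", sym), collapse = " ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Silhouette-coefficient baseline solution
#'
#' The baseline picks, among the non-trivial cluster solutions (between 2 and
#' k-1 clusters), the one maximizing the average silhouette coefficient.
#' Distances between cliques are derived from the co-membership matrix by the
#' max-shift conversion d(i,j) = max(off-diagonal of S) - S(i,j). For clique
#' i, a is the mean distance to its own cluster's other cliques, b the
#' smallest mean distance to another cluster, and s(i) = (b - a) / max(a, b);
#' cliques in singleton clusters score 0 by convention. Ties in ASC resolve
#' toward fewer clusters.
#'
#' @param S Co-membership matrix.
#' @param solutions A `solution_set` over the same cliques (at least 3).
#' @return A `baseline_result`: list with `index` (chosen row), `partition`,
#'   `asc`, and `asc_table` (per-row cluster counts and ASC; trivial rows
#'   `NA`).
#' @export
silhouette_baseline <- function(S, solutions) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 3) stop("silhouette baseline needs at least 3 cliques")
  D <- comembership_distance(S)
  n_rows <- length(solutions$solutions)
  asc <- rep(NA_real_, n_rows)
  sizes <- integer(n_rows)
  for (i in seq_len(n_rows)) {
    part <- solutions$solutions[[i]]
    sizes[i] <- length(part)
    if (length(part) >= 2 && length(part) <= k - 1) {
      asc[i] <- average_silhouette(D, part)
    }
  }
  if (all(is.na(asc))) stop("no non-trivial cluster solution to score")
  best <- max(asc, na.rm = TRUE)
  candidates <- which(!is.na(asc) & asc >= best - 1e-12)
  # Ties toward fewer clusters (the more summary-like solution).
  index <- candidates[which.min(sizes[candidates])]
  structure(list(index = index,
                 partition = solutions$solutions[[index]],
                 asc = asc[index],
                 asc_table = data.frame(row = seq_len(n_rows),
                                        n_clusters = sizes, asc = asc)),
            class = "baseline_result")
}

# Max-shift similarity-to-distance conversion.
comembership_distance <- function(S) {
  S <- as.matrix(S)
  off <- S
  diag(off) <- NA
  shift <- if (all(is.na(off))) 0 else max(off, na.rm = TRUE)
  D <- shift - S
  diag(D) <- 0
  D
}

# Average silhouette coefficient of a partition under distance matrix D.
average_silhouette <- function(D, partition) {
  k <- nrow(D)
  assignment <- integer(k)
  for (ci in seq_along(partition)) assignment[partition[[ci]]] <- ci
  s <- numeric(k)
  for (i in seq_len(k)) {
    own <- partition[[assignment[i]]]
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(seq_along(partition)[-assignment[i]], function(cj) {
      mean(D[i, partition[[cj]]])
    }, numeric(1)))
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  mean(s)
}
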