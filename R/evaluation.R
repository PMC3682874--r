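#' Cohesion, separation and overall validity of labeled clusters
#'
#' For cluster i with theme label L(i): x counts the distinct predications in
#' its predication set assigned to L(i), y those assigned otherwise (or
#' unmapped), and z the distinct predications outside cluster i — present in
#' at least one other cluster's set but not in i's — assigned to L(i), each
#' counted once however many other clusters hold it. Then cohesion =
#' x / (x + y), separation = x / (x + z), and overall validity is their
#' harmonic mean 2·Coh·Sep / (Coh + Sep). Unlabeled clusters are excluded
#' from scoring and reported; a cluster with x + y = 0 scores `NA`.
#'
#' Corpus-level scores are reported both micro-averaged (x, y, z pooled over
#' clusters before applying the formulas — the headline) and macro-averaged
#' (mean of the per-cluster scores).
#'
#' @param cluster_labels List of `cluster_label` objects (one per cluster of
#'   one partition), as produced by [label_cluster()] / [label_solutions()].
#' @return A `validity_result`: list with `per_cluster` (data frame of x, y,
#'   z, cohesion, separation, overall), `micro`, `macro`, and
#'   `n_unlabeled`.
#' @export
cluster_validity <- function(cluster_labels) {
  labeled <- Filter(function(cl) !is.na(cl$label), cluster_labels)
  n_unlabeled <- length(cluster_labels) - length(labeled)
  if (length(labeled) == 0) {
    empty <- data.frame(label = character(0), x = integer(0), y = integer(0),
                        z = integer(0), cohesion = numeric(0),
                        separation = numeric(0), overall = numeric(0))
    return(structure(list(per_cluster = empty,
                          micro = c(cohesion = NA, separation = NA, overall = NA),
                          macro = c(cohesion = NA, separation = NA, overall = NA),
                          n_unlabeled = n_unlabeled),
                     class = "validity_result"))
  }
  all_labels <- vapply(cluster_labels, `[[`, character(1), "label")
  lab_pos <- which(!is.na(all_labels))
  rows <- lapply(lab_pos, function(i) {
    cl <- cluster_labels[[i]]
    x <- sum(cl$assignments == cl$label, na.rm = TRUE)
    y <- length(cl$pred_idx) - x
    # Distinct predications matching L(i) held by other clusters but not i.
    others <- cluster_labels[-i]
    z_idx <- unique(unlist(lapply(others, function(o) {
      o$pred_idx[!is.na(o$assignments) & o$assignments == cl$label]
    })))
    z <- length(setdiff(z_idx, cl$pred_idx))
    data.frame(label = cl$label, x = x, y = y, z = z,
               cohesion = safe_ratio(x, x + y),
               separation = safe_ratio(x, x + z),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per$overall <- harmonic_mean(per$cohesion, per$separation)

  micro <- with(per, {
    coh <- safe_ratio(sum(x), sum(x) + sum(y))
    sep <- safe_ratio(sum(x), sum(x) + sum(z))
    c(cohesion = coh, separation = sep, overall = harmonic_mean(coh, sep))
  })
  macro <- c(cohesion = mean(per$cohesion, na.rm = TRUE),
             separation = mean(per$separation, na.rm = TRUE),
             overall = mean(per$overall, na.rm = TRUE))
  structure(list(per_cluster = per, micro = micro, macro = macro,
                 n_unlabeled = n_unlabeled),
            class = "validity_result")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

harmonic_mean <- function(a, b) {
  ifelse(is.na(a) | is.na(b), NA_real_,
         ifelse(a + b == 0, 0, 2 * a * b / (a + b)))
}

#' @export
print.validity_result <- function(x, ...) {
  cat("Cluster validity (", nrow(x$per_cluster), " labeled cluster(s), ",
      x$n_unlabeled, " unlabeled)\n", sep = "")
  cat(sprintf("  micro: cohesion %.3f  separation %.3f  overall %.3f\n",
              x$micro["cohesion"], x$micro["separation"], x$micro["overall"]))
  cat(sprintf("  macro: cohesion %.3f  separation %.3f  overall %.3f\n",
              x$macro["cohesion"], x$macro["separation"], x$macro["overall"]))
  invisible(x)
}

#' Compare system validity to the silhouette baseline
#'
#' Per-metric differences (system minus baseline), micro and macro.
#'
#' @param system,baseline `validity_result` objects computed on the same
#'   clique set.
#' @return List with `micro_delta` and `macro_delta` named vectors.
#' @export
compare_to_baseline <- function(system, baseline) {
  list(micro_delta = system$micro - baseline$micro,
       macro_delta = system$macro - baseline$macro)
}

#' Evaluate cluster labeling against major MeSH descriptors
#'
#' For each cluster, the major MeSH descriptors of every citation that
#' contributes at least one predication to the cluster are collected and
#' ranked by the number of contributing citations carrying them (ties
#' lexicographic). The top k descriptors, k = the cluster's number of
#' distinct argument concepts, form the reference; concepts match reference
#' descriptors by exact name or through the supplied synonym table. Recall is
#' matched reference descriptors over k, precision matched concepts over the
#' concept count, F their harmonic mean; corpus scores pool the counts.
#'
#' @param cluster_labels List of `cluster_label` objects for one partition.
#' @param graph The condensed `predication_graph`.
#' @param citation_mesh Data frame (`citation_id`, `descriptor`) from
#'   [read_mesh_table()]; descriptors must be qualifier-free.
#' @param synonyms Optional named list, concept id -> character vector of
#'   descriptor synonyms.
#' @return A `mesh_eval_result`: per-cluster data frame plus pooled `recall`,
#'   `precision`, `f_score`.
#' @export
mesh_evaluate <- function(cluster_labels, graph, citation_mesh,
                          synonyms = list()) {
  citation_mesh$descriptor <- strip_qualifier(citation_mesh$descriptor)
  citation_mesh <- unique(citation_mesh)
  names_of <- stats::setNames(graph$nodes$name, graph$nodes$id)

  rows <- lapply(seq_along(cluster_labels), function(i) {
    cl <- cluster_labels[[i]]
    preds <- graph$predications[cl$pred_idx, , drop = FALSE]
    concepts <- unique(c(preds$subject_id, preds$object_id))
    k <- length(concepts)
    cites <- unique(unlist(preds$citations))
    known <- cites %in% citation_mesh$citation_id
    if (any(!known)) {
      warning(sum(!known), " citation(s) missing from the MeSH table; skipped")
    }
    mesh <- citation_mesh[citation_mesh$citation_id %in% cites[known], ,
                          drop = FALSE]
    if (nrow(mesh) == 0 || k == 0) {
      return(data.frame(cluster = i, n_concepts = k, n_descriptors = 0,
                        matched_descriptors = 0, matched_concepts = 0))
    }
    counts <- table(mesh$descriptor)
    ranked <- names(counts)[order(-as.integer(counts), names(counts))]
    top <- ranked[seq_len(min(k, length(ranked)))]

    concept_terms <- lapply(concepts, function(id) {
      unique(c(names_of[[id]], synonyms[[id]]))
    })
    concept_matched <- vapply(concept_terms, function(terms) {
      any(terms %in% top)
    }, logical(1))
    descriptor_matched <- vapply(top, function(d) {
      any(vapply(concept_terms, function(terms) d %in% terms, logical(1)))
    }, logical(1))
    data.frame(cluster = i, n_concepts = k, n_descriptors = length(top),
               matched_descriptors = sum(descriptor_matched),
               matched_concepts = sum(concept_matched))
  })
  per <- do.call(rbind, rows)
  recall <- safe_ratio(sum(per$matched_descriptors), sum(per$n_descriptors))
  precision <- safe_ratio(sum(per$matched_concepts), sum(per$n_concepts))
  f <- harmonic_mean(recall, precision)
  structure(list(per_cluster = per, recall = recall, precision = precision,
                 f_score = f),
            class = "mesh_eval_result")
}

#' @export
print.mesh_eval_result <- function(x, ...) {
  cat(sprintf("MeSH labeling evaluation: recall %.3f  precision %.3f  F %.3f\n",
              x$recall, x$precision, x$f_score))
  invisible(x)
}
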