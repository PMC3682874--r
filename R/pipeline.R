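#' Summarize a predication corpus into labeled themes
#'
#' Runs the full pipeline: graph construction, novelty filter, degree
#' centrality filter, citation frequency filter, maximal clique enumeration,
#' co-membership clustering, metapredication labeling and semantic selection
#' of the optimal cluster solution, optionally followed by the dynamic cut
#' that merges same-theme clusters along the remaining tree. If the graph
#' empties mid-pipeline the result is an empty summary with a warning, not
#' an error.
#'
#' @param records Predication occurrence records.
#' @param config A `group_config` (default: the bundled configuration).
#' @param min_clique_size Smallest reported clique (default 3).
#' @param sd_multiplier Multiplier on the population SD in both cutoffs
#'   (default 0.5).
#' @param max_singletons Most singleton clusters tolerated in the starting
#'   icicle row (default 3).
#' @param dynamic_cut Apply [dynamic_merge()] after solution selection.
#' @param linkage Between-cluster similarity aggregation for
#'   [cluster_cliques()].
#' @param selection_mode `"conservative"` or `"permissive"`, see
#'   [select_solution()].
#' @return A `clique_summary`: the condensed graph, filter reports, cliques,
#'   co-membership matrix, solution set with per-solution labels, selected
#'   row, and the final `clusters` (each with clique ids, concepts, label and
#'   metapredication counts).
#' @export
summarize_corpus <- function(records, config = default_group_config(),
                             min_clique_size = 3, sd_multiplier = 0.5,
                             max_singletons = 3, dynamic_cut = FALSE,
                             linkage = "average",
                             selection_mode = "conservative") {
  stopifnot(inherits(config, "group_config"))
  params <- list(min_clique_size = min_clique_size,
                 sd_multiplier = sd_multiplier,
                 max_singletons = max_singletons,
                 dynamic_cut = dynamic_cut, linkage = linkage,
                 selection_mode = selection_mode)
  graph <- build_graph(records)
  cond <- condense_graph(graph, config, sd_multiplier)

  empty_summary <- function(cliques = structure(list(), class = "clique_set")) {
    warning("pipeline produced an empty summary")
    structure(list(graph = cond$graph, reports = cond$reports,
                   cliques = cliques, S = NULL, solutions = NULL,
                   labels = NULL, selected = NA_integer_, clusters = list(),
                   config = config, params = params, empty = TRUE),
              class = "clique_summary")
  }
  if (nrow(cond$graph$predications) == 0) return(empty_summary())

  cliques <- find_maximal_cliques(cond$graph, min_clique_size)
  if (length(cliques) == 0) return(empty_summary(cliques))

  S <- co_membership(cliques)
  solutions <- if (length(cliques) == 1) {
    suppressWarnings(cluster_cliques(S))
  } else {
    cluster_cliques(S, linkage)
  }
  lab <- label_solutions(solutions, cliques, cond$graph, config)
  selected <- select_solution(solutions, lab$labels, max_singletons,
                              selection_mode)

  partition <- solutions$solutions[[selected]]
  detail <- lab$detail[[selected]]
  if (dynamic_cut && length(solutions$merge_events) > 0) {
    assignments <- assign_all_metapredications(cond$graph, config)
    labeller <- function(cluster) {
      label_cluster(cluster, cliques, cond$graph, config, assignments)$label
    }
    dm <- dynamic_merge(solutions, selected, labeller)
    partition <- dm$partition
    detail <- lapply(partition, label_cluster, cliques = cliques,
                     graph = cond$graph, config = config,
                     assignments = assignments)
  }

  clusters <- lapply(seq_along(partition), function(i) {
    cl <- detail[[i]]
    concepts <- sort(unique(unlist(clique_members(cliques)[partition[[i]]])))
    list(cliques = partition[[i]], concepts = concepts, label = cl$label,
         counts = cl$counts, pred_idx = cl$pred_idx,
         assignments = cl$assignments)
  })

  structure(list(graph = cond$graph, reports = cond$reports,
                 cliques = cliques, S = S, solutions = solutions,
                 labels = lab, selected = selected, clusters = clusters,
                 cluster_detail = detail, config = config, params = params,
                 empty = FALSE),
            class = "clique_summary")
}

#' @export
print.clique_summary <- function(x, ...) {
  cat("Clique-clustering summary\n")
  for (r in x$reports) {
    cat(sprintf("  %-10s predications %d -> %d, nodes %d -> %d%s\n",
                r$stage, r$predications_before, r$predications_after,
                r$nodes_before, r$nodes_after,
                if (!is.na(r$cutoff)) sprintf(" (cutoff %.4g)", r$cutoff) else ""))
  }
  if (x$empty) { cat("  empty summary\n"); return(invisible(x)) }
  cat("  cliques: ", length(x$cliques), "; solutions: ",
      length(x$solutions$solutions), "; selected row ", x$selected, "\n",
      sep = "")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d [%s]: %d clique(s), %d concept(s), %d predication(s)\n",
                i, if (is.na(cl$label)) "UNLABELED" else cl$label,
                length(cl$cliques), length(cl$concepts), length(cl$pred_idx)))
  }
  invisible(x)
}

#' Evaluate a summary: validity, baseline comparison, MeSH, recovery
#'
#' Computes cohesion/separation/overall validity of the summary's clusters;
#' when the clique set admits a silhouette baseline (at least 3 cliques),
#' labels the baseline partition and reports its validity and the per-metric
#' deltas; optionally scores the cluster labeling against major MeSH
#' descriptors and, for synthetic corpora, against the planted ground truth.
#'
#' @param summary A `clique_summary`.
#' @param truth Optional ground truth from [generate_corpus()].
#' @param citation_mesh Optional citation-to-descriptor table.
#' @param synonyms Optional concept synonym list.
#' @return List with `system_validity`, `baseline` (baseline result,
#'   validity), `delta`, and optional `mesh` / `recovery` entries.
#' @export
evaluate_summary <- function(summary, truth = NULL, citation_mesh = NULL,
                             synonyms = list()) {
  stopifnot(inherits(summary, "clique_summary"))
  if (summary$empty) stop("cannot evaluate an empty summary")
  out <- list(system_validity = cluster_validity(summary$cluster_detail))

  base <- if (length(summary$cliques) >= 3) {
    # a solution set can lack any non-trivial row (e.g. disjoint cliques
    # collapsing in one step); there is no baseline then
    tryCatch(silhouette_baseline(summary$S, summary$solutions),
             error = function(e) NULL)
  }
  if (!is.null(base)) {
    base_detail <- lapply(base$partition, label_cluster,
                          cliques = summary$cliques, graph = summary$graph,
                          config = summary$config)
    base_validity <- cluster_validity(base_detail)
    out$baseline <- list(result = base, validity = base_validity)
    out$delta <- compare_to_baseline(out$system_validity, base_validity)
  }
  if (!is.null(citation_mesh)) {
    out$mesh <- mesh_evaluate(summary$cluster_detail, summary$graph,
                              citation_mesh, synonyms)
  }
  if (!is.null(truth)) {
    out$recovery <- score_recovery(summary, truth)
  }
  out
}

#' Serialize a summary to a deterministic JSON document
#'
#' The document carries the run manifest (parameters, configuration digest,
#' filter reports), the condensed graph, the cliques, every cluster solution
#' with its labels, the selected row and the final labeled clusters. No
#' timestamps are included: identical inputs and parameters produce
#' byte-identical files.
#'
#' @param summary A `clique_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "clique_summary"))
  doc <- summary_document(summary)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

summary_document <- function(summary) {
  g <- summary$graph
  preds <- g$predications
  doc <- list(
    tool = list(name = "cliquesum",
                version = as.character(utils::packageVersion("cliquesum"))),
    manifest = list(params = summary$params,
                    config_digest = config_digest(summary$config),
                    reports = summary$reports),
    graph = list(
      nodes = lapply(seq_len(nrow(g$nodes)), function(i) {
        list(id = g$nodes$id[i], name = g$nodes$name[i],
             semtypes = g$nodes$semtypes[[i]])
      }),
      predications = lapply(seq_len(nrow(preds)), function(i) {
        list(subject = preds$subject_id[i], predicate = preds$predicate[i],
             object = preds$object_id[i], frequency = preds$frequency[i])
      })
    ),
    cliques = lapply(summary$cliques, function(q) {
      list(id = q$id, members = q$members)
    }),
    empty = summary$empty
  )
  if (!summary$empty) {
    doc$co_membership <- unname(lapply(seq_len(nrow(summary$S)), function(i) {
      as.integer(summary$S[i, ])
    }))
    doc$solutions <- lapply(seq_along(summary$solutions$solutions), function(i) {
      list(row = i, height = summary$solutions$heights[i],
           clusters = summary$solutions$solutions[[i]],
           labels = as.list(summary$labels$labels[[i]]))
    })
    doc$selected_row <- summary$selected
    doc$clusters <- lapply(summary$clusters, function(cl) {
      list(label = cl$label, cliques = cl$cliques, concepts = cl$concepts,
           metapredication_counts = as.list(cl$counts))
    })
  }
  doc
}

# Stable digest of a group_config (md5 of its canonical serialization).
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
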