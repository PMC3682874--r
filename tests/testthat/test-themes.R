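cfg <- default_group_config()

test_that("predications map to metapredication families through both tables", {
  drug <- assign_metapredication("TREATS", "phsu", "dsyn", cfg)
  expect_equal(drug$name, "Drug treatment")
  expect_equal(drug$triple, c("Chemicals & Drugs", "Therapy", "Disorders"))

  proc <- assign_metapredication("TREATS", "Therapeutic or Preventive Procedure",
                                 "Disease or Syndrome", cfg)
  expect_equal(proc$name, "Procedure treatment")
  expect_equal(proc$triple, c("Procedures", "Therapy", "Disorders"))

  expect_null(assign_metapredication("PROCESS_OF", "dsyn", "humn", cfg))
  expect_null(assign_metapredication("TREATS", "unknown_type", "dsyn", cfg))
  # Disorders TREATS Disorders realizes no allowed triple
  expect_null(assign_metapredication("TREATS", "dsyn", "dsyn", cfg))
})

test_that("with several semantic types the first allowed combination wins", {
  # subject types in file order: humn (no triple with TREATS) then phsu
  hit <- assign_metapredication("TREATS", c("humn", "phsu"), c("dsyn"), cfg)
  expect_equal(hit$name, "Drug treatment")
  # phsu before topp: Drug treatment outranks Procedure treatment
  hit2 <- assign_metapredication("TREATS", c("phsu", "topp"), "dsyn", cfg)
  expect_equal(hit2$name, "Drug treatment")
  hit3 <- assign_metapredication("TREATS", c("topp", "phsu"), "dsyn", cfg)
  expect_equal(hit3$name, "Procedure treatment")
})

make_cluster_graph <- function(triples, semtypes) {
  g <- build_graph(make_records(triples, semtypes))
  cl <- structure(list(list(id = 1L, members = sort(g$nodes$id),
                            size = nrow(g$nodes))),
                  class = "clique_set")
  list(graph = g, cliques = cl)
}

test_that("the most frequent metapredication labels the cluster", {
  semtypes <- c("DBS" = "topp", "Pallidotomy" = "topp", "PD" = "dsyn",
                "Tremor" = "dsyn")
  fx <- make_cluster_graph(data.frame(
    subject = c("DBS", "Pallidotomy", "DBS", "Tremor"),
    predicate = c("TREATS", "TREATS", "TREATS", "COEXISTS_WITH"),
    object = c("PD", "PD", "Tremor", "PD"),
    stringsAsFactors = FALSE
  ), semtypes)
  lab <- label_cluster(1L, fx$cliques, fx$graph, cfg)
  expect_equal(lab$label, "Procedure treatment")
  expect_equal(unname(lab$counts[order(-lab$counts)][1]), 3L)

  # majority vote: 3 drug-treatment vs 1 comorbidity
  semtypes2 <- c("d1" = "phsu", "d2" = "phsu", "d3" = "phsu", "pd" = "dsyn")
  fx2 <- make_cluster_graph(data.frame(
    subject = c("d1", "d2", "d3", "pd"),
    predicate = c("TREATS", "TREATS", "TREATS", "COEXISTS_WITH"),
    object = c("pd", "pd", "pd", "d1"),
    stringsAsFactors = FALSE
  ), semtypes2)
  # COEXISTS_WITH over dsyn/phsu is unmapped; it stays in the set, not the vote
  lab2 <- label_cluster(1L, fx2$cliques, fx2$graph, cfg)
  expect_equal(lab2$label, "Drug treatment")
  expect_length(lab2$pred_idx, 4)
})

test_that("clusters with no mapped predication stay unlabeled", {
  fx <- make_cluster_graph(data.frame(
    subject = c("a", "b"), predicate = c("PROCESS_OF", "ISA"),
    object = c("b", "a"), stringsAsFactors = FALSE
  ), c(a = "dsyn", b = "dsyn"))
  lab <- label_cluster(1L, fx$cliques, fx$graph, cfg)
  expect_true(is.na(lab$label))
  expect_length(lab$counts, 0)
})

test_that("count ties break by summed citation frequency, then config order", {
  semtypes <- c("drug" = "phsu", "pd" = "dsyn", "gene" = "gngm")
  # one Drug treatment (freq 5) vs one Etiology (freq 2): tie on counts
  fx <- make_cluster_graph(data.frame(
    subject = c("drug", "gene"), predicate = c("TREATS", "CAUSES"),
    object = c("pd", "pd"), freq = c(5L, 2L), stringsAsFactors = FALSE
  ), semtypes)
  expect_equal(label_cluster(1L, fx$cliques, fx$graph, cfg)$label,
               "Drug treatment")
  # equal frequencies: configuration (table) order decides; Drug treatment
  # precedes Etiology
  fx2 <- make_cluster_graph(data.frame(
    subject = c("drug", "gene"), predicate = c("TREATS", "CAUSES"),
    object = c("pd", "pd"), freq = c(2L, 2L), stringsAsFactors = FALSE
  ), semtypes)
  expect_equal(label_cluster(1L, fx2$cliques, fx2$graph, cfg)$label,
               "Drug treatment")
})

test_that("cluster predication sets follow clique membership", {
  # two triangles sharing an edge; the shared-edge predication belongs to both
  semtypes <- stats::setNames(rep("phsu", 4), c("a", "b", "c", "d"))
  recs <- make_records(data.frame(
    subject = c("a", "a", "b", "b", "c"), predicate = "INTERACTS_WITH",
    object = c("b", "c", "c", "d", "d"), stringsAsFactors = FALSE
  ), semtypes)
  g <- build_graph(recs)
  cl <- find_maximal_cliques(g)
  expect_length(cl, 2)
  l1 <- label_cluster(1L, cl, g, cfg)
  l2 <- label_cluster(2L, cl, g, cfg)
  expect_length(l1$pred_idx, 3)
  expect_length(l2$pred_idx, 3)
  shared <- which(g$predications$subject_id == "b" &
                    g$predications$object_id == "c")
  expect_true(shared %in% l1$pred_idx && shared %in% l2$pred_idx)
})

test_that("the icicle walk advances through same-label merges and stops", {
  fx <- icicle_walk_fixture()
  expect_equal(select_solution(fx$solutions, fx$labels), 5L)
})

test_that("the walk stops immediately when no merge shares labels", {
  fx <- icicle_walk_fixture()
  labels <- lapply(fx$solutions$solutions, function(part) {
    paste0("L", seq_along(part))  # every cluster uniquely labeled
  })
  expect_equal(select_solution(fx$solutions, labels), 3L)  # the starting row
})

test_that("a uniformly labeled tree runs to the coarsest row", {
  fx <- icicle_walk_fixture()
  labels <- lapply(fx$solutions$solutions, function(part) {
    rep("Drug treatment", length(part))
  })
  expect_equal(select_solution(fx$solutions, labels),
               length(fx$solutions$solutions))
})

test_that("the selected row never precedes the starting row", {
  fx <- icicle_walk_fixture()
  idx <- select_solution(fx$solutions, fx$labels)
  start_candidates <- which(vapply(fx$solutions$solutions, function(p) {
    !(all(lengths(p) == 1) && length(p) > 1) && sum(lengths(p) == 1) <= 3
  }, logical(1)))
  expect_gte(idx, min(start_candidates))
})

test_that("without any qualifying row the walk starts at the coarsest", {
  sol <- structure(list(
    solutions = list(as.list(1:9),
                     c(list(c(1L, 2L)), as.list(3:9)),
                     list(1:9)),
    heights = c(NA, 2, 1), merge_events = list()
  ), class = "solution_set")
  labels <- lapply(sol$solutions, function(p) paste0("L", seq_along(p)))
  # rows 1 and 2 have too many singletons (9 and 7): fall back to the last
  expect_equal(select_solution(sol, labels, max_singletons = 3), 3L)
})

test_that("the dynamic cut merges same-theme branches and skips others", {
  fx <- dynamic_cut_fixture()
  out <- dynamic_merge(fx$solutions, 1L, fx$labeller)
  expect_equal(out$partition, list(c(1L, 2L), c(3L, 4L), 5L, 6L, c(7L, 8L)))
  expect_equal(out$labels, c("Substance interaction", "Body location",
                             "Etiology", "Drug treatment", "Etiology"))
})

test_that("a label-distinct tree leaves the partition unchanged", {
  fx <- dynamic_cut_fixture()
  distinct <- function(members) {
    if (length(members) == 1) paste0("L", members) else NA_character_
  }
  out <- dynamic_merge(fx$solutions, 1L, distinct)
  expect_equal(out$partition, as.list(1:8))
})

test_that("a uniformly labeled tree collapses to one cluster", {
  fx <- dynamic_cut_fixture()
  out <- dynamic_merge(fx$solutions, 1L, function(members) "Etiology")
  expect_equal(out$partition, list(1:8))
})

test_that("no two dynamic-cut clusters share a label across an applied event", {
  fx <- dynamic_cut_fixture()
  out <- dynamic_merge(fx$solutions, 1L, fx$labeller)
  # clusters 5 and {7,8} share "Etiology" but no tree event merges them with
  # label-consistent participants, so they legitimately stay apart
  for (ev in fx$solutions$merge_events) {
    holders <- unique(vapply(ev$children, function(ch) {
      which(vapply(out$partition, function(cl) all(ch %in% cl), logical(1)))[1]
    }, integer(1)))
    if (length(holders) < 2) next
    ls <- out$labels[holders]
    expect_false(!anyNA(ls) && length(unique(ls)) == 1)
  }
})
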