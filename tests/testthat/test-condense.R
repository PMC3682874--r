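test_that("the cutoff is the mean plus half the population SD", {
  p <- compute_cutoff(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(p$mean, 0.5)
  expect_equal(p$sd, sqrt(0.05))
  expect_equal(p$cutoff, 0.5 + 0.5 * sqrt(0.05))

  expect_equal(compute_cutoff(c(7, 7, 7))$cutoff, 7)   # zero variance
  expect_equal(compute_cutoff(c(0, 1))$cutoff, 0.75)   # 0.5 + 0.5 * 0.5
  expect_equal(compute_cutoff(c(1, 1, 1, 9))$cutoff, 3 + 0.5 * sqrt(12))
  expect_equal(compute_cutoff(c(0, 10), sd_multiplier = 1)$cutoff, 10)
  expect_error(compute_cutoff(3), "at least 2")
})

test_that("the novelty filter removes predications with a generic argument", {
  cfg <- default_group_config()
  cfg$generic_concepts <- "Pharmaceutical Preparations"
  recs <- make_records(data.frame(
    subject = c("Pharmaceutical Preparations", "Dopamine Agonists"),
    predicate = "TREATS", object = "Parkinson Disease",
    stringsAsFactors = FALSE
  ))
  out <- novelty_filter(build_graph(recs), cfg)
  expect_equal(nrow(out$graph$predications), 1)
  expect_equal(out$graph$predications$subject_id, "Dopamine Agonists")
  expect_false("Pharmaceutical Preparations" %in% out$graph$nodes$id)
  expect_equal(out$report$predications_before, 2)
  expect_equal(out$report$predications_after, 1)

  cfg$generic_concepts <- character(0)
  out2 <- novelty_filter(build_graph(recs), cfg)
  expect_equal(nrow(out2$graph$predications), 2)  # identity without generics
})

test_that("hierarchy depth marks shallow concepts generic", {
  cfg <- default_group_config()
  cfg$hierarchy <- rbind(c("Pharmaceutical Preparations", "Entity"),
                         c("Dopamine Agonists", "Pharmaceutical Preparations"),
                         c("Parkinson Disease", "Disease"),
                         c("Disease", "Entity"))
  colnames(cfg$hierarchy) <- c("child", "parent")
  recs <- make_records(data.frame(
    subject = c("Pharmaceutical Preparations", "Dopamine Agonists"),
    predicate = "TREATS", object = "Parkinson Disease",
    stringsAsFactors = FALSE
  ))
  g <- build_graph(recs)
  expect_error(novelty_filter(g, cfg), "generic_depth")
  cfg$generic_depth <- 2L
  out <- novelty_filter(g, cfg)
  # depth(Pharmaceutical Preparations) = 1 < 2 -> generic;
  # Dopamine Agonists and Parkinson Disease sit at depth 2 -> kept
  expect_equal(nrow(out$graph$predications), 1)
  expect_equal(out$graph$predications$subject_id, "Dopamine Agonists")
})

test_that("the centrality filter keeps arcs between two high-degree nodes", {
  # two adjacent hubs connected to every leaf: only the hub-hub arc has both
  # endpoints above the mean + sd/2 cutoff
  n <- 6
  adj <- matrix(0L, n, n, dimnames = list(sprintf("v%02d", 1:n),
                                          sprintf("v%02d", 1:n)))
  adj[1, 2:n] <- adj[2:n, 1] <- 1L
  adj[2, 3:n] <- adj[3:n, 2] <- 1L
  g <- build_graph(records_from_adjacency(adj))
  ct <- degree_centrality(g)
  cutoff <- mean(ct) + 0.5 * sqrt(mean((ct - mean(ct))^2))
  expect_setequal(names(ct)[ct > cutoff], c("v01", "v02"))  # fixture sanity

  out <- centrality_filter(g)
  expect_equal(nrow(out$graph$predications), 1)
  expect_setequal(c(out$graph$predications$subject_id,
                    out$graph$predications$object_id), c("v01", "v02"))
  expect_equal(out$report$cutoff, cutoff)
})

test_that("a zero-variance centrality population skips the filter", {
  # In a vertex-transitive graph every centrality is identical; a strict cut
  # would empty the graph, so the filter passes it through with a warning.
  k4 <- build_graph(records_from_adjacency(matrix(1, 4, 4) - diag(4)))
  expect_warning(out <- centrality_filter(k4), "identical centrality")
  expect_equal(nrow(out$graph$predications), nrow(k4$predications))
  expect_match(out$report$note, "zero variance")
})

test_that("the frequency filter drops predications strictly below the cutoff", {
  recs <- make_records(data.frame(
    subject = c("a", "b", "c", "d"), predicate = "AFFECTS",
    object = c("b", "c", "d", "a"), freq = c(1L, 1L, 1L, 9L),
    stringsAsFactors = FALSE
  ))
  out <- frequency_filter(build_graph(recs))
  # mean 3 + 0.5 * sqrt(12) ~ 4.73: only the frequency-9 predication survives
  expect_equal(out$graph$predications$frequency, 9)
  expect_equal(out$report$cutoff, 3 + 0.5 * sqrt(12))

  eq <- make_records(data.frame(subject = c("a", "b", "c"),
                                predicate = "AFFECTS",
                                object = c("b", "c", "a"), freq = 4L,
                                stringsAsFactors = FALSE))
  out2 <- frequency_filter(build_graph(eq))
  expect_equal(nrow(out2$graph$predications), 3)  # equality survives

  single <- build_graph(make_records(data.frame(subject = "a",
                                                predicate = "TREATS",
                                                object = "b",
                                                stringsAsFactors = FALSE)))
  expect_warning(out3 <- frequency_filter(single), "single predication")
  expect_equal(nrow(out3$graph$predications), 1)
})

test_that("every filter returns a subgraph of its input", {
  set.seed(202)
  cfg <- default_group_config()
  for (rep in 1:100) {
    adj <- random_adjacency(sample(5:9, 1), runif(1, 0.3, 0.8))
    if (sum(adj) == 0) next
    recs <- records_from_adjacency(adj, freq = sample(1:6, 1))
    g <- build_graph(recs)
    cfg$generic_concepts <- sample(rownames(adj), sample(0:2, 1))
    for (res in list(novelty_filter(g, cfg),
                     suppressWarnings(centrality_filter(g)),
                     suppressWarnings(frequency_filter(g)))) {
      expect_true(all(res$graph$nodes$id %in% g$nodes$id))
      key <- function(gr) paste(gr$predications$subject_id,
                                gr$predications$predicate,
                                gr$predications$object_id)
      expect_true(all(key(res$graph) %in% key(g)))
      expect_lte(res$report$predications_after, res$report$predications_before)
      expect_lte(res$report$nodes_after, res$report$nodes_before)
    }
  }
})

test_that("the condensation pipeline is deterministic", {
  gen <- generate_corpus(synthetic_config(n_themes = 2, noise_predications = 10,
                                          seed = 11))
  g <- build_graph(gen$records)
  r1 <- suppressWarnings(condense_graph(g, gen$group_config))
  r2 <- suppressWarnings(condense_graph(g, gen$group_config))
  expect_identical(r1$reports, r2$reports)
  expect_identical(r1$graph, r2$graph)
})

test_that("condensation keeps planted cores and sheds noise", {
  gen <- generate_corpus(synthetic_config(n_themes = 3, noise_predications = 30,
                                          generic_noise_fraction = 0.3,
                                          seed = 21))
  g <- build_graph(gen$records)
  out <- suppressWarnings(condense_graph(g, gen$group_config))
  key <- paste(out$graph$predications$subject_id,
               out$graph$predications$predicate,
               out$graph$predications$object_id)
  expect_length(intersect(key, gen$truth$noise_keys), 0)
  core <- g$predications$frequency >= 15  # planted core tier
  core_key <- paste(g$predications$subject_id[core],
                    g$predications$predicate[core],
                    g$predications$object_id[core])
  expect_true(all(core_key %in% key))
})
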