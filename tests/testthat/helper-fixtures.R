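# Shared fixtures and independent oracles for the test suite.

# Build occurrence records from a compact spec: one row per occurrence.
# `triples` is a data frame with columns subject, predicate, object and
# optionally freq (distinct citations; default 1), subject_semtype,
# object_semtype. Concept ids double as names unless a names map is given.
make_records <- function(triples, semtypes = character(0)) {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  if (is.null(triples$freq)) triples$freq <- 1L
  cite <- 0L
  rows <- lapply(seq_len(nrow(triples)), function(i) {
    tr <- triples[i, ]
    st <- if (!is.null(tr$subject_semtype)) tr$subject_semtype else
      if (tr$subject %in% names(semtypes)) semtypes[[tr$subject]] else "dsyn"
    ot <- if (!is.null(tr$object_semtype)) tr$object_semtype else
      if (tr$object %in% names(semtypes)) semtypes[[tr$object]] else "dsyn"
    ids <- sprintf("CITE%05d", cite + seq_len(tr$freq))
    cite <<- cite + tr$freq
    data.frame(citation_id = ids, sentence_id = "s1",
               subject_id = tr$subject, subject_name = tr$subject,
               subject_semtype = st,
               predicate = tr$predicate,
               object_id = tr$object, object_name = tr$object,
               object_semtype = ot,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# A small Parkinson-disease-style corpus: 9 distinct predications over 8
# concepts, frequencies next to them, with one concept pair (Parkinson
# Disease / Movement Disorders) carrying two predicates on a single arc.
parkinson_records <- function() {
  semtypes <- c("Parkinson Disease" = "dsyn", "Movement Disorders" = "dsyn",
                "Deep Brain Stimulation" = "topp", "Dopamine Agonists" = "phsu",
                "Levodopa" = "phsu", "Dyskinetic syndrome" = "dsyn",
                "Subthalamic Nucleus" = "bpoc", "Pallidotomy" = "topp")
  make_records(data.frame(
    subject = c("Parkinson Disease", "Parkinson Disease",
                "Deep Brain Stimulation", "Dopamine Agonists", "Levodopa",
                "Dyskinetic syndrome", "Subthalamic Nucleus", "Pallidotomy",
                "Levodopa"),
    predicate = c("ISA", "COEXISTS_WITH", "TREATS", "TREATS", "TREATS",
                  "COEXISTS_WITH", "LOCATION_OF", "TREATS", "CAUSES"),
    object = c("Movement Disorders", "Movement Disorders",
               "Parkinson Disease", "Parkinson Disease", "Parkinson Disease",
               "Parkinson Disease", "Deep Brain Stimulation",
               "Parkinson Disease", "Dyskinetic syndrome"),
    freq = c(3L, 2L, 10L, 6L, 5L, 2L, 3L, 2L, 2L),
    stringsAsFactors = FALSE
  ), semtypes)
}

# Records for an arbitrary undirected simple graph given by an adjacency
# matrix (nodes named by its dimnames or v01..).
records_from_adjacency <- function(adj, freq = 1L) {
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_len(n))
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  stopifnot(nrow(edges) > 0)
  make_records(data.frame(subject = ids[edges[, 1]], predicate = "AFFECTS",
                          object = ids[edges[, 2]], freq = freq,
                          stringsAsFactors = FALSE))
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  rownames(adj) <- colnames(adj) <- sprintf("v%02d", seq_len(n))
  adj
}

# Independent oracle: maximal cliques by exhaustive subset enumeration.
# Returns a sorted list of sorted member-id vectors of size >= min_size.
brute_force_maximal_cliques <- function(adj, min_size = 2) {
  n <- nrow(adj)
  ids <- rownames(adj)
  complete_sets <- list()
  for (k in seq_len(n)) {
    sets <- utils::combn(n, k, simplify = FALSE)
    for (s in sets) {
      if (k == 1 || all(adj[s, s][upper.tri(matrix(0, k, k))] > 0)) {
        complete_sets[[length(complete_sets) + 1]] <- s
      }
    }
  }
  maximal <- Filter(function(s) {
    !any(vapply(complete_sets, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, logical(1)))
  }, complete_sets)
  maximal <- Filter(function(s) length(s) >= min_size, maximal)
  out <- lapply(maximal, function(s) sort(ids[s]))
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# Canonical form of a clique_set for comparison with the oracle.
clique_member_sets <- function(cliques) {
  out <- lapply(cliques, `[[`, "members")
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# Independent oracle: average silhouette coefficient, written as plain
# nested loops over an assignment vector.
oracle_asc <- function(D, assignment) {
  n <- nrow(D)
  total <- 0
  for (i in seq_len(n)) {
    mine <- which(assignment == assignment[i])
    if (length(mine) == 1) next  # singleton: s = 0
    a <- sum(D[i, setdiff(mine, i)]) / (length(mine) - 1)
    b <- Inf
    for (cl in setdiff(unique(assignment), assignment[i])) {
      members <- which(assignment == cl)
      b <- min(b, sum(D[i, members]) / length(members))
    }
    s <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    total <- total + s
  }
  total / n
}

partition_to_assignment <- function(partition, k) {
  assignment <- integer(k)
  for (ci in seq_along(partition)) assignment[partition[[ci]]] <- ci
  assignment
}

# Hand-built solution set mirroring the icicle walk used for optimal-solution
# selection: nine cliques; Drug treatment = {1,2}, Etiology = {3,4},
# Substance interaction = {5,6}, Body location = {7,8,9}. The walk starts at
# row 3 (three singletons), advances through the two Body-location merges
# (rows 4 and 5) and stops at row 6 where differently-labeled clusters merge.
icicle_walk_fixture <- function() {
  sol <- list(
    lapply(1:9, identity),                                             # row 1
    list(c(1L, 2L), 3L, 4L, c(5L, 6L), 7L, 8L, 9L),                    # row 2
    list(c(1L, 2L), c(3L, 4L), c(5L, 6L), 7L, 8L, 9L),                 # row 3
    list(c(1L, 2L), c(3L, 4L), c(5L, 6L), 7L, c(8L, 9L)),              # row 4
    list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L, 9L)),              # row 5
    list(c(1L, 2L, 3L, 4L), c(5L, 6L), c(7L, 8L, 9L)),                 # row 6
    list(1:9)                                                          # row 7
  )
  base <- c("Drug treatment", "Drug treatment", "Etiology", "Etiology",
            "Substance interaction", "Substance interaction",
            "Body location", "Body location", "Body location")
  labels <- lapply(sol, function(part) {
    vapply(part, function(cl) base[cl[1]], character(1))
  })
  solutions <- structure(list(solutions = sol,
                              heights = c(NA, 6, 5, 4, 3, 2, 1),
                              merge_events = list()),
                         class = "solution_set")
  list(solutions = solutions, labels = labels)
}

# Hand-built eight-cluster tree for the dynamic cut: clusters 1,2 share one
# theme, 3,4 another, 7,8 a third shared with 5; cluster 6 differs. The tree
# merges 1-2, 3-4 and 7-8 below events whose participants carry different
# labels, so the dynamic cut applies exactly those three merges.
dynamic_cut_fixture <- function() {
  base <- c("Substance interaction", "Substance interaction",
            "Body location", "Body location",
            "Etiology", "Drug treatment", "Etiology", "Etiology")
  labeller <- function(members) {
    ls <- unique(base[members])
    if (length(ls) == 1) ls else NA_character_
  }
  events <- list(
    list(step = 1, height = 6, children = list(1L, 2L), parent = c(1L, 2L)),
    list(step = 2, height = 5, children = list(3L, 4L), parent = c(3L, 4L)),
    list(step = 3, height = 4, children = list(5L, 6L), parent = c(5L, 6L)),
    list(step = 4, height = 3, children = list(7L, 8L), parent = c(7L, 8L)),
    list(step = 5, height = 2,
         children = list(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
         parent = 1:6),
    list(step = 6, height = 1, children = list(1:6, c(7L, 8L)), parent = 1:8)
  )
  solutions <- structure(list(
    solutions = list(lapply(1:8, identity)),  # only the starting row is used
    heights = NA_real_,
    merge_events = events
  ), class = "solution_set")
  list(solutions = solutions, labeller = labeller, base = base)
}

# Minimal cluster_label objects realizing prescribed validity counts: one
# focal cluster with x matching / y non-matching predications and a second
# cluster holding z distinct predications matching the focal label.
validity_fixture <- function(x, y, z) {
  focal <- structure(list(
    cluster = 1L,
    pred_idx = seq_len(x + y),
    assignments = c(rep("L", x), rep("M", y)),
    counts = NULL, label = "L"
  ), class = "cluster_label")
  other <- structure(list(
    cluster = 2L,
    pred_idx = x + y + seq_len(z + 1),
    assignments = c(rep("L", z), "M"),
    counts = NULL, label = "M"
  ), class = "cluster_label")
  list(focal, other)
}
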