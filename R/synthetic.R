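#' Theme templates for the synthetic generator
#'
#' Five homogeneous theme blueprints, one per metapredication family whose
#' triples close over a single semantic group, so that every predication
#' generated inside a theme maps to that theme's family. Each template names
#' the expected label, a pool of argument semantic types and a pool of
#' predicates drawn from the bundled configuration.
#'
#' @return List of templates (`label`, `prefix`, `semtypes`, `predicates`).
#' @export
theme_templates <- function() {
  list(
    list(label = "Substance interaction", prefix = "Substance",
         semtypes = c("phsu", "orch", "aapp"),
         predicates = c("INTERACTS_WITH", "INHIBITS", "STIMULATES")),
    list(label = "Body location", prefix = "Anatomy",
         semtypes = c("bpoc", "tisu", "blor"),
         predicates = c("PART_OF", "LOCATION_OF")),
    list(label = "Disease comorbidities", prefix = "Disorder",
         semtypes = c("dsyn", "mobd"),
         predicates = c("COEXISTS_WITH")),
    list(label = "Etiology", prefix = "Condition",
         semtypes = c("dsyn", "neop"),
         predicates = c("CAUSES", "PREDISPOSES", "ASSOCIATED_WITH")),
    list(label = "Affect", prefix = "Process",
         semtypes = c("dsyn", "patf"),
         predicates = c("AFFECTS"))
  )
}

#' Configuration for a synthetic predication corpus
#'
#' Each planted theme is a near-complete subgraph over `concepts_per_theme`
#' concepts built around two overlapping high-frequency concept cores (sizes
#' `ceiling((m+1)/2)` and `m - ceiling((m+1)/2) + 1`, sharing one hub
#' concept): core concept pairs always carry a predication repeated in
#' `core_frequency` citations, while the remaining within-theme pairs are
#' included with probability `intra_theme_density` at low citation frequency.
#' This two-tier frequency profile emulates the heavy skew of real
#' predication corpora — a few heavily repeated relations against many
#' asserted once — and the two cores make hub concepts members of several
#' cliques. Noise predications connect a separate pool of low-degree noise
#' concepts; a fraction of them use a generic concept as one argument.
#'
#' @param n_themes Number of planted themes (1 to 5; each uses a distinct
#'   template from [theme_templates()]).
#' @param concepts_per_theme Concepts per theme (at least 5).
#' @param intra_theme_density Inclusion probability of non-core within-theme
#'   pairs, in (0, 1].
#' @param bridge_concepts Number of concepts shared between adjacent themes
#'   (each bridge concept is also connected to the next theme's first core).
#' @param core_frequency Citation frequency of core predications.
#' @param periphery_frequency_mean Mean citation frequency of non-core
#'   within-theme predications (>= 1).
#' @param noise_predications Number of noise predications.
#' @param noise_concepts Size of the noise concept pool (default scales with
#'   `noise_predications`).
#' @param generic_noise_fraction Fraction of noise predications with a
#'   generic argument, in \[0, 1\].
#' @param seed Mandatory integer seed.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_themes = 3, concepts_per_theme = 6,
                             intra_theme_density = 1.0, bridge_concepts = 0,
                             core_frequency = 15,
                             periphery_frequency_mean = 1.2,
                             noise_predications = 0, noise_concepts = NULL,
                             generic_noise_fraction = 0.2, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_themes < 1 || n_themes > length(theme_templates())) {
    stop("n_themes must be between 1 and ", length(theme_templates()))
  }
  if (concepts_per_theme < 5) stop("concepts_per_theme must be at least 5")
  if (intra_theme_density <= 0 || intra_theme_density > 1) {
    stop("intra_theme_density must be in (0, 1]")
  }
  if (generic_noise_fraction < 0 || generic_noise_fraction > 1) {
    stop("generic_noise_fraction must be in [0, 1]")
  }
  if (core_frequency < 2) stop("core_frequency must be at least 2")
  if (periphery_frequency_mean < 1) stop("periphery_frequency_mean must be >= 1")
  if (is.null(noise_concepts)) {
    # roughly one background concept per noise assertion: the sparse long
    # tail of rarely mentioned concepts outnumbers the connected cores
    noise_concepts <- max(10, noise_predications)
  }
  structure(list(n_themes = as.integer(n_themes),
                 concepts_per_theme = as.integer(concepts_per_theme),
                 intra_theme_density = intra_theme_density,
                 bridge_concepts = as.integer(bridge_concepts),
                 core_frequency = as.integer(core_frequency),
                 periphery_frequency_mean = periphery_frequency_mean,
                 noise_predications = as.integer(noise_predications),
                 noise_concepts = as.integer(noise_concepts),
                 generic_noise_fraction = generic_noise_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

random_tag <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, 5, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic predication corpus with planted themes
#'
#' Deterministic given the config's seed: the same config yields the same
#' corpus, and two seeds yield corpora with different concept names but
#' identical structural statistics.
#'
#' @param config A `synthetic_config`.
#' @return List with `records` (predication occurrence data frame), `truth`
#'   (`theme_of` concept-to-theme map, `expected_labels`, `noise_concepts`,
#'   `noise_keys`) and `group_config` (the bundled configuration with the
#'   generated generic concepts installed).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  templates <- theme_templates()[seq_len(config$n_themes)]
  m <- config$concepts_per_theme

  rows <- list()
  citation_counter <- 0L
  theme_of <- character(0)
  concept_sem <- character(0)
  concept_name <- character(0)

  emit <- function(subj, obj, predicate, freq) {
    cites <- sprintf("PMID%06d", citation_counter + seq_len(freq))
    citation_counter <<- citation_counter + freq
    data.frame(citation_id = cites, sentence_id = "s1",
               subject_id = subj, subject_name = concept_name[[subj]],
               subject_semtype = concept_sem[[subj]],
               predicate = predicate,
               object_id = obj, object_name = concept_name[[obj]],
               object_semtype = concept_sem[[obj]],
               stringsAsFactors = FALSE)
  }

  theme_concepts <- list()
  for (t in seq_len(config$n_themes)) {
    tpl <- templates[[t]]
    ids <- sprintf("T%dC%02d", t, seq_len(m))
    tags <- random_tag(m)
    names_t <- paste0(tpl$prefix, " ", tags)
    sem_t <- sample(tpl$semtypes, m, replace = TRUE)
    concept_name[ids] <- names_t
    concept_sem[ids] <- sem_t
    theme_of[ids] <- as.character(t)
    theme_concepts[[t]] <- ids

    a <- ceiling((m + 1) / 2)
    core_a <- ids[seq_len(a)]
    core_b <- ids[a:m]
    core_pairs <- unique(rbind(pair_matrix(core_a), pair_matrix(core_b)))
    all_pairs <- pair_matrix(ids)
    key_all <- paste(all_pairs[, 1], all_pairs[, 2])
    key_core <- paste(core_pairs[, 1], core_pairs[, 2])
    periph <- all_pairs[!(key_all %in% key_core), , drop = FALSE]
    keep <- stats::runif(nrow(periph)) <= config$intra_theme_density
    periph <- periph[keep, , drop = FALSE]

    for (r in seq_len(nrow(core_pairs))) {
      ends <- sample(core_pairs[r, ])
      rows[[length(rows) + 1]] <- emit(ends[1], ends[2],
                                       sample(tpl$predicates, 1),
                                       config$core_frequency)
    }
    for (r in seq_len(nrow(periph))) {
      ends <- sample(periph[r, ])
      freq <- 1L + stats::rpois(1, config$periphery_frequency_mean - 1)
      rows[[length(rows) + 1]] <- emit(ends[1], ends[2],
                                       sample(tpl$predicates, 1), freq)
    }
  }

  # Bridge concepts: link the first bridge_concepts concepts of theme t to
  # the first core of theme t+1 at core frequency (exercises clique overlap
  # across themes).
  if (config$bridge_concepts > 0 && config$n_themes > 1) {
    for (t in seq_len(config$n_themes - 1)) {
      tpl <- templates[[t]]
      from <- theme_concepts[[t]][seq_len(min(config$bridge_concepts, m))]
      a <- ceiling((m + 1) / 2)
      to <- theme_concepts[[t + 1]][seq_len(a)]
      for (b in from) {
        for (o in to) {
          rows[[length(rows) + 1]] <- emit(b, o, sample(tpl$predicates, 1),
                                           config$core_frequency)
        }
      }
    }
  }

  # Noise pool plus generic concepts.
  noise_ids <- character(0)
  generic_ids <- character(0)
  noise_keys <- character(0)
  if (config$noise_predications > 0) {
    noise_ids <- sprintf("N%03d", seq_len(config$noise_concepts))
    all_sem <- unlist(lapply(theme_templates(), `[[`, "semtypes"))
    concept_name[noise_ids] <- paste("Background", random_tag(length(noise_ids)))
    concept_sem[noise_ids] <- sample(all_sem, length(noise_ids), replace = TRUE)
    generic_ids <- sprintf("G%02d", 1:3)
    concept_name[generic_ids] <- paste("Generic entity", 1:3)
    concept_sem[generic_ids] <- sample(all_sem, 3, replace = TRUE)

    n_generic <- round(config$generic_noise_fraction * config$noise_predications)
    all_predicates <- unique(unlist(lapply(theme_templates(), `[[`, "predicates")))
    for (i in seq_len(config$noise_predications)) {
      if (i <= n_generic) {
        ends <- c(sample(generic_ids, 1), sample(noise_ids, 1))
      } else {
        ends <- sample(noise_ids, 2)
      }
      ends <- sample(ends)
      predicate <- sample(all_predicates, 1)
      freq <- 1L + stats::rpois(1, 0.3)
      noise_keys <- c(noise_keys, paste(ends[1], predicate, ends[2]))
      rows[[length(rows) + 1]] <- emit(ends[1], ends[2], predicate, freq)
    }
  }

  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  class(records) <- c("predication_records", class(records))

  group_config <- default_group_config()
  group_config$generic_concepts <- generic_ids

  truth <- list(
    n_themes = config$n_themes,
    theme_of = theme_of,
    expected_labels = stats::setNames(
      vapply(templates, `[[`, character(1), "label"),
      seq_len(config$n_themes)),
    theme_concepts = theme_concepts,
    noise_concepts = noise_ids,
    generic_concepts = generic_ids,
    noise_keys = unique(noise_keys)
  )
  list(records = records, truth = truth, group_config = group_config)
}

pair_matrix <- function(ids) {
  if (length(ids) < 2) return(matrix(character(0), ncol = 2))
  t(utils::combn(ids, 2))
}

#' Score how well a summary recovers the planted themes
#'
#' Concepts are assigned to the output cluster holding them in the most
#' cliques (ties toward the lowest cluster index); agreement with the planted
#' concept partition is measured with the adjusted Rand index. Each output
#' cluster is mapped to its dominant planted theme by concept majority, and
#' label accuracy is the fraction of clusters whose theme label equals that
#' theme's expected label.
#'
#' @param summary A `clique_summary` from [summarize_corpus()].
#' @param truth The `truth` element of [generate_corpus()]'s result.
#' @return List with `theme_count_match`, `n_clusters`, `ari`,
#'   `label_accuracy`.
#' @export
score_recovery <- function(summary, truth) {
  stopifnot(inherits(summary, "clique_summary"))
  clusters <- summary$clusters
  if (length(clusters) == 0) {
    return(list(theme_count_match = FALSE, n_clusters = 0L,
                ari = NA_real_, label_accuracy = NA_real_))
  }
  members <- clique_members(summary$cliques)
  # concept -> cluster by majority clique membership
  concept_votes <- list()
  for (ci in seq_along(clusters)) {
    for (q in clusters[[ci]]$cliques) {
      for (concept in members[[q]]) {
        concept_votes[[concept]] <- c(concept_votes[[concept]], ci)
      }
    }
  }
  assigned <- vapply(concept_votes, function(v) {
    tab <- table(v)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))

  common <- intersect(names(assigned), names(truth$theme_of))
  ari <- if (length(common) >= 2) {
    mclust::adjustedRandIndex(assigned[common], truth$theme_of[common])
  } else {
    NA_real_
  }

  label_ok <- vapply(seq_along(clusters), function(ci) {
    ids <- names(assigned)[assigned == ci]
    ids <- intersect(ids, names(truth$theme_of))
    if (length(ids) == 0) return(NA)
    dominant <- names(which.max(table(truth$theme_of[ids])))
    isTRUE(clusters[[ci]]$label == truth$expected_labels[[dominant]])
  }, logical(1))

  list(theme_count_match = length(clusters) == truth$n_themes,
       n_clusters = length(clusters),
       ari = ari,
       label_accuracy = mean(label_ok, na.rm = TRUE))
}
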