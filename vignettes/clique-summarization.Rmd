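---
title: "Clique-clustering summarization of semantic predication graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clique-clustering summarization of semantic predication graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliquesum)
```

## The problem and the model

A PubMed-scale search returns thousands of citations. Natural-language
systems such as SemRep reduce each citation to *semantic predications* —
subject–PREDICATE–object triples whose arguments are controlled-vocabulary
concepts ("Dopamine Agonists TREATS Parkinson Disease"). cliquesum condenses
a corpus of such predications into a small graph summary and partitions that
summary into labeled *themes*, so that a reader can see at a glance which
points of view (drug treatment, etiology, comorbidity, ...) the literature
on a topic contains.

The procedure has two phases.

**Phase 1 — condensation.** Concepts become nodes and predicates arcs; all
predications between one unordered concept pair share a single multi-label
arc, and each predication's *frequency* is the number of distinct citations
asserting it (repeats within a citation count once). Three filters then run
in a fixed order:

1. *Novelty filter*: predications with a generic argument (a concept too
   high in the concept hierarchy to be informative, e.g. "Patients") are
   removed.
2. *Centrality filter*: Freeman degree centrality, degree / (n − 1), is
   recomputed on the filtered graph; only predications whose **both**
   arguments score strictly above the cutoff mean + ½·SD survive.
3. *Frequency filter*: the same cutoff form is applied to the citation
   frequencies of the surviving predications; frequencies strictly below the
   cutoff are removed (equality survives).

The surviving graph is small and dense around salient content. Maximal
cliques (complete subgraphs contained in no larger one, size ≥ 3 by default)
are enumerated in its undirected simple view; cliques may overlap, which is
essential — hub concepts near the topic of the corpus sit in several cliques.

**Phase 2 — theme identification.** The clique co-membership matrix S
(S[i,j] = concepts shared by cliques i and j, diagonal = clique sizes) feeds
a Johnson-style agglomerative clustering on similarity: the most similar
clusters merge first, ties at one height merge simultaneously, and every
distinct merge height emits one cluster solution — the rows of an icicle
plot, from all-singletons down to one cluster. Each cluster is labeled with
its dominant *metapredication*: predicates map to one of seven predicate
groups, argument semantic types to semantic groups, and the resulting
〈group, predicate group, group〉 triple is looked up among eight allowed
metapredication families ("Drug treatment" = 〈Chemicals & Drugs, Therapy,
Disorders〉, ...). The most frequent family over a cluster's distinct
predications is its theme label.

The *optimal solution* is chosen by walking the icicle from the first row
with at most three singleton clusters: while every merge into the next row
combines clusters sharing one non-missing label, the next row is better;
the walk stops at the first label-inconsistent merge. The optional *dynamic
cut* continues along the remaining merge tree, applying only label-consistent
events and skipping the rest, which cuts different branches at different
heights.

**Scoring.** With x = in-cluster predications matching the cluster label,
y = in-cluster non-matching, and z = matching predications held only by
other clusters:

- cohesion = x / (x + y),
- separation = x / (x + z),
- overall validity = their harmonic mean.

The reference partition for comparison is the solution maximizing the
average silhouette coefficient (ASC) on the max-shift distance
d = max(S off-diagonal) − S. A second, label-quality evaluation compares
each cluster's concepts against the top-k major MeSH descriptors (k = number
of cluster concepts) of the citations behind the cluster, with qualifier
stripping and table-driven synonym matching, reporting recall, precision
and F.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sd_multiplier` | 0.5 | both condensation cutoffs are mean + `sd_multiplier`·SD; larger keeps less |
| `min_clique_size` | 3 | smallest reported clique; 3 is the smallest clique in the social-network sense, 2 admits dyads |
| `linkage` | average | between-cluster similarity aggregation (single/complete available) |
| `max_singletons` | 3 | most singletons tolerated in the starting icicle row |
| `selection_mode` | conservative | advance only if *all* merges in a step are label-consistent; permissive requires one |
| `dynamic_cut` | FALSE | branch-wise merging of same-theme clusters after selection |
| `generic_depth` | none | with a concept hierarchy, depth below which concepts are generic |

## Numerical and design choices

- **Population SD.** The cutoff uses the population standard deviation: the
  node and predication sets are complete populations, not samples.
- **Strict vs. inclusive cuts.** Centrality keeps strictly above the cutoff
  ("above ... are kept"); frequency removes strictly below it ("below ...
  eliminated"), so equality survives. The asymmetry is intentional.
- **Zero-variance centrality populations.** When every node has the same
  centrality the strict rule would empty the graph on a degenerate
  population carrying no ranking information; the filter instead passes the
  graph through with a warning. The frequency filter needs no such special
  case: with equal frequencies nothing falls strictly below the cutoff. A
  single remaining value (one predication) also skips its cutoff.
- **Emptying is a warning, not an error.** A graph that empties mid-pipeline
  short-circuits the remaining stages and yields an empty summary.
- **Degree is multiplicity-free.** Several predicates or directions between
  one concept pair contribute one arc to each endpoint's degree, matching
  the single-arc graphical representation; direction is per-predication
  metadata and cliques are undirected objects.
- **Tie handling in clustering.** Equal-similarity merges at one height are
  applied simultaneously (chains of ties collapse into one multi-way merge),
  so heights strictly decrease and every row of the icicle is a distinct
  solution. Comparisons are at tolerance 1e-9.
- **Silhouette conventions.** Cliques in singleton clusters score 0
  (Kaufman–Rousseeuw); an all-zero distance pair scores 0 rather than 0/0;
  ASC ties resolve toward fewer clusters, the more summary-like solution.
- **Label ties.** Equal family counts resolve by higher summed citation
  frequency, then by configuration (table) order; counting is over distinct
  predications, with frequency only as tie-breaker.
- **Family-level labels.** A metapredication is a named family of triples
  (the configuration lists several triples under one display name), so
  labeling and validity matching operate on family names.
- **Starting-row scan.** The all-singleton row is not a candidate starting
  row (it summarizes nothing); when no row has few enough singletons the
  walk starts at the coarsest row. An argument with several semantic types
  tries them in stored order, subject-major, and the first allowed
  combination wins.
- **Maximal cliques** are enumerated by igraph; the package contributes the
  deterministic ordering contract (descending size, then lexicographic
  member lists) and everything downstream of the clique set.

## The synthetic generator

Real predication corpora require a literature pipeline; the generator
(`synthetic_config()` / `generate_corpus()`) instead plants known themes so
that every stage is testable offline. Its defaults define the study
conditions and are chosen to emulate three robust features of real corpora:

- **Two-tier citation frequencies.** A few relations are asserted in many
  citations while most appear once or twice. Each theme therefore has two
  overlapping concept *cores* (sizes ⌈(m+1)/2⌉ and m − ⌈(m+1)/2⌉ + 1,
  sharing one hub concept) whose pairs carry a constant high frequency
  (default 15), against periphery and noise frequencies near 1. The
  mean + ½·SD frequency cutoff then separates the tiers cleanly.
- **Overlapping cliques.** The two cores per theme survive condensation as
  two maximal cliques sharing the hub, exercising the co-membership
  clustering the way hub concepts do in real summaries.
- **A sparse low-degree background.** Noise predications connect a separate
  pool of background concepts (by default one per noise assertion), so the
  degree distribution shows the realistic pattern of a small highly
  connected core against a long tail of rarely mentioned concepts — the
  regime the centrality filter is designed for. A configurable fraction of
  noise uses generic arguments to exercise the novelty filter.

Theme templates are the five metapredication families whose triples close
over one semantic group (Substance interaction, Body location, Disease
comorbidities, Etiology, Affect), so every within-theme predication maps to
the planted label and ground truth is exact.

What the generator does **not** emulate: word-sense-disambiguation errors in
concept mapping, mixed-group themes whose predications straddle several
families, correlated citation structure (every citation asserts one
predication), and corpus-scale class imbalance. Passing the planted-recovery
tests therefore shows the machinery is correct under clean conditions, not
that real corpora will score as well; on real data both validity and
labeling quality are far below 1.

## Problem sizes in the shipped tests

The test-suite batches are sized for quick, repeated runs: 200 random graphs
of up to 12 nodes against the exhaustive clique oracle, 100 random graphs
for filter monotonicity, 1,000 random (x, y, z) triples for the validity
algebra, 30 small clique sets (3–6 cliques) against the brute-force
silhouette oracle, and 20 seeds each of the zero-noise (2–5 themes, 6
concepts per theme, density 1) and 30%-noise planted-recovery conditions.
`scripts/acceptance.R` reruns the two 20-seed recovery batches from scratch.

## Known limitations

- Clustering uses only shared concepts between cliques; predicate similarity
  does not contribute to the proximity matrix.
- The conservative advance rule makes solution selection sensitive to a
  single label-inconsistent merge event high in the tree; the dynamic cut
  mitigates but does not remove this.
- Validity treats unmapped predications as non-matching (they lower
  cohesion); corpora dominated by predicates outside the seven groups will
  score poorly however clean their structure.
- The MeSH evaluation depends entirely on user-supplied descriptor and
  synonym tables; without synonymy, name mismatches depress recall and
  precision.
```{r example, eval = FALSE}
gen <- generate_corpus(synthetic_config(n_themes = 3, seed = 42))
s <- summarize_corpus(gen$records, gen$group_config)
print(s)
evaluate_summary(s, truth = gen$truth)$system_validity
```
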