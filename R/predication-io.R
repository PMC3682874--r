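# Required columns of a predication TSV, modeled on the SemMedDB PREDICATION
# table (one row per predication occurrence in one sentence of one citation).
predication_columns <- c(
  "citation_id", "sentence_id",
  "subject_id", "subject_name", "subject_semtype",
  "predicate",
  "object_id", "object_name", "object_semtype"
)

#' Default SemRep predicate vocabulary
#'
#' The predicates of the seven predicate groups in the bundled configuration
#' plus additional core SemRep predicates that occur in predication corpora
#' but do not participate in any metapredication (and therefore never label a
#' theme).
#'
#' @return Character vector of uppercase predicate names.
#' @export
semrep_predicates <- function() {
  cfg <- default_group_config()
  sort(unique(c(
    names(cfg$predicate_to_pgroup),
    c("ADMINISTERED_TO", "CONVERTS_TO", "ISA", "MANIFESTATION_OF",
      "METHOD_OF", "OCCURS_IN", "PRECEDES", "PROCESS_OF", "PRODUCES")
  )))
}

#' Read a predication corpus from a tab-separated file
#'
#' Reads a 9-column TSV of predication occurrences. Rows with an empty
#' citation id, subject id, object id or predicate are counted as malformed
#' and skipped; self-predications (subject id equal to object id) are dropped
#' with a warning, since all downstream graph constructs (degree centrality,
#' cliques) are defined on simple graphs. Duplicate occurrence rows are
#' retained: frequency counting deduplicates per citation later.
#'
#' @param path Path to the TSV file. A header row must name the nine columns
#'   `citation_id, sentence_id, subject_id, subject_name, subject_semtype,
#'   predicate, object_id, object_name, object_semtype`.
#' @param vocabulary Character vector of known predicates; predicates outside
#'   it are kept but flagged in the `predicate_known` column.
#' @return A data frame of predication occurrence records (class
#'   `predication_records`), with attributes `n_malformed` and `n_self`
#'   giving the skipped-row counts.
#' @export
read_predications <- function(path, vocabulary = semrep_predicates()) {
  if (!file.exists(path)) stop("predication file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, fill = TRUE,
                          check.names = FALSE)
  missing_cols <- setdiff(predication_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("predication file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[predication_columns]
  if (nrow(df) == 0) stop("predication file contains no records: ", path)

  required <- c("citation_id", "subject_id", "object_id", "predicate")
  ok <- Reduce(`&`, lapply(df[required], function(x) !is.na(x) & nzchar(x)))
  n_malformed <- sum(!ok)
  df <- df[ok, , drop = FALSE]

  self <- df$subject_id == df$object_id
  n_self <- sum(self)
  if (n_self > 0) {
    warning(n_self, " self-predication(s) (subject_id == object_id) dropped")
    df <- df[!self, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no valid predication records after filtering: ", path)

  df$predicate <- toupper(df$predicate)
  df$predicate_known <- df$predicate %in% vocabulary
  rownames(df) <- NULL
  attr(df, "n_malformed") <- n_malformed
  attr(df, "n_self") <- n_self
  class(df) <- c("predication_records", class(df))
  df
}

#' Write a predication corpus to a tab-separated file
#'
#' @param records A data frame of predication occurrence records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predications <- function(records, path) {
  utils::write.table(as.data.frame(records)[predication_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a grouping configuration
#'
#' A grouping configuration supplies the semantic-type to semantic-group map,
#' the predicate to predicate-group map, the allowed metapredication families
#' (each a display name plus one or more
#' `<semantic group, predicate group, semantic group>` triples), the set of
#' generic concept identifiers, and optionally a concept hierarchy
#' (child/parent pairs) with a depth threshold below which concepts count as
#' generic.
#'
#' @param path Path to a YAML (or JSON) configuration file declaring
#'   `semantic_groups`, `predicate_groups`, `metapredications`, and
#'   `generic_concepts` (plus optional `hierarchy` and `generic_depth`).
#' @return A validated `group_config` object.
#' @seealso [default_group_config()] for the bundled configuration.
#' @export
read_group_config <- function(path) {
  if (!file.exists(path)) stop("group config file not found: ", path)
  raw <- yaml::read_yaml(path)
  as_group_config(raw, source = path)
}

#' Bundled default grouping configuration
#'
#' Loads the configuration shipped with the package: the seven predicate
#' groups, the eight metapredication families, and a semantic-type map
#' covering the UMLS semantic types routinely produced as SemRep predication
#' arguments.
#'
#' @return A `group_config` object.
#' @export
default_group_config <- function() {
  path <- system.file("extdata", "default_groups.yaml", package = "cliquesum")
  read_group_config(path)
}

# Validate a raw configuration list into a group_config object.
as_group_config <- function(raw, source = "<config>") {
  for (field in c("semantic_groups", "predicate_groups", "metapredications")) {
    if (is.null(raw[[field]])) {
      stop("group config ", source, " is missing required table: ", field)
    }
  }
  semtype_to_group <- vapply(raw$semantic_groups, as.character, character(1))
  predicate_to_pgroup <- vapply(raw$predicate_groups, as.character, character(1))
  names(predicate_to_pgroup) <- toupper(names(predicate_to_pgroup))

  declared_groups <- unique(unname(semtype_to_group))
  declared_pgroups <- unique(unname(predicate_to_pgroup))

  metas <- lapply(raw$metapredications, function(m) {
    if (is.null(m$name) || is.null(m$triples)) {
      stop("metapredication entries need 'name' and 'triples' fields")
    }
    triples <- lapply(m$triples, function(tr) {
      tr <- as.character(unlist(tr))
      if (length(tr) != 3) stop("metapredication triple must have 3 elements")
      bad_group <- setdiff(tr[c(1, 3)], declared_groups)
      if (length(bad_group) > 0 || !(tr[2] %in% declared_pgroups)) {
        stop("metapredication '", m$name, "' triple <", paste(tr, collapse = ", "),
             "> references undeclared group(s)")
      }
      tr
    })
    list(name = as.character(m$name), triples = triples)
  })
  keys <- unlist(lapply(metas, function(m) {
    vapply(m$triples, paste, character(1), collapse = "\r")
  }))
  if (anyDuplicated(keys)) stop("duplicate metapredication triple in config")

  hierarchy <- NULL
  if (length(raw$hierarchy) > 0) {
    hierarchy <- do.call(rbind, lapply(raw$hierarchy, function(p) {
      p <- as.character(unlist(p))
      if (length(p) != 2) stop("hierarchy entries must be (child, parent) pairs")
      p
    }))
    colnames(hierarchy) <- c("child", "parent")
  }
  generic_depth <- raw$generic_depth
  if (!is.null(generic_depth)) generic_depth <- as.integer(generic_depth)

  structure(list(
    semtype_to_group = semtype_to_group,
    predicate_to_pgroup = predicate_to_pgroup,
    metapredications = metas,
    generic_concepts = as.character(unlist(raw$generic_concepts)),
    hierarchy = hierarchy,
    generic_depth = generic_depth
  ), class = "group_config")
}

#' @export
print.group_config <- function(x, ...) {
  cat("Grouping configuration\n")
  cat("  semantic types mapped: ", length(x$semtype_to_group),
      " into ", length(unique(x$semtype_to_group)), " groups\n", sep = "")
  cat("  predicates mapped:     ", length(x$predicate_to_pgroup),
      " into ", length(unique(x$predicate_to_pgroup)), " groups\n", sep = "")
  cat("  metapredication families: ", length(x$metapredications), "\n", sep = "")
  cat("  generic concepts:      ", length(x$generic_concepts), "\n", sep = "")
  invisible(x)
}

#' Write a predication graph in Pajek .net format
#'
#' Nodes are written in lexicographic order of concept name with 1-based ids
#' and quoted labels; each unordered concept pair becomes a single `*Edges`
#' line (multiple predicates between a pair collapse onto one arc) whose
#' weight is the summed citation frequency of the arc's predications.
#'
#' @param graph A `predication_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(graph, path) {
  stopifnot(inherits(graph, "predication_graph"))
  if (nrow(graph$nodes) == 0) stop("cannot write an empty graph")
  nodes <- graph$nodes[order(graph$nodes$name, graph$nodes$id), , drop = FALSE]
  idx <- seq_len(nrow(nodes))
  names(idx) <- nodes$id

  lines <- c(sprintf("*Vertices %d", nrow(nodes)),
             sprintf("%d \"%s\"", idx, nodes$name),
             "*Edges")
  preds <- graph$predications
  if (nrow(preds) > 0) {
    i <- idx[preds$subject_id]
    j <- idx[preds$object_id]
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    w <- tapply(preds$frequency, paste(lo, hi), sum)
    pair <- do.call(rbind, strsplit(names(w), " "))
    ord <- order(as.integer(pair[, 1]), as.integer(pair[, 2]))
    lines <- c(lines, sprintf("%s %s %d", pair[ord, 1], pair[ord, 2],
                              as.integer(w[ord])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a predication graph in GraphML format
#'
#' Secondary export via igraph; arcs carry their summed citation frequency as
#' an edge `weight` attribute and nodes their concept name as `label`.
#'
#' @param graph A `predication_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "predication_graph"))
  if (nrow(graph$nodes) == 0) stop("cannot write an empty graph")
  ig <- as_igraph(graph, weighted = TRUE)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read a citation-to-MeSH-descriptor table
#'
#' Two tab-separated columns: citation id and one major MeSH descriptor per
#' row. Qualifiers (the part after "/") are stripped on load, so e.g.
#' "Antipsychotic Agents/therapeutic use" and "Antipsychotic
#' Agents/administration & dosage" collapse to one descriptor.
#'
#' @param path Path to the TSV file (no header).
#' @return Data frame with columns `citation_id` and `descriptor`.
#' @export
read_mesh_table <- function(path) {
  if (!file.exists(path)) stop("MeSH table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("MeSH table needs 2 columns (citation id, descriptor)")
  out <- data.frame(citation_id = df[[1]],
                    descriptor = strip_qualifier(df[[2]]),
                    stringsAsFactors = FALSE)
  unique(out)
}

strip_qualifier <- function(x) sub("/.*$", "", x)

#' Read a concept-synonym table
#'
#' Two tab-separated columns: concept id and one synonymous descriptor string
#' per row (Metathesaurus synonymy, user-supplied).
#'
#' @param path Path to the TSV file (no header).
#' @return Named list: concept id -> character vector of synonyms.
#' @export
read_synonym_table <- function(path) {
  if (!file.exists(path)) stop("synonym table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("synonym table needs 2 columns (concept id, synonym)")
  split(df[[2]], df[[1]])
}
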