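# Ingest of the six study tables: drugs (with in-cell target and indicated
# disease lists), interaction evidence, target essentiality annotations,
# interaction interfaces, and disease-gene associations.

#' Read a drug table
#'
#' Reads a tab-separated drug table into a validated data frame with one row
#' per drug. The table must carry either a `side_effect_count` column or a
#' `side_effect_list` column (semicolon-separated terms); in the latter case
#' the count is the number of distinct lowercased terms. Targets and
#' indicated diseases are semicolon-separated in-cell lists.
#'
#' @param path path to a TSV file with header columns `drug_id`, `group`,
#'   `side_effect_count` (or `side_effect_list`), `fatal`, `approval_year`,
#'   `targets`, `diseases`, `cancer`.
#' @return a data frame of class `drug_table` with columns `drug_id`,
#'   `group` (factor: nutraceutical/approved/withdrawn/unknown),
#'   `side_effect_count`, `has_fatal_effect`, `approval_year`, `targets`
#'   (list column of character vectors), `indicated_diseases` (list column),
#'   `is_cancer_drug`.
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("drug_id", "group", "fatal", "approval_year",
                        "targets", "diseases", "cancer"), "drug table")
  if (!("side_effect_count" %in% names(df)) &&
      !("side_effect_list" %in% names(df)))
    stop("drug table: missing required column(s): side_effect_count or side_effect_list",
         call. = FALSE)

  if ("side_effect_count" %in% names(df)) {
    cnt <- suppressWarnings(as.numeric(df$side_effect_count))
    bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
    if (length(bad))
      stop(sprintf("drug table: invalid side_effect_count '%s' at row %d",
                   df$side_effect_count[bad[1L]], bad[1L]), call. = FALSE)
    cnt <- as.integer(cnt)
  } else {
    cnt <- vapply(df$side_effect_list, function(s)
      length(unique(tolower(split_list_cell(s)))), integer(1),
      USE.NAMES = FALSE)
  }

  if (anyDuplicated(df$drug_id))
    stop(sprintf("drug table: duplicate drug_id '%s'",
                 df$drug_id[anyDuplicated(df$drug_id)]), call. = FALSE)

  grp <- tolower(trimws(as.character(df$group)))
  grp[!grp %in% c("nutraceutical", "approved", "withdrawn")] <- "unknown"

  out <- data.frame(drug_id = as.character(df$drug_id),
                    side_effect_count = cnt,
                    stringsAsFactors = FALSE)
  out$group <- factor(grp, levels = c("nutraceutical", "approved",
                                      "withdrawn", "unknown"))
  out$has_fatal_effect <- as_flag(df$fatal, "fatal")
  out$approval_year <- suppressWarnings(as.integer(df$approval_year))
  out$targets <- lapply(as.character(df$targets), split_list_cell)
  out$indicated_diseases <- lapply(as.character(df$diseases), split_list_cell)
  out$is_cancer_drug <- as_flag(df$cancer, "cancer")
  class(out) <- c("drug_table", "data.frame")
  out
}

#' Read an interaction-evidence table
#'
#' Reads protein-pair evidence records, canonicalizes each pair to unordered
#' form, drops self-interactions with a warning, and merges duplicate pair
#' lines: boolean flags by OR, publication counts by max (conservative union
#' of evidence).
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `ht_quality`,
#'   `publication_count`, `is_binary`.
#' @return data frame of class `interaction_table`, one row per unordered
#'   pair, `protein_a < protein_b` lexicographically.
#' @export
read_interaction_table <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("protein_a", "protein_b", "ht_quality",
                        "publication_count", "is_binary"),
                  "interaction table")
  canonicalize_interactions(data.frame(
    protein_a = as.character(df$protein_a),
    protein_b = as.character(df$protein_b),
    ht_quality = as_flag(df$ht_quality, "ht_quality"),
    publication_count = as.integer(df$publication_count),
    is_binary = as_flag(df$is_binary, "is_binary"),
    stringsAsFactors = FALSE))
}

#' Canonicalize interaction-evidence records
#'
#' Applies the unordered-pair and duplicate-merge semantics of
#' [read_interaction_table()] to an in-memory record frame.
#'
#' @param df data frame with the interaction-record columns.
#' @return data frame of class `interaction_table`.
#' @export
canonicalize_interactions <- function(df) {
  if (any(df$publication_count < 0, na.rm = TRUE))
    stop("interaction table: negative publication_count", call. = FALSE)
  self <- df$protein_a == df$protein_b
  if (any(self)) {
    warning(sprintf("dropped %d self-interaction record(s)", sum(self)),
            call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  key <- paste(a, b, sep = "\t")
  ord <- order(key)
  df <- df[ord, , drop = FALSE]; a <- a[ord]; b <- b[ord]; key <- key[ord]
  grp <- match(key, unique(key))
  out <- data.frame(
    protein_a = a[!duplicated(grp)],
    protein_b = b[!duplicated(grp)],
    ht_quality = as.logical(tapply(df$ht_quality, grp, any)),
    publication_count = as.integer(tapply(df$publication_count, grp, max)),
    is_binary = as.logical(tapply(df$is_binary, grp, any)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Apply the interaction-quality filter
#'
#' Keeps an interaction iff it comes from a high-throughput high-quality
#' experiment or is supported by at least two independent publications.
#'
#' @param records an `interaction_table`.
#' @return the kept subset, input order preserved.
#' @export
filter_interactions <- function(records) {
  keep <- records$ht_quality | records$publication_count >= 2L
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read target essentiality annotations
#'
#' @param path TSV with columns `protein_id`, `is_essential`.
#' @return named logical vector: `TRUE` for essential targets.
#' @export
read_target_annotations <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("protein_id", "is_essential"), "annotation table")
  if (anyDuplicated(df$protein_id))
    stop("annotation table: duplicate protein_id", call. = FALSE)
  stats::setNames(as_flag(df$is_essential, "is_essential"),
                  as.character(df$protein_id))
}

#' Read a disease-gene association table
#'
#' @param path TSV with columns `disease_id`, `genes` (semicolon-separated).
#' @return named list mapping disease id to a character vector of gene ids.
#' @export
read_disease_gene_table <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("disease_id", "genes"), "disease-gene table")
  if (anyDuplicated(df$disease_id))
    stop("disease-gene table: duplicate disease_id", call. = FALSE)
  m <- lapply(as.character(df$genes), split_list_cell)
  names(m) <- as.character(df$disease_id)
  empty <- lengths(m) == 0L
  if (any(empty))
    stop(sprintf("disease-gene table: empty gene set for disease '%s'",
                 names(m)[which(empty)[1L]]), call. = FALSE)
  m
}

#' Select drugs with exactly one non-essential target
#'
#' The confound-free analysis subset used for the degree and
#' interface-sharing regressions: drugs whose target set has exactly one
#' member, and that member is non-essential.
#'
#' @param drugs a `drug_table`.
#' @param annotations named logical essentiality vector
#'   (see [read_target_annotations()]); every target of every drug must be
#'   annotated.
#' @return the selected subset of `drugs`.
#' @export
select_single_nonessential_target_drugs <- function(drugs, annotations) {
  all_targets <- unique(unlist(drugs$targets, use.names = FALSE))
  unk <- setdiff(all_targets, names(annotations))
  if (length(unk))
    stop(sprintf("unannotated target protein(s): %s",
                 paste(utils::head(unk, 5L), collapse = ", ")),
         call. = FALSE)
  keep <- vapply(drugs$targets, function(ts)
    length(ts) == 1L && !annotations[[ts]], logical(1))
  out <- drugs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
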