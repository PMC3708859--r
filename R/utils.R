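# Internal helpers: seed substreams and strict TSV io.

#' Derive a reproducible substream seed
#'
#' Hashes a stream name together with a master seed into an integer seed,
#' so that independent stages of the pipeline (bootstrap, null trials,
#' generator steps) draw from non-interfering streams and changing the
#' number of draws in one stage does not perturb another.
#'
#' @param seed master integer seed.
#' @param name character stream label.
#' @return an integer seed in [1, 2^31 - 1).
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483563
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  v <- ((abs(seed) %% m) * 40014) %% m
  v <- (v + (h * 40692) %% m) %% m
  as.integer(v) + 1L
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Strict TSV reader: header row, tab delimiter, "NA" missing, no quoting.
read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Split a semicolon-separated in-cell list into a character vector
# of distinct, trimmed entries (empty/NA cell -> character(0)).
split_list_cell <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
  unique(parts[nzchar(parts)])
}

join_list_cell <- function(x) {
  if (length(x) == 0L) NA_character_ else paste(x, collapse = ";")
}

# Coerce 0/1/true/false cells to logical with a named error.
as_flag <- function(x, col) {
  out <- rep(NA, length(x))
  xs <- tolower(as.character(x))
  out[xs %in% c("1", "true", "t", "yes")] <- TRUE
  out[xs %in% c("0", "false", "f", "no")] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("column '%s': non-boolean value '%s' at row %d",
                 col, x[bad[1L]], bad[1L]), call. = FALSE)
  as.logical(out)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
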