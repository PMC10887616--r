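series_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read and write count series files
#'
#' A series file is delimited text (comma for `.csv`, tab otherwise) with a
#' header and four columns: `t` (strictly increasing 1-based time index),
#' `x1`, `x2` (nonnegative integer counts) and `state` (regime label in
#' `1..S`). `write_series()` followed by `read_series()` is the identity.
#'
#' @param path file path; the delimiter is chosen from the extension.
#' @param S optional regime-space size override; default is the largest
#'   observed label.
#' @return `read_series()` returns a [cubinar_series()];
#'   `write_series()` returns `path` invisibly.
#' @export
read_series <- function(path, S = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = series_sep(path),
               colClasses = "character", strip.white = TRUE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  need <- c("t", "x1", "x2", "state")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  parse_int <- function(col, what, min_ok) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v) | v < min_ok)
    if (length(bad))
      stop(sprintf("row %d of %s: %s must be an integer >= %d (got '%s')",
                   bad[1] + 1L, path, what, min_ok, df[[col]][bad[1]]))
    as.integer(v)
  }
  tt <- parse_int("t", "time index t", 1L)
  if (any(diff(tt) <= 0))
    stop("row ", which(diff(tt) <= 0)[1] + 2L, " of ", path,
         ": time index t must be strictly increasing")
  x1 <- parse_int("x1", "count x1", 0L)
  x2 <- parse_int("x2", "count x2", 0L)
  st <- parse_int("state", "state label", 1L)
  cubinar_series(x1, x2, st, S = S %||% max(st))
}

#' @rdname read_series
#' @param series a [cubinar_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "cubinar_series"))
  write.table(as.data.frame(series), path, sep = series_sep(path),
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a recovery study as tidy CSV
#'
#' One row per estimator x parameter x sample size, with MC mean, bias and
#' standard error — the layout of the usual estimator-recovery tables.
#'
#' @param study a `"cubinar_study"` from [run_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "cubinar_study"))
  write.table(as.data.frame(study), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
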