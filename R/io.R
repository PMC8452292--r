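# Delimited-table input/output. Units are fixed (h, ng/ml); no unit parsing.

.read_table_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
}

.check_numeric_column <- function(df, col, path, positive = FALSE) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]])) # non-numeric entries
  bad <- union(bad, which(is.na(df[[col]])))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric or missing '%s' on line %s", path, col,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  neg <- if (positive) which(x <= 0) else which(x < 0)
  if (length(neg)) {
    stop(sprintf("%s: %s '%s' on line %s", path,
                 if (positive) "non-positive" else "negative", col,
                 paste(neg + 1L, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Read a concentration table
#'
#' Reads either a dyad table (columns `dyad_id`, `time_post_dose_h`,
#' `mp_ng_ml`, `uv_ng_ml`; one paired sample per maternal-fetal dyad) or a
#' dense profile table (columns `time_h`, `mp_ng_ml`, `uv_ng_ml`), deciding
#' by the header. Units are assumed h and ng/ml. Malformed rows are
#' reported with their line number (header is line 1).
#'
#' @param path path to a delimited (CSV) file with a header.
#' @return an [observed_dyads()] or [concentration_profile()] object.
#' @export
read_concentration_table <- function(path) {
  df <- .read_table_checked(path)
  dyad_cols <- c("dyad_id", "time_post_dose_h", "mp_ng_ml", "uv_ng_ml")
  prof_cols <- c("time_h", "mp_ng_ml", "uv_ng_ml")
  if (all(dyad_cols %in% names(df))) {
    if (!nrow(df)) stop(sprintf("%s: no data rows", path), call. = FALSE)
    observed_dyads(
      df$dyad_id,
      .check_numeric_column(df, "time_post_dose_h", path, positive = TRUE),
      .check_numeric_column(df, "mp_ng_ml", path, positive = TRUE),
      .check_numeric_column(df, "uv_ng_ml", path, positive = TRUE))
  } else if (all(prof_cols %in% names(df))) {
    if (!nrow(df)) stop(sprintf("%s: no data rows", path), call. = FALSE)
    concentration_profile(
      .check_numeric_column(df, "time_h", path),
      .check_numeric_column(df, "mp_ng_ml", path),
      .check_numeric_column(df, "uv_ng_ml", path))
  } else {
    stop(sprintf(
      "%s: header must contain either %s (dyads) or %s (profile); found: %s",
      path, paste(dyad_cols, collapse = ", "),
      paste(prof_cols, collapse = ", "),
      paste(names(df), collapse = ", ")), call. = FALSE)
  }
}

#' Write a concentration table
#'
#' Writes dyads or profiles in the same CSV format
#' [read_concentration_table()] reads, so tables round-trip.
#'
#' @param x an [observed_dyads()] or [concentration_profile()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(x, path) {
  stopifnot(inherits(x, "observed_dyads") ||
              inherits(x, "concentration_profile"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
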