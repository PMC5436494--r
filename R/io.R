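# Sample-table CSV I/O. RFC-4180 dialect, "." decimal, UTF-8; metadata
# travels in leading "#"-prefixed comment lines.

SAMPLE_TABLE_REQUIRED <- c("ramp_id", "t_min", "tau_res_min", "temp_C",
  "equivalents", "Q_total_mL_min")

#' Write a campaign sample table to CSV
#'
#' Writes the table with leading comment lines carrying campaign metadata
#' (scheme id and config hash) so a read round trip is lossless.
#'
#' @param table A sample table tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  meta <- c(
    sprintf("# scheme_id: %s", attr(table, "scheme_id") %||% "NA"),
    sprintf("# config_hash: %s", attr(table, "config_hash") %||% "NA")
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a campaign sample table from CSV
#'
#' Restores metadata from comment lines, validates the required column set,
#' and reports malformed numeric cells with their row numbers. Extra user
#' columns are preserved untouched.
#'
#' @param path CSV file written by [write_sample_table()] (or any CSV with
#'   the required columns).
#' @return A sample table tibble with `scheme_id` and `config_hash`
#'   attributes when present in the file.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("Sample table file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  first_body <- which(!is_meta)[1]
  meta <- if (!is.na(first_body) && first_body > 1) lines[1:(first_body - 1)] else character(0)
  body <- lines[!is_meta]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
    colClasses = "character", check.names = FALSE)
  missing <- setdiff(SAMPLE_TABLE_REQUIRED, names(df))
  if (length(missing) > 0) {
    abort_data(sprintf("Sample table is missing required columns: %s.",
      paste(missing, collapse = ", ")))
  }
  numeric_cols <- union(setdiff(SAMPLE_TABLE_REQUIRED, "ramp_id"),
    grep("^C[0-9]+(_0)?_M$|^beta$", names(df), value = TRUE))
  for (cl in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(parsed) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad) > 0) {
      abort_data(sprintf("Malformed numeric cell(s) in column '%s', row(s): %s.",
        cl, paste(bad, collapse = ", ")))
    }
    df[[cl]] <- parsed
  }
  rid <- suppressWarnings(as.numeric(df$ramp_id))
  if (!anyNA(rid)) df$ramp_id <- rid
  out <- tibble::as_tibble(df)
  grab <- function(key) {
    hit <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(hit) > 0) trimws(sub(sprintf("^# %s:", key), "", hit[1])) else NULL
  }
  attr(out, "scheme_id") <- grab("scheme_id")
  attr(out, "config_hash") <- grab("config_hash")
  out
}
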