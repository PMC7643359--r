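feature_table_columns <- function() c("subject_id", "sex", "gf", feature_names())

#' Validate a feature table's schema
#'
#' Checks for the exact column set `subject_id`, `sex`, `gf` plus the 45
#' predictors, finite numeric predictor values, and known sex codes.
#'
#' @param table A data frame.
#' @return The table, with columns reordered canonically.
#' @export
validate_feature_table <- function(table) {
  want <- feature_table_columns()
  missing <- setdiff(want, names(table))
  if (length(missing) > 0L) {
    stopf("schema error: missing column(s) %s", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(table), want)
  if (length(unknown) > 0L) {
    stopf("schema error: unknown column(s) %s", paste(unknown, collapse = ", "))
  }
  if (!all(table$sex %in% c("M", "W"))) {
    stopf("schema error: sex codes must be 'M' or 'W'")
  }
  table[, want]
}

#' Write a feature table to CSV
#'
#' Values are written with 15 significant digits so a write/read
#' round-trip is lossless to at least 12 significant digits.
#'
#' @param table A feature table (see [validate_feature_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  num <- vapply(table, is.numeric, TRUE)
  out <- table
  out[num] <- lapply(table[num], function(v) format(v, digits = 15, trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path.
#' @param rename Optional named character vector mapping file column
#'   names to the canonical names (`c(file_name = "canonical_name")`),
#'   for tables produced outside this package.
#' @return A validated feature table.
#' @export
read_feature_table <- function(path, rename = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(rename)) {
    hit <- names(tab) %in% names(rename)
    names(tab)[hit] <- rename[names(tab)[hit]]
  }
  if ("subject_id" %in% names(tab)) tab$subject_id <- as.character(tab$subject_id)
  validate_feature_table(tab)
}
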