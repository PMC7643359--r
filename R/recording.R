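#' Construct a multichannel recording
#'
#' A recording is a channels-by-samples numeric matrix (microvolts) with
#' channel labels, a sampling rate and a subject identifier.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate = 256,
                          subject_id = "S000") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stopf("recording data must be a finite numeric matrix")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stopf("label count (%d) does not match channel row count (%d)",
          length(channel_labels), nrow(data))
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stopf("sampling_rate must be a positive scalar")
  }
  if (abs(sampling_rate - 256) > 1e-9) {
    message(sprintf("note: sampling rate %g Hz differs from 256 Hz; the pipeline operates on sample counts",
                    sampling_rate))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels,
                 sampling_rate = sampling_rate,
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_rate))
  cat("  channels:", paste(head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Read a multichannel recording from disk
#'
#' Supported formats: `delimited` (first line = channel labels, then one
#' channel per line), `edf` (16-bit European Data Format) and `rds`
#' (a serialized recording). `auto` picks by file extension.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"delimited"`, `"edf"`, `"rds"`.
#' @param sampling_rate Sampling rate to assume for delimited input
#'   (EDF carries its own).
#' @param subject_id Optional subject id; defaults to the file stem.
#' @param sep Field separator for delimited input.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "delimited", "edf", "rds"),
                           sampling_rate = 256, subject_id = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     edf = "edf", rds = "rds",
                     csv = , tsv = , txt = , dat = "delimited",
                     stopf("cannot infer format from extension '.%s'", ext))
  }
  subject_id <- subject_id %||% tools::file_path_sans_ext(basename(path))
  rec <- switch(format,
    delimited = read_recording_delimited(path, sampling_rate, subject_id, sep),
    edf = read_edf(path, subject_id = subject_id),
    rds = {
      obj <- readRDS(path)
      if (!inherits(obj, "eeg_recording")) {
        stopf("rds file does not contain an eeg_recording")
      }
      obj
    })
  rec$channel_labels <- normalize_labels(rec$channel_labels)
  rownames(rec$data) <- rec$channel_labels
  rec
}

# case normalization against the 10-20 vocabulary: known labels take their
# canonical capitalization, unknown labels are upper-cased
normalize_labels <- function(labels) {
  vocab <- montage_labels()
  idx <- match(toupper(labels), toupper(vocab))
  ifelse(is.na(idx), toupper(labels), vocab[idx])
}

read_recording_delimited <- function(path, sampling_rate, subject_id, sep) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("delimited recording needs a header and data rows")
  hdr <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  hdr <- trimws(hdr)
  if (!anyNA(suppressWarnings(as.numeric(hdr)))) {
    stopf("missing header: first line of %s must hold channel labels", path)
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != length(hdr)) {
    stopf("schema error: %d labels in header but %d data rows", length(hdr),
          length(body))
  }
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, sep, fixed = TRUE)[[1L]]))
    if (anyNA(v)) stopf("non-numeric values in data rows of %s", path)
    v
  })
  ns <- lengths(rows)
  if (length(unique(ns)) != 1L) stopf("ragged data rows in %s", path)
  eeg_recording(do.call(rbind, rows), hdr, sampling_rate, subject_id)
}

#' Write a recording as a delimited text matrix
#'
#' First line holds the channel labels; each further line is one channel's
#' samples. Lossless to the printed precision (15 significant digits).
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = "\t") {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_labels, collapse = sep), con)
  apply(rec$data, 1L, function(row) {
    writeLines(paste(format(row, digits = 15, scientific = TRUE,
                            trim = TRUE), collapse = sep), con)
  })
  invisible(path)
}
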