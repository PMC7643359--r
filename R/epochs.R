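#' Extract disjoint epochs with amplitude rejection
#'
#' Cuts the recording into contiguous, non-overlapping epochs of
#' `epoch_length` samples starting at the first sample (trailing remainder
#' dropped), then rejects any epoch in which any channel sample exceeds
#' `amp_threshold` microvolts in absolute value. This is the last-line
#' amplitude quality control applied after preprocessing; defaults follow
#' standard resting-state practice at 256 Hz (40 s epochs, 111 uV).
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length Epoch length in samples (default 10240).
#' @param amp_threshold Absolute amplitude rejection threshold in
#'   microvolts (default 111; `Inf` disables rejection).
#' @return List of epochs; each is a channels x `epoch_length` matrix with
#'   attributes `index` (ordinal position within the recording) and
#'   `channel_labels`. The list carries attributes `n_candidates` and
#'   `n_rejected`.
#' @export
extract_epochs <- function(rec, epoch_length = 10240, amp_threshold = 111) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is_count(epoch_length)) stopf("epoch_length must be a positive integer")
  n <- ncol(rec$data)
  if (n < epoch_length) {
    stopf("recording (%d samples) shorter than one epoch (%d)", n, epoch_length)
  }
  k <- floor(n / epoch_length)
  epochs <- vector("list", k)
  keep <- logical(k)
  for (i in seq_len(k)) {
    cols <- ((i - 1L) * epoch_length + 1L):(i * epoch_length)
    e <- rec$data[, cols, drop = FALSE]
    keep[i] <- max(abs(e)) <= amp_threshold
    attr(e, "index") <- i
    attr(e, "channel_labels") <- rec$channel_labels
    epochs[[i]] <- e
  }
  out <- epochs[keep]
  if (length(out) == 0L) {
    stopf("no usable epochs: all %d candidate epochs exceeded |%g| uV",
          k, amp_threshold)
  }
  attr(out, "n_candidates") <- k
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Select the rows of a channel set from an epoch or recording
#'
#' Returns the 4 x samples submatrix for a named channel set (or an
#' explicit label vector), rows ordered as in the set definition. Label
#' matching is case-insensitive; if a label occurs more than once, the
#' first occurrence is used with a warning.
#'
#' @param x An epoch matrix, an [eeg_recording()], or any labeled
#'   channels-by-samples matrix.
#' @param set_def A set name from [channel_set_names()] or a character
#'   vector of labels.
#' @param labels Channel labels of `x`'s rows; taken from `x` when absent.
#' @return Numeric matrix with one row per set label, in set order.
#' @export
select_channel_set <- function(x, set_def, labels = NULL) {
  if (inherits(x, "eeg_recording")) {
    labels <- labels %||% x$channel_labels
    x <- x$data
  }
  labels <- labels %||% attr(x, "channel_labels") %||% rownames(x)
  if (is.null(labels)) stopf("no channel labels available for selection")
  if (length(labels) != nrow(x)) stopf("label count does not match row count")
  want <- if (is.character(set_def) && length(set_def) == 1L &&
              toupper(set_def) %in% channel_set_names()) {
    channel_sets(set_def)
  } else {
    as.character(set_def)
  }
  up <- toupper(labels)
  idx <- vapply(toupper(want), function(l) {
    hits <- which(up == l)
    if (length(hits) == 0L) return(NA_integer_)
    if (length(hits) > 1L) {
      warnf("duplicate channel label '%s'; using first occurrence", l)
    }
    hits[1L]
  }, integer(1L))
  if (anyNA(idx)) {
    stopf("missing channel(s): %s", paste(want[is.na(idx)], collapse = ", "))
  }
  out <- x[idx, , drop = FALSE]
  rownames(out) <- want
  out
}
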