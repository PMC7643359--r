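# Minimal European Data Format (EDF) support: enough of the 16-bit format
# to round-trip multichannel recordings with labels and sampling rate.
# Header fields are fixed-width ASCII; samples are little-endian int16,
# mapped linearly between the digital and physical ranges.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF file
#'
#' Reads continuous 16-bit EDF. All signals must share the same number of
#' samples per record; annotation channels are not supported.
#'
#' @param path Path to an `.edf` file.
#' @param subject_id Subject id; defaults to the file stem.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- rd(8L)
  if (!grepl("^0", trimws(version))) stopf("not an EDF file: %s", path)
  rd(80L); rd(80L); rd(8L); rd(8L)               # patient, recording, date, time
  rd(8L)                                          # header bytes
  rd(44L)                                         # reserved
  n_records <- as.integer(trimws(rd(8L)))
  record_dur <- as.numeric(trimws(rd(8L)))
  ns <- as.integer(trimws(rd(4L)))
  if (is.na(ns) || ns < 1L) stopf("EDF header reports no signals")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), ""))
  rd(80L * ns); rd(8L * ns)                       # transducer, physical dim
  phys_min <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  phys_max <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  dig_min <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  dig_max <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  rd(80L * ns)                                    # prefiltering
  spr <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8L), "")))
  rd(32L * ns)                                    # reserved
  if (length(unique(spr)) != 1L) {
    stopf("EDF signals with heterogeneous sampling rates are not supported")
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1L])
  for (rec in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      cols <- ((rec - 1L) * spr[s] + 1L):(rec * spr[s])
      data[s, cols] <- phys_min[s] + gain[s] * (raw - dig_min[s])
    }
  }
  fs <- spr[1L] / record_dur
  eeg_recording(data, labels, fs,
                subject_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a recording as EDF
#'
#' Quantizes to 16 bits over the per-channel physical range, so the
#' round-trip is exact only to the quantization step. One data record per
#' second of signal; a trailing partial second is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- as.integer(rec$sampling_rate)
  if (spr != rec$sampling_rate) stopf("EDF writer requires an integer sampling rate")
  n_records <- floor(ncol(rec$data) / spr)
  if (n_records < 1L) stopf("recording shorter than one EDF record (1 s)")
  used <- rec$data[, seq_len(n_records * spr), drop = FALSE]
  phys_min <- apply(used, 1L, min)
  phys_max <- apply(used, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(edf_pad(x, w), con, eos = NULL)
  wr("0", 8L)
  wr(rec$subject_id, 80L)
  wr("neurocx export", 80L)
  wr("01.01.26", 8L); wr("00.00.00", 8L)
  wr(256L + 256L * ns, 8L)
  wr("", 44L)
  wr(n_records, 8L)
  wr(1, 8L)
  wr(ns, 4L)
  for (l in rec$channel_labels) wr(l, 16L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr("uV", 8L)
  for (v in phys_min) wr(formatC(v, digits = 6, format = "g"), 8L)
  for (v in phys_max) wr(formatC(v, digits = 6, format = "g"), 8L)
  for (v in dig_min) wr(v, 8L)
  for (v in dig_max) wr(v, 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(spr, 8L)
  for (i in seq_len(ns)) wr("", 32L)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round(dig_min[s] + (used[s, cols] - phys_min[s]) / gain[s])
      dig <- pmin(pmax(dig, dig_min[s]), dig_max[s])
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
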