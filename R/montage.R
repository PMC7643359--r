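#' Standard 64-channel 10-20 montage labels
#'
#' The electrode labels of a standard 64-channel extended 10-20 layout
#' (Biosemi ordering). Used as the default channel naming of the synthetic
#' signal generator and as the vocabulary against which recording labels
#' are normalized.
#'
#' @return Character vector of 64 electrode labels.
#' @export
montage_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

.channel_sets <- list(
  F  = c("F7", "F8", "F3", "F4"),
  FL = c("FP1", "F7", "F3", "FC3"),
  FR = c("FP2", "F8", "F4", "FC4"),
  C  = c("Fz", "Cz", "Pz", "Oz"),
  P  = c("P3", "P4", "P7", "P8"),
  PL = c("P7", "P3", "O1", "PO3"),
  PR = c("P8", "P4", "O2", "PO4"),
  ML = c("T7", "C3", "CP5", "CP1"),
  MR = c("T8", "C4", "CP6", "CP2")
)

#' Built-in scalp channel sets
#'
#' Nine named 4-electrode groups covering frontal (`F`, `FL`, `FR`),
#' central midline (`C`), parietal (`P`, `PL`, `PR`) and middle
#' temporo-central (`ML`, `MR`) scalp regions. Entropy profiles are
#' computed per set, so each set defines one 4-variate signal.
#'
#' @param name Optional set name; if given, only that definition is
#'   returned.
#' @return A named list of character vectors of 4 electrode labels
#'   (or a single vector if `name` is given).
#' @examples
#' channel_sets()[["P"]]
#' @export
channel_sets <- function(name = NULL) {
  if (is.null(name)) return(.channel_sets)
  name <- toupper(as.character(name))
  if (!name %in% names(.channel_sets)) {
    stopf("unknown channel set '%s' (known: %s)", name,
          paste(names(.channel_sets), collapse = ", "))
  }
  .channel_sets[[name]]
}

#' Names of the built-in channel sets
#' @return Character vector of the nine set names.
#' @export
channel_set_names <- function() names(.channel_sets)
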