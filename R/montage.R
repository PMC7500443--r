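#' Build the 31-channel 10-20 recording montage
#'
#' Fixed electrode layout used throughout the package: a standard 10-20 cap
#' with 31 Ag-AgCl positions and *without* Oz and Cz (those sites carry the
#' stimulation electrodes). Positions are schematic 2-D head-centered
#' coordinates (unit head radius, x: left negative, y: anterior positive),
#' intended for topography export and for the posterior-weighted artifact
#' model, not for source modeling.
#'
#' @return object of class `channel_layout`: data.frame with columns
#'   `label`, `x`, `y` (31 rows).
#' @export
build_montage <- function() {
  tbl <- matrix(c(
    "Fp1", -0.25,  0.95,  "Fp2",  0.25,  0.95,
    "F7",  -0.80,  0.55,  "F3",  -0.40,  0.55,  "Fz", 0,  0.55,
    "F4",   0.40,  0.55,  "F8",   0.80,  0.55,
    "FC5", -0.60,  0.30,  "FC1", -0.20,  0.30,
    "FC2",  0.20,  0.30,  "FC6",  0.60,  0.30,
    "T7",  -0.95,  0.00,  "C3",  -0.40,  0.00,
    "C4",   0.40,  0.00,  "T8",   0.95,  0.00,
    "CP5", -0.60, -0.30,  "CP1", -0.20, -0.30,
    "CP2",  0.20, -0.30,  "CP6",  0.60, -0.30,
    "P7",  -0.80, -0.55,  "P3",  -0.40, -0.55,  "Pz", 0, -0.55,
    "P4",   0.40, -0.55,  "P8",   0.80, -0.55,
    "PO7", -0.60, -0.78,  "PO3", -0.30, -0.78,  "POz", 0, -0.78,
    "PO4",  0.30, -0.78,  "PO8",  0.60, -0.78,
    "O1",  -0.25, -0.95,  "O2",   0.25, -0.95
  ), ncol = 3, byrow = TRUE)
  layout <- data.frame(
    label = tbl[, 1],
    x = as.numeric(tbl[, 2]),
    y = as.numeric(tbl[, 3]),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(layout) == 31, !anyDuplicated(layout$label))
  class(layout) <- c("channel_layout", "data.frame")
  layout
}

#' The parieto-occipital cluster (POC) channel set
#'
#' Nine-channel posterior cluster used for the multi-channel power analysis.
#' @return character vector of channel labels.
#' @export
poc_channels <- function() {
  c("P3", "PO3", "PO7", "O1", "POz", "O2", "PO8", "PO4", "P4")
}

channel_index <- function(layout, label) {
  idx <- match(label, layout$label)
  if (anyNA(idx)) {
    stop("channel(s) not in layout: ", paste(label[is.na(idx)], collapse = ", "))
  }
  idx
}
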