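## ---- standard-format I/O --------------------------------------------------

#' Write a recording as a BrainVision triplet
#'
#' Writes `<stem>.vhdr` / `<stem>.vmrk` / `<stem>.eeg` (IEEE float32,
#' multiplexed, unit uV). Stimulus markers are written at each trial's
#' stimulation onset; the authoritative event table should additionally be
#' saved with [write_events_tsv()].
#'
#' @param recording an [eeg_recording()].
#' @param stem output path without extension.
#' @param events optional `event_table` for stimulus markers.
#' @return invisibly, the three file paths.
#' @export
write_brainvision <- function(recording, stem, events = NULL) {
  vhdr <- paste0(stem, ".vhdr"); vmrk <- paste0(stem, ".vmrk")
  eeg <- paste0(stem, ".eeg")
  base <- basename(stem)
  nch <- nrow(recording$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / recording$srate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), recording$layout$label)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (!is.null(events)) {
    ## marker positions are 1-based data points in BrainVision files
    mk <- c(mk, sprintf("Mk%d=Stimulus,S %s,%d,%d,0",
                        seq_len(nrow(events)) + 1,
                        events$stimulation,
                        events$stim_onset + 1,
                        events$stim_offset - events$stim_onset))
  }
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$data), con, size = 4, endian = "little")
  invisible(c(vhdr = vhdr, vmrk = vmrk, eeg = eeg))
}

parse_ini <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

#' Read a BrainVision triplet
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return an [eeg_recording()] (channels matched to the package montage
#'   where labels agree; positions are NA for unknown labels).
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) stop("header not found: ", vhdr)
  ini <- parse_ini(readLines(vhdr, encoding = "UTF-8"))
  if (!identical(ini[["DataFormat"]], "BINARY") ||
      !identical(ini[["DataOrientation"]], "MULTIPLEXED") ||
      !identical(ini[["BinaryFormat"]], "IEEE_FLOAT_32")) {
    stop("unsupported BrainVision variant (need BINARY/MULTIPLEXED/IEEE_FLOAT_32)")
  }
  nch <- as.integer(ini[["NumberOfChannels"]])
  srate <- 1e6 / as.numeric(ini[["SamplingInterval"]])
  dir <- dirname(vhdr)
  vmrk <- file.path(dir, ini[["MarkerFile"]])
  if (!file.exists(vmrk)) stop("marker file missing: ", vmrk)
  eeg <- file.path(dir, ini[["DataFile"]])
  if (!file.exists(eeg)) stop("data file missing: ", eeg)
  ch_keys <- paste0("Ch", seq_len(nch))
  labels <- vapply(ch_keys, function(k) strsplit(ini[[k]], ",")[[1]][1], "")
  n_bytes <- file.size(eeg)
  n_samples <- n_bytes / 4 / nch
  if (n_samples != floor(n_samples)) stop("data file size not a whole sample count")
  con <- file(eeg, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = nch * n_samples, size = 4, endian = "little")
  data <- matrix(raw, nrow = nch)
  rownames(data) <- labels
  layout <- build_montage()
  if (!setequal(labels, layout$label)) {
    layout <- data.frame(label = labels,
                         x = layout$x[match(labels, layout$label)],
                         y = layout$y[match(labels, layout$label)],
                         stringsAsFactors = FALSE)
    class(layout) <- c("channel_layout", "data.frame")
  } else {
    data <- data[layout$label, , drop = FALSE]
  }
  eeg_recording(data, srate, layout)
}

#' Write / read the trial event table as TSV
#'
#' Columns: `trial_id`, `block`, `onset_sample`, `offset_sample`, `state`,
#' `stimulation`. Sample indices are 0-based with half-open intervals.
#'
#' @param events an `event_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(trial_id = events$trial_id, block = events$block,
                    onset_sample = events$stim_onset,
                    offset_sample = events$stim_offset,
                    state = events$state, stimulation = events$stimulation)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param n_samples optional recording length for bounds validation.
#' @return for the reader: an `event_table`.
#' @export
read_events_tsv <- function(path, n_samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "block", "onset_sample", "offset_sample", "state",
            "stimulation")
  if (!all(need %in% names(df))) {
    stop("events TSV lacks columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  ev <- data.frame(trial_id = df$trial_id, block = df$block, state = df$state,
                   stimulation = df$stimulation, iti_ms = NA_real_,
                   stim_onset = df$onset_sample, stim_offset = df$offset_sample,
                   stringsAsFactors = FALSE)
  if (is.unsorted(ev$stim_onset, strictly = TRUE)) {
    stop("event onsets must be strictly increasing")
  }
  if (!is.null(n_samples) && any(ev$stim_offset > n_samples)) {
    stop("event beyond end of recording")
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Read a recording plus its companion events
#'
#' Dispatches on the file extension: `.vhdr` (BrainVision triplet) or
#' `.edf` (EDF+). Events are read from `<stem>_events.tsv` next to the
#' recording and validated against the recording length.
#'
#' @param path path to the `.vhdr` or `.edf` file.
#' @return list with `recording` and `events` (NULL if no events file).
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    vhdr = read_brainvision(path),
    edf = read_edf(path),
    stop("unsupported recording format: .", ext)
  )
  ev_path <- paste0(tools::file_path_sans_ext(path), "_events.tsv")
  events <- if (file.exists(ev_path)) {
    read_events_tsv(ev_path, n_samples = ncol(rec$data))
  }
  list(recording = rec, events = events)
}

## ---- EDF+ -----------------------------------------------------------------

edf_pad <- function(x, width) {
  formatC(substr(as.character(x), 1, width), width = width, flag = "-")
}

#' Write a recording as EDF+ (continuous)
#'
#' 16-bit EDF+C with 1-s data records, per-channel physical scaling covering
#' the data range, and a minimal annotations channel carrying the record
#' time stamps. Quantization error is bounded by the physical range divided
#' by 2^16.
#'
#' @param recording an [eeg_recording()].
#' @param path output `.edf` path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  sr <- round(recording$srate)
  nch <- nrow(data)
  n_rec <- ceiling(ncol(data) / sr)
  if (ncol(data) < n_rec * sr) {            # pad final partial record
    data <- cbind(data, matrix(0, nch, n_rec * sr - ncol(data)))
  }
  ## physical bounds rounded outward so they fit the 8-char ASCII header
  ## fields exactly (the reader reconstructs from the written strings)
  round_phys <- function(x, up) {
    y <- if (up) ceiling(x * 100) / 100 else floor(x * 100) / 100
    s <- sprintf("%.2f", y)
    wide <- nchar(s) > 8
    y[wide] <- if (up) ceiling(x[wide]) else floor(x[wide])
    y
  }
  phys_str <- function(y) {
    s <- sprintf("%.2f", y)
    s[nchar(s) > 8] <- sprintf("%.0f", y[nchar(s) > 8])
    s
  }
  pmin_ <- round_phys(apply(data, 1, min), up = FALSE)
  pmax_ <- round_phys(apply(data, 1, max), up = TRUE)
  flat <- pmax_ - pmin_ < 0.01
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  ann_bytes <- 60                            # annotation channel, 2-byte ints
  ns <- nch + 1
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    edf_pad((ns + 1) * 256, 8),
    edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    paste0(edf_pad(recording$layout$label, 16), collapse = ""),
    edf_pad("EDF Annotations", 16),
    paste0(rep(edf_pad("AgAgCl electrode", 80), nch), collapse = ""),
    edf_pad("", 80),
    paste0(rep(edf_pad("uV", 8), nch), collapse = ""), edf_pad("", 8),
    paste0(edf_pad(phys_str(pmin_), 8), collapse = ""), edf_pad(-1, 8),
    paste0(edf_pad(phys_str(pmax_), 8), collapse = ""), edf_pad(1, 8),
    paste0(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste0(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste0(rep(edf_pad("", 80), ns), collapse = ""),
    paste0(rep(edf_pad(sr, 8), nch), collapse = ""),
    edf_pad(ann_bytes / 2, 8),
    paste0(rep(edf_pad("", 32), ns), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * sr + 1):(r * sr)
    dig <- round((data[, cols, drop = FALSE] - pmin_) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
    tal <- sprintf("+%d\x14\x14", r - 1)
    ann <- c(charToRaw(tal), raw(ann_bytes - nchar(tal, type = "bytes")))
    writeBin(ann, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Supports the continuous layout written by [write_edf()] (equal-rate
#' signal channels; any "EDF Annotations" channel is dropped).
#'
#' @param path `.edf` path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8 + 80 + 80 + 8 + 8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  field <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- field(16); field(80); field(8)
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  nsamp <- as.integer(field(8))
  field(32)
  keep <- labels != "EDF Annotations"
  if (length(unique(nsamp[keep])) != 1) stop("unequal channel rates unsupported")
  srate <- nsamp[keep][1] / rec_dur
  out <- matrix(0, sum(keep), n_rec * nsamp[keep][1])
  col0 <- 0
  for (r in seq_len(n_rec)) {
    j <- 0
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = nsamp[s], size = 2,
                      endian = "little", signed = TRUE)
      if (keep[s]) {
        j <- j + 1
        out[j, (col0 + 1):(col0 + nsamp[s])] <-
          (vals - dmin[s]) / (dmax[s] - dmin[s]) * (pmax_[s] - pmin_[s]) + pmin_[s]
      }
    }
    col0 <- col0 + nsamp[keep][1]
  }
  labels <- labels[keep]
  rownames(out) <- labels
  layout <- build_montage()
  if (setequal(labels, layout$label)) {
    out <- out[layout$label, , drop = FALSE]
  } else {
    layout <- data.frame(label = labels,
                         x = rep(NA_real_, length(labels)),
                         y = rep(NA_real_, length(labels)))
    class(layout) <- c("channel_layout", "data.frame")
  }
  eeg_recording(out, srate, layout)
}

#' Write ground truth as JSON
#'
#' @param ground_truth a `ground_truth` from [simulate_subject()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(unclass(ground_truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
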