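#' Sample a session schedule
#'
#' Draws the trial/block schedule: `n_blocks` blocks alternating eyes-open /
#' eyes-closed (starting with `first_state`), each containing
#' `trials_per_block` trials of which exactly half are in-phase and half
#' anti-phase, in shuffled order. Inter-trial intervals are drawn uniformly
#' from `iti_range` (ms) and rounded to whole samples.
#'
#' Sample indices are 0-based with half-open stimulation intervals
#' `[stim_onset, stim_offset)`, the convention used throughout the package
#' and in all exported event tables.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed (local RNG; caller's stream untouched).
#' @return `event_table`: data.frame with columns `trial_id`, `block`,
#'   `state`, `stimulation`, `iti_ms`, `stim_onset`, `stim_offset`.
#' @export
sample_schedule <- function(config, seed = NULL) {
  validate_config(config)
  with_seed(seed, {
    sr <- config$srate
    pre_n <- round(config$pre_dur * sr)
    stim_n <- round(config$stim_dur * sr)
    post_n <- round(config$post_dur * sr)
    break_n <- round(config$block_break * sr)
    states <- rep(c(config$first_state, setdiff(c("EO", "EC"), config$first_state)),
                  length.out = config$n_blocks)
    npb <- config$trials_per_block
    rows <- vector("list", config$n_blocks)
    cursor <- 0L
    tid <- 0L
    for (b in seq_len(config$n_blocks)) {
      stim <- sample(rep(c("in", "anti"), each = npb / 2))
      iti_ms <- stats::runif(npb, config$iti_range[1], config$iti_range[2])
      iti_n <- round(iti_ms / 1000 * sr)
      onset <- offset <- integer(npb)
      for (i in seq_len(npb)) {
        onset[i] <- cursor + pre_n
        offset[i] <- onset[i] + stim_n
        cursor <- offset[i] + post_n + iti_n[i]
      }
      rows[[b]] <- data.frame(
        trial_id = tid + seq_len(npb), block = b, state = states[b],
        stimulation = stim, iti_ms = iti_ms,
        stim_onset = onset, stim_offset = offset,
        stringsAsFactors = FALSE
      )
      tid <- tid + npb
      cursor <- cursor + break_n
    }
    ev <- do.call(rbind, rows)
    attr(ev, "n_samples") <- cursor + 0L
    class(ev) <- c("event_table", "data.frame")
    ev
  })
}

## 1/f^beta noise via spectral shaping, standardized to unit SD.
## Returns an n x m matrix of independent columns.
powerlaw_noise <- function(n, m = 1, exponent = 1) {
  N <- stats::nextn(n, c(2, 3, 5))       # composite length keeps the FFT fast
  f <- c(0, seq_len(N - 1))
  f <- pmin(f, N - f)                    # bin distance to DC
  shape <- c(0, f[-1]^(-exponent / 2))   # zero out DC
  scale <- sqrt(sum(shape^2) / N)        # unit output variance
  out <- matrix(0, n, m)
  ## shape white gaussian noise in the frequency domain, batched through
  ## mvfft in channel chunks to bound transient memory
  chunk <- max(1, min(m, floor(2^23 / N)))
  for (j0 in seq(1, m, by = chunk)) {
    js <- j0:min(j0 + chunk - 1, m)
    W <- matrix(stats::rnorm(N * length(js)), N)
    Z <- stats::mvfft(W) * shape
    x <- Re(stats::mvfft(Z, inverse = TRUE))[seq_len(n), , drop = FALSE] / N
    out[, js] <- x / scale
  }
  out
}

## slow (<= cutoff Hz) standardized gaussian fluctuation, FFT brick-wall.
## The default cutoff keeps the alpha envelope coherent across the ~1.6 s
## separating the pre and post analysis windows, as real posterior alpha
## waxing-and-waning is; fast envelope fluctuations would bias per-trial
## post/pre power ratios upward (noisy denominators).
slow_fluctuation <- function(n, srate, cutoff = 0.05) {
  N <- stats::nextn(n, c(2, 3, 5))
  z <- stats::rnorm(N)
  Z <- stats::fft(z)
  f <- c(0, seq_len(N - 1)) * srate / N
  f <- pmin(f, srate - f)
  Z[f > cutoff] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE))[seq_len(n)] / N
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else (x - mean(x)) / s
}

## spatially unstructured narrow-band background alpha: independent per
## channel, gaussian spectral bump centred at the subject's IAF. Real EEG
## carries distributed alpha from many generators besides the targeted
## posterior source; without this floor, in-band power of an arbitrary
## spatial-filter direction can be near zero on single trials and per-trial
## post/pre ratios develop divergent tails. The narrow bandwidth (sigma_f)
## makes its envelope slow, so pre and post windows of a trial share it.
background_alpha <- function(n, m, srate, iaf, sigma_f = 0.5) {
  N <- stats::nextn(n, c(2, 3, 5))
  f <- (seq_len(N) - 1) * srate / N
  f <- pmin(f, srate - f)
  amp <- exp(-(f - iaf)^2 / (2 * sigma_f^2))
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    spec <- complex(modulus = amp, argument = stats::runif(N, 0, 2 * pi))
    x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
    out[, j] <- x / stats::sd(x)
  }
  out
}

## default posterior alpha-source topography on the montage: gaussian bump
## centred between O1/O2/POz
alpha_source_pattern <- function(layout, jitter_sd = 0) {
  d2 <- layout$x^2 + (layout$y + 0.85)^2
  w <- exp(-d2 / (2 * 0.35^2))
  if (jitter_sd > 0) w <- w * exp(jitter_sd * stats::rnorm(length(w)))
  w / sqrt(sum(w^2))
}

#' Simulate one closed-loop tACS-EEG session
#'
#' Generates a continuous 31-channel recording as 1/f^beta background noise
#' plus a single posterior alpha source at the subject's individual alpha
#' frequency (IAF). The source is an amplitude-modulated cosine (slow
#' log-normal envelope), with state-dependent amplitude (`alpha_amp_ec`
#' during eyes-closed blocks, `alpha_amp_eo` during eyes-open), projected to
#' the channels through a unit-norm spatial pattern. Immediately after each
#' stimulation offset the source envelope is multiplied by
#' `1 - suppression_depth * exp(-t / suppression_tau)`, identically for
#' in-phase and anti-phase trials (the suppression is phase-independent by
#' construction). Resting-state EC/EO segments for IAF estimation are
#' simulated with the same model.
#'
#' No stimulation artifact is added here; see [inject_stim_artifact()].
#'
#' @param config a [simulation_config()].
#' @param subject_id identifier stored in the ground truth.
#' @param seed optional integer seed.
#' @return list with elements `recording` (`eeg_recording`), `events`
#'   (`event_table`), `ground_truth` (IAF, source phase/pattern, realized
#'   suppression parameters and ITIs), `rest_ec`, `rest_eo`.
#' @export
simulate_subject <- function(config, subject_id = 1, seed = NULL) {
  validate_config(config)
  with_seed(seed, {
    layout <- build_montage()
    sr <- config$srate
    events <- sample_schedule(config)
    n <- attr(events, "n_samples")

    iaf <- stats::runif(1, config$iaf_range[1], config$iaf_range[2])
    phase0 <- stats::runif(1, -pi, pi)
    pattern <- alpha_source_pattern(layout, jitter_sd = 0.1)

    ## per-sample state amplitude; gaps between blocks keep the block's state
    amp <- numeric(n)
    block_state <- tapply(events$state, events$block, `[`, 1)
    block_start <- tapply(events$stim_onset, events$block, min) -
      round(config$pre_dur * sr)
    block_end <- c(block_start[-1], n)
    for (b in seq_along(block_state)) {
      a <- if (block_state[b] == "EC") config$alpha_amp_ec else config$alpha_amp_eo
      amp[(block_start[b] + 1):block_end[b]] <- a
    }

    env <- alpha_envelope(n, sr, config$alpha_env_sd)
    supp <- suppression_profile(n, sr, events, config$suppression_depth,
                                config$suppression_tau)

    t <- (seq_len(n) - 1) / sr
    src <- amp * env * supp * cos(2 * pi * iaf * t + phase0)
    nch <- nrow(layout)
    data <- tcrossprod(pattern, src)
    if (config$noise_amp > 0) {
      data <- data + config$noise_amp *
        t(powerlaw_noise(n, nch, config$noise_exponent))
    }
    if (config$alpha_bg > 0) {
      data <- data + config$alpha_bg * t(background_alpha(n, nch, sr, iaf))
    }
    rownames(data) <- layout$label
    rec <- eeg_recording(data, sr, layout)

    rest <- lapply(c(EC = "EC", EO = "EO"), function(st) {
      nr <- round(config$rest_dur * sr)
      a <- if (st == "EC") config$alpha_amp_ec else config$alpha_amp_eo
      tr <- (seq_len(nr) - 1) / sr
      s <- a * alpha_envelope(nr, sr, config$alpha_env_sd) *
        cos(2 * pi * iaf * tr + stats::runif(1, -pi, pi))
      d <- tcrossprod(pattern, s)
      if (config$noise_amp > 0) {
        d <- d + config$noise_amp *
          t(powerlaw_noise(nr, nrow(layout), config$noise_exponent))
      }
      if (config$alpha_bg > 0) {
        d <- d + config$alpha_bg * t(background_alpha(nr, nrow(layout), sr, iaf))
      }
      rownames(d) <- layout$label
      eeg_recording(d, sr, layout)
    })

    gt <- list(
      subject_id = subject_id, iaf = iaf, phase0 = phase0,
      source_pattern = stats::setNames(pattern, layout$label),
      suppression_depth = config$suppression_depth,
      suppression_tau = config$suppression_tau,
      iti_ms = events$iti_ms
    )
    class(gt) <- "ground_truth"
    list(recording = rec, events = events, ground_truth = gt,
         rest_ec = rest$EC, rest_eo = rest$EO)
  })
}

alpha_envelope <- function(n, srate, env_sd) {
  if (env_sd <= 0) return(rep(1, n))
  exp(env_sd * slow_fluctuation(n, srate) - env_sd^2 / 2)
}

## multiplicative post-stimulation suppression profile (1 everywhere except
## an exponentially recovering dip after each stimulation offset)
suppression_profile <- function(n, srate, events, depth, tau_ms) {
  supp <- rep(1, n)
  if (depth <= 0) return(supp)
  tau_s <- tau_ms / 1000
  next_onset <- c(events$stim_onset[-1], n)
  for (i in seq_len(nrow(events))) {
    idx0 <- events$stim_offset[i]             # 0-based
    span <- idx0:(next_onset[i] - 1)
    tt <- (span - idx0) / srate
    supp[span + 1] <- supp[span + 1] * (1 - depth * exp(-tt / tau_s))
  }
  supp
}

#' EEG recording container
#'
#' @param data channels x samples numeric matrix (uV), rows named by channel.
#' @param srate sampling rate (Hz).
#' @param layout a `channel_layout` matching the rows of `data`.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, layout) {
  stopifnot(is.matrix(data), nrow(data) == nrow(layout))
  rng <- range(data)                     # single pass; no 27M-element logical
  if (anyNA(rng) || any(is.infinite(rng))) stop("non-finite values in data")
  structure(list(data = data, srate = srate, layout = layout),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

#' Add a stimulation artifact to a recording
#'
#' Adds `artifact_gain`-scaled stimulation waveforms, spatially weighted with
#' a linear anterior-to-posterior gradient (peaking at the posterior
#' channels), strictly within each trial's `[stim_onset, stim_offset)`
#' interval. Samples outside stimulation intervals are untouched.
#'
#' @param recording an [eeg_recording()].
#' @param events matching `event_table`.
#' @param waveforms list of [make_stim_waveform()] objects (or numeric
#'   vectors), one per trial, each of length `stim_offset - stim_onset`.
#' @param artifact_gain artifact-to-neural scale: the RMS of the injected
#'   artifact at the most posterior channel equals `artifact_gain` times the
#'   RMS of the neural signal at that channel (tACS artifacts are several
#'   orders of magnitude larger than EEG, so realistic values are 1e2-1e4).
#' @return a new `eeg_recording` with the artifact added.
#' @export
inject_stim_artifact <- function(recording, events, waveforms, artifact_gain) {
  stopifnot(inherits(recording, "eeg_recording"), artifact_gain >= 0)
  if (length(waveforms) != nrow(events)) {
    stop("need exactly one waveform per trial")
  }
  y <- recording$layout$y
  topo <- (max(y) - y) / diff(range(y))   # 0 anterior .. 1 posterior
  data <- recording$data
  ref_rms <- sqrt(mean(data[which.max(topo), ]^2))
  for (i in seq_len(nrow(events))) {
    w <- waveforms[[i]]
    if (inherits(w, "stim_waveform")) w <- w$samples
    span <- (events$stim_onset[i] + 1):events$stim_offset[i]
    if (length(w) != length(span)) {
      stop(sprintf("trial %d: waveform length %d != stimulation interval %d",
                   i, length(w), length(span)))
    }
    w_rms <- sqrt(mean(w^2))
    if (w_rms > 0) {
      data[, span] <- data[, span] +
        artifact_gain * ref_rms * tcrossprod(topo, w / w_rms)
    }
  }
  eeg_recording(data, recording$srate, recording$layout)
}

#' Simulate a cohort of subjects
#'
#' @param config a [simulation_config()]; `config$n_subjects` sessions are
#'   generated with per-subject seeds derived from `seed`.
#' @param seed integer seed for the cohort.
#' @return list of per-subject session lists (see [simulate_subject()]).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  validate_config(config)
  base <- if (is.null(seed)) {
    with_seed(NULL, sample.int(.Machine$integer.max %/% 2, 1))
  } else {
    seed
  }
  lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(config, subject_id = i, seed = cohort_seed(base, i))
  })
}

#' Per-subject seed of a cohort stream
#'
#' Derives the seed [simulate_cohort()] uses for subject `i`, so callers can
#' regenerate single subjects of a cohort without materializing all
#' recordings at once (a full-size 20-subject cohort occupies several GB).
#'
#' @param seed cohort master seed.
#' @param i subject index.
#' @return integer seed below 2^31.
#' @export
cohort_seed <- function(seed, i) {
  (seed + 1013L * i) %% 2147483647L
}
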