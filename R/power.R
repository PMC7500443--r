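#' Alpha-band power of a 500 ms window
#'
#' Linearly detrends the window, zero-pads to `nfft` samples, computes the
#' FFT power spectrum (`|X_k|^2 / nfft`, one-sided without doubling -- the
#' band average only ever enters ratio and contrast statistics, which are
#' scale-invariant) and averages the bins whose center frequency lies in
#' `[iaf - 1, iaf + 1]` Hz inclusive, on the `srate / nfft` frequency grid.
#'
#' @param window numeric vector (one source, one trial) or a trials x samples
#'   matrix; window length must not exceed `nfft`.
#' @param iaf individual alpha frequency (Hz).
#' @param srate sampling rate (Hz).
#' @param nfft FFT length after zero-padding, default 512.
#' @return alpha power (uV^2): scalar for a vector input, vector for a matrix.
#' @export
window_alpha_power <- function(window, iaf, srate, nfft = 512) {
  x <- if (is.null(dim(window))) matrix(window, nrow = 1) else as.matrix(window)
  if (ncol(x) > nfft) {
    stop(sprintf("window length %d exceeds nfft = %d", ncol(x), nfft))
  }
  xt <- t(detrend_linear(t(x)))                 # detrend along time
  padded <- cbind(xt, matrix(0, nrow(x), nfft - ncol(x)))
  P <- Mod(stats::mvfft(t(padded)))^2 / nfft    # nfft x trials
  freqs <- (seq_len(nfft) - 1) * srate / nfft
  keep <- freqs >= iaf - 1 & freqs <= iaf + 1 & freqs <= srate / 2
  out <- colMeans(P[keep, , drop = FALSE])
  if (is.null(dim(window))) out[[1]] else out
}

#' Percent pre-to-post power modulation
#'
#' @param pre_power,post_power alpha power values (uV^2); `pre_power` must be
#'   strictly positive.
#' @return `(post - pre) / pre * 100`.
#' @export
percent_modulation <- function(pre_power, post_power) {
  if (any(pre_power <= 0)) stop("pre_power must be strictly positive")
  (post_power - pre_power) / pre_power * 100
}

#' Channel-based alpha power sources (POz and POC)
#'
#' Computes per-trial alpha power for the single-channel POz source and the
#' 9-channel parieto-occipital cluster (POC) source, defined as the mean of
#' the nine per-channel window powers (power is averaged, not the signals,
#' so the cluster value is robust to phase cancellation across channels).
#'
#' @param epochs a *filtered* [trial_epochs()] (one analysis window).
#' @param layout the recording's `channel_layout`.
#' @param iaf individual alpha frequency (Hz).
#' @param nfft FFT length.
#' @return long-format data.frame: `trial`, `window`, `source`, `alpha_power`.
#' @export
aggregate_sources <- function(epochs, layout, iaf, nfft = 512) {
  stopifnot(inherits(epochs, "trial_epochs"))
  poc <- poc_channels()
  idx <- channel_index(layout, poc)            # errors name missing channels
  n_tr <- dim(epochs$data)[1]
  pow <- sapply(idx, function(ch) {
    window_alpha_power(epochs$data[, ch, , drop = TRUE], iaf, epochs$srate, nfft)
  })
  pow <- matrix(pow, nrow = n_tr)              # trials x 9
  poz_pow <- pow[, match("POz", poc)]
  rbind(
    data.frame(trial = seq_len(n_tr), window = epochs$window_name,
               source = "POz", alpha_power = poz_pow),
    data.frame(trial = seq_len(n_tr), window = epochs$window_name,
               source = "POC", alpha_power = rowMeans(pow))
  )
}

#' Trial-averaged power spectra per condition
#'
#' Computes detrended, zero-padded FFT power spectra per trial for a pre and
#' a post window of one signal source, averages them within each
#' state x stimulation condition, and forms the post/pre spectral ratio.
#'
#' @param pre,post trials x samples matrices (one source).
#' @param events matching `event_table` (defines the conditions).
#' @param srate sampling rate (Hz).
#' @param nfft FFT length.
#' @return list with `spectra` (data.frame: freq, state, stimulation, window,
#'   power) and `ratio` (data.frame: freq, state, stimulation, ratio).
#' @export
mean_spectra <- function(pre, post, events, srate, nfft = 512) {
  spec <- function(x) {
    x <- as.matrix(x)
    padded <- cbind(t(detrend_linear(t(x))), matrix(0, nrow(x), nfft - ncol(x)))
    Mod(stats::mvfft(t(padded)))^2 / nfft      # nfft x trials
  }
  if (nrow(events) < 1) stop("empty condition: no trials")
  P_pre <- spec(pre); P_post <- spec(post)
  keep <- seq_len(nfft %/% 2 + 1)
  freqs <- (keep - 1) * srate / nfft
  cond <- interaction(factor(events$state), factor(events$stimulation),
                      drop = FALSE)
  out <- list(); ratio <- list()
  for (cl in levels(cond)) {
    sel <- cond == cl
    if (!any(sel)) stop("empty condition: ", cl)
    st <- sub("\\..*$", "", cl); sti <- sub("^.*\\.", "", cl)
    m_pre <- rowMeans(P_pre[keep, sel, drop = FALSE])
    m_post <- rowMeans(P_post[keep, sel, drop = FALSE])
    out[[cl]] <- data.frame(
      freq = rep(freqs, 2), state = st, stimulation = sti,
      window = rep(c("pre", "post"), each = length(freqs)),
      power = c(m_pre, m_post)
    )
    ratio[[cl]] <- data.frame(freq = freqs, state = st, stimulation = sti,
                              ratio = m_post / m_pre)
  }
  list(spectra = do.call(rbind, c(out, make.row.names = FALSE)),
       ratio = do.call(rbind, c(ratio, make.row.names = FALSE)))
}
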