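#' Digital Butterworth band-pass design
#'
#' Designs an order-`order` Butterworth band-pass filter (analog prototype,
#' low-pass to band-pass transform, bilinear transform with frequency
#' pre-warping). Note the resulting transfer function has `2 * order` poles,
#' following the usual "Nth-order Butterworth band-pass" naming used in the
#' EEG literature (and by scipy's `butter`).
#'
#' @param order prototype filter order (4 gives an 8-pole band-pass).
#' @param low,high band edges in Hz.
#' @param srate sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @export
butter_bandpass <- function(order, low, high, srate) {
  stopifnot(order >= 1, low > 0, high > low, high < srate / 2)
  ## analog Butterworth prototype: poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * (pi * (2 * k - 1) / (2 * order) + pi / 2))
  g <- 1

  ## pre-warped band edges (bilinear with fs = 2)
  fs <- 2
  warped <- 2 * fs * tan(pi * c(low, high) / srate)
  bw <- warped[2] - warped[1]
  wo <- sqrt(prod(warped))

  ## low-pass -> band-pass: each pole splits in two; order zeros at origin
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
  z_bp <- rep(0 + 0i, order)
  g <- g * bw^order

  ## bilinear transform
  fs2 <- 2 * fs
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)
  g_d <- g * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  ## pad zeros at z = -1 to match pole count
  z_d <- c(z_d, rep(-1 + 0i, length(p_d) - length(z_d)))

  b <- Re(g_d * poly_from_roots(z_d))
  a <- Re(poly_from_roots(p_d))
  list(b = b / a[1], a = a / a[1])
}

## expand prod(x - r_i) into monic polynomial coefficients
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

#' Squared-magnitude frequency response of a digital filter
#'
#' @param filt list with `b`, `a` as from [butter_bandpass()].
#' @param f frequencies in Hz at which to evaluate.
#' @param srate sampling rate in Hz.
#' @return numeric vector `|H(f)|^2`.
#' @export
filter_gain2 <- function(filt, f, srate) {
  w <- exp(-1i * 2 * pi * f / srate)
  num <- vapply(w, function(z) sum(filt$b * z^(seq_along(filt$b) - 1)), complex(1))
  den <- vapply(w, function(z) sum(filt$a * z^(seq_along(filt$a) - 1)), complex(1))
  Mod(num / den)^2
}

## steady-state initial filter state for a unit step (Gustafsson-style zi),
## mirrors scipy.signal.lfilter_zi
lfilter_zi <- function(b, a) {
  n <- length(a)
  stopifnot(length(b) == n, n >= 2)
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[2:n] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

## direct-form-II-transposed IIR filter, vectorized across columns of x
## zi: (length(a)-1) x ncol(x) initial state, or NULL for zero state
iir_filter <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  no <- length(a) - 1
  z <- if (is.null(zi)) matrix(0, no, m) else zi
  y <- matrix(0, n, m)
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    if (no > 1) {
      for (k in seq_len(no - 1)) {
        z[k, ] <- b[k + 1] * xt + z[k + 1, ] - a[k + 1] * yt
      }
    }
    z[no, ] <- b[no + 1] * xt - a[no + 1] * yt
    y[t, ] <- yt
  }
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-reflection edge padding and
#' steady-state initial conditions, so that the net phase response is zero
#' (the effective amplitude response is the squared magnitude response).
#' Operates column-wise on a matrix.
#'
#' @param filt list with `b`, `a`.
#' @param x numeric vector or matrix (time along rows).
#' @return filtered data, same shape as `x`.
#' @export
filtfilt <- function(filt, x) {
  b <- filt$b; a <- filt$a
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  padlen <- 3 * (length(a) - 1)
  if (n <= padlen) {
    stop("signal too short for zero-phase filtering (need > ", padlen, " samples)")
  }
  ## odd reflection about the end points
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[(n - 1):(n - padlen), , drop = FALSE]
  ext <- rbind(top, x, bot)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi = outer(zi, ext[1, ]))
  y <- y[nrow(y):1, , drop = FALSE]
  y <- iir_filter(b, a, y, zi = outer(zi, y[1, ]))
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(padlen + 1):(padlen + n), , drop = FALSE]
  if (vec) drop(out) else out
}

## filtfilt is linear in its input, so for fixed length n it is an n x n
## operator; epochs of equal length are filtered as one BLAS multiply.
## Cache keyed by coefficients and length (a handful of entries per session).
.filtfilt_ops <- new.env(parent = emptyenv())
filtfilt_operator <- function(filt, n) {
  key <- paste(n, paste(signif(c(filt$b, filt$a), 15), collapse = ","),
               sep = "|")
  op <- .filtfilt_ops[[key]]
  if (is.null(op)) {
    op <- filtfilt(filt, diag(n))
    .filtfilt_ops[[key]] <- op
  }
  op
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real-valued numeric vector.
#' @return complex vector; `Mod()` is the envelope, `Arg()` the instantaneous
#'   phase under the cosine convention (phase 0 at a signal maximum).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## remove per-column linear trend (constant + slope)
detrend_linear <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  t <- seq_len(n) - (n + 1) / 2
  slope <- crossprod(t, x) / sum(t * t)
  x - rep(colMeans(x), each = n) - outer(t, drop(slope))
}
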