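#' Trace-normalized trial covariance
#'
#' `C = X X' / n_samples`, normalized to unit trace so that trials contribute
#' equally to the class covariance regardless of their overall power.
#'
#' @param epoch channels x samples matrix (one trial, band-passed).
#' @return channels x channels symmetric matrix with trace 1.
#' @export
trial_covariance <- function(epoch) {
  stopifnot(is.matrix(epoch))
  C <- tcrossprod(epoch) / ncol(epoch)
  tr <- sum(diag(C))
  if (tr <= 0) stop("zero-variance epoch")
  C / tr
}

## shrinkage towards a scaled identity to guarantee positive definiteness
shrink_cov <- function(C, gamma) {
  d <- nrow(C)
  (1 - gamma) * C + gamma * (sum(diag(C)) / d) * diag(d)
}

#' Fit common spatial patterns contrasting two covariance matrices
#'
#' Solves the generalized eigenproblem `C_pre w = lambda (C_pre + C_post) w`
#' via whitening of the composite covariance. Filters (columns of `W`) are
#' sorted by eigenvalue descending, so the first filter maximizes the
#' pre/post power ratio (the CSP(pre) component) and the last maximizes the
#' post/pre ratio (CSP(post)). Eigenvalues lie in [0, 1]. Activation
#' patterns are `A = C_comp W (W' C_comp W)^-1` with
#' `C_comp = C_pre + C_post`.
#'
#' @param C_pre,C_post symmetric covariance matrices (same dimension).
#' @param gamma shrinkage regularization applied to each input
#'   (`C <- (1 - gamma) C + gamma (tr(C)/d) I`), default `1e-6`.
#' @return object of class `spatial_filters`: list with `W`
#'   (channels x filters), `eigenvalues`, `patterns` (channels x filters),
#'   `orientation = "pre-max"`.
#' @export
csp_fit <- function(C_pre, C_post, gamma = 1e-6) {
  stopifnot(is.matrix(C_pre), all(dim(C_pre) == dim(C_post)))
  C_pre <- shrink_cov((C_pre + t(C_pre)) / 2, gamma)
  C_post <- shrink_cov((C_post + t(C_post)) / 2, gamma)
  comp <- C_pre + C_post
  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) <= 0) {
    stop("composite covariance not positive definite after regularization")
  }
  whitener <- ec$vectors %*% diag(1 / sqrt(ec$values), nrow(comp))
  S <- crossprod(whitener, C_pre) %*% whitener
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)   # eigenvalues descending
  W <- whitener %*% es$vectors
  ## deterministic sign: largest-magnitude coefficient positive
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  patterns <- comp %*% W %*% solve(crossprod(W, comp) %*% W)
  rownames(W) <- rownames(patterns) <- rownames(C_pre)
  structure(list(W = W, eigenvalues = es$values, patterns = patterns,
                 orientation = "pre-max"),
            class = "spatial_filters")
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("<spatial_filters> %d filters (%s), lambda in [%.3f, %.3f]\n",
              ncol(x$W), x$orientation,
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

## mean trial covariance of an epochs array over the given trials;
## summation in ascending trial order (deterministic float result)
mean_trial_cov <- function(data, trials) {
  C <- 0
  for (i in trials) C <- C + trial_covariance(data[i, , ])
  C / length(trials)
}

## same, from a precomputed list of per-trial covariances
mean_cov_list <- function(covs, trials) {
  C <- 0
  for (i in trials) C <- C + covs[[i]]
  C / length(trials)
}

#' Leave-one-trial-out cross-validated CSP components
#'
#' For every trial i, CSP filters are estimated from the mean pre- and
#' post-window covariances of *all other* trials and then applied to trial
#' i's own pre and post windows, avoiding overfitting of the spatial filter
#' to the trial it is evaluated on. One component per orientation is kept:
#' the top (pre-max) filter for CSP(pre) and the bottom filter for
#' CSP(post). Per-fold filter signs are aligned so that each filter's inner
#' product with the mean filter across folds is positive.
#'
#' @param pre_epochs,post_epochs band-passed [trial_epochs()] with equal
#'   trial counts (>= 3).
#' @param gamma shrinkage passed to [csp_fit()].
#' @return list with `csp_pre`, `csp_post`: each a list of `pre` and `post`
#'   trials x samples component matrices; `filters`: per-fold filter matrices
#'   (trials x channels, one row per fold) for both orientations; `patterns`:
#'   the mean activation pattern per orientation (channels).
#' @export
loto_components <- function(pre_epochs, post_epochs, gamma = 1e-6) {
  stopifnot(inherits(pre_epochs, "trial_epochs"),
            inherits(post_epochs, "trial_epochs"))
  n <- dim(pre_epochs$data)[1]
  if (dim(post_epochs$data)[1] != n) stop("unequal trial counts")
  if (n < 3) stop("need at least 3 trials for leave-one-trial-out CSP")
  nch <- dim(pre_epochs$data)[2]
  W_pre <- W_post <- matrix(0, n, nch)
  A_pre <- A_post <- matrix(0, n, nch)
  cov_pre <- lapply(seq_len(n), function(i) trial_covariance(pre_epochs$data[i, , ]))
  cov_post <- lapply(seq_len(n), function(i) trial_covariance(post_epochs$data[i, , ]))
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    fit <- csp_fit(mean_cov_list(cov_pre, keep),
                   mean_cov_list(cov_post, keep), gamma = gamma)
    W_pre[i, ] <- fit$W[, 1]
    W_post[i, ] <- fit$W[, nch]
    A_pre[i, ] <- fit$patterns[, 1]
    A_post[i, ] <- fit$patterns[, nch]
  }
  align <- function(W, A) {
    ref <- W[1, ]
    s <- sign(drop(W %*% ref)); s[s == 0] <- 1
    m <- colMeans(W * s)
    s <- sign(drop(W %*% m)); s[s == 0] <- 1
    list(W = W * s, A = A * s)
  }
  al_pre <- align(W_pre, A_pre)
  al_post <- align(W_post, A_post)
  apply_w <- function(W, data) {
    t(sapply(seq_len(n), function(i) drop(W[i, ] %*% data[i, , ])))
  }
  list(
    csp_pre = list(pre = apply_w(al_pre$W, pre_epochs$data),
                   post = apply_w(al_pre$W, post_epochs$data)),
    csp_post = list(pre = apply_w(al_post$W, pre_epochs$data),
                    post = apply_w(al_post$W, post_epochs$data)),
    filters = list(csp_pre = al_pre$W, csp_post = al_post$W),
    patterns = list(csp_pre = colMeans(al_pre$A),
                    csp_post = colMeans(al_post$A)),
    channels = pre_epochs$channels,
    srate = pre_epochs$srate
  )
}

#' Alpha power of cross-validated CSP component signals
#'
#' @param components output of [loto_components()].
#' @param iaf individual alpha frequency (Hz).
#' @param srate sampling rate (Hz); defaults to the components' rate.
#' @param nfft FFT length.
#' @return long-format data.frame: `trial`, `window` (pre/post), `source`
#'   (CSPpre/CSPpost), `alpha_power`.
#' @export
component_alpha_power <- function(components, iaf, srate = components$srate,
                                  nfft = 512) {
  out <- list()
  map <- c(csp_pre = "CSPpre", csp_post = "CSPpost")
  for (key in names(map)) {
    src <- map[[key]]
    for (win in c("pre", "post")) {
      x <- components[[key]][[win]]
      out[[paste(src, win)]] <- data.frame(
        trial = seq_len(nrow(x)), window = win, source = src,
        alpha_power = window_alpha_power(x, iaf, srate, nfft)
      )
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Group-average activation pattern topography
#'
#' Sign-aligns per-subject activation patterns (sign of the correlation with
#' the grand mean, iterated once) and averages them into a group topography.
#'
#' @param patterns list (or matrix subjects x channels) of per-subject
#'   pattern vectors.
#' @param layout the `channel_layout` giving channel positions.
#' @return data.frame: `label`, `x`, `y`, `weight`.
#' @export
average_pattern <- function(patterns, layout) {
  P <- if (is.list(patterns)) do.call(rbind, patterns) else as.matrix(patterns)
  stopifnot(ncol(P) == nrow(layout), nrow(P) >= 1)
  m <- colMeans(P)
  s <- sign(drop(P %*% m)); s[s == 0] <- 1
  m <- colMeans(P * s)
  data.frame(label = layout$label, x = layout$x, y = layout$y, weight = m)
}
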