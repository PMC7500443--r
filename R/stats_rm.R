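## ---- repeated-measures inference from first principles -------------------
##
## Fully within-subject factorial ANOVA via an orthonormal-contrast sums-of-
## squares decomposition: for each effect e (a non-empty subset of the within
## factors) the Kronecker product of orthonormal factor contrasts maps the
## subject x cell matrix to per-subject effect scores; SS_effect is n times
## the squared norm of the mean score vector and the error stratum is the
## scatter of the scores around their mean (the subject x effect
## interaction). Greenhouse-Geisser epsilon is Box's epsilon-hat computed
## from the covariance of those scores.

## orthonormal contrast matrix (k x (k-1)); helmert, orthonormalized
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

## subject x cell matrix of means, cells fully crossed in factor-level order
cell_mean_matrix <- function(table, dv, within_factors, subject_id) {
  for (f in c(within_factors, subject_id)) {
    if (!f %in% names(table)) stop("column not found: ", f)
  }
  table[[subject_id]] <- factor(table[[subject_id]])
  for (f in within_factors) table[[f]] <- factor(table[[f]])
  levs <- lapply(table[within_factors], levels)
  ## first factor varies fastest, matching the Kronecker ordering below
  cells <- interaction(table[within_factors], lex.order = FALSE)
  agg <- tapply(table[[dv]], list(table[[subject_id]], cells), mean)
  incomplete <- apply(is.na(agg), 1, any)
  if (any(incomplete)) {
    warning(sum(incomplete), " subject(s) dropped listwise (empty cells): ",
            paste(rownames(agg)[incomplete], collapse = ", "))
    agg <- agg[!incomplete, , drop = FALSE]
  }
  if (nrow(agg) < 2) stop("need at least 2 complete subjects")
  list(Y = agg, levels = levs)
}

#' Within-subject repeated-measures ANOVA
#'
#' Classical univariate repeated-measures ANOVA for fully crossed
#' within-subject designs. The dependent variable is first aggregated to one
#' cell mean per subject x factor combination; each effect is tested against
#' its own subject x effect error stratum. The Greenhouse-Geisser correction
#' is applied to effects involving a factor with more than two levels
#' (sphericity is vacuous for purely 2-level effects, where epsilon = 1).
#' Generalized eta squared uses
#' `SS_effect / (SS_effect + sum of all error-stratum SS)`, with the
#' between-subject stratum included in the sum. Bonferroni-adjusted p-values
#' use the number of effects in the model as the family size.
#'
#' @param table long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param within_factors character vector of within-subject factor columns.
#' @param subject_id name of the subject identifier column.
#' @return object of class `rm_anova`: data.frame with one row per effect
#'   (`effect`, `df_num`, `df_den`, `epsilon`, `df_num_corr`, `df_den_corr`,
#'   `F`, `p`, `p_gg`, `p_bonferroni`, `eta_g_sq`) plus attributes
#'   `n_subjects` and `ss` (per-stratum sums of squares).
#' @export
fit_rm_anova <- function(table, dv, within_factors, subject_id = "subject") {
  cm <- cell_mean_matrix(table, dv, within_factors, subject_id)
  Y <- cm$Y
  k <- vapply(cm$levels, length, integer(1))
  n <- nrow(Y)
  m <- length(within_factors)

  ## unit vectors and orthonormal contrasts per factor; cells vary fastest in
  ## the FIRST factor (matches interaction(rev(...)) ordering above)
  Cs <- lapply(k, orthonormal_contrasts)
  us <- lapply(k, function(kk) matrix(rep(1 / sqrt(kk), kk)))

  effects <- unlist(lapply(seq_len(m), function(r) {
    utils::combn(m, r, simplify = FALSE)
  }), recursive = FALSE)

  ## subject stratum (between-subject error)
  u_all <- Reduce(kronecker, rev(us))
  s0 <- drop(Y %*% u_all)
  ss_subject <- sum((s0 - mean(s0))^2)

  ## scale-relative floor: contrast scores of a constant dv are O(eps), and
  ## ratios of such round-off must report as F = 0, not noise/noise
  tiny <- .Machine$double.eps^0.5 * max(sum(Y^2) / length(Y), .Machine$double.xmin)
  rows <- list()
  ss_err_total <- ss_subject
  for (e in effects) {
    M <- Reduce(kronecker, rev(lapply(seq_len(m), function(j) {
      if (j %in% e) Cs[[j]] else us[[j]]
    })))
    S <- Y %*% M                                    # n x df_e scores
    sbar <- colMeans(S)
    df_e <- prod(k[e] - 1)
    ss_e <- n * sum(sbar^2)
    R <- sweep(S, 2, sbar)
    ss_err <- sum(R^2)
    if (ss_e < tiny) ss_e <- 0
    if (ss_err < tiny) ss_err <- 0
    df_err <- df_e * (n - 1)
    Fval <- if (ss_err > 0) (ss_e / df_e) / (ss_err / df_err) else 0
    p <- stats::pf(Fval, df_e, df_err, lower.tail = FALSE)
    ## Box's epsilon-hat from the score covariance; vacuous for 2-level-only
    if (any(k[e] > 2)) {
      Sig <- crossprod(R) / (n - 1)
      eps <- box_epsilon(Sig)
      p_gg <- stats::pf(Fval, eps * df_e, eps * df_err, lower.tail = FALSE)
    } else {
      eps <- 1
      p_gg <- p
    }
    rows[[paste(within_factors[e], collapse = " x ")]] <- data.frame(
      effect = paste(within_factors[e], collapse = " x "),
      df_num = df_e, df_den = df_err, epsilon = eps,
      df_num_corr = eps * df_e, df_den_corr = eps * df_err,
      F = Fval, p = p, p_gg = p_gg, ss_effect = ss_e, ss_error = ss_err,
      stringsAsFactors = FALSE
    )
    ss_err_total <- ss_err_total + ss_err
  }
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$eta_g_sq <- ifelse(res$ss_effect + ss_err_total > tiny,
                         res$ss_effect / (res$ss_effect + ss_err_total), 0)
  res$p_bonferroni <- bonferroni(res$p_gg, nrow(res))
  res$ss_effect <- res$ss_error <- NULL
  attr(res, "n_subjects") <- n
  attr(res, "ss_subject") <- ss_subject
  class(res) <- c("rm_anova", "data.frame")
  res
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d subjects)\n",
              attr(x, "n_subjects")))
  df <- as.data.frame(x)
  df$df <- sprintf("(%.4g, %.4g)", df$df_num_corr, df$df_den_corr)
  df$p_disp <- ifelse(df$p_bonferroni > 0.999, ">0.999",
                      sprintf("%.4g", df$p_bonferroni))
  print(df[, c("effect", "df", "F", "p_disp", "eta_g_sq")], row.names = FALSE,
        digits = 4)
  invisible(x)
}

## Box's epsilon-hat for an already contrast-transformed covariance
box_epsilon <- function(D) {
  d <- nrow(D)
  tr <- sum(diag(D))
  denom <- d * sum(D * D)
  if (denom <= 0) return(1)
  max(min(tr^2 / denom, 1), 1 / d)
}

#' Greenhouse-Geisser epsilon from a repeated-measures covariance
#'
#' Box's epsilon-hat computed from the k x k covariance matrix of the
#' repeated measures (double-centering via orthonormal contrasts). Bounded
#' in `[1/(k-1), 1]`; equals 1 under compound symmetry and for k = 2.
#'
#' @param cell_covariance k x k covariance matrix of the k repeated measures.
#' @return epsilon estimate.
#' @export
gg_epsilon <- function(cell_covariance) {
  S <- as.matrix(cell_covariance)
  k <- nrow(S)
  if (k < 2 || ncol(S) != k) stop("need a k x k covariance with k >= 2")
  M <- orthonormal_contrasts(k)
  box_epsilon(crossprod(M, S) %*% M)
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of p-values.
#' @param m family size (>= 1).
#' @return `pmin(1, p_values * m)`.
#' @export
bonferroni <- function(p_values, m) {
  stopifnot(m >= 1)
  pmin(1, p_values * m)
}

#' Marginal means of a within-subject factor
#'
#' Per-level means of subject-cell means (each subject contributes one value
#' per level, averaged over all other factors), with a symmetric 95 percent
#' t-interval using the across-subject standard error at each level
#' (`df = n - 1`).
#'
#' @param table long-format data.frame.
#' @param dv dependent-variable column name.
#' @param factor_name within-subject factor column name.
#' @param level optional single level; default all levels.
#' @param conf confidence level.
#' @param subject_id subject identifier column name.
#' @return data.frame of class `contrast_result`: `level`, `M`, `SE`, `df`,
#'   `ci_lo`, `ci_hi`.
#' @export
marginal_means <- function(table, dv, factor_name, level = NULL, conf = 0.95,
                           subject_id = "subject") {
  cm <- cell_mean_matrix(table, dv, factor_name, subject_id)
  X <- cm$Y                                       # subjects x levels
  levs <- cm$levels[[1]]
  colnames(X) <- levs
  if (!is.null(level)) {
    if (!level %in% levs) stop("unknown level: ", level)
    levs <- level
  }
  n <- nrow(X)
  tcrit <- stats::qt(1 - (1 - conf) / 2, n - 1)
  out <- do.call(rbind, lapply(levs, function(l) {
    m <- mean(X[, l]); se <- stats::sd(X[, l]) / sqrt(n)
    data.frame(level = l, M = m, SE = se, df = n - 1,
               ci_lo = m - tcrit * se, ci_hi = m + tcrit * se)
  }))
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Linear polynomial contrast over ordered within-subject levels
#'
#' Applies centered, unit-norm linear contrast weights (for k = 4:
#' `(-3, -1, 1, 3) / sqrt(20)`) to each subject's level means and tests the
#' mean contrast score against zero. Two error models are available:
#' `"subject"` (default) is a one-sample t on the per-subject scores with
#' `df = n - 1`; `"pooled"` uses the factor-by-subject interaction stratum
#' with `df = (n - 1)(k - 1)` (the error model implied by a contrast on the
#' pooled repeated-measures error term).
#'
#' @param cell_means subjects x k matrix of per-subject level means
#'   (columns in level order, k >= 3).
#' @param error `"subject"` or `"pooled"`.
#' @param conf confidence level for the estimate's interval.
#' @return data.frame of class `contrast_result`: `estimate`, `SE`, `t`,
#'   `df`, `p`, `ci_lo`, `ci_hi`, `degenerate` (TRUE when the contrast SE is
#'   zero, in which case `t` is `Inf`-signed and `p` is 0).
#' @export
linear_contrast <- function(cell_means, error = c("subject", "pooled"),
                            conf = 0.95) {
  error <- match.arg(error)
  X <- as.matrix(cell_means)
  k <- ncol(X); n <- nrow(X)
  if (k < 3) stop("need at least 3 levels for a linear contrast")
  w <- seq_len(k) - (k + 1) / 2
  w <- w / sqrt(sum(w^2))
  L <- drop(X %*% w)
  est <- mean(L)
  if (error == "subject") {
    se <- stats::sd(L) / sqrt(n)
    df <- n - 1
  } else {
    R <- X - rowMeans(X) - rep(colMeans(X), each = n) + mean(X)
    ms <- sum(R^2) / ((n - 1) * (k - 1))
    se <- sqrt(ms / n)                            # unit-norm weights
    df <- (n - 1) * (k - 1)
  }
  degenerate <- se == 0
  tval <- if (degenerate) sign(est) * Inf else est / se
  p <- if (degenerate) 0 else 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  out <- data.frame(estimate = est, SE = se, t = tval, df = df, p = p,
                    ci_lo = est - tcrit * se, ci_hi = est + tcrit * se,
                    degenerate = degenerate)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Cohen's d for paired samples (d_z)
#'
#' `d_z = mean(a - b) / sd(a - b)`.
#'
#' @param paired_a,paired_b paired numeric vectors of equal length (>= 2).
#' @return effect size d_z.
#' @export
cohens_d <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 2)
  d <- paired_a - paired_b
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(0)          # identical samples: no effect
    stop("zero standard deviation of the paired differences")
  }
  mean(d) / s
}
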