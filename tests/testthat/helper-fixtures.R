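## small configurations and hand-rolled oracles shared across tests

## compact session: 2 blocks x 10 trials, short rest -- seconds to simulate
small_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, n_blocks = 2,
                                 trials_per_block = 10, rest_dur = 20),
                            list(...))
  do.call(simulation_config, args)
}

## brute-force DFT power at bin k (0-based): |sum_n x[n] e^{-i 2 pi k n / N}|^2 / N
dft_power_oracle <- function(x, nfft) {
  n <- seq_along(x) - 1
  sapply(seq_len(nfft) - 1, function(k) {
    Mod(sum(x * exp(-2i * pi * k * n / nfft)))^2 / nfft
  })
}

## closed-form percent modulation of mean squared envelope over a post window
## [t1, t2] s after stimulation offset, for suppression 1 - d exp(-t / tau)
envelope_modulation_oracle <- function(depth, tau_ms, t1 = 0.1, t2 = 0.6) {
  tau <- tau_ms / 1000
  dur <- t2 - t1
  int <- dur - 2 * depth * tau * (exp(-t1 / tau) - exp(-t2 / tau)) +
    depth^2 * tau / 2 * (exp(-2 * t1 / tau) - exp(-2 * t2 / tau))
  (int / dur - 1) * 100
}

## synthetic band-passed epochs with a rank-1 source in white noise:
## returns trials x channels x samples array
source_epochs <- function(n_trials, pattern, amp, noise_sd = 0.3,
                          srate = 500, n_samples = 250, freq = 10) {
  nch <- length(pattern)
  a <- array(0, c(n_trials, nch, n_samples))
  for (i in seq_len(n_trials)) {
    src <- amp * sin(2 * pi * freq * seq_len(n_samples) / srate +
                       stats::runif(1, 0, 2 * pi))
    a[i, , ] <- outer(pattern, src) +
      noise_sd * matrix(stats::rnorm(nch * n_samples), nch)
  }
  a
}

as_epochs <- function(a, window = "pre", srate = 500) {
  trial_epochs(a, window, c(0, dim(a)[3] / srate * 1000), srate,
               paste0("ch", seq_len(dim(a)[2])))
}

circ_deg <- function(x) abs(tacsloop::wrap_phase(x)) * 180 / pi

## explicit sums-of-squares oracle for fully within-subject factorial ANOVA:
## every SS term computed by direct inclusion-exclusion summation over the
## design formulae, independent of the contrast-matrix implementation under
## test
rm_anova_oracle <- function(df, dv, factors, subject) {
  df[[subject]] <- factor(df[[subject]])
  for (f in factors) df[[f]] <- factor(df[[f]])
  agg <- aggregate(df[[dv]], df[c(subject, factors)], mean)
  names(agg)[ncol(agg)] <- "y"
  grand <- mean(agg$y)
  n <- nlevels(agg[[subject]])
  ## per-row marginal mean over the given columns
  marg <- function(cols) {
    if (length(cols) == 0) return(rep(grand, nrow(agg)))
    key <- interaction(agg[cols], drop = TRUE)
    mu <- tapply(agg$y, key, mean)
    as.numeric(mu[key])
  }
  ## highest-order interaction estimate among `cols` by inclusion-exclusion
  ie_est <- function(cols) {
    est <- rep(0, nrow(agg))
    for (r in 0:length(cols)) {
      for (sset in utils::combn(cols, r, simplify = FALSE)) {
        est <- est + (-1)^(length(cols) - r) * marg(sset)
      }
    }
    est
  }
  effects <- unlist(lapply(seq_along(factors), function(r) {
    utils::combn(factors, r, simplify = FALSE)
  }), recursive = FALSE)
  out <- lapply(effects, function(e) {
    ss_e <- sum(ie_est(e)^2)
    ss_int <- sum(ie_est(c(subject, e))^2)
    df_e <- prod(vapply(e, function(f) nlevels(agg[[f]]) - 1, 0))
    df_err <- df_e * (n - 1)
    data.frame(effect = paste(e, collapse = " x "),
               F = (ss_e / df_e) / (ss_int / df_err),
               df_num = df_e, df_den = df_err, ss_effect = ss_e)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

make_rm_data <- function(n_subj, levels_list, effect = 0, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(levels_list, stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
    d <- cells
    d$subject <- s
    d$y <- rnorm(nrow(cells)) + rnorm(1)        # cell noise + subject offset
    d
  }))
  if (effect != 0) {
    f1 <- df[[names(levels_list)[1]]]
    df$y <- df$y + effect * (f1 == sort(unique(f1))[1])
  }
  df
}


## slim per-subject offline chain for cohort-level Monte-Carlo: band-passed
## windows -> leave-one-trial-out CSP -> per-trial CSP(pre) alpha power with
## condition labels (the ingredients of the TIME x STATE x STIMULATION model)
csp_power_rows <- function(session, iaf) {
  iv <- epoch_intervals(session$recording, session$events)
  pre_w <- tacsloop:::trim_interval(bandpass_5_40(iv$pre), -600, -100, "pre")
  post_w <- tacsloop:::trim_interval(bandpass_5_40(iv$post), 100, 600, "post")
  comp <- loto_components(pre_w, post_w)
  pp <- component_alpha_power(comp, iaf)
  pp <- pp[pp$source == "CSPpre", ]
  meta <- data.frame(trial = seq_len(nrow(session$events)),
                     state = session$events$state,
                     stimulation = session$events$stimulation)
  merge(pp, meta, by = "trial")
}

## p-value of the TIME (window) main effect at the CSP(pre) source for one
## simulated cohort
csp_time_pvalue <- function(cfg, seed, use_rest_iaf = TRUE) {
  cohort <- simulate_cohort(cfg, seed = seed)
  tab <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    iaf <- if (use_rest_iaf) estimate_iaf(s$rest_ec, s$rest_eo)$iaf
           else s$ground_truth$iaf
    cbind(subject = i, csp_power_rows(s, iaf))
  }))
  fit <- fit_rm_anova(tab, "alpha_power",
                      c("window", "state", "stimulation"), "subject")
  fit$p[fit$effect == "window"]
}
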