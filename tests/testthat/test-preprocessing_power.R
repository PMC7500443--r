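test_that("analysis windows are 500 ms, trial-complete and exclude stimulation", {
  cfg <- small_config()
  s <- simulate_subject(cfg, seed = 1)
  w <- epoch_windows(s$recording, s$events)
  expect_equal(dim(w$pre$data), c(nrow(s$events), 31, 250))
  expect_equal(dim(w$post$data), c(nrow(s$events), 31, 250))
  ## extracted index sets never intersect the stimulation intervals
  ev <- s$events
  sr <- s$recording$srate
  for (i in c(1, nrow(ev))) {
    pre_idx <- ev$stim_onset[i] + round(-0.6 * sr):(round(-0.1 * sr) - 1)
    post_idx <- ev$stim_offset[i] + round(0.1 * sr):(round(0.6 * sr) - 1)
    stim_idx <- ev$stim_onset[i]:(ev$stim_offset[i] - 1)
    expect_length(intersect(c(pre_idx, post_idx), stim_idx), 0)
  }
  ## window content matches a direct slice of the recording (0-based indexing)
  i <- 3
  a <- ev$stim_onset[i] - 300          # -600 ms
  expect_equal(w$pre$data[i, , ],
               unname(s$recording$data[, (a + 1):(a + 250)]))
  ## out-of-bounds windows name the trial
  ev_bad <- ev
  ev_bad$stim_onset[2] <- 10
  expect_error(epoch_windows(s$recording, ev_bad), "trial 2")
})

test_that("band-pass filter has the designed frequency response, zero-phase", {
  filt <- butter_bandpass(4, 5, 40, 500)
  ## response oracle: evaluate |H|^2; filtfilt applies it twice
  g10 <- filter_gain2(filt, 10, 500)   # |H|^2 = zero-phase amplitude gain
  g1 <- filter_gain2(filt, 1, 500)
  expect_true(g10 >= 0.95 && g10 <= 1)
  expect_lt(g1, 0.1)
  ## measured amplitude gain of a 10 Hz sinusoid through the epochs API
  t <- (0:499) / 500
  x <- sin(2 * pi * 10 * t)
  ep <- as_epochs(array(x, c(1, 1, 500)))
  y <- drop(bandpass_5_40(ep)$data)
  mid <- 100:400
  meas <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_equal(meas, g10, tolerance = 0.01)
  ## 1 Hz attenuated
  x1 <- sin(2 * pi * 1 * t)
  y1 <- drop(bandpass_5_40(as_epochs(array(x1, c(1, 1, 500))))$data)
  expect_lt(sqrt(mean(y1[mid]^2) / mean(x1[mid]^2)), 0.1)
  ## zero-phase: cross-correlation of in/out peaks at lag 0
  cc <- ccf(y[mid], x[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("window_alpha_power equals the brute-force DFT oracle", {
  t <- (0:249) / 500
  x <- sin(2 * pi * 10 * t)
  p <- window_alpha_power(x, 10, 500, nfft = 512)
  ## oracle: explicit DFT sum on the detrended, zero-padded window
  xd <- x - mean(x) - (t - mean(t)) * sum((x - mean(x)) * (t - mean(t))) /
    sum((t - mean(t))^2)
  P <- dft_power_oracle(c(xd, rep(0, 262)), 512)
  freqs <- (0:511) * 500 / 512
  keep <- freqs >= 9 & freqs <= 11 & freqs <= 250
  expect_equal(p, mean(P[keep]), tolerance = 1e-10)
  ## all-zero window
  expect_equal(window_alpha_power(rep(0, 250), 10, 500), 0)
  ## pure ramp: detrending removes it
  ramp <- seq(0, 5, length.out = 250)
  p_ramp <- window_alpha_power(ramp, 10, 500)
  p_ramp_raw <- mean(dft_power_oracle(c(ramp, rep(0, 262)), 512)[keep])
  expect_lt(p_ramp, 0.01 * p_ramp_raw)
  ## DC offsets are invisible
  expect_equal(window_alpha_power(x + 100, 10, 500), p, tolerance = 1e-8)
  expect_error(window_alpha_power(rnorm(600), 10, 500), "exceeds nfft")
})

test_that("Parseval sanity holds for the detrended window", {
  set.seed(4)
  x <- rnorm(250)
  nfft <- 512
  xd <- drop(tacsloop:::detrend_linear(matrix(x)))
  P <- Mod(stats::fft(c(xd, rep(0, nfft - 250))))^2 / nfft
  expect_equal(sum(P), sum(xd^2), tolerance = 1e-8)
})

test_that("POz and POC sources aggregate as specified", {
  layout <- build_montage()
  set.seed(5)
  ## identical data on all channels -> POC = POz
  x <- matrix(rnorm(3 * 250), 3)
  a <- array(0, c(3, 31, 250))
  for (ch in 1:31) a[, ch, ] <- x
  ep <- trial_epochs(a, "pre", c(-600, -100), 500, layout$label)
  tab <- aggregate_sources(ep, layout, 10)
  expect_equal(tab$alpha_power[tab$source == "POC"],
               tab$alpha_power[tab$source == "POz"])
  ## alpha only on POz -> POC = POz / 9
  b <- array(0, c(2, 31, 250))
  b[, match("POz", layout$label), ] <- matrix(sin(2 * pi * 10 * (0:249) / 500),
                                              2, 250, byrow = TRUE)
  tab2 <- aggregate_sources(trial_epochs(b, "pre", c(-600, -100), 500,
                                         layout$label), layout, 10)
  expect_equal(tab2$alpha_power[tab2$source == "POC"],
               tab2$alpha_power[tab2$source == "POz"] / 9)
  ## random data: POC equals the hand-computed mean of 9 single-channel calls
  d <- array(rnorm(4 * 31 * 250), c(4, 31, 250))
  ep3 <- trial_epochs(d, "post", c(100, 600), 500, layout$label)
  tab3 <- aggregate_sources(ep3, layout, 10)
  manual <- rowMeans(sapply(match(poc_channels(), layout$label), function(ch) {
    window_alpha_power(d[, ch, ], 10, 500)
  }))
  expect_equal(tab3$alpha_power[tab3$source == "POC"], manual)
  ## missing channel named in the error
  bad_layout <- layout[layout$label != "PO3", ]
  ep_bad <- trial_epochs(d[, 1:30, ], "pre", c(-600, -100), 500,
                         bad_layout$label)
  expect_error(aggregate_sources(ep_bad, bad_layout, 10), "PO3")
})

test_that("percent modulation is exact arithmetic with guarded denominator", {
  expect_equal(percent_modulation(4, 3), -25)
  expect_equal(percent_modulation(2, 2), 0)
  expect_equal(percent_modulation(1.25, 1.5), 20)
  expect_equal(percent_modulation(c(1, 2), c(2, 1)), c(100, -50))
  expect_error(percent_modulation(0, 1), "positive")
})

test_that("time bins overlap by 400 ms and bin 1 equals the standard post window", {
  cfg <- small_config()
  s <- simulate_subject(cfg, seed = 6)
  tb <- timebin_windows(s$recording, s$events)
  expect_named(tb, c("pre", paste0("post_bin", 1:4)))
  for (nm in names(tb)) expect_equal(dim(tb[[nm]]$data)[3], 250)
  w <- epoch_windows(s$recording, s$events)
  expect_equal(tb$post_bin1$data, w$post$data)
  expect_equal(tb$pre$data, w$pre$data)
  ## consecutive bins share exactly 400 ms = 200 samples
  expect_equal(tb$post_bin1$data[, , 51:250], tb$post_bin2$data[, , 1:200])
  expect_equal(tb$post_bin3$data[, , 51:250], tb$post_bin4$data[, , 1:200])
})

test_that("mean spectra average per condition and form post/pre ratios", {
  cfg <- small_config()
  s <- simulate_subject(cfg, seed = 8)
  w <- epoch_windows(s$recording, s$events)
  poz <- match("POz", s$recording$layout$label)
  pre <- w$pre$data[, poz, ]
  ## identical pre and post -> ratio identically 1
  ms <- mean_spectra(pre, pre, s$events, 500)
  expect_equal(ms$ratio$ratio, rep(1, nrow(ms$ratio)))
  expect_equal(sort(unique(paste(ms$spectra$state, ms$spectra$stimulation))),
               c("EC anti", "EC in", "EO anti", "EO in"))
  ## averaging a single trial returns that trial's spectrum
  ev1 <- s$events[1, ]
  one <- mean_spectra(pre[1, , drop = FALSE], pre[1, , drop = FALSE], ev1, 500)
  p1 <- dft_power_oracle(
    c(drop(tacsloop:::detrend_linear(matrix(pre[1, ]))), rep(0, 262)), 512)
  expect_equal(one$spectra$power[one$spectra$window == "pre"],
               p1[1:257], tolerance = 1e-8)
  ## suppression generator: ratio minimum within IAF +/- 2 Hz. Deep, slow
  ## suppression for a pronounced dip; moderate alpha amplitude so that
  ## rectangular-window leakage of the coherent alpha line stays below the
  ## off-band noise floor (otherwise every bin inherits the alpha ratio)
  cfg2 <- simulation_config(n_blocks = 4, trials_per_block = 50, rest_dur = 20,
                            alpha_amp_ec = 20, alpha_amp_eo = 10,
                            suppression_depth = 0.6, suppression_tau = 400,
                            noise_amp = 8, alpha_env_sd = 0)
  s2 <- simulate_subject(cfg2, seed = 13)
  w2 <- epoch_windows(s2$recording, s2$events)
  poz2 <- match("POz", s2$recording$layout$label)
  ms2 <- mean_spectra(w2$pre$data[, poz2, ], w2$post$data[, poz2, ],
                      s2$events, 500)
  rat <- aggregate(ratio ~ freq, ms2$ratio, mean)
  in_range <- rat$freq >= 4 & rat$freq <= 30        # away from DC/detrend bins
  f_min <- rat$freq[in_range][which.min(rat$ratio[in_range])]
  expect_lt(abs(f_min - s2$ground_truth$iaf), 2)
  expect_error(mean_spectra(pre[0, , drop = FALSE], pre[0, , drop = FALSE],
                            s$events[0, ], 500), "empty condition")
  ## a condition with no trials errors too
  sub <- s$events$state == "EO"
  expect_error(mean_spectra(pre[sub, ], pre[sub, ], s$events, 500))
})

test_that("null generator: per-condition modulation is stationary", {
  ## one full-size session (500 trials) without suppression. The +/- 3 SEM
  ## bound applies to the channel sources; for CSP components the per-trial
  ## post/pre ratio has no finite mean under the null (the component is an
  ## arbitrary noise direction with ~2-DoF band-power denominators), so
  ## centrality is asserted via the median and the null TIME calibration is
  ## covered at the power level in the acceptance suite.
  cfg <- simulation_config(rest_dur = 20, suppression_depth = 0)
  s <- simulate_subject(cfg, seed = 2)
  an <- analyze_subject(s$recording, s$events,
                        estimate_iaf(s$rest_ec, s$rest_eo)$iaf)
  for (src in c("POz", "POC")) {
    for (cond in unique(paste(an$modulation$state, an$modulation$stimulation))) {
      m <- an$modulation$modulation[an$modulation$source == src &
             paste(an$modulation$state, an$modulation$stimulation) == cond]
      sem <- sd(m) / sqrt(length(m))
      expect_lt(abs(mean(m)), 3 * sem,
                label = sprintf("|mean mod| (%s, %s)", src, cond))
    }
  }
  for (src in c("CSPpre", "CSPpost")) {
    m <- an$modulation$modulation[an$modulation$source == src]
    expect_lt(abs(median(m)), 25, label = paste("median mod", src))
  }
})
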