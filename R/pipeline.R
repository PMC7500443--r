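#' Full analysis configuration
#'
#' Extends [simulation_config()] with the offline-analysis options.
#'
#' @param sim a [simulation_config()].
#' @param nfft FFT length for window power.
#' @param filter_band,filter_order offline band-pass settings.
#' @param csp_gamma CSP shrinkage regularization.
#' @param latency simulated closed-loop transduction delay (s).
#' @param seed master seed for the run.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), nfft = 512,
                       filter_band = c(5, 40), filter_order = 4,
                       csp_gamma = 1e-6, latency = 0, seed = 1,
                       out_dir = "tacsloop_run") {
  stopifnot(nfft > 0, length(filter_band) == 2, filter_band[1] > 0,
            filter_band[2] > filter_band[1], filter_order >= 1,
            csp_gamma >= 0, csp_gamma < 1, latency >= 0)
  validate_config(sim)
  structure(list(sim = sim, nfft = nfft, filter_band = filter_band,
                 filter_order = filter_order, csp_gamma = csp_gamma,
                 latency = latency, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' Minimal YAML-style `key: value` format (one pair per line, `#` comments).
#' Keys are the arguments of [simulation_config()] and [run_config()];
#' two-element ranges are written as comma-separated pairs.
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl(":", lines)])
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  kv <- stats::setNames(lapply(vals, parse_val), keys)
  sim_args <- intersect(names(kv), names(formals(simulation_config)))
  run_args <- intersect(names(kv), setdiff(names(formals(run_config)), "sim"))
  unknown <- setdiff(names(kv), c(sim_args, run_args))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim <- do.call(simulation_config, kv[sim_args])
  do.call(run_config, c(list(sim = sim), kv[run_args]))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[setdiff(names(config), "out_dir")], file = tmp)
  unname(tools::md5sum(tmp))
}

## write a TSV with a provenance header comment
write_result_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Offline analysis of one session
#'
#' Runs the complete per-subject offline chain: extract the 1-s pre/post
#' intervals, zero-phase band-pass filter them, trim to the 500 ms analysis
#' windows, compute POz and POC alpha power, fit leave-one-trial-out CSP
#' components and their alpha power, per-trial percent modulations, and the
#' four overlapping post-stimulation time-bin modulations for the CSP(pre)
#' component.
#'
#' @param recording an [eeg_recording()].
#' @param events matching `event_table`.
#' @param iaf the subject's individual alpha frequency (Hz).
#' @param nfft,filter_band,filter_order,csp_gamma analysis options, see
#'   [run_config()].
#' @return list with `power` (long PowerTable rows: subject columns added by
#'   the caller), `modulation`, `timebins` (CSP(pre) per-trial bin
#'   modulations), `csp_patterns`, `spectra` (CSP(pre) condition spectra).
#' @export
analyze_subject <- function(recording, events, iaf, nfft = 512,
                            filter_band = c(5, 40), filter_order = 4,
                            csp_gamma = 1e-6) {
  layout <- recording$layout
  iv <- epoch_intervals(recording, events)
  pre_f <- bandpass_5_40(iv$pre, band = filter_band, order = filter_order)
  post_f <- bandpass_5_40(iv$post, band = filter_band, order = filter_order)
  pre_w <- trim_interval(pre_f, -600, -100, "pre")
  post_w <- trim_interval(post_f, 100, 600, "post")

  pow <- rbind(aggregate_sources(pre_w, layout, iaf, nfft),
               aggregate_sources(post_w, layout, iaf, nfft))

  comp <- loto_components(pre_w, post_w, gamma = csp_gamma)
  pow <- rbind(pow, component_alpha_power(comp, iaf, nfft = nfft))

  meta <- data.frame(trial = seq_len(nrow(events)), block = events$block,
                     state = events$state, stimulation = events$stimulation)
  pow <- merge(pow, meta, by = "trial", sort = FALSE)

  wide <- merge(pow[pow$window == "pre", c("trial", "source", "alpha_power")],
                pow[pow$window == "post", c("trial", "source", "alpha_power")],
                by = c("trial", "source"), suffixes = c("_pre", "_post"))
  wide$modulation <- percent_modulation(wide$alpha_power_pre,
                                        wide$alpha_power_post)
  modulation <- merge(wide[, c("trial", "source", "modulation")], meta,
                      by = "trial", sort = FALSE)

  ## time-bin analysis on the CSP(pre) component: apply each trial's fold
  ## filter to the four post bins (filtered full post interval covers
  ## +100..+900 ms except bin 4's tail; re-extract from the recording)
  tb <- timebin_windows(recording, events)
  tb_f <- lapply(tb, bandpass_5_40, band = filter_band, order = filter_order)
  W <- comp$filters$csp_pre
  pre_comp <- comp$csp_pre$pre
  pre_pow <- window_alpha_power(pre_comp, iaf, recording$srate, nfft)
  timebins <- do.call(rbind, lapply(1:4, function(k) {
    ep <- tb_f[[paste0("post_bin", k)]]
    x <- t(sapply(seq_len(nrow(events)), function(i) {
      drop(W[i, ] %*% ep$data[i, , ])
    }))
    data.frame(trial = seq_len(nrow(events)), timebin = paste0("bin", k),
               modulation = percent_modulation(
                 pre_pow, window_alpha_power(x, iaf, recording$srate, nfft)))
  }))
  timebins <- merge(timebins, meta, by = "trial", sort = FALSE)

  spectra <- mean_spectra(comp$csp_pre$pre, comp$csp_pre$post, events,
                          recording$srate, nfft)

  list(power = pow, modulation = modulation, timebins = timebins,
       csp_patterns = comp$patterns, spectra = spectra)
}

#' Run the full simulate-analyze pipeline
#'
#' Simulates a cohort, runs the closed-loop stage and the per-subject
#' offline analysis, assembles cohort-level tables, fits the three
#' repeated-measures models (TIME x STATE x STIMULATION per source on alpha
#' power; BLOCK x STATE x STIMULATION and TIMEBIN x STATE x STIMULATION on
#' CSP(pre) modulation), compares recovered suppression against the
#' generator's ground truth, and writes all result tables plus a JSON
#' manifest to `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param write_recordings also write per-subject BrainVision files
#'   (default FALSE; they are large).
#' @return the run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, write_recordings = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()["elapsed"]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage_time <- c()
  tick <- function(name) {
    now <- proc.time()["elapsed"]
    stage_time[[name]] <<- round(now - t0, 3)
    t0 <<- now
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_result_tsv(df, path, hash)
    files <<- c(files, path)
  }

  ## subjects are simulated, analyzed and discarded one at a time: a
  ## full-size recording is ~220 MB, so a materialized 20-subject cohort
  ## would not fit the memory budget
  n_subj <- config$sim$n_subjects
  layout <- build_montage()
  tick("setup")

  per_subj <- vector("list", n_subj)
  gt_recovery <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    s <- simulate_subject(config$sim, subject_id = i,
                          seed = cohort_seed(config$seed, i))
    iaf_est <- estimate_iaf(s$rest_ec, s$rest_eo)
    cl <- run_closed_loop_session(s$recording, s$events, iaf_est$iaf,
                                  latency = config$latency,
                                  ground_truth = s$ground_truth)
    rec <- if (config$sim$artifact_gain > 0) {
      inject_stim_artifact(s$recording, s$events, cl$waveforms,
                           config$sim$artifact_gain)
    } else {
      s$recording
    }
    an <- analyze_subject(rec, s$events, iaf_est$iaf, nfft = config$nfft,
                          filter_band = config$filter_band,
                          filter_order = config$filter_order,
                          csp_gamma = config$csp_gamma)
    an$iaf_est <- iaf_est
    an$closed_loop_log <- cl$log
    per_subj[[i]] <- an

    ## ground-truth recovery: measured CSP(pre) modulation vs the closed-form
    ## prediction from the generator's suppression envelope
    mod_meas <- mean(an$modulation$modulation[an$modulation$source == "CSPpre"])
    gt_recovery[[i]] <- data.frame(
      subject = i, iaf_true = s$ground_truth$iaf, iaf_est = iaf_est$iaf,
      modulation_measured = mod_meas,
      modulation_predicted = predicted_modulation(
        s$ground_truth$suppression_depth, s$ground_truth$suppression_tau)
    )
    if (write_recordings) {
      stem <- file.path(config$out_dir, sprintf("subject%02d", i))
      write_brainvision(rec, stem, s$events)
      write_events_tsv(s$events, paste0(stem, "_events.tsv"))
      write_ground_truth(s$ground_truth, paste0(stem, "_ground_truth.json"))
      files <- c(files, paste0(stem, c(".vhdr", ".vmrk", ".eeg",
                                       "_events.tsv", "_ground_truth.json")))
    }
  }
  tick("analyze")

  power <- do.call(rbind, lapply(seq_along(per_subj), function(i) {
    cbind(subject = i, per_subj[[i]]$power)
  }))
  modulation <- do.call(rbind, lapply(seq_along(per_subj), function(i) {
    cbind(subject = i, per_subj[[i]]$modulation)
  }))
  timebins <- do.call(rbind, lapply(seq_along(per_subj), function(i) {
    cbind(subject = i, per_subj[[i]]$timebins)
  }))
  emit(power, "power_table.tsv")
  emit(modulation, "modulation_table.tsv")
  emit(timebins, "timebin_table.tsv")

  anova_main <- do.call(rbind, lapply(c("CSPpost", "CSPpre", "POC", "POz"),
    function(src) {
      res <- fit_rm_anova(power[power$source == src, ], "alpha_power",
                          c("window", "state", "stimulation"), "subject")
      cbind(source = src, as.data.frame(res))
    }))
  emit(anova_main, "anova_main.tsv")

  ## BLOCK is confounded with STATE in the raw schedule (each block has one
  ## state); the crossed time-course factor is the within-state block
  ## ordinal (pair index of consecutive EO/EC blocks)
  mod_csp <- modulation[modulation$source == "CSPpre", ]
  mod_csp$block_ws <- ceiling(mod_csp$block / 2)
  block_factors <- if (length(unique(mod_csp$block_ws)) > 1) {
    c("block_ws", "state", "stimulation")
  } else {
    c("state", "stimulation")
  }
  anova_block <- as.data.frame(fit_rm_anova(
    mod_csp, "modulation", block_factors, "subject"))
  emit(anova_block, "anova_block.tsv")
  tb_csp <- timebins
  anova_timebin <- as.data.frame(fit_rm_anova(
    tb_csp, "modulation", c("timebin", "state", "stimulation"), "subject"))
  emit(anova_timebin, "anova_timebin.tsv")

  ## linear contrast over the four time bins (subject x bin cell means)
  tb_cells <- tapply(tb_csp$modulation, list(tb_csp$subject, tb_csp$timebin),
                     mean)
  if (nrow(tb_cells) >= 2) {
    emit(as.data.frame(linear_contrast(tb_cells)), "timebin_linear_contrast.tsv")
  }

  topo <- average_pattern(lapply(per_subj, function(s) s$csp_patterns$csp_pre),
                          layout)
  emit(topo, "csp_pre_topography.tsv")
  emit(do.call(rbind, gt_recovery), "ground_truth_recovery.tsv")
  spectra <- cbind(subject = 1,
                   per_subj[[1]]$spectra$spectra)  # exemplar subject spectra
  emit(spectra, "csp_pre_spectra_subject1.tsv")
  tick("statistics")

  manifest <- list(
    package_version = as.character(utils::packageVersion("tacsloop")),
    config_hash = hash, seed = config$seed,
    n_subjects = config$sim$n_subjects,
    stage_seconds = as.list(stage_time),
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## closed-form percent modulation implied by an exponential suppression of
## depth d and time constant tau over the +100..+600 ms post window
predicted_modulation <- function(depth, tau_ms, t1 = 0.1, t2 = 0.6) {
  tau <- tau_ms / 1000
  dur <- t2 - t1
  integral <- dur -
    2 * depth * tau * (exp(-t1 / tau) - exp(-t2 / tau)) +
    depth^2 * tau / 2 * (exp(-2 * t1 / tau) - exp(-2 * t2 / tau))
  (integral / dur - 1) * 100
}
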