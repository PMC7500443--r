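#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults reproduce the
#' experimental design the simulator emulates: 20 subjects, 31-channel EEG at
#' 500 Hz, 10 alternating eyes-open/eyes-closed blocks of 50 trials
#' (25 in-phase / 25 anti-phase, shuffled), trials of 1 s pre-stimulation,
#' 1 s stimulation and 1 s post-stimulation with a uniform 333-666 ms
#' inter-trial interval, and a transient phase-independent post-stimulation
#' alpha suppression.
#'
#' @param n_subjects number of subjects in a cohort.
#' @param srate sampling rate (Hz).
#' @param n_blocks number of blocks, alternating EO/EC.
#' @param trials_per_block trials per block (must be even: half in-phase,
#'   half anti-phase).
#' @param pre_dur,stim_dur,post_dur trial segment durations (s).
#' @param iti_range inter-trial interval range (ms), sampled uniformly.
#' @param iaf_range individual alpha frequency range (Hz); each subject's IAF
#'   is drawn uniformly from it.
#' @param alpha_amp_ec,alpha_amp_eo alpha source amplitude (uV, at the
#'   unit-norm source pattern) for eyes-closed / eyes-open blocks; EC must
#'   exceed EO.
#' @param suppression_depth fraction of the alpha envelope removed immediately
#'   after stimulation offset (0 disables the effect).
#' @param suppression_tau recovery time constant of the suppression (ms).
#'   The default 150 ms decays to under 10 percent of its initial depth
#'   within ~350 ms, i.e. the effect vanishes within roughly 400 ms.
#' @param noise_exponent spectral slope beta of the 1/f^beta background noise.
#' @param noise_amp per-channel background noise RMS (uV).
#' @param alpha_bg per-channel RMS (uV) of spatially unstructured narrow-band
#'   background alpha (distributed alpha from non-targeted generators).
#'   Default 0: its envelope decorrelates across the pre-to-post gap and
#'   thereby destabilizes per-trial power ratios; enable for spectral
#'   realism only.
#' @param alpha_env_sd log-scale SD of the slow multiplicative alpha envelope
#'   fluctuation (0 gives a deterministic envelope).
#' @param artifact_gain scale of the stimulation artifact added by
#'   [inject_stim_artifact()] (0 = no artifact).
#' @param first_state state of the first block, `"EO"` or `"EC"`.
#' @param block_break gap between blocks (s).
#' @param rest_dur duration of each simulated resting-state segment (s).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 20,
                              srate = 500,
                              n_blocks = 10,
                              trials_per_block = 50,
                              pre_dur = 1, stim_dur = 1, post_dur = 1,
                              iti_range = c(333, 666),
                              iaf_range = c(8, 13),
                              alpha_amp_ec = 80,
                              alpha_amp_eo = 40,
                              suppression_depth = 0.3,
                              suppression_tau = 150,
                              noise_exponent = 1,
                              noise_amp = 8,
                              alpha_bg = 0,
                              alpha_env_sd = 0.25,
                              artifact_gain = 0,
                              first_state = "EO",
                              block_break = 0,
                              rest_dur = 60) {
  cfg <- list(
    n_subjects = n_subjects, srate = srate, n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    pre_dur = pre_dur, stim_dur = stim_dur, post_dur = post_dur,
    iti_range = iti_range, iaf_range = iaf_range,
    alpha_amp_ec = alpha_amp_ec, alpha_amp_eo = alpha_amp_eo,
    suppression_depth = suppression_depth, suppression_tau = suppression_tau,
    noise_exponent = noise_exponent, noise_amp = noise_amp, alpha_bg = alpha_bg,
    alpha_env_sd = alpha_env_sd, artifact_gain = artifact_gain,
    first_state = first_state, block_break = block_break, rest_dur = rest_dur
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1) stop("n_subjects must be >= 1")
    if (srate <= 0) stop("srate must be positive")
    if (n_blocks < 1) stop("n_blocks must be >= 1")
    if (trials_per_block < 2 || trials_per_block %% 2 != 0) {
      stop("trials_per_block must be even (half in-phase, half anti-phase)")
    }
    if (any(c(pre_dur, stim_dur, post_dur) <= 0)) stop("durations must be > 0")
    if (length(iti_range) != 2 || diff(iti_range) < 0 || iti_range[1] < 0) {
      stop("iti_range must be an ascending non-negative pair (ms)")
    }
    if (length(iaf_range) != 2 || diff(iaf_range) < 0 || iaf_range[1] <= 0) {
      stop("iaf_range must be an ascending positive pair (Hz)")
    }
    if (!(alpha_amp_ec > alpha_amp_eo && alpha_amp_eo > 0)) {
      stop("need alpha_amp_ec > alpha_amp_eo > 0")
    }
    if (suppression_depth < 0 || suppression_depth >= 1) {
      stop("suppression_depth must lie in [0, 1)")
    }
    if (suppression_tau <= 0) stop("suppression_tau must be positive (ms)")
    if (noise_amp < 0 || alpha_bg < 0 || alpha_env_sd < 0 || artifact_gain < 0) {
      stop("noise_amp, alpha_bg, alpha_env_sd and artifact_gain must be >= 0")
    }
    if (!first_state %in% c("EO", "EC")) stop('first_state must be "EO" or "EC"')
    if (block_break < 0) stop("block_break must be >= 0")
    if (rest_dur <= 0) stop("rest_dur must be positive")
  })
  cfg
}

## evaluate expr under a temporary RNG state seeded with `seed`;
## leaves the caller's RNG untouched. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
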