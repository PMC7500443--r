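---
title: "Simulating and analyzing closed-loop phase-locked tACS-EEG experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing closed-loop phase-locked tACS-EEG experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tacsloop)
```

## The problem this package addresses

Intermittent, phase-locked transcranial alternating current stimulation
(tACS) applies a short (1 s) sinusoidal current at the subject's individual
alpha frequency (IAF), phase-aligned ("in") or phase-reversed ("anti") with
the ongoing posterior alpha rhythm measured concurrently with EEG. The
analysis question is whether the stimulation transiently modulates alpha
amplitude, whether any modulation depends on the phase relation or the
visual state (eyes open, EO, vs eyes closed, EC), and whether the effect is
visible only in individually fitted spatial components rather than in
single channels.

Because such closed-loop data sets are rarely deposited, `tacsloop` pairs
the complete offline analysis chain with a generative simulator whose
ground truth is known, so that every stage — phase estimation and
forecasting, windowed alpha power, cross-validated common spatial patterns
(CSP), repeated-measures inference — can be validated end to end.

## The simulated world

One subject's session follows the standard design: 10 blocks alternating
EO/EC (the starting state is configurable; the design only fixes the
alternation), 50 trials per block, each trial 1 s pre-stimulation, 1 s
stimulation, 1 s post-stimulation, and a uniform 333–666 ms inter-trial
interval (mean 500 ms, rounded to whole samples). 31 channels of a 10-20
cap without Oz and Cz (the stimulation sites) are sampled at 500 Hz.

The recording is a sum of:

* **One posterior alpha source.** An amplitude-modulated cosine at the
  subject's IAF (drawn uniformly from 8–13 Hz), projected through a
  unit-norm spatial pattern peaked between O1/O2/POz with per-subject
  jitter. The state-dependent amplitude is `alpha_amp_ec = 80` µV during EC
  and `alpha_amp_eo = 40` µV during EO (source units at the unit-norm
  pattern; at POz this projects to roughly 30/15 µV — a strong but
  realistic posterior alpha, and the 2:1 EC:EO ratio reproduces the robust
  STATE effect). A multiplicative log-normal envelope (`alpha_env_sd =
  0.25`) adds the waxing and waning of real alpha. The envelope's
  fluctuation is band-limited below 0.05 Hz: posterior alpha power has
  long-range autocorrelation, and an envelope that decorrelated between the
  pre- and post-stimulation windows of the same trial (1.6 s apart) would
  bias per-trial post/pre power ratios upward purely through noisy
  denominators — a generator artifact, not physiology.
* **1/f background noise**, independent per channel (`noise_amp = 8` µV
  RMS, spectral exponent 1), generated by frequency-domain shaping of white
  Gaussian noise. The broadband background sets the trace share of the
  alpha source in the covariance matrices that CSP contrasts; both a
  source-saturated and a noise-saturated world destroy the CSP contrast
  (see below), and the default puts the EO/EC source share at roughly
  0.3/0.6.
* **Optionally** (`alpha_bg`, default 0), spatially unstructured
  narrow-band background alpha; and a stimulation artifact
  (`inject_stim_artifact()`) confined to the stimulation interval with a
  posterior-peaked linear topography, scaled relative to the neural RMS
  (real tACS artifacts are orders of magnitude above EEG).

**Ground-truth effect.** Immediately after each stimulation offset, the
source envelope is multiplied by `1 - d * exp(-t / tau)` with
`suppression_depth d = 0.3` and `suppression_tau = 150` ms by default: the
suppression is deepest right after stimulation and has decayed to under 10
percent of its initial depth within ~350 ms, i.e. it vanishes on the
400 ms scale. It is identical for in- and anti-phase trials, making the
ground truth phase-independent by construction. The closed-form percent
modulation it implies over the +100..+600 ms analysis window,
$100\,(\frac{1}{T}\int (1 - d e^{-t/\tau})^2 dt - 1) \approx -8.6\%$,
is the recovery target for the generator tests.

What the generator does **not** emulate: volume conduction and realistic
forward models, eye blinks and muscle artifacts, transcutaneous
co-stimulation, non-stationary IAF drift. A green test therefore
establishes correctness of the analysis machinery on a compliant world,
not robustness to every pathology of real EEG.

## The closed-loop stage

The online side estimates the IAF by contrasting EC against EO resting
spectra at POz (mean FFT power over 1-s segments, 1 Hz resolution; the
estimate is the frequency in 7–13 Hz with the largest EC−EO difference),
then per trial:

1. extracts the final 250 ms of POz data before stimulation onset;
2. estimates the instantaneous alpha phase at the segment's final sample;
3. forecasts the phase across the transduction latency as
   $\hat\varphi = \varphi + 2\pi f_\mathrm{IAF}\,\Delta t$, wrapped to
   $(-\pi, \pi]$;
4. synthesizes a 1 s, 1 mA peak-to-peak cosine at the IAF with onset phase
   $\hat\varphi$ ("in") or $\hat\varphi + \pi$ ("anti").

**Phase estimation numerics.** The textbook recipe — band-pass the padded
segment with a 4th-order Butterworth at IAF ± 2 Hz and read the Hilbert
phase at the end — is biased at exactly the sample that matters: a ± 2 Hz
band-pass rings for ~80 ms, a substantial fraction of the 250 ms window,
and the mirror continuation pulls the endpoint phase toward even symmetry
by up to ~17°. `estimate_phase()` therefore (i) extends the segment into
its even periodic continuation `c(x, rev(x))` and applies the *squared
magnitude response* of the Butterworth circularly in the frequency domain —
the zero-phase response of forward-backward filtering with no finite-length
transient at all; (ii) widens the band to IAF ± 3 Hz; (iii) back-rotates
the interior (central 20–80 %) instantaneous phases to the final sample at
the IAF and averages them circularly. Residual bias on noiseless sinusoids
is below 2°, and at 10 dB SNR the absolute error stays below 20° in ~100 %
of draws. The cosine convention (phase 0 at a maximum) defines what
"in-phase" means throughout.

## The offline analysis chain

Per trial, the full 1-s pre- and post-stimulation intervals are extracted
and band-pass filtered (5–40 Hz, 4th-order Butterworth, forward–backward;
the filter design is implemented in the package and matches the reference
`scipy.signal.butter` coefficients to machine precision). The analysis
windows then trim 100 ms from each side that touches the stimulation:
pre = −600..−100 ms relative to onset, post = +100..+600 ms relative to
offset, so filter edge effects and residual artifact fall into the trimmed
margins. Windows are linearly detrended, zero-padded to 512 samples,
Fourier transformed (power `|X|²/nfft`, no one-sided doubling — the
convention cancels from every ratio and contrast used downstream), and
averaged over the bins whose center frequency lies in IAF ± 1 Hz inclusive
on the 500/512 ≈ 0.977 Hz grid.

Four signal sources enter the statistics: the single channel POz; the
parieto-occipital cluster POC (mean of the nine per-channel powers of P3,
PO3, PO7, O1, POz, O2, PO8, PO4, P4 — power is averaged, not the signals,
so the cluster is immune to phase cancellation); and two CSP components.

**Cross-validated CSP.** Per trial, a covariance matrix `X Xᵀ / n` of the
band-passed 500 ms window is trace-normalized. For each held-out trial,
the mean pre- and post-window covariances of *all other* trials enter the
generalized eigenproblem
$C_\mathrm{pre} w = \lambda (C_\mathrm{pre} + C_\mathrm{post}) w$
(solved by whitening the composite; eigenvalues in [0, 1]; shrinkage
`gamma = 1e-6` guarantees positive definiteness). The top filter maximizes
pre-over-post power — CSP(pre) — and the bottom filter the reverse —
CSP(post); one component per orientation, applied only to the held-out
trial. Activation patterns `A = C W (Wᵀ C W)⁻¹` are sign-aligned across
folds and subjects before averaging into topographies.

Two properties of this construction matter for interpreting results:

* Under trace normalization, a *suppressed source* reduces the post-window
  trace, so every noise direction gains relative share in the post
  covariance: non-source directions carry a small *reversed*
  pseudo-contrast. CSP(pre) finds the genuinely suppressed source only
  when the covariance contrast exceeds estimation noise — in this world
  that requires roughly the full 500-trial session; scaled-down sessions
  lose the component (this is why the acceptance suite runs the full
  design for the detection check).
* The per-trial percent modulation of a *null* CSP component (a noise
  direction) is a ratio of ~2-degree-of-freedom band-power estimates whose
  mean does not converge: its per-trial modulation distribution is heavy
  tailed by construction. Null behavior of the CSP sources is therefore
  tested where it is well posed — at the level of power cell means
  (Type-I calibration of the TIME effect) — while the ±3-SEM stationarity
  bound applies to the channel sources POz and POC.

**Time course and time bins.** Per-trial percent modulations
`(post − pre)/pre · 100` feed the block model, with the block factor
defined as the *within-state* block ordinal (a raw block index is
confounded with state, since every block has exactly one state). The
transience analysis compares the fixed pre window against four overlapping
500 ms post windows starting +100, +200, +300, +400 ms after stimulation
offset. The published description anchors these bins once to the onset
and once (implicitly) to the offset of stimulation; the package anchors
them to the offset so that bin 1 coincides exactly with the standard post
window.

## Repeated-measures inference

`fit_rm_anova()` implements the classical fully-within-subject factorial
ANOVA from first principles: the dependent variable is aggregated to one
cell mean per subject and condition, orthonormal factor contrasts
(Kronecker products across factors) map the subject × cell matrix to
per-subject effect scores, `SS_effect = n ‖mean score‖²`, and each effect
is tested against its own subject × effect stratum. Greenhouse–Geisser's
$\hat\varepsilon$ (Box's estimate from the score covariance) corrects the
degrees of freedom of any effect involving a factor with more than two
levels — sphericity is vacuous at two levels, where $\varepsilon = 1$
exactly. Generalized eta squared divides `SS_effect` by `SS_effect` plus
the sum of *all* error strata including the between-subject stratum.
Bonferroni correction uses the number of effects in the model (7 for the
2×2×2 models) and caps at 1, reproducing the ">0.999" display convention.
Subjects with any empty cell are dropped listwise with a warning.

Marginal means are per-level means of subject-level means with symmetric
t-intervals from the across-subject SE (`df = n − 1`); this is the
documented CI model (a within-subject error-stratum CI would exclude
between-subject variance and is not what a CI *on the mean itself*
should cover). The linear contrast over k ordered levels uses centered
unit-norm weights; its default error model is the subject-level one-sample
t (`df = n − 1`), with the pooled interaction-stratum variant
(`df = (n−1)(k−1)`, the model implied by a t with 57 degrees of freedom at
20 subjects and 4 bins) selectable — the published analysis does not state
which was used, so both are provided. Cohen's d for paired designs is
`d_z = mean(diff)/sd(diff)`; identical samples return 0, a constant
nonzero difference is an error.

## Numerical choices

* Butterworth design by bilinear transform with pre-warping; zero-phase
  filtering with odd-reflection padding and steady-state initial
  conditions (scipy-parity verified). Equal-length epochs are filtered
  through a cached linear operator (filtfilt applied to the identity),
  turning per-epoch filtering into one BLAS multiply.
* FFT lengths are rounded to 2-3-5-smooth sizes in the simulator; the
  noise scale is set analytically (Parseval), so channel RMS fluctuates
  naturally around its nominal value.
* Sample indices are 0-based with half-open intervals
  `[stim_onset, stim_offset)` in all event tables and on-disk formats;
  R-side code converts at the slicing boundary.
* Ratios guard their denominators (`pre_power > 0`); an ANOVA on a
  constant response reports F = 0 rather than round-off noise ratios.
* CSP filter signs are fixed deterministically (largest coefficient
  positive) and fold filters are re-aligned against their mean so that
  averaged patterns do not cancel.

## Scaling of the acceptance Monte-Carlo

The acceptance criteria prescribe cohort-level Monte-Carlo (100 cohorts of
20 subjects for detection power; 200, scalable to 50, for null
calibration). One full-size subject costs ~20 s to simulate and analyze,
so 100 full cohorts (~11 h) are infeasible in the test budget. The suite
runs: (a) *one* full-size 20-subject cohort for the detection check,
together with the per-subject standardized effect `d_z` and the analytic
detection probability it implies at n = 20 (required ≥ 0.9 — the
desk-scale equivalent of "detected in ≥ 90 % of cohorts"); (b) 50 null
cohorts of 20 subjects with minimal sessions (2 blocks × 4 trials) for the
Type-I calibration — a null calibration is valid at any session size
because the subject-level F-test only requires exchangeability of the pre
and post windows. Session-size scaling is *not* applied to the detection
cohort because the CSP contrast needs the full trial count (see above).

## Known limitations

* The simulator's single-source world makes CSP recovery easier than
  multi-generator real data; the spatial specificity finding is mimicked,
  not reproduced.
* BrainVision support covers the IEEE float32 multiplexed variant only;
  EDF+ support covers the continuous equal-rate layout written by the
  package.
* The phase estimator assumes a stationary IAF within the 250 ms window;
  frequency drift maps into phase error at about 11° per 0.5 Hz of
  mismatch.
* The null distribution of per-trial CSP modulation ratios is heavy
  tailed by construction (see above); block- and bin-level modulation
  tables inherit this and should be interpreted via their medians or the
  power-mean-based modulations also provided.
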