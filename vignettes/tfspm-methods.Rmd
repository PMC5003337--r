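---
title: "Time-frequency statistical parametric mapping for intracranial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency statistical parametric mapping for intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfspm)
```

## The analysis problem

Intracranial EEG recorded during a two-stimulus gaze paradigm asks two
questions of a temporal-pole electrode: does spectral power respond to the
*presence of eyes* (eyes versus eye-scrambled mosaics, first stimulus
presentation), and to a *change in gaze direction* (second presentation,
whose direction always differs from the first)? The signature of interest
is induced gamma-band power -- oscillatory energy that is time-locked but
not phase-locked to the stimulus, so it is visible in single-trial
time-frequency power maps but cancels from the event-related potential
(ERP).

`tfspm` implements the full chain as reusable pieces:

1. trial schedule and events table (`stimulus_set_config()`,
   `build_trial_schedule()`);
2. a synthetic iEEG generator emulating that paradigm
   (`simulate_epochs()`);
3. preprocessing: epoch extraction and two artifact-rejection rules
   (`extract_epochs()`, `reject_artifacts()`);
4. Morlet wavelet power maps, cropping, per-frequency log baseline
   correction (`tf_power()`, `tf_crop()`, `log_baseline_correct()`);
5. a trial-level mass-univariate factorial GLM with ReML non-sphericity
   correction (`build_design()`, `estimate_nonsphericity()`, `glm_fit()`,
   `contrast_map()`);
6. random-field-theory (RFT) cluster-level family-wise-error inference,
   with a label-permutation oracle for validation
   (`estimate_smoothness()`, `cluster_inference()`,
   `permutation_oracle()`);
7. the parallel one-dimensional sensor-time SPM for ERPs (`erp_images()`,
   `erp_spm()`); and
8. orchestration (`run_pipeline()`, `simulate_and_analyze()`, plus a thin
   command-line script in `inst/cli/`).

## The statistical model

Every artifact-free non-target trial contributes one observation per
temporal-pole electrode. A trial's cropped, baseline-corrected
time-frequency map (or baseline-corrected voltage trace, in the ERP arm)
is treated as an image $y_i$, and at every pixel the cell-means model

$$ y_i = \mu_{c(i)} + \varepsilon_i, \qquad
   \mathrm{Cov}(\varepsilon) = V = \textstyle\sum_k \lambda_k Q_k $$

is fitted, where $c(i)$ is the design cell of observation $i$ in the
2 (stimulus type) x 2 (direction) x 2 (hemisphere) factorial, and the
covariance components $Q_k$ encode one error variance per cell (uneven
variances between factor levels) plus a dependence term coupling the two
hemisphere observations of the same trial. This is a fixed-effects
analysis pooling the error over all trials of all participants: trials,
not participants, are the replicates, so inferences are about this set of
recordings rather than a population -- the standard trade-off of
trial-level iEEG SPM, and a stated limitation.

The $\lambda_k$ are estimated once per analysis by restricted maximum
likelihood, pooling pixels inside the analysis mask as replicates of a
single covariance (the one-V-for-the-whole-image convention of
mass-univariate imaging). Because $V$ is block diagonal with 2 x 2 trial
blocks, the restricted log-likelihood and all its trace terms are computed
blockwise, which keeps ReML at trial-level sample sizes (thousands of
observations) essentially free. Data and design are then pre-whitened with
$W = V^{-1/2}$, so the pooled trial-level degrees of freedom apply; an
unwhitened path (`whiten = FALSE`) instead adjusts the degrees of freedom
by the Satterthwaite trace formula, and is where df shrinkage under
heterogeneity can be observed directly.

Contrast T images are computed for the main effect of stimulus type and
the three interactions involving it; follow-up simple effects can be
inclusively masked by a positive main effect of type at uncorrected
p < 0.05 (the conventional default; the threshold is configurable).

## Wavelet decomposition and baseline correction

Power is obtained by convolution with 7-cycle complex Morlet wavelets
($\sigma_t = n_c / 2\pi f$, truncated at $\pm 5\sigma_t$, unit L2 norm) on
a 4--300 Hz grid, over the whole -1000--2000 ms epoch; maps are cropped to
-200--500 ms so that wavelet edge effects fall outside the analyzed
window. The convolution is exact zero-padded linear convolution evaluated
in the Fourier domain. Two optimizations serve large trial stacks without
changing results beyond stated tolerances: only the spectral band where
the kernel spectrum exceeds `spectrum_eps` of its peak is multiplied
(`spectrum_eps = 0`, the default, keeps this exact; the batch profile uses
1e-5, a relative error of order 1e-6), and when power is needed only on a
decimated time grid the product spectrum is folded modulo N/m before a
short inverse FFT, which returns exactly the decimated samples of the full
convolution.

Each map is log-transformed and expressed relative to the mean power of
its own trial over the -200--0 ms baseline, separately per frequency
(`method = "log_mean"`). A mathematical note: for stationary noise the
expectation of $\ln P - \ln \bar P_{\mathrm{baseline}}$ is not zero but a
common negative constant (Jensen's inequality applied to the log of the
averaged baseline), of order $-\gamma \approx -0.58$ when many independent
baseline samples are averaged. This offset is shared by all conditions and
cancels exactly from every contrast, so inference is unaffected; the
alternative `method = "mean_log"` (subtract the mean of log power) is
provided for applications that need zero-mean corrected maps.

## Image smoothing and random-field inference

Before entering the GLM the corrected maps are smoothed with a separable
Gaussian kernel, by default 24 ms x 36 Hz FWHM (edge-renormalized, so
constants are preserved). Smoothing sensor-level images before a
mass-univariate GLM is standard in electrophysiological SPM for exactly
the reason it is applied here: RFT's cluster-extent distribution assumes
the statistic field is smooth relative to the pixel lattice (in practice
FWHM of at least ~3 pixels). The intrinsic smoothness of a Morlet power
map is strongly frequency-dependent (temporal FWHM $\propto 1/f$, spectral
FWHM $\propto f$); the applied kernel both lifts the minimum smoothness
above the lattice and flattens that non-stationarity. The default was
chosen as ~3 pixels of the coarse batch grid and is configurable
(`smooth_fwhm_ms`, `smooth_fwhm_hz`; 0 disables).

Field smoothness is then *estimated*, not assumed, from the variance of
the spatial derivatives of the standardized residual images, with the
forward-difference estimate unbiased under a Gaussian autocorrelation
model ($g = 2(1 - e^{-\lambda/2})$ inverted for $\lambda$) and FWHM
clamped below at one pixel. Cluster inference thresholds the T image at
uncorrected p = 0.001 (Student t with the model's effective df), labels
8-connected components (4-connectivity is a flag), and converts each
extent to resels using the estimated FWHM. The cluster-level family-wise
p-value uses the standard expected-Euler-characteristic cluster count for
T fields ($\rho_1$, $\rho_2$ densities) with the Poisson clumping
approximation $P = 1 - \exp(-E_m e^{-\beta k^{2/D}})$, implemented for
D = 1 (ERP) and D = 2 (time-frequency). The explicit mask restricts the
search region to 0--500 ms x 4--300 Hz.

Two empirical checks back the analytic machinery, both run routinely in
the test suite: a null-calibration batch (no injected effects) whose
fraction of datasets with any FWE-significant cluster should sit near the
nominal 0.05, and a label-permutation oracle (condition labels permuted
across trials within participant, hemisphere pairing preserved, whitening
held fixed) whose significance calls should agree with RFT on
effect-present data. Mild liberality of RFT cluster inference at moderate
smoothness is a documented property of the method itself; the calibration
band used in the tests (0.03--0.08) reflects it.

The permutation p-value uses the add-one rank convention
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$; a permutation scheme
with no effective relabelings therefore yields p = 1, never a spuriously
small value.

## The synthetic generator: what it emulates, and what not

`simulate_epochs()` reproduces the statistical structure the analysis
assumes: 1000 Hz sampling, -1000--2000 ms epochs, one temporal-pole
channel per hemisphere, a 183-trial schedule (42 trials per condition
sequence plus 15 targets), 1/f background noise (spectral shaping of white
Gaussian noise, exponent 1, 40 uV SD -- typical intracranial background),
and condition-selective effects: oscillatory bursts with Gaussian
envelopes and per-trial random carrier phase (induced power, invisible to
the ERP), and optionally phase-locked evoked deflections. Per-trial
amplitudes jitter log-normally with CV 0.2 -- real inter-trial power
variability is unknown, so this is an explicit free parameter. The default
burst emulates the kind of effect the pipeline is designed to detect: an
eyes-selective gamma burst at 226 ms / 121 Hz, ~21 ms temporal FWHM, 50 Hz
carrier bandwidth; its default amplitude (13 uV) was calibrated once, by
simulation against the default background, to produce a log-power
elevation of ~0.5 at the locus of the corrected wavelet maps.

The generator does *not* emulate: biophysical (dipole/forward-model)
sources, spatial correlation between electrodes beyond the modelled
within-trial dependence, non-stationary or heavy-tailed background
regimes, line noise unless requested, or any relationship between the
stimulus images themselves and the signal (it works at the event-label
level). Passing tests therefore demonstrate that the pipeline recovers
effects with the assumed structure at realistic SNR, and that its error
control holds under well-behaved 1/f noise -- not that either property is
guaranteed for arbitrary patient data.

## Presentations, problem sizes, and numerical choices

Separate analyses are run for the first and second stimulus presentation;
the second re-locks the window at +500 ms with its own -200--0 ms baseline
(the baseline convention for the second presentation is not externally
fixed; re-locked -200--0 ms was chosen and is configurable via
`second_onset_ms` and `baseline_ms`). At the lowest frequencies the
re-locked window sits close enough to the epoch end that kernels extend
past the recorded data, where the signal is treated as zero -- the same
behaviour as computing over the whole epoch and cropping.

Two resolution profiles exist. `analysis_config()` defaults to the native
1 ms x 1 Hz grid. `batch_profile()` computes maps on an 8 ms x 12 Hz grid
with `spectrum_eps = 1e-5`; it is the profile used for the package's
Monte-Carlo work: 200 null datasets for family-wise-error calibration, 50
effect-present datasets (shared by the recovery, RFT-vs-permutation
concordance, and TF/ERP dissociation checks, with 119 permutations per
dataset), all at the paradigm's full scale of 42 trials per condition
sequence and 6 virtual participants. These batch sizes are the package's
choice of problem size for routine verification; the same harness
(`simulate_and_analyze()`) accepts larger values.

Other numerical decisions: randomization of the schedule is a uniform
shuffle (breaks every 45 trials are bookkeeping, not modelled);
inter-trial intervals are drawn uniformly on 2000--5000 ms as integer ms
so events round-trip losslessly through TSV; mirror-image stimuli are not
distinct schedule entries (the analysis factors are only direction and
type); the 5-SD rejection rule operates on the per-trial peak absolute
amplitude, compared against both the mean- and median-centred across-trial
distribution, rejecting on either, in a single pass over the
absolute-rule survivors (SD = 0 rejects nothing); rejection removes whole
trials across channels, preserving the hemisphere pairing; pixels the
model fits perfectly (residual sum of squares at rounding level) have
their statistics defined as 0 and are flagged rather than producing 0/0;
cluster peak ties break to the earliest time, then the lowest frequency.

## Worked example

```{r example, eval = FALSE}
sched <- build_trial_schedule(stimulus_set_config(), seed = 1)
eps <- simulate_epochs(sched, effect_spec(gaze_burst()), noise_spec(),
                       n_participants = 6, seed = 2)
run <- run_pipeline(eps, batch_profile(), out_dir = "demo_run")
print(run)
```

The printed report lists, per contrast, the significant clusters with
peak time (ms), peak frequency (Hz), peak T, extent ranges and cluster
size (ms x Hz), or "none". With the default injected burst the main
effect of stimulus type yields a cluster at ~224 ms / ~124 Hz on the
8 ms x 12 Hz grid, and the ERP arm stays empty -- the induced/evoked
dissociation the design is built around.

## Known limitations

* Fixed-effects pooling: no population-level (random-effects) inference.
* Global smoothness: one FWHM per image; non-stationarity is mitigated by
  smoothing, not modelled (no local resels-per-voxel correction).
* RFT formulas implemented for 1-D and 2-D fields only; peak-level and
  set-level inference are out of scope.
* The epochs container is a package-documented raw binary + JSON sidecar;
  EDF export is not provided.
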