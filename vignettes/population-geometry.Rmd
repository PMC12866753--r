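---
title: "Population geometry of cortical sound representations across sleep and wake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population geometry of cortical sound representations across sleep and wake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`sleepgeom` re-implements, as a tested pipeline, a family of population-level
analyses for large two-photon calcium recordings of auditory cortex followed
across wakefulness and NREM sleep: automated sleep scoring from EMG/LFP,
sigma-band spindle detection, trial-aligned response extraction,
noise-ceiling-corrected representational similarity analysis (RSA),
cross-validated PCA dimensionality with a circular-shift null, a
spontaneous/evoked subspace inclusion index, balanced linear decoding of sound
identity, and bootstrap detection of coordinated population response failures
("non-responsive" or gated trials). Because real recordings are large and
noisy, the package ships a synthetic-session generator with full ground truth;
every analysis is validated by recovering what the generator planted.

## The synthetic world

`generate_session()` emulates the statistical structure the analyses assume,
not the biophysics of calcium imaging. A session alternates 2-min silence and
2-min stimulation blocks; within a stimulation block each of 60 sounds is
presented once with a 2 s onset interval; blocks cycle deterministically
through wake and NREM rounds so per-state presentation counts are exactly
balanced (a real protocol randomizes block order; randomization would only
jitter state boundaries, so the deterministic schedule is used and documented
here). Activity of neuron $i$ in frame $t$ (43 ms frames, 23.26 Hz) is

$$x_{it} = b_i + [Q z_t]_i + g_k \, w_{is(k)} \,\mathbb{1}[t \in \text{resp.
window of trial } k] + \varepsilon_{it},$$

rectified at zero and (by default) rounded to integer event counts. The terms:

* **Baseline** $b_i \sim \Gamma(2, \cdot)$ with mean 0.1 events/frame.
* **Spontaneous dynamics** $Q z_t$: `spont_rank` (default 10) orthonormal
  loadings, AR(1) latents ($\phi = 0.9$) with mildly decaying scales
  $\sigma_k = k^{-1/4}$, plus sparse population bursts along the leading
  loading. The scales are chosen so every planted dimension sits clearly above
  the circular-shift detection floor (the generator's own contract); the
  generative law for spontaneous activity is a modeling convention — the
  analyses make no claim about it.
* **Evoked response**: per-presentation gain $g_k$ shared by all neurons
  (the coordinated fluctuation that the gating analysis targets). In wake
  $g_k \sim \max(0, \mathcal N(1, 0.2))$, zeroed with probability 0.078; in
  NREM the same draw is scaled by 0.5 and zeroed with probability 0.17.
  Tuning $w_{is}$ is built from unit directions with a controlled cosine
  `evoked_overlap` with $\mathrm{span}(Q)$, so subspace analyses can be swept
  against ground truth.
* **Noise** $\varepsilon_{it} \sim \mathcal N(0, 0.3)$ per frame.

Amplitudes are in events/frame and deliberately generous (single-frame evoked
SNR near 1-3): the generator's purpose is statistical-structure validation at
desk scale, and smaller populations than a real session (hundreds rather than
~650 neurons) must still resolve the planted structure. What a green test
establishes is that each analysis recovers what was planted *in this world*;
it does not establish robustness to artifacts the generator omits (motion,
neuropil residuals, spike-inference bias, non-stationary baselines).

The exactness tests (`noise_sd = 0` reproducing gain x tuning to machine
precision) run with `quantize = FALSE`, since integer rounding is
incompatible with exact equality for non-integer tuning.

`generate_physio()` synthesizes 1250 Hz LFP/EMG with the features scoring
needs: state-scaled broadband EMG (bimodal 50-300 Hz power), hippocampal
delta (2-5 Hz) strong in NREM versus theta (5-10 Hz) strong in REM,
olfactory-bulb gamma (50-70 Hz) elevated in wake, and 12 Hz spindles injected
during NREM only. Spindles occur at ~3/min of NREM (rodent literature ranges
2-7/min), last 0.6-2 s, and have a tapered-cosine amplitude envelope
(waxing-waning onto a plateau) at 5x the sigma-band background SD - strong
but within the physiological range, and individually detectable by the
2-SD rule, which is what "planted events obeying the detection rules" must
mean for a recovery test.

## Sleep scoring

Scoring is two-step. Step 1 fits a two-component Gaussian mixture to log
EMG power (50-300 Hz, Hilbert envelope squared, 3 s smoothing; or OB gamma
power via `use_ob`), rescales each component density to unit area and uses
the intersection abscissa between the means as the wake/sleep threshold, so
the split does not depend on how much time the animal spent asleep.
`separation_ok` reports whether the sample actually supports a bimodal split:
the two-component fit must beat a single Gaussian under BIC *and* the
components must satisfy Ashman's D >= 2 (EM happily splits a tight unimodal
blob into two components ~2 SD apart, so either criterion alone misfires);
without separation the session is scored as all wake and the flag tells the
caller the threshold was not usable. Step 2
computes the hippocampal theta/delta power ratio (2 s smoothing) within sleep
and fits a single Gaussian; the published criterion ("the fit explained less
than 50% of the data") does not pin down an estimator, so this package uses a
robust location/scale fit (median/MAD, so the NREM bulk dominates) and places
the REM threshold at the smallest ratio above the fitted mode where the
fitted density falls below half of the kernel-smoothed empirical density.
With no REM mode the criterion never triggers and no REM is scored. NREM/REM
intervals shorter than 3 s are merged into the longer neighbor (ties to the
preceding one).

Spindle detection follows the fixed rules: zero-phase 10-15 Hz Butterworth
(order 4, forward-backward, implemented as second-order sections because at
1250 Hz the narrow bands are numerically singular in transfer-function form),
element-wise squared amplitude, threshold mean + 2 SD with statistics over
NREM samples only, merge gaps < 200 ms, keep durations in [0.4, 3] s.

## Responses, RSA and the noise ceiling

Responses are window means over presentation plus 250 ms, baselines over the
500 ms before onset (the baseline window is not pinned down for the firing
rate figures; 500 ms pre-onset is used everywhere, and "relative to baseline"
subtracts the per-trial baseline). The RSA similarity between sounds $i, j$
splits each sound's presentations into ensembles $r, r'$ and corrects the
cross-ensemble correlation by the split-half reliabilities:

$$\rho^{corr}_{ij} = \frac{\tfrac12\left[\rho(\langle S_i\rangle_r, \langle
S_j\rangle_{r'}) + \rho(\langle S_i\rangle_{r'}, \langle S_j\rangle_r)\right]}
{\sqrt{\rho(\langle S_i\rangle_r, \langle S_i\rangle_{r'})\,
\rho(\langle S_j\rangle_r, \langle S_j\rangle_{r'})}}.$$

The denominator is the square root of the product of reliabilities - the
unique normalization for which identical underlying representations score 1
(the published typesetting drops the radical; without it the ceiling is not
1). The cross-state version averages the four $r/r' \times q/q'$
cross-correlations and normalizes by the within-state reliabilities; the
printed numerator repeats one ensemble twice, and the symmetric completion
over all four combinations is used. Sounds with non-positive reliability are
flagged `NA`, never clipped. Chance comes from mismatching sound identity
between states (a derangement), the ceiling from a 4-way within-state split
treated as two pseudo-states. Results are averaged over 20 random split
schemes (the source does not state a count; averaging only reduces split
noise). Because Pearson correlations are scale-invariant, a uniform gain
applied to one state moves response amplitude but not similarity - this is
what lets the analysis separate representation geometry from amplitude.

## Subspaces

`cv_scree()` z-scores frames over the session, splits them into 5 contiguous
blocks, estimates PCs on train blocks (train-mean centering for both train
and test — standard cross-validation hygiene, on which the source is silent)
and measures per-component test variance ratios; chance is the 95th
percentile over 20 per-neuron circular time shifts of the test block, and
dimensionality is the *initial* run of components above chance (curves
re-cross in noise; the initial-run reading is documented as a choice).

`inclusion_index()` splits spontaneous activity into 10 contiguous blocks;
odd blocks give the reference subspace $V_{ref}$ (first $n$ PCs, $n$ = the
reference's cv dimensionality), and
$\%Var(X) = Var(X V_{ref} V_{ref}^T) / Var(X V_{src} V_{src}^T)$ with
$V_{src}$ the first $n$ PCs of $X$ itself. `var_max` uses even spontaneous
blocks, `var_projected` the evoked frames, `var_chance` per-neuron circularly
shifted evoked frames, and the index is
$(\%Var_{proj} - \%Var_{chance}) / (\%Var_{max} - \%Var_{chance})$.

One subtlety worth stating. On full sessions the evoked frames carry the
shared spontaneous background *and* strong low-rank stimulus structure, and
the chance normalization (shuffled data concentrates less variance in its top
PCs) can push the zero-overlap endpoint negative rather than to 0. That is a
property of the formula, not an error: the index reaches exactly 0 for
evoked data with *no* cross-neuron structure at all - which is precisely the
null hypothesis the circular-shift chance embodies. The test suite therefore
checks the ~1 and ~0 limits on constructed matrices (shared-subspace latents
and independent-neuron null) and checks strict monotonicity of the index in
`evoked_overlap` on full sessions.

## Decoding and gating

Decoding uses stratified 5-fold cross-validation with per-sound counts
equalized (and optionally equalized across states), and reports the weighted
F1 over pooled test folds (weights = per-class test support; the alternative
uniform weighting is not used). The classifier is ridge-regularized
multinomial logistic regression (glmnet) - a linear decision rule; no SVM
implementation is available in the supported dependency set, and the source
itself describes the decoder both as a linear SVC and as logistic
regression. The penalty is fixed (`lambda = 0.01` at the end of a warm-start
path) and exposed; no hyperparameter search is performed.

Gating: per recording, sounds are ranked by mean baseline-subtracted
population response and the top 10 kept; per sound, the strongest 30% of
trials (by mean baseline-subtracted population rate - the same statistic used
for trial sorting; ties broken by trial id) are averaged into a template.
Each trial's cosine similarity with its template is bootstrapped by
resampling neurons with replacement 1000 times (plain percentile bounds, no
bias correction), and the trial is non-responsive when 0 lies inside the
5th-95th percentile interval. Zero trial vectors are non-responsive by
convention and counted. Template trials are not excluded from labeling. Note
the procedure's operating characteristics, visible in the recovery tests: a
truly gated trial is missed when its noise cosine happens to sit away from 0
(about 10% at the 5-95 bounds), so recovered fractions run slightly below
planted probabilities - within the binomial tolerance the tests use.

## Numerical choices

* Butterworth band-passes: order 4 (order 2 for the physio synthesis), >20 dB
  stop-band one octave out; zero-phase application squares the attenuation.
* Hilbert envelopes are computed on signals reflect-padded to 2-3-5-smooth
  lengths (R's FFT is O(n p) for a large prime factor p).
* Gaussian raster smoothing truncates at 4 SD and renormalizes to unit area,
  so event mass is conserved away from edges.
* Mixture fits: EM with quantile-based initialization and 3 deterministic
  restarts, best likelihood kept.
* One master seed drives named RNG streams (schedule, tuning, gains, noise,
  spindles, physio), so stages can be re-run independently and sessions are
  bit-reproducible.

## Known limitations

No spike inference, motion correction or ROI segmentation; rasters are taken
as given. The anesthesia condition is just another state label on synthetic
data - no anesthesia-specific generative model is provided. The generator's
spontaneous law (low-rank AR(1) plus bursts) is a convention; analyses that
depend on fine temporal structure beyond autocorrelation are only as valid as
that convention. Serialization uses flat float32 + JSON sidecars and CSV
rather than HDF5 (no HDF5 bindings in the supported dependency set).
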