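---
title: "Methods: decoding cross-modal congruency and neurally informed diffusion modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding cross-modal congruency and neurally informed diffusion modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the choices made where the
method left room, and what the validation suite does and does not show.

## The task and the question

In the implicit-association task (IAT) implemented here, one stimulus
feature is presented per trial (an auditory pitch or a visual circle
size) and the mapping between features and response keys switches
between blocks. When the auditory mapping matches the preferential
pitch-size association (high pitch with small circle), the block is
*congruent*; otherwise *incongruent*. The scientific question is whether
the behavioural benefit of congruency arises early (sensory encoding)
or late (decision dynamics). The pipeline answers it in two stages:
single-trial decoding of congruency from EEG, then a hierarchical
drift-diffusion model (HDDM) whose parameters are regressed, trial by
trial, on the decoded component amplitudes.

## Synthetic sessions

No public dataset accompanies this design, so the package ships a
generator whose defaults are the study conditions: 20 subjects, 8
blocks (4 congruent, 4 incongruent, randomized per subject), 40 trials
per stimulus feature per block (1,280 trials per subject), 128 channels
at 200 Hz, epochs from −0.5 to 1.5 s. Each epoch is

* spatially correlated noise: unit-variance Gaussian with a
  squared-exponential channel covariance (lengthscale 5 channel
  indices, 20% white mixture to keep it well conditioned), AR(1) in
  time (coefficient 0.3), scaled to 10 µV per channel — the minimal
  structure that makes multivariate decoding nontrivial without a head
  model;
* a stimulus-feature response: a smooth unit-norm channel pattern at
  95 ms, with inverted polarity at 175 ms, signed by the presented
  feature (amplitude 0.25);
* two congruency components: unit-norm patterns at 105 ms (early) and
  335 ms (late) under Gaussian envelopes (FWHM 60 ms — the method
  reports only peak windows, so a width had to be chosen), scaled by
  per-trial amplitudes drawn from N(±0.8, 0.5) (early) and N(±0.6, 0.5)
  (late), negative mean for congruent trials. The signed-amplitude
  convention matches the classifier's mapping of congruent trials to
  negative projections, and the early component is made the more
  discriminable of the two — the ordering of peak discriminabilities
  the generator is designed to emulate.

Behaviour is drawn from the diffusion simulator under accuracy coding:
per condition, group-level drift 1.85, boundary 1.3, non-decision time
0.33 s (between-subject SDs 0.15, 0.10, 0.03), and per trial the
boundary and non-decision time are shifted by the planted absolute
amplitudes: boundary slope −0.3 per unit |late amplitude| on congruent
trials, non-decision slope +0.06 s per unit |early amplitude| on
incongruent trials. Two calibration notes:

* *RT reference.* RTs are generated and reported from stimulus onset.
  The group parameters are set so that onset-referenced medians fall
  near 600 ms with accuracy near 0.92, inside the 300–1200 ms exclusion
  window; condition medians reported relative to stimulus offset are a
  presentation choice, not a generator concept.
* *Effect sizes.* The planted slopes and the 12 µV/unit scalp gain are
  sized so that, at the package's validation scale (about 5,000 trials
  across 12 subjects), the neurally informed fit recovers both planted
  directions decisively (posterior log-odds well above the 2.944
  threshold), i.e. so the generator emulates decisively detectable
  effects rather than effects invisible by construction. Two
  attenuations make this calibration necessary and easy to
  underestimate: taking absolute values folds the signed amplitude
  distribution (|y| tracks |amplitude| much more weakly than y tracks
  the signed amplitude), and single-trial projections carry irreducible
  noise along the spatial filter.

What the generator does **not** emulate: volume-conducted head-model
topographies (patterns are smooth random vectors), eye-movement or
muscle artifacts, non-stationary noise, learning or fatigue across
blocks, and any visual-condition congruency effect (visual trials carry
no planted congruency signal unless configured). Passing tests
therefore show that the *methods* recover what was planted under this
noise model — not that real EEG satisfies these assumptions.

## Behavioural statistics

Trials with RT < 300 ms (fast guesses) or > 1200 ms (attentional
lapses) are excluded; both bounds are strict, so a trial at exactly
300 or 1200 ms is kept. Medians and accuracy are computed per subject ×
condition. Rank tests report a standardized Z from the normal
approximation with continuity correction and tie-corrected variance —
the approximation is stated explicitly because effect sizes are defined
as Z/√N and must be reproducible; the implementation is cross-checked
against `stats::wilcox.test` p-values in the tests. N is an explicit
argument because different comparisons standardize by different
populations (20 subjects for condition medians; trial counts for
correct-vs-incorrect RT comparisons, where more than one pooling of
the denominator is defensible — the API takes `n_effect` explicitly).
Bootstrap confidence intervals resample *subjects* (the experimental
unit of the group figures), 1000 iterations, percentile bounds.

## Signal conditioning

Band-pass filtering is zero-phase (forward-backward Butterworth, order
4 per pass): the decoder measures component latencies, and causal
filtering would shift them. Downsampling low-passes at 90% of the
target Nyquist (order 8, zero-phase) before spline interpolation onto a
uniform axis spanning the same interval (2 s at 512 Hz → 400 samples at
200 Hz). The ±120 µV rejection is applied after filtering, matching the
stated processing order, and uses a strict "exceeds" comparison. No
baseline correction is applied anywhere — none is part of the method.

## Sliding-window decoding

For each 50 ms window (centres every 5 ms from −100 to 800 ms), all
(trial, sample) pairs inside the window are pooled as training rows for
an L2-regularized logistic regression on the channel vector; the
trial-level projection is the within-window mean of `w'x + b`. Pooling
samples as independent rows and averaging the decision values is this
package's aggregation choice; it matches the forward-model
construction, which stacks all within-window samples. Regularization
(default λ = 1, configurable) is needed because 128 channels against a
few hundred trials is ill-posed under leave-one-out refitting. The
IRLS solver caps step norms so that perfectly separable windows do not
diverge.

Az is the rank-based ROC area of *held-out* projections:
leave-one-trial-out, refitting exactly (warm-started at the full-data
solution and iterated to tolerance — not a one-step approximation). The
permutation threshold shuffles trial labels, reruns the LOO procedure,
and takes the 95th percentile of the null Az. Permutations are run at
the observed peak-Az window: a single reference window keeps the cost
linear, at the price of not correcting for selection across windows —
the null-calibration test shows the resulting false-positive rate stays
near the nominal 5% in this regime. The desk default is 200
permutations; `preset = "paper"` restores 1000.

Component search intervals default to 50–200 ms (early) and 250–450 ms
(late) around the group peaks; the bounds are package defaults, not
constants of the method. Peak ties break toward the earlier window
(documented, arbitrary). Amplitudes are the maximum-magnitude signed
projection within each subject's component window, stored signed and
absolute; the absolute values are the model regressors.

## The hierarchical diffusion model

Accuracy coding (upper boundary = correct), starting point fixed at
z = 0.5 (the task has no response bias), unit diffusion coefficient
(scale convention), no inter-trial variability parameters. Per
condition c and trial i:

* drift δ_i = α₀ + α₁|y_early| + α₂|y_late|
* boundary θ_i = β₀ + β₁|y_early| + β₂|y_late|
* non-decision τ_i = γ₀ + γ₁|y_early| + γ₂|y_late|

Subject-level intercepts (α₀, β₀, γ₀) are drawn from condition-level
normal distributions with estimated means and variances; slopes are
condition-level parameters shared across subjects — the standard
hierarchical-regression layout. Regressors enter untransformed by
default; `build_design(standardize = TRUE)` offers within-condition
standardization for numerical stability (both parameterizations are
legitimate, so both are exposed).

**Likelihood.** The Wiener first-passage-time density is evaluated by
the standard series expansions (small-time and large-time forms, term
counts from the usual truncation bounds, switching to whichever needs
fewer terms), compiled in C++. Any proposal implying θ ≤ 0, τ < 0 or
RT ≤ τ on an observed trial has zero likelihood and is rejected rather
than crashing the sampler.

**Priors** (weakly informative, config-exposed): diffuse normals on
drift intercept means N(0, 5²) and slopes (SD 2 for drift, 1 for
boundary, 0.5 for non-decision slopes); positive-truncated normals on
boundary and non-decision group means (N(1.5, 1.5²), N(0.3, 0.5²));
inverse-gamma on group variances (shape 2; scales 0.5, 0.1, 0.01).
The conformance contract is the posterior, not the prior: any setting
passing the recovery suite is acceptable.

**Sampler.** Adaptive Metropolis-within-Gibbs: joint random-walk
updates of each subject's intercept triple (scales adapted to 25%
acceptance during burn-in), a joint 6-slope adaptive-Metropolis update
per condition whose proposal covariance is the empirical slope
covariance accumulated during burn-in (frozen afterwards, three
repetitions per sweep — slope mixing limits convergence otherwise), and
conjugate Gibbs draws for group means and variances. Regressors are
mean-centred internally to decorrelate slopes from intercepts; stored
intercept draws are de-centred, so the reported parameterization is
unchanged. Chains initialize from per-cell moment (EZ-style) estimates
with chain-specific jitter. The canonical run is 5 chains × 11,000
samples, burn-in 1,000, thinned by 2 (25,000 retained draws); the desk
preset is 3 × 2,000 with 500 burn-in. Convergence is declared when all
split-chain Gelman-Rubin statistics lie in [0.98, 1.02].

**Inference.** Directional hypotheses are summarized by the posterior
proportion of draws in the hypothesized direction, expressed as
log-odds via the logit; the proportion is clipped to
[1/(M+1), M/(M+1)] over M draws so log-odds stay finite, and compared
with ln(0.95/0.05) = 2.944, the log-odds of a 5% false-positive rate.
Posterior predictive checks simulate RTs from posterior draws and
compare the 10/30/50/70/90% RT quantiles by condition × correctness.

## Numerical choices

* Diffusion simulation: Euler-Maruyama with a Brownian-bridge
  correction for intra-step boundary crossings at dt = 1 ms, crossing
  times placed mid-step. This removes the leading discretization bias;
  against the series density the empirical distribution agrees to
  Kolmogorov-Smirnov distance ≈ 0.003 at n = 100,000.
* Series density tolerance 1e−9 in the likelihood (1e−10 for density
  evaluation); truncation undershoot near t → τ is clipped at 0.
* Degenerate inputs: empty filtered tables warn rather than fail;
  flat Az curves select the earliest window and warn; single-class
  windows, mismatched labels, non-positive implied boundaries and
  missing amplitudes are errors.

## Validation scales

The test suite exercises every stage at desk scale, chosen so the whole
suite completes in minutes while keeping each check informative:
behaviour-level properties at 2,600–6,000 simulated trials; oracle
equivalences exactly (forward model, LOO Az vs brute-force ROC area) or
at n = 100,000 (simulator vs density); convergence at 8 subjects × 300
trials with 3 × 2,000 draws; parameter recovery over 20 replicate fits
of 4 subjects × 200 trials; decoder null calibration over 100 replicate
null datasets with 200 permutations each; and the end-to-end
direction-of-effect run at 12 subjects × 432 trials (≈5,200 trials,
the scale at which slope recovery is meant to be decisive), 16
channels, 50 ms steps. Full-scale settings (128 channels, 5 ms steps,
1000 permutations, 5 × 11,000 chains) remain the defaults or presets.

## Known limitations

* The permutation threshold is estimated at one reference window, not
  max-corrected across the curve.
* The sampler is a random-walk scheme: it meets the R̂ criterion at the
  scales above, but very small cells or near-boundary parameters mix
  slowly; gradient-based samplers would be faster per effective draw.
* Absolute-value regressors discard the sign information that the
  decoder explicitly provides; this follows the original model
  definition, but it is the main reason single-trial slope estimates
  attenuate (see the calibration note above).
* The generator's noise is stationary and Gaussian; real EEG artifacts
  (blinks, saccades, electrode drift) are out of scope, as is ICA-based
  cleaning — the ±120 µV rejection is the only artifact defence
  implemented.
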