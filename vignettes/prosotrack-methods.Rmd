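---
title: "Methods: linking neural pitch tracking to prosodic cue weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking neural pitch tracking to prosodic cue weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prosotrack)
```

## The scientific question

Speech conveys prosodic categories — word emphasis, lexical stress, phrase
boundaries — through several acoustic dimensions at once, chiefly pitch and
duration. Listeners differ stably in how much weight they place on each
dimension when categorizing what they hear. One candidate mechanism for this
variability is sensory reliability: if a listener's early auditory system
tracks the pitch contour of running speech less faithfully, downstream
decision processes should learn to lean on pitch less. `prosotrack`
implements the full analysis chain needed to test that idea: estimating how
reliably each listener's EEG tracks the pitch of continuous speech
(temporal response functions), estimating how strongly each listener weights
pitch and duration behaviorally (penalized logistic regression on
categorization trials), and relating the two across a cohort with
rank-based statistics and cluster-corrected lag-resolved tests.

Because the original raw EEG is not required for verifying the machinery,
the package ships a forward-model simulator with complete ground truth.
Every stage can therefore be validated by parameter recovery: the simulator
plants a known brain–behavior link and the pipeline must find it (and must
*not* find one when none was planted).

## Behavioral cue weights

Each categorization task presents a 4 × 4 grid of morphed stimuli: pitch
and duration are morphed independently in four steps (coded 1–4) between
two natural renditions, and the listener gives a binary response. Cue
weights are the slopes of a logistic model

$$\mathrm{logit}\, P(y = 1) = \beta_0 + \beta_p \cdot \mathrm{pitch} +
\beta_d \cdot \mathrm{duration},$$

with levels entered raw as 1–4 (`firth_fit()`). Sharp categorical listeners
produce quasi-separated tables on which ordinary maximum likelihood
diverges, so the model is fit by Firth's bias reduction: the likelihood is
penalized by half the log-determinant of the Fisher information (a Jeffreys
prior), which keeps estimates finite under complete separation. The fitter
(`firth_logistic()`) runs Newton iterations on the hat-value-modified score
with step-halving whenever the penalized likelihood would decrease,
converging when the largest score component drops below 1e-6 (at most 50
iterations). Per-coefficient p-values use the penalized likelihood-ratio
test — the coefficient is fixed at zero, the other parameters are
re-estimated with the penalty still computed from the full design, and
twice the penalized log-likelihood difference is referred to a chi-square
with 1 df. Wald p-values are available behind a flag but the
likelihood-ratio test is the default, being the standard choice for this
penalty. The fitter is verified in the test suite against an independent
refining grid search over the penalized likelihood surface.

Three screening rules mirror standard practice for these tasks:

* **Compliance** (`compliance_filter()`): a participant is retained only if
  at least one cue relates to their responses (p < 0.05) on *every* task;
  otherwise they are assumed to be responding randomly.
* **Outliers** (`outlier_flag()`): a cue weight is dropped from group
  analyses only when it is both significantly *negative* and extreme
  relative to the cohort (more than 3 SD from the mean by default; the
  threshold is configurable because published reports give post-hoc
  distances rather than a screening rule). When a task's weight is dropped,
  the participant's other tasks are retained, and task-averaged weights are
  computed over the available tasks.
* **Attention control** (`unambiguous_accuracy()`): accuracy on the two
  grid corners where both cues agree, 20 trials at the standard 10
  repetitions.

An intercept is always included; the morph coding leaves it to absorb any
response bias.

## Temporal response functions

The TRF is the linear kernel mapping a stimulus feature (the z-scored pitch
contour, or the amplitude envelope) to the EEG at each channel over lags
−50 to 350 ms. With 128 Hz data the lag grid is `round(t·fs/1000)` samples
at both ends — integer lags −6…45, 52 lag columns plus an unpenalized
intercept (`build_lag_matrix()`, zero-padded outside the series, ascending
lag order, positive lag = stimulus precedes EEG). Per channel the ridge
solution is

$$w = (X^\top X + \lambda M)^{-1} X^\top y,$$

with `M` the identity except zero at the intercept, solved by Cholesky
factorization rather than explicit inversion (`ridge_fit()`).

Penalty selection and evaluation use a doubly-nested leave-one-trial-out
scheme (`nested_cv_trf()`): each trial serves once as the held-out test
trial; an inner leave-one-out loop over the remaining trials scores each
candidate penalty (grid 1, 10, 100, 1000 — integer powers spanning
10^0–10^3) by the Pearson correlation between predicted and actual EEG,
averaged over channels and then inner folds, with ties broken toward the
smaller penalty; the model is retrained on all training trials at the
selected penalty and tested on the held-out trial. Reported weights and
per-channel r-values are averages over the outer folds. The first 0.5 s of
every trial is removed before any model sees it, so onset transients do not
dominate. Implementation note: all leave-one-out refits and prediction
correlations are computed from per-trial sufficient statistics
(`X'X`, `X'Y`, column sums), which makes the inner loop's cost independent
of trial duration without changing any result.

Predictors are z-scored at the trial level and are *not* re-standardized
within folds; this matches the convention of supplying trial-level z-scored
contours, but is worth noting as the one place where a different convention
would rescale the penalty.

The envelope-residualized pitch model (`residualized_pitch_trf()`) isolates
pitch tracking beyond what the envelope explains: within each outer fold an
envelope TRF is trained on the training trials only (with its own inner-CV
penalty), its predictions are subtracted from *all* trials' EEG, and the
pitch model is then trained and tested on those residuals. Residualizing
with a fold-specific envelope model avoids test-set leakage; the
alternative (one global envelope model) was rejected for exactly that
reason, though with 9-of-10 trials shared between folds the two are close
in practice. Note a property of any regularized two-stage scheme: stage 1
leaves a small under-fit remnant in the residuals, and since correlation is
scale-free the stage-2 r does not collapse all the way to zero for a
predictor collinear with the envelope unless noise dominates that remnant;
the tests assess this collapse in an EEG-like noise regime.

Cross-channel summaries use the nine channels with the highest fold-averaged
r (`select_best_channels()`); weights and r are averaged over that subset.
Lags outside 0–300 ms are flagged as edges and excluded from group
analyses, where model weights carry boundary artifacts.

## Group-level inference

Scalar brain–behavior relationships use Spearman correlations
(`spearman()`; average ranks for ties, two-sided p from the t
approximation, appropriate at cohort sizes of tens; an exact permutation p
is available for very small n). The six tests (2 cues × 3 tasks) form one
Benjamini–Hochberg FDR family (`fdr_adjust()`, delegating to
`stats::p.adjust`). The pitch-versus-duration contrast on task-averaged
weights uses the Fisher r-to-z comparison of two correlations
(`compare_correlations()`).

The lag-resolved analysis (`lagwise_correlation()`) correlates the
channel-averaged TRF weight at each interior lag with the behavioral pitch
weight, then corrects across lags by cluster-based permutation
(`cluster_permutation()`): clusters are maximal runs of contiguous lags
with p below 0.05 and a common correlation sign; each is scored by the sum
of the per-lag t-statistics of rho (the t-statistic, rather than raw rho,
keeps masses comparable across lags; the choice of summed statistic is a
design decision since rho, t and z orderings rarely differ). The null
distribution is the maximum absolute cluster mass over 1000 permutations of
the behavior vector across participants — a fresh rank correlation per lag
per permutation, implemented as a matrix product on rank-standardized data,
which is algebraically identical. Cluster p-values use the add-one rule
`(count + 1)/(n_perm + 1)`, so the observed labeling can never yield p = 0;
clusters are sign-specific but tested against a two-sided max-|mass| null.

Descriptive tercile contrasts (`tercile_summarize()`) rank the cohort by a
grouping variable and split it into three near-equal groups (remainder
assigned from the bottom group upward; ties broken by stable participant
order; a constant grouping variable is an error rather than an arbitrary
split).

## The synthetic cohort

`make_cohort()` draws, per participant *i*:

* a pitch gain $g_i \sim \mathrm{lognormal}(0, 0.4)$, the single
  ground-truth quantity linking brain to behavior;
* true behavioral slopes: for emphasis and stress,
  $\beta_{p,i} = 1.0 + \ell \cdot \mathrm{z}(\log g_i) + \varepsilon$,
  with link strength $\ell = 0.5$ and residual SD 0.25 by default; for the
  boundary task the pitch slope is drawn *independently* of $g_i$ with the
  same marginal spread (mean 0.6), mirroring the expectation that boundary
  categorization is duration-led; duration slopes are independent of
  $g_i$ throughout (mean 0.7 for emphasis/stress, 1.2 for boundary);
* an EEG noise amplitude, lognormal around 24 (see below).

Behavior: each task presents the 16-cell morph grid 10 times (160 trials)
and draws Bernoulli responses from the centered logistic model (centering
at 2.5 keeps the simulator's intercept interpretable; the fitting side uses
raw 1–4 coding).

EEG: ten shared stimulus-feature trials (60 s at 128 Hz by default) are
generated as z-scored 8 Hz-lowpass Gaussian noise (pitch) and a rectified,
mostly positive lowpass process (envelope). Each channel of each trial is

$$y_c(t) = \mathrm{gain}_c \left[ (\mathrm{env}_z * K_{env})(t) +
(\mathrm{pitch} * (K_{late} + g_i K_{early}))(t) \right] +
\sigma_i \cdot \mathrm{pink}(t).$$

The kernels are compact asymmetric bumps: the early pitch component
supported on 0–100 ms peaking near 70 ms (the component whose amplitude
carries the individual-difference signal), the late component on
120–250 ms peaking near 170 ms, and an envelope kernel on 0–180 ms. Only
the peak latencies and supports are anchored to what is known about pitch
TRF morphology; the exact bump shapes are free parameters recorded in
`kernel_spec()`. The 32-channel topography is a Gaussian falloff centered
frontocentrally (between Fz and Cz), where speech-tracking responses are
typically largest. Background noise is pink (1/f) rather than white, the
standard first-order description of EEG background spectra; slope fixed at
1, amplitude set by `noise_sd`.

The default `noise_sd_mean = 24` was calibrated once so that the best-9
channel-averaged prediction r lands around 0.10–0.20 — the weak-tracking
regime in which the real analyses of this kind operate — and then frozen.
At that level the nested-CV pipeline still recovers the generating kernel
with profile correlation above 0.9 and the correct peak latency.

What the simulator does *not* emulate: real speech statistics (features are
filtered noise, so pitch–envelope dependencies of natural speech are absent
unless explicitly requested), artifacts and their removal (components such
as blinks are out of scope, so no ICA stage exists), volume-conduction
structure beyond a smooth gain topography, and any nonlinearity in the
stimulus–response mapping. Passing recovery tests therefore demonstrates
the correctness of the estimation machinery under the model's own
assumptions, not the realism of those assumptions.

## Numerical and design choices

* **Zero-phase filtering**: Butterworth designs applied forward and
  reverse (effective order doubled), with odd edge extension whose length
  grows with the filter time constant; equality of filter-then-reverse and
  reverse-then-filter holds to 1e-9 away from the edges.
* **Envelope extraction**: band-pass 80–2800 Hz, magnitude of the analytic
  signal via the frequency-domain Hilbert transform, anti-alias lowpass at
  0.4 × the output rate (order 4, zero-phase) before resampling to 128 Hz.
  The anti-alias cutoff is a design decision; published descriptions say
  only that the envelope is low-pass filtered. Both predictors are
  z-scored at trial level before modeling, for symmetry between pitch and
  envelope.
* **Epoch alignment**: EEG and feature streams are truncated to the
  shorter of the two; a mismatch beyond 1 s raises an error as it indicates
  misalignment rather than rounding.
* **Ridge at λ = 0** with collinear columns raises an error advising a
  positive penalty rather than silently pseudo-inverting.
* **Degenerate rank inputs** (constant behavior, constant grouping) raise
  labeled errors rather than returning NaN.
* **Determinism**: every stochastic stage consumes an explicit seed;
  cohort manifests record every drawn value, and `run_pipeline()` reports
  content hashes of each stage's outputs so that identical configurations
  reproduce identical results hash-for-hash.

## Problem sizes used in the shipped validation

The package's own validation runs (test suite and `scripts/acceptance.R`)
use a scaled cohort chosen as the smallest that exercises every stage with
comfortable statistical margins: 60 participants, 10 EEG trials of 30 s
each (60 s for single-participant kernel-recovery checks), 160 behavioral
trials per task, 500 cluster permutations, and 200 cohort replicates for
the type-I-error check of the cluster test. With the default link strength
the full pipeline reproduces the qualitative target pattern — positive,
FDR-significant pitch-weight correlations for emphasis and stress but not
boundary, and an early-lag cluster overlapping the generating 0–100 ms
kernel support — in essentially every seed.

## Known limitations

* The Spearman p-value uses the t approximation; for n below ~10 prefer
  `exact = TRUE`.
* The cluster test corrects over time only (channel-averaged weights);
  channel × time clustering is out of scope.
* The residualized model's stage-2 r retains a small positive bias from
  stage-1 under-fitting at strong regularization (see above); comparisons
  of residual r across participants are unaffected, absolute values should
  be read with this in mind.
* The simulator's compliance failures are modeled as pure random
  responders; real non-compliance is likely more structured.
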