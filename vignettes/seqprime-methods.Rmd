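---
title: "Overlapping-sequence designs, synthetic cohorts, and the integration analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlapping-sequence designs, synthetic cohorts, and the integration analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The paradigm and what the package models

Two triplet sequences ABC₁ and ABC₂ share their A→B stem: B always follows
its A, and C₁ or C₂ each follow B half of the time. C₁ and C₂ therefore
never co-occur but share their full predictive context, and the scientific
question is whether — and when — they become behaviorally and neurally
*integrated*. The package implements the three measurement channels end to
end:

* **recognition priming**: in a surprise old/new test, each C₂ directly
  follows its overlapping C₁ (primed), while each tested C₁ follows an
  unrelated same-session baseline object (control). The per-subject score is
  the median of within-sequence differences RT(C₁) − RT(C₂); positive means
  responding to C₂ was facilitated by its across-sequence associate.
* **pattern-similarity change**: per-object *t*-patterns are estimated from
  pre- and post-learning exposure scans, cross-scan C₁ × C₂ Pearson
  similarity matrices are fit to a binary same-sequence model by
  point-biserial correlation, and the Fisher-z fits are differenced
  (post − pre). Negative change = differentiation.
* **rest-coupling change**: Fisher-z Pearson correlation between two ROIs'
  nuisance-cleaned, band-passed mean time courses, differenced against the
  single pre-learning baseline scan.

Group inference ties the three together: one-sample tests with Bonferroni
families (4 ROIs for patterns, 5 ROI pairs for rest), across-subject
correlations, dependent-correlation comparisons, and a two-predictor
regression of priming on Δ-integration and Δ-coupling with semi-partial R².

# Design generation

Hard constraints are enforced exactly, not approximately. The learning order
is built per block by restarting sequential construction: the next triplet
variant is drawn from the remaining multiset, excluding the previous
triplet's sequence; a dead end discards the attempt (rejection sampling with
a `max_attempts` budget, default 10,000 — failure errors rather than
silently relaxing a constraint). Baseline objects are assigned to a random
subset of inter-triplet gaps, at most one per gap, which structurally
guarantees that baselines are never adjacent and are always followed by an
A. Per session this yields 672 stimulus events: 6 sequences × 2 variants ×
16 repetitions × 3 objects + 96 baseline presentations (16 per baseline
object, 4 per block — chosen over the alternative 2-per-block reading
because only 16 total presentations equate baseline exposure with C objects
and reproduce the design's P(baseline follows C) = 0.5).

The recognition order treats (baseline, C₁, C₂) triples, (A, B) pairs and
foils as atomic units; a shuffle is accepted only if no triple directly
follows another triple, which keeps every structural transition cell exact
(in particular, a C₂ is never immediately followed by a baseline object).
Exposure scans split roles so that an overlapping pair never shares a scan
(scan 1: A, C₁, half the baselines; scan 2: B, C₂, the rest); `n_targets`
objects receive a fifth, pound-sign presentation that the GLM routes to a
junk regressor; the same order serves the pre and post phase verbatim.

Timing: stimuli 2 s; learning ITIs uniform on {0,…,4} s and exposure ITIs on
{2,…,5} s (plain uniform jitter — scanner-efficiency ITI optimization is out
of scope); recognition ITI fixed at 1 s; explicit trials 6 s (ratings) or
4 s (2AFC).

# The synthetic cohort

Three subject latents drive every data channel, drawn from a multivariate
normal with means (60 ms, −0.10, 0.25), SDs (90 ms, 0.20, 0.80) and
correlations 0.6 (priming–integration), 0.6 (priming–coupling), 0.4
(integration–coupling):

* **priming** is subtracted from remote-session C₂ recognition RTs
  (log-normal around 800 ms, trial noise σ = 0.015 log-units);
* **integration** sets the pre-to-post change, on the Fisher-z scale, of the
  same-pair voxel-pattern correlation in mPFC for remotely learned C pairs
  (ρ_pre = 0.15, 250 voxels per ROI). Object patterns keep the same random
  basis across phases — representations persist; only the shared-component
  weight changes — so a zero change yields exactly zero measured change in
  the noiseless limit. Other ROI × session cells get non-latent draws that
  encode the qualitative background pattern (LOC integrates recent pairs
  immediately; hippocampal C-pair fits do not change; anterior hippocampus
  and LOC integrate recent AB pairs).
* **coupling** raises the posterior-hippocampus–LOC coupling (Fisher z) in
  the post-remote rest scan above the 0.3 baseline shared by all ROI pairs.
  Rest signals are mixtures of band-limited (0.01–0.1 Hz) unit-variance
  sources with a Cholesky factor of the target correlation matrix, plus
  voxel noise and nuisance contamination (smoothed random-walk motion,
  Bernoulli(0.02) spikes, tissue signals, linear drift) built from the
  returned nuisance table so that the nuisance GLM can remove it exactly.

Learning RTs are log-normal with a repetition decay (−0.15 log-units across
the 16 repetitions), extra decay for predictable roles (−0.08), a remote-
session slowdown (+0.05), and trial noise σ = 0.15; accuracy is generated
only for trials whose predecessor occupies the other size bin, the only
comparisons with a defined answer.

**Why the between-subject SDs are generous.** A 6-minute rest scan
band-limited to 0.01–0.1 Hz carries roughly 2·B·T ≈ 65 effective samples, so
a coupling Fisher-z estimate has an irreducible SD near 0.13 per scan
(≈ 0.18 for a change score); a 36-cell similarity matrix similarly bounds
the precision of an integration fit. For individual differences to be
recoverable at these fixed scan lengths, the latent SDs must comfortably
exceed those noise floors. The defaults were fixed once from this
reliability calculation (target measurement reliabilities ≈ 0.97–0.99)
together with a power calculation at n = 24 (remote priming detected in most
cohorts, recent-session effects null); they exaggerate between-subject
variance relative to typical human data, which is the price of making
recovery a sharp test.

**Two modes.** `mode = "patterns"` emits estimated patterns directly (truth
plus independent estimation noise, SD 0.12 per voxel), emulating GLM output;
`mode = "timeseries"` builds full voxel × volume scans by convolving each
object's 3-s boxcar train with the double-gamma HRF weighted by its pattern,
plus Gaussian noise (SD 1.2) and slow drift. The two are linked by a
fidelity check: at the default SNR, GLM *t*-patterns correlate > 0.9 with
the generating patterns, and on noise-free scans the GLM reproduces the
betas exactly, so large-cohort analyses can use the fast pattern mode while
the GLM path is validated separately.

# Numerical and statistical choices

* **HRF**: double-gamma, response delay 6 s, undershoot delay 16 s, unit
  dispersions, undershoot ratio 6, peak-normalized; sampled at TR/10 and
  decimated. Boxcars are 3 s although stimuli last 2 s, matching the
  estimation convention this pipeline targets.
* **GLM**: OLS per voxel via QR; t = β/SE with df = volumes − rank; rank
  deficiency is an error naming the collinear columns. Exposure scans are
  high-passed at 0.01 Hz (zero-phase Butterworth) before fitting.
* **Similarity**: patterns enter raw (no z-scoring; point-biserial fits are
  invariant to per-pattern mean shifts anyway — asserted as a property).
  Only cross-scan pairs are correlated, so within-scan temporal proximity
  cannot drive similarity; the 6×6 C₁ × C₂ matrix is the default and a
  within-scan variant is deliberately not offered.
* **Fisher z at |r| = 1** is capped at atanh(1 − 1e-15) and flagged
  degenerate; constant vectors are flagged rather than propagated as NaN.
* **Rest order of operations**: nuisance regression first, then band-pass of
  the residuals. The swapped order is exposed
  (`order = "filter_then_regress"`) and differs on contaminated data (spike
  regressors lose their one-hot structure after filtering) — the tests
  assert the inequality. ROI mean extraction commutes with both linear steps
  and is applied first for efficiency.
* **Sensitivity A**: the three-branch closed form was re-derived from the
  construction (mean of the areas under the minimal and maximal proper ROC
  curves through the observed point). Note the first branch is
  3/4 + (h−f)/4 − f(1−h); the variant with f(1−h)/2, which circulates in
  some secondary sources, is discontinuous on the chance diagonal and does
  not equal the geometric construction. Ties return exactly 0.5;
  below-diagonal points use A(h,f) = 1 − A(f,h).
* **Dependent correlation comparison** (e.g. remote vs recent brain–behavior
  correlations on the same subjects, no shared variable): the
  Raghunathan–Rosenthal–Rubin modification of Pearson–Filon, with the
  four cross-correlations computed from the data; with zero
  cross-correlations it reduces to the independent-samples Fisher test, and
  a simulated null puts its rejection rate at the nominal α.
* **Semi-partial R²** is the R²-drop of nested refits; the tests pin it to
  the independent identity t²(1 − R²)/df.
* **Mixed models** (lme4/lmerTest): random effects start maximal and are
  reduced along a fixed ladder until the fit is non-singular; the reduction
  path is recorded in the report. Learning curves are fit on per-repetition
  median RTs per predictability class; repetition is standardized inside the
  model for stable convergence.

# Parameter recovery and calibration

The cohort's acceptance surface is recovery: at n = 200 the analysis chain's
estimated cross-subject correlations among (priming, Δ-integration,
Δ-coupling) must land within ±0.1 of the generating targets. Two
finite-sample facts shape how this is run:

1. At n = 200, the *sample* correlation of an iid multivariate-normal draw
   has SD ≈ 0.05–0.06 around its population value — alone enough to leave
   the ±0.1 band occasionally even if measurement were perfect. Recovery
   analyses therefore condition the latent draw on the nominal moments
   (`empirical = TRUE`, exact sample mean and covariance), so the check
   isolates what it is meant to test: measurement fidelity. Calibration and
   power analyses use ordinary iid draws.
2. The measured integration change is a nonlinearly amplified version of the
   generating Fisher-z change (the point-biserial fit is steep in ρ when
   between-cell spread is small). Correlations are invariant to monotone
   near-linear maps, so recovery is unaffected, but group *means* on the
   measured scale are larger than the generating means and carry a small
   negative Jensen bias wherever the change varies across subjects. Group
   means should therefore be read qualitatively (sign and significance), not
   as estimates of the generating constants; one visible consequence is that
   the recent-session mPFC change, generated with a small negative mean,
   can reach significance on the measured scale.

Null calibration simulates all-zero-effect cohorts and checks that the group
tests on priming, integration change, coupling change and brain–behavior
correlations reject at α = 0.05 within binomial tolerance (800–2000 cohorts
per test; the integration and coupling nulls run on reduced problem sizes —
60 voxels, course-level coupling — since t-test calibration is scale-free).

The end-to-end qualitative check runs the full pipeline across 20 seeds at
n = 24 and requires the majority to reproduce the headline sign pattern:
remote-only priming; negative group mPFC change with a positive
across-subject correlation with priming; positive posterior-hippocampus–LOC
coupling change correlated with remote priming; both regression
semi-partials strictly positive.

Problem sizes used by the shipped tests and acceptance script — 100
Monte-Carlo learning orders, 200-subject recovery cohorts in pattern mode,
single-subject GLM fidelity runs, 20-seed sign-pattern sweeps — were chosen
as the package's own balance between Monte-Carlo precision and a test suite
that runs comfortably on a laptop.

# What passing tests do and do not show

The generator emulates the paradigm's structure, not scanner physics: no
slice timing, motion, registration, multi-echo combination, physiological
noise, or anatomical ROI definition; voxel noise is Gaussian and
object-pattern geometry is isotropic; RTs are log-normal with multiplicative
effects. Passing recovery therefore demonstrates that the analysis chain is
a faithful estimator of the quantities it claims to estimate under a known
generative model — it does not certify performance on real fMRI data, where
nuisance structure is richer and effect sizes smaller. The design generator,
by contrast, is exact: every structural constraint is enforced and verified
by exhaustive scans, so generated event tables are usable as-is for real
experiments.

# Known limitations

* Recognition foil placement matches the paradigm's hard constraints; the
  remaining foil-row transition probabilities are emergent and only
  approximately match descriptive values from human-run orders.
* The measured-scale amplification of integration change (above) makes group
  means scale-dependent; comparisons across ROIs with different voxel counts
  should use correlations or standardized effects.
* `simulate_rest` clamps target correlation matrices to the positive-
  definite cone; extreme latent draws (|Δz| ≳ 1.5) are therefore realized
  slightly shrunken.
* The mixed-model reduction ladder is fixed (slopes dropped before
  intercepts); other reduction orders are defensible and may change
  borderline F statistics.
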