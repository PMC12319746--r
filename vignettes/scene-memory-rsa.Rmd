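---
title: "Detecting reinstated and transformed scene memories with scenersa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reinstated and transformed scene memories with scenersa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenersa)
```

## The problem

When people repeatedly encode different objects against a small set of
recurring scenes, two distinct neural signatures of memory can be measured
with multivoxel pattern analysis the next day:

* **Reinstatement** — during successful recall, the scene-specific voxel
  pattern from the *encoding* phase reappears. It is measured as
  *encoding-retrieval similarity* (ERS): the Fisher-z-transformed Pearson
  correlation between an encoding-trial pattern and a retrieval-trial
  pattern, higher for same-scene than different-scene pairs, and gated by
  whether the trial was remembered.
* **Transformation / convergence** — retrieval patterns of trials that share
  a scene converge onto a *shared* representation that need not resemble the
  encoding pattern at all. It is measured as *retrieval-retrieval
  similarity* (RRS): the correlation between two retrieval-trial patterns,
  higher for same-scene pairs. Reward at encoding can gate this convergence.

The two signatures are easily confounded: if two retrieval trials both
reinstate the same encoding pattern, they also resemble each other. The
package therefore implements, besides the two similarity analyses, the
control analyses that separate them (RRS-vs-ERS effect contrasts,
across-subject correlations, within-subject slope regressions, and
label-permutation z-scores), plus a searchlight variant with sign-flip
max-statistic family-wise error control.

## The task design

One synthetic subject mirrors the reference design: 160 objects, each
paired with one of 4 recurring scenes; two scenes carry high reward, two
low reward (reward is a pure function of the scene). Encoding presents each
object-scene pair twice within one of 4 runs (320 trials), pseudo-randomized
so that every scene occurs equally often in every run and all pairs of a run
appear once before any repetition. Retrieval the next day shows each object
once across 4 runs (160 trials); the subject picks one of the four scene
labels or "don't know". Behavioral parameters default to the reference
values: encoding accuracy 0.97 per repetition, recall probability 0.537
(high reward) and 0.513 (low reward). The split of non-remembered responses
between wrong scenes and "don't know" is not constrained by any reported
value; it is a parameter (`p_dont_know`, default 0.5).

```{r design}
d <- make_design(n_objects = 160, n_scenes = 4, n_runs = 4, n_reps = 2, seed = 1)
nrow(d$encoding); nrow(d$retrieval)
table(d$encoding$run, d$encoding$scene_id)
```

## The generative pattern model

Patterns are built from unit-norm prototype vectors in voxel space:

* scene encoding prototypes `P_s` (one per scene),
* scene retrieval prototypes `Q_s`, drawn independently and then
  **orthogonalized against the span of all `P_s`**,
* one unit vector per object.

An encoding trial is `g_enc * P_s + g_obj * O_o + noise`; a retrieval trial
is `g_reinst(memory) * P_s + g_conv(reward) * Q_s + g_obj * O_o + noise`,
with i.i.d. Gaussian noise (`noise_sd = 1`). Because `Q` is orthogonal to
`P`, planted convergence cannot masquerade as reinstatement or vice versa —
the generator plants exactly the dissociation the analyses are meant to
detect, which is what makes every downstream stage testable without scanner
data.

Four presets (`region_profile()`) encode the characteristic regional
patterns as ground truth: `phc_like` (memory-gated reinstatement only),
`mpfc_like` (reward-independent convergence only), `ahc_like` (high-reward
convergence only), and `null` (no structure; the exchangeable null).

### Choice of the default gains

With unit-norm prototypes and `V` voxels, two components with gains `g1`,
`g2` sharing a prototype induce an expected pair correlation of roughly
`g1 * g2 / (V * s1 * s2)`, with `s` the per-voxel pattern standard
deviations. The defaults (`g_enc = 10`, `g_obj = 8`, `g_conv = 1`,
`g_reinst = 0.15`, `V = 150`) were fixed once, by this analytic power
computation plus a small pilot, to satisfy two opposing constraints at the
study's size (n = 40 subjects):

* the on-target effects (ERS memory-by-overlap for `phc_like`, RRS overlap
  for `mpfc_like`, RRS reward-by-overlap for `ahc_like`) are detected in
  well over 90% of cohorts;
* the *second-order leakage* of reinstatement into RRS — two remembered
  same-scene retrieval trials share `g_reinst * P_s`, giving an unavoidable
  RRS covariance proportional to `g_reinst^2` while the ERS signal scales
  with `g_enc * g_reinst` — stays near the 5% false-positive level. This is
  why the reinstatement gain is an order of magnitude below the convergence
  gain: a physically faithful reminder that a *perfect* dissociation is
  impossible in this generative family, only a quantitative one.

The resulting per-subject similarity landscape is realistic in scale: mean
pair z values of a few hundredths, ~1400 retained ERS pairs and ~260
retained RRS pairs per condition cell.

## Pair bookkeeping

All similarity values are binned into 8 cells: reward (high/low) x memory
(remembered/forgotten) x scene overlap (same/different), in the fixed order
`HR-same ... LF-diff`. The inclusion rules are exact and testable:

* ERS pairs join one encoding and one retrieval trial, never of the same
  object (same-object similarity is perceptual, not mnemonic), with both
  members in the same reward-by-memory condition, and both objects answered
  correctly on *every* encoding repetition.
* RRS pairs join two retrieval trials from *different runs* (within-run
  pairs share slow scanner noise), same condition, both objects fully
  correct at encoding.

Condition membership requires both members to share reward *and* memory
status; since reward is a function of the scene, different-scene pairs in a
condition always join the two scenes of one reward level. An encoding trial
inherits its object's retrieval outcome. The test suite checks the
enumeration against an exhaustive double-loop oracle on 100 randomized
designs.

For bilateral regions, cell means are computed per hemisphere and then
averaged (`combine_hemispheres()`) — pooling pairs instead would let
hemisphere size differences reweight the average.

## Group inference

`rm_anova_2x2x2()` implements the three-way repeated-measures ANOVA by
per-subject contrast scores: each effect's F(1, n-1) is the squared
one-sample t of the contrast-weighted cell means. For two-level
within-subject designs this is algebraically identical to the classical
sums-of-squares decomposition (verified to 1e-8 in the tests against an
independent implementation); sphericity corrections are moot at two levels.
Subjects with any empty cell are excluded from that region's ANOVA, with a
message.

Because recall rates differ across conditions, per-cell pair counts are
imbalanced within and across subjects. `permutation_z()` guards against
count-driven artifacts: cell labels are permuted across *all* included
pairs of a subject (preserving the per-cell counts exactly), the effect is
recomputed per permutation, and the subject's true effect is z-scored
against this null (`(true - mean) / sd`; a rank-based variant would be an
alternative reading, but the mean/sd z is the straightforward one and is
what the calibration tests check: under the exchangeable null the z's have
mean ~0 and sd ~1). The group test on the z's is one-sided (greater), as the
question is whether the true effects exceed their permutation nulls;
everything else in the package is two-sided. ROI-scale default is 10,000
permutations; searchlight scale, 1,000; tests use reduced counts via the
`n_perm` argument (a precision choice, not a different procedure).

Control analyses: `rrs_vs_ers_contrast()` (paired t on per-subject effect
scores from the two analyses), `across_subject_corr()`,
`single_trial_index()` plus `slope_regression()` (per-subject OLS slope of
the single-trial convergence index on the single-trial reinstatement index,
group t against zero).

## Single-trial GLM

`beta_series()` estimates one GLM per trial on concatenated runs: an
HRF-convolved regressor for the trial of interest; per-condition
"all other onsets" regressors (HR/HF/LR/LF); a button-press regressor; seven
non-convolved confounds (six motion parameters plus framewise displacement,
consumed, never computed); and one constant per run. Betas are converted to
t maps using the OLS residual variance with `df = scans - rank(X)`.
Choices the reference procedure leaves open, made here and parameterized:

* HRF: canonical double-gamma (delay 6/16 s, dispersion 1/1, ratio 6).
* Event regressors are boxcars of the stimulus duration (3.75 s encoding,
  3 s retrieval) rather than impulses; `trial_duration` overrides.
* No temporal autocorrelation model: t values are OLS t's. This biases
  single-trial t's equally across conditions and cancels in all contrasts.
* Condition groups left empty after removing the trial of interest are
  omitted with a notice rather than entered as all-zero columns.

`gaussian_smooth()` applies the separable Gaussian kernel
(`sigma = FWHM / (2 sqrt(2 log 2))` per axis, zero-padded edges, kernel
truncated at 4 sigma and renormalized); 2 mm FWHM is the minimal smoothing
used before RSA, 6 mm the group-map smoothing.

## Searchlight and FWE

`searchlight_effects()` repeats the ROI analysis in a moving sphere
(default radius 3 voxels = 123 lattice offsets) centered on every in-mask
voxel, reusing the globally enumerated pair list; centers whose sphere
holds fewer than `min_voxels` in-mask voxels (default: half the sphere, at
least 2 — a correlation needs two voxels) are missing. Peak-level
family-wise error control is by **sign-flip max-statistic permutation**
(`fwe_maxstat()`): under the group null the subject effect maps are
symmetric around zero, so random sign flips generate the null distribution
of the volume-wide maximum |t|; a voxel's corrected p is the proportion of
permutations (observed map included) whose maximum reaches its |t|, with
minimum attainable p of `1/(n_perm+1)`. This replaces parametric
random-field-theory peak correction deliberately: it is assumption-light,
exact under exchangeability, and its family-wise error rate is directly
testable (the suite verifies ~5% under the null). Small-volume correction
restricts the maximum to a mask subset and can only shrink corrected p's.
Group maps assume a shared voxel grid; real data must be spatially
normalized upstream.

## Numerical and degenerate-input policy

* Correlations with |r| within 1e-7 of 1, and zero-variance patterns, raise
  errors rather than being clipped — with noisy data they indicate a bug
  (duplicated trials, constant voxels), not signal.
* Contrast scores below 64 machine epsilons of the cell-value scale are
  treated as exact zeros, so identical cells give F = 0 rather than
  floating-point noise ratios.
* Zero-variance t-test inputs: t = 0 / p = 1 when the mean matches the null
  value, otherwise `NA` with an explanatory note attribute.
* A degenerate permutation null (sd = 0) is an explicit error.
* All randomness flows from explicit integer seeds; identical configurations
  produce byte-identical pipeline outputs.

## What the synthetic data do and do not establish

The generator emulates the design's combinatorics, behavioral rates, and a
low-rank signal-plus-noise pattern structure with i.i.d. Gaussian noise. It
does not emulate spatial autocorrelation, physiological noise spectra,
scanner drift in the pattern domain, inter-subject anatomical variability,
or any systematic relation between confidence/RT and the neural patterns.
Passing tests therefore establish that the *pipeline* is correct and
calibrated (rule-exact pair bookkeeping, exact ANOVA algebra, honest
type-I error, recovery of planted effects at realistic sizes) — not that
real tissue behaves like the model. Problem sizes in the test suite (e.g.
48-object designs for null calibrations, 40-cohort pilots, reduced
permutation counts) were chosen as the smallest sizes at which the checked
quantities are statistically decisive.

## Known limitations

* No representational-distance measures beyond Pearson correlation (no
  crossnobis/Mahalanobis), matching the reference analysis.
* No mixed-effects or hierarchical trial-level models; group inference is
  subject-summary based.
* No cluster-extent or TFCE inference for the searchlight; peak-level only.
* The GLM stage omits slice-timing, motion correction, distortion
  correction and normalization — it consumes preprocessed data.
* `fwe_maxstat()` assumes subject exchangeability and symmetric null
  effects; heavy-tailed subject effects would make it conservative, not
  invalid.
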