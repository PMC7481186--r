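---
title: "Decoding and representational similarity analysis of illusory-face dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and representational similarity analysis of illusory-face dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pareidorsa)
```

## The analysis problem

Face pareidolia — the spontaneous perception of an illusory face in an
inanimate object — offers a window on the brain's face-detection machinery:
an illusory face shares its object identity and most of its visual features
with a matched non-face object, so any neural difference between the two is
attributable to the illusory facial configuration. The analysis implemented
here asks two questions about that difference. *Where* is it represented:
which category-selective visual regions (FFA, OFA, LO, PPA) carry patterns
that discriminate illusory faces from matched objects? And *when*: how does
the whole-brain representation of an illusory face evolve, relative to human
faces and matched objects, over the first several hundred milliseconds?

The package implements the full pipeline for both questions — pairwise
cross-decoding with exemplar-generalizing cross-validation, time-resolved
representational dissimilarity analysis, image-computable and behavioral
model comparison, threshold-free cluster enhancement (TFCE) inference, and
fMRI–MEG fusion — together with a synthetic-data generator that emulates the
yoked three-category design, so every stage is exercised end to end without
access to recordings.

## The design and its estimators

**Stimulus design.** 96 images: 32 human faces, 32 illusory faces, and 32
matched objects, with every illusory face yoked to a matched object of the
same kind. `stimulus_set()` enforces the yoke bijection and equal category
counts. All decoding is *cross-exemplar*: a classifier is trained on all but
one exemplar (pair) per category and tested on the held-out exemplars, so
above-chance accuracy requires generalization to new images rather than
memorization of image-specific patterns. `make_folds()` provides three
schemes:

* `paired_exemplar` — N folds; exemplar *i* of each category held out
  together. For the illusory/matched pair the *yoked partner* is held out
  with its yoke: yoked images are visually similar by construction, and
  leaving one of them in the training set would leak test-specific visual
  structure.
* `exhaustive_exemplar` — all N² cross-category combinations (the
  time-resolved sensor-level procedure).
* `run_by_exemplar` — the combined leave-one-run-out and
  leave-one-exemplar-out procedure used for run-wise beta patterns: the
  held-out pair is tested only on the held-out run.

The methods text for the sensor-level analysis ("each combination of
exemplars") admits both the paired and the exhaustive reading; both are
implemented and the scheme tag is carried into every result. The exhaustive
scheme is the sensor-space default; the pipeline's desk-scale configuration
uses the paired scheme, which agrees with it to within ~2 accuracy points on
high-SNR data (a property the test suite checks) at 1/N the cost.

**Classifiers.** Time-resolved decoding uses regularized linear discriminant
analysis (`fit_predict_lda()`): pooled within-class covariance shrunk toward
a scaled identity, `S* = (1 - γ) S + γ (tr(S)/p) I`, equal priors, ties
broken toward the lexicographically first label. The shrinkage default is
γ = 0.05: at high component counts trials-per-fold can approach the feature
count and the unregularized pooled covariance becomes ill-conditioned; 0.05
is small enough to leave well-conditioned problems essentially unchanged
(γ = 1 degenerates, by design, to nearest-centroid — a property used as a
test oracle). ROI and searchlight decoding default to a linear soft-margin
SVM (cost 1), matching common practice for beta-pattern MVPA.

**RDMs.** `compute_rdm()` defines dissimilarity as 1 − Spearman correlation
between feature vectors; entries therefore live in [0, 2] and the container
enforces symmetry and a zero diagonal. All RDM–RDM statistics consume one
canonical vectorization — the strict lower triangle in row-major order — so
two statistics can never silently disagree about entry order. Group RDMs are
arithmetic means of subject RDMs; no rank transform is applied before
averaging.

**Model comparison.** RDM–RDM agreement uses Kendall's τ-a
(`kendall_tau_a()`): (concordant − discordant) / (n(n−1)/2), with tied pairs
counting as neither. τ-a rather than τ-b or Spearman because model RDMs
(categorical predictors, behavioral ratings) are full of ties, and τ-a does
not reward a model for predicting ties it happens to share with the data.
The noise ceiling (`noise_ceiling()`) brackets the best achievable τ-a:
upper bound — each subject's RDM against the all-subject mean; lower bound —
against the mean excluding that subject. Model and fusion correlations
remove the human faces from both sides by default: human faces evoke a
dominant response that would inflate any model correlation, and the
scientific question concerns objects with and without an illusory face.

**Fusion.** `fusion_timecourse()` correlates one *group-average* region RDM
with each sensor-level subject's RDM at every timepoint. The two cohorts are
different individuals, so pairing at the subject level is impossible;
inference is across the sensor-level cohort.

**Inference.** Decoding-vs-chance and τ-vs-zero use one-tailed tests
(the hypotheses are directional); two-tailed variants are available.
Timecourses are corrected with TFCE (E = 0.5, H = 2, dh = 0.1 — the standard
parameterization of the reference implementation; the enhanced score of an
isolated unit-height sample, 0.385, is pinned as an exact oracle) and
sign-flip permutation across subjects with max-statistic family-wise
control. For n ≤ 12 subjects all 2ⁿ sign assignments are enumerated, making
the test exact; above that, `n_perm` random flips are drawn (default 1000,
seeded). Permutation p-values include the observed statistic in the null
(+1/+1 convention), so p = 0 is impossible. Batch p-values are adjusted with
Benjamini–Hochberg FDR by default.

## The synthetic-data generator

The generator is not a fixture factory; it is the package's specification of
the study conditions. Its central object is a *trajectory*
(`build_trajectory()`): a set of keyframes, each holding a 3×3 matrix of
target category-centroid distances Δ(t) and a within-category exemplar
spread σ_ex(t), interpolated piecewise-linearly, zero before a response
onset (default 60 ms), held constant after the last keyframe. The default
trajectory places keyframes at 130, 160, and 260 ms:

* 130 ms — all three categories separable; illusory faces already closer to
  human faces than the matched objects are (Δ(H,I) = 0.8 < Δ(H,M) = 1.0,
  Δ(I,M) = 0.4);
* 160 ms — peak separation, same ordering (1.2 / 1.6 / 0.8);
* 260 ms — illusory faces regroup with matched objects (Δ(I,M) collapses to
  0.15) while human faces remain maximally distinct (1.6 / 1.7).

This encodes the transient face-like response: an early period in which the
illusory-face representation resembles human faces, resolved within a
quarter second into an object-like representation.

Data are constructed by embedding Δ(t) as three centroids in a 2-D latent
plane (classical MDS; any three distances satisfying the triangle inequality
embed exactly, and convex combinations of embeddable matrices stay
embeddable, so validity is checked only at keyframes), adding fixed
per-exemplar offsets in an orthogonal latent subspace (default 4-D) scaled
by σ_ex(t), mixing into sensors through a subject-specific random matrix,
and adding i.i.d. Gaussian sensor noise. Exemplar offsets are fixed across
time and subjects (stimulus identity is stable); mixing matrices differ
across subjects (sensor-space analysis assumes no cross-subject pattern
alignment). Yoked illusory/matched pairs receive correlated offsets
(default r = 0.5), mimicking the visual similarity of yokes. The fMRI
generator reuses the same latent construction with per-region distance
profiles: the face-selective profiles (FFA, OFA) carry
Δ(illusory, matched) > 0, the object/scene profiles (LO, PPA) set it to 0.

Ratings are generated on the bounded 0–10 scale with scaled Beta
distributions matched to the target mean and SD by moments (human faces
9.96 ± 0.10, illusory faces 6.27 ± 0.79, matched objects 0.70 ± 0.36 across
items). A Beta rather than a clipped Gaussian because clipping near the
scale ends (human faces sit 0.4 SD below the maximum) would bias the
realized category means, and the generator's contract is to hit those means
exactly in expectation.

What the generator does *not* emulate: biophysical forward models, temporal
autocorrelation of sensor noise (analysis is per-timepoint), hemodynamic
convolution, eye movements, and — importantly — the rich full-rank
covariance of real sensor noise. Passing tests therefore demonstrate that
the estimators recover known geometry and calibrate correctly under the
stated noise model, not that they would do so under every real-data
pathology.

## Numerical and design choices

**Downsampling** (`downsample()`) is bin-mean anti-aliasing, not decimation:
the output grid keeps the first input latency with step 1000/rate ms, and
each source sample is averaged into its nearest gridpoint. On the
−100..1000 ms epoch at 1000 Hz this yields the canonical 221-point, 5 ms
grid with the 130/160/260 ms keyframes exactly on-grid; the two edge bins
are partial.

**PCA** (`pca_reduce()`) is fitted once per subject on all trial-timepoints
jointly (not per timepoint), retaining the smallest component count reaching
99% cumulative variance. The pre-stimulus window is included in the fit —
the procedure is a dimensionality reduction of the whole recording, not a
stimulus-locked transform — and component signs are fixed deterministically.

**RDMs are computed in sensor space, not component space.** This is a
deliberate deviation, and the reason is worth recording. A Spearman
correlation distance is not invariant to rotations of feature space. In the
PC basis, feature variances are sorted, and the *rank* transform then gives
every retained component equal weight — including components that carry
nothing but isotropic noise. With a low-rank latent geometry (as in the
generator, and plausibly in any strongly structured dataset), this flattens
and can even invert the category geometry, while the same RDMs computed on
raw channels recover it exactly. On real 160-channel recordings with
spatially structured noise, computing RDMs after 99% PCA is a benign
computational convenience; at the package's desk scale (≤ 32 channels)
there is nothing to reduce, so the pipeline computes RDM timecourses from
sensor epochs and reserves PCA for the decoding path, where the classifier's
covariance model handles component scaling correctly.

**Degenerate inputs.** Zero within-class scatter (noise-free repeats) makes
the shrinkage target itself zero; the LDA falls back to the identity metric,
i.e. nearest centroid. A constant pattern has no defined correlation and is
rejected with the offending item named; a constant *image* in the GIST path
instead returns a zero descriptor with a warning record, since a blank
stimulus is a representable (if degenerate) input. A group of subjects all
exactly at chance yields t = 0 and one-tailed p = 0.5; all at the same
non-chance value is reported by `report()` as a saturated (infinite-t)
limit. t-maps inside the TFCE permutation engine are capped at |t| = 1000 so
a zero-variance timepoint cannot stretch the height integration
indefinitely.

**Image models.** GBVS builds, per feature map, a fully connected Markov
chain over map locations with transition weight
|log(m_i/m_j)| · exp(−d²/(2σ²)), takes its equilibrium distribution (power
iteration, tolerance 1e−9), and applies a second, identically structured
mass-concentration pass; internal resolution 32×32, σ = 0.15 × map width,
channels (intensity, two color-opponency maps, four orientation energies) at
two scales, equal weights. GIST uses a local-contrast-normalization
prefilter and a 4-scale × 8-orientation log-Gabor bank pooled over a 4×4
grid (512-dimensional descriptor). These are published-default
parameterizations, recorded in each output's parameterization attribute;
the original studies do not state the exact settings used, so exact numeric
replication of their printed statistics is contingent on matching those
defaults.

**Determinism.** Every stochastic operation takes a seed; generators restore
the caller's RNG state. The pipeline derives per-stage seeds from one master
seed, and re-running a configuration reproduces byte-identical CSV outputs
(a test asserts this).

## Problem sizes

The package's tests and acceptance analyses run the full design logic at a
reduced scale chosen once: 8 subjects, 8 exemplars per category, 24
channels, 6 runs × 4 repeats (24 trials per stimulus), and a −100..390 ms
epoch at 100 Hz — 50 timepoints covering all three keyframes. High-SNR
recovery conditions use signal gain 3 with sensor noise SD 0.5, under which
illusory-vs-matched decoding reaches ~100% at the 160 ms keyframe and falls
to ~70% by 260 ms; null calibration uses signal gain 0. The fMRI experiment
uses 8 subjects, 4 runs, and 36–60 voxels per region. The full-size design
(22 subjects, 160 channels, 2304 trials at 1000 Hz) is supported by the same
code paths; `meg_dims()` reports the implied array dimensions.

## Known limitations

* Magnitudes are not calibrated: the generator's SNR parameters are free, so
  only ordinal and qualitative patterns (which region decodes, which
  keyframe peaks, which windows are significant) are meaningful recovery
  targets — not absolute accuracy values.
* The searchlight is volumetric and exemplar-only (no run-wise CV), matching
  the faster whole-brain procedure; surface-based mapping is out of scope.
* Sign-permutation inference with fewer than ~6 subjects cannot reach
  p < 0.05 under exhaustive enumeration (2ⁿ flips); this is a property of
  the exact test, not a bug.
* The epoch container round-trips through R serialization; vendor MEG
  formats and NIfTI volumes are expected to be converted upstream.
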