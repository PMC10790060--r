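---
title: "Cross-sample entropy connectivity and seed-ROI CNN classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sample entropy connectivity and seed-ROI CNN classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csefc)
```

## Overview

`csefc` implements a pipeline for predicting a binary clinical outcome —
suicidality in late-life depression is the motivating application — from
resting-state fMRI. The chain is:

1. **Time-series cleaning** of per-region (ROI) signals: motion censoring,
   detrending, band-pass filtering to 0.01–0.08 Hz, nuisance regression.
2. **Cross-sample entropy (CSE)** between every pair of the R atlas regions,
   giving an R × R asynchrony matrix per subject.
3. **Reference normalization**: entrywise z-scoring of each matrix against
   the mean and SD of the non-suicidal (NS) reference group.
4. **Seed-ROI volume painting**: row *i* of the normalized matrix is painted
   into the atlas grid (every voxel of region *k* receives entry (*i*, *k*)),
   yielding one 3D volume per seed region — 91 × 109 × 91 on the 2-mm MNI
   grid with a 90-region parcellation.
5. **Per-seed 3D CNN classification** with stratified k-fold
   cross-validation, per-region accuracy aggregation, 95% confidence
   intervals, threshold/reliability ranking, and majority-vote ensembling
   across seed regions.

A synthetic cohort generator with known, tunable group structure makes every
stage testable without clinical data.

## Cross-sample entropy

For standardized series $x$, $y$ of length $N$, embedding dimension $m$ and
tolerance $r$, count ordered template pairs $(i, j)$, $i, j \le N - m$, whose
length-$m$ sub-vectors lie within Chebyshev distance $< r$ ($B$ matches) and
whose length-$(m+1)$ continuations also do ($A$ matches). Then

$$\mathrm{CSE} = -\ln\frac{A}{B}.$$

Lower values mean the two signals are more mutually predictable (more
synchronous). Defaults are $m = 2$ and $r = 0.6$.

Conventions, each of which matters numerically:

* **Template range.** Both lengths are counted over the same $N - m$ start
  positions (the Richman–Moorman sample-entropy convention). This guarantees
  $A \le B$ and therefore $\mathrm{CSE} \ge 0$. Using $N - m - 1$ positions
  for one length but not the other would break the inequality.
* **Tolerance units.** Each series is standardized to unit SD before
  matching, so $r$ is in SD units; this also makes CSE invariant to affine
  rescaling of the raw signal. A raw-units mode
  (`entropy_params(standardize = FALSE)`) exists for sensitivity checks.
* **Strict inequality** $d < r$ defines a match.
* **Degenerate counts.** If $B = 0$ the value is undefined and recorded in
  the matrix's undefined mask. If $B > 0$ but $A = 0$, the default `"cap"`
  policy substitutes the largest observable value,
  $-\ln\!\big(1 / n_{\mathrm{templates}}^2\big)$, keeping matrices complete
  for the classifier; the `"missing"` policy records `NA` instead.
* **Diagonal.** Self-pairs are computed by the same formula applied to
  $(x, x)$; `include_diagonal = FALSE` masks them.

The production counter is a vectorized shift-and-AND over the $T \times T$
proximity matrix; the test suite verifies it exactly (same integer counts)
against an explicit double-loop enumeration on hundreds of random pairs.

## Reference normalization and leakage

The reference normalization centers and scales each CSE entry by the NS
group's mean and sample SD ($n-1$ denominator; the reference group is
small, so the unbiased estimator is used). Whether the NS subjects of the
*test* fold belong in that reference is a genuinely open design choice; a
global reading includes them, which leaks test statistics into training
inputs. The default here is therefore fold-scoped: reference statistics are
fitted per CV fold on the training-fold NS subjects only
(`normalization = "fold"`), and a `"global"` flag reproduces the global
reading. The fold-scoped reference is auditable: perturbing any test-fold
subject leaves the serialized reference statistics bit-identical.

Background voxels of painted volumes carry 0, which after z-scoring is the
reference mean — uninformative to the classifier by construction.

## The 3D CNN

Layer sequence (all convolutions unpadded, pooling with floor division):

average-pool 2³ → conv 32×3³ → ReLU → max-pool 2³ → batch-norm →
conv 64×3³ → ReLU → max-pool 2³ → batch-norm → conv 128×2³ → ReLU →
flatten → fc 500 → fc 500 → fc 500 → fc 2 + softmax.

Training uses categorical cross-entropy, Adam at learning rate $10^{-3}$,
batch size 32, at most 400 epochs, early stopping when the monitored loss
has not improved for 60 epochs, with best-epoch weights restored. Classes
are one-hot in the order (non-suicidal, suicidal).

Decisions taken where the design was genuinely open:

* **Max-pool / batch-norm order** after conv1 and conv2 is pool-then-norm,
  configurable via `bn_before_pool`.
* **Early-stopping monitor** is the *validation* loss — the validation fold
  exists to estimate generalization error, so "the loss" is read as that
  quantity.
* **Padding** is "valid" everywhere; this minimizes the first fully
  connected layer's parameter count and is the conservative reading of an
  unstated choice.
* **Ties** in the softmax argmax break toward the suicidality class, as does
  the ensemble majority vote.

The network is implemented natively in the package: convolutions run as
im2col gathers (compiled) followed by BLAS matrix products, pooling uses
precomputed window index maps, and all randomness flows through R's RNG, so
seeded training is bit-reproducible on one CPU. An introspection routine
(`cnn_audit()`) emits the realized layer sequence so the architecture can be
asserted rather than assumed.

### Desk-scale profile

The full stack needs input extents of at least 28³ (two max-pools between
three valid convolutions). For toy atlases the `"reduced"` profile keeps the
identical layer sequence but uses average-pool size 1, filters 4/8/8 and
fully connected widths 32/32/32/2, which fits a 24³ volume and trains in
seconds per model on one CPU. The reduced profile is a test vehicle; the
full profile is the default for MNI-sized volumes.

## Cross-validation design

Subjects are split into $k$ folds (default 6) stratified over the three
clinical groups (NS, suicidal ideation, suicide attempt): each stratum is
shuffled and dealt a base allocation of $\lfloor n_s / k \rfloor$ per fold,
and stratum remainders go greedily to the folds with the smallest current
totals (ties to the lowest index). For the 35/26/22 cohort this yields the
fold sizes 14, 14, 14, 14, 14, 13 while keeping every stratum in every
fold. Within each CV iteration, fold $f$ is the test set, fold
$(f \bmod k) + 1$ the validation set (a deterministic rotation; any fixed
choice of validation fold is equally valid, so the rotation is logged), and the remaining $k - 2$ folds
train the model, retrained from scratch per fold with a fold-specific seed
derived from the master seed.

Per seed ROI, the report carries the $k$ fold accuracies, their mean, the
pooled-prediction accuracy (identical to the fold mean only at equal fold
sizes; both are reported), a t-based 95% confidence interval
$\bar a \pm t_{0.975, k-1}\, s/\sqrt{k}$ clamped to $[0, 1]$ (a Wilson
interval on pooled predictions is a documented alternative with known
divergence risk at small $k$), and two flags with *strict* comparisons:
`above_threshold` (mean $> 0.75$) and `reliable` (every fold $> 0.75$).

## The synthetic cohort generator

The generator emulates the target acquisition and cohort: 90 regions, 180 timepoints at
TR = 2 s, signals band-limited to 0.01–0.08 Hz, and group sizes 35 NS /
26 SI / 22 SA. Each region carries standardized band-passed AR(1) noise
(AR coefficient 0.3). Regions in `effect_rois` additionally mix a latent
signal shared within the subject:

$$x_i = \sqrt{1 - w^2}\,\varepsilon_i + w\, z,$$

with $w$ = `coupling_ns` for NS subjects and `coupling_s` for SI/SA (an SA
override exists for future three-class work). A master seed derives
per-subject seeds by a fixed offset, so cohorts are reproducible while
subjects stay independent.

**Choice of the latent's spectral band.** The latent is band-passed Gaussian
noise in 0.01–0.04 Hz — the slow half of the pass band — emulating the slow
coherent fluctuations that dominate resting-state network coupling. This
choice is load-bearing for what CSE can see. Characterizing CSE
($m = 2$, $r = 0.6$, $T = 180$) on band-limited Gaussian pairs shows that
*pure phase synchrony is nearly invisible to it*: template matching scans
all lag pairs, so two independent narrowband series already match wherever
their phases coincide, leaving little room for a same-spectrum shared
latent to change the match ratio. What CSE does sense is
the regularity of the joint waveform: mixing in a *smoother* common
component makes coupled regions more mutually predictable, and mean
effect-pair CSE then decreases monotonically in $w$ — the property the test
suite verifies over 50 simulated subjects per coupling level on the grid
$w = 0, 0.45, 0.9$. A latent concentrated
at the fast end of the band instead produces a non-monotone bump at
intermediate coupling (mixture roughness) and leaks a rough-waveform
signature into every row of the CSE matrix.

**What the generator does not emulate:** hemodynamics, spatial noise,
physiological artifacts, scanner drift, or voxel-level 4D structure beyond
painting region series uniformly into atlas voxels (a helper provided for
end-to-end extraction tests). Passing synthetic-recovery tests therefore
demonstrates that the pipeline's statistics and learning machinery work as
designed — not that real fMRI cohorts carry a recoverable effect of any
particular size. The coupling levels are calibration knobs, not estimates of
the clinical effect.

## The recovery benchmark

`recovery_benchmark()` is the package's standard end-to-end experiment,
sized so the complete method (simulation → CSE → fold-scoped normalization →
seed-ROI volumes → CNN training → report) runs in minutes on one CPU:
48 subjects (20/14/14), 20 regions on a 24³ toy atlas, effect regions
{1, 2} with coupling 0 (NS) vs 0.8 (suicidal), threefold CV, reduced
profile, and desk-scale training (30 epochs maximum, batch 16, patience 6 —
chosen once as appropriate for 16-subject training folds). With
`coupling_s = 0` the identical experiment becomes a null-calibration run, in
which per-region accuracies should stay within the exact binomial chance
band around the majority-class rate and essentially no region should clear
the 75% threshold.

## Numerical notes and limitations

* The band-pass filter is an ideal rectangular spectral mask with inclusive
  edges (matching the common resting-state toolbox behavior); it assumes
  circular stationarity and will ring on strong transients.
* Nuisance regression uses the minimum-norm (SVD) solution, so
  rank-deficient confound sets cannot fail.
* Motion censoring applies the 2 mm / 2° thresholds to all three
  translation axes and all three rotation angles (conservative reading of an
  "axial displacement" criterion; `axial_only = TRUE` restricts to z) and
  drops flagged frames without interpolation, shortening the series seen by
  CSE.
* Constant (zero-SD) series standardize to all-zeros rather than NaN; CSE of
  two such series is 0.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1) at inference; with very few epochs the running
  estimates are coarse, which is one reason desk-scale runs train for at
  least ~10 epochs.
* Fold-level accuracies from a trained classifier are correlated across
  subjects within a fold, so binomial bands on pooled accuracy are
  approximate; the suite uses them as calibrated guards, not as exact
  hypothesis tests.
* The three-class problem (NS / ideation / attempt) is out of scope; the
  generator exposes a per-stratum coupling override so a three-class
  extension can reuse it.
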