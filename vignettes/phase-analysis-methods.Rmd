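---
title: "Phase analysis of gated blood-pool studies: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase analysis of gated blood-pool studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnvgphase)
```

## The measurement model

A gated blood-pool study bins scintigraphic counts into F frames (default
24) over one averaged cardiac cycle on a 64×64 matrix. For each pixel the
time–activity curve tracks regional blood volume: counts fall as the
region empties. The package models each curve by its first Fourier
harmonic,

$$ c_k = a_0 - A\,\cos\!\left(\frac{2\pi k}{F} - \frac{2\pi\varphi}{360}\right),
\qquad k = 0,\dots,F-1, $$

estimated exactly by the DFT at the fundamental frequency (for complete
cycles this coincides with the least-squares fit, so no separate LS path
is offered). Counts are **minimal** at cycle fraction $\varphi/360$:
$\varphi$ is the timing of end-systole, so a *larger phase angle means
later contraction*. The sign convention is not dictated by the data — the
mirrored convention (counts maximal at $\varphi$) fits equally well — and
was fixed this way so that delayed emptying maps to larger $\varphi$, the
reading used throughout clinical phase imaging.

Pixels whose amplitude falls below 5% of the image maximum (configurable)
are flagged invalid: at negligible modulation the phase estimate is pure
noise and must not enter any data series. A constant curve returns
$A = 0$ with an invalid phase. Count-based LVEF uses
$100\,(ED_{net}-ES_{net})/ED_{net}$ with per-pixel background correction;
in simulated studies ED is frame 1 (the R wave) and ES the frame with
minimal ROI counts, since no manual dual-region procedure exists here.

## Approximate entropy over the serpentine series

The LV ROI is flattened into a single data series by a boustrophedon
scan: the topmost ROI row is read left→right, the next right→left, and so
on, so that consecutive series elements are spatially adjacent pixels.
Masked or invalid pixels are skipped without restarting the series — the
series is one continuous sequence, which is what makes template
comparisons meaningful across row boundaries. Row parity is anchored at
the topmost ROI row.

For a series $x_1..x_N$, template length $m$ and tolerance $r$:

$$ \mathrm{ApEn} = -\frac{1}{N-m}\sum_{i=1}^{N-m}
   \ln\frac{c_i^{m+1}(r)}{c_i^{m}(r)} $$

where $c_i^m(r)$ counts templates $j \in 1..N{-}m$ (self-match included)
whose maximum componentwise distance from template $i$ is at most $r$.
Three numerical choices deserve note:

* **Shared index range.** Both counts run $j$ over $1..N{-}m$ (not
  $N{-}m{+}1$ for the shorter template). The ratio is then a true
  conditional probability, bounded by 1, and ApEn is non-negative on
  every input — the single-sum form of the statistic forces a shared
  range but not which one; this choice is the one that preserves the
  probabilistic reading.
* **Chebyshev distance** between templates, the standard choice for
  ApEn.
* **Linear phase.** Phase values are treated as plain numbers inside
  ApEn, phase SD and the histogram; no circular wrap-around is applied.
  Since simulated and clinical phases concentrate well inside (0°, 360°),
  the seam never carries mass; a circular treatment would silently alias
  late contraction into early.

$r$ is in degrees of phase — the units of the series. Defaults are
$m = 2$, $r = 7°$, the operating point selected by the flip-point
optimization below. The implementation is an $O(N^2 m)$ C++ kernel; the
test suite checks it against an independently written brute-force R
reference on randomized series to $10^{-10}$.

ApEn ≥ 0 always, and → 0 at both tolerance extremes (only self-matches
as $r \to 0^+$; everything matches once $r$ covers the data range), so
its $r$-profile rises and falls rather than growing monotonically.

## Companion parameters

* **Synchrony** $= |\sum_j A_j e^{i\varphi_j}| / \sum_j A_j$: the
  amplitude-weighted resultant length of the phase phasors; 1 for
  perfectly simultaneous contraction, circular by construction. The
  originating literature does not print its formula; this phasor form is
  the natural amplitude-weighted reading and is documented here as the
  adopted definition.
* **Entropy**: Shannon entropy of the ROI phase histogram over 64
  equal-width bins on [0°, 360°), normalized by $\ln 64$ to [0, 1]. The
  bin count of the original derivation is unknown; 64 bins give ≈5.6°
  resolution, comparable to a normal ventricle's phase SD, and the count
  is configurable.
* **Phase SD**: unweighted sample SD (denominator $N-1$) of ROI phases,
  degrees.

Both adopted formulas are invariant under a common rotation of all
phases (entropy up to bin-edge crossings).

## Tolerance optimization and flip points

ApEn lacks *relative consistency*: the ordering of two series can
reverse as $(m, r)$ changes. On a normal/abnormal pair the difference
$d(r) = \mathrm{ApEn}_{abn}(r) - \mathrm{ApEn}_{nrm}(r)$ typically starts
negative (at small $r$ the *normal* image scores higher), crosses zero
at a **flip point**, and is positive at large $r$. At the flip the
statistic cannot discriminate at all, so the operating tolerance must
keep clear of every flip observed for the data type. `find_flip_points()`
reports each sign change with a linearly interpolated crossing (the
original analysis located flips graphically); `recommend_r()` returns the
grid tolerance maximizing clearance from the union of flip intervals — a
maximal-margin rule that is this package's own invention, since no formal
selection objective is documented for the historical choice of r = 7.
Default sweep grids are m ∈ {1..5}, r = 0.25–21 by 0.25, the historically
tested ranges. A sweep report also warns whenever any image pair swaps
ApEn ordering anywhere on the grid.

## What the simulator states, and what it does not

`make_phase_image()` divides an elliptical LV ROI into equal angular
sectors (default 8 — the historical simulator's segment count is not
documented) about the centroid, sector 1 at 12 o'clock, clockwise, and
draws each pixel's phase from the sector's normal(mean, SD), clamped to
[0, 360). The presets encode canonical patterns: *normal* (common mean
140°, SD 7.5°), *mi* (one sector +60° late), *lbbb* (linear 0→45°
gradient), *aneurysm* (two blocks 150° apart). The normal baseline was
chosen once so that the preset's synchrony (~0.991) and phase SD (~7.5°)
sit near stable-patient values; the abnormal effect sizes are
conventions, not measured quantities.

`make_gated_study()` inverts the extraction: expected curves
$a_0 - A\cos(2\pi k/F - 2\pi\varphi/360)$ with $A = 0.5\,a_0$ in the LV
(50% count modulation keeps all rates positive), a flat background at
10% of the LV mean outside, everything scaled to a target of 5×10⁶ total
study counts, and Poisson draws per frame-pixel. Zero-noise mode returns
the exact expectation (unrounded — rounding alone would perturb phase by
~0.1° at clinical count levels, destroying the machine-precision
round-trip property that mode exists to provide). At 5M counts the mean
absolute phase error over the LV is ≈1.7°, from which the 2° acceptance
tolerance was set.

`make_cohort()` draws per-group feature vectors (ApEn, synchrony,
entropy, phase SD, baseline LVEF) from multivariate normals calibrated
by default to a published stable (166) vs CTRCD (11) cohort summary,
truncated to admissible ranges (probabilities in [0,1], baseline
LVEF ≥ 55% — the post-exclusion population). Serial LVEFs are built so
ground truth survives the labeling rule: CTRCD trajectories decline to a
nadir ~N(45, 3) forced below both 50% and baseline − 10.5; stable
trajectories hover near baseline (SD 3 points) and are redrawn if they
would cross the cardiotoxicity criterion. Within-group feature
correlation is 0 by default (no covariances are published) but
`rho` couples ApEn and LVEF when a correlated world is wanted.

What a green test does **not** establish: the simulator has no
anatomical torso, attenuation, scatter, RV/atrial overlap, or gating
artifacts; preset phase images are per-pixel independent given the
sector, so their ApEn level (~0.8–0.9 for the presets) is higher than
smoothed clinical phase images (~0.35); and the cohort generator samples
features directly rather than deriving them from simulated images, so
cohort-level statistics validate the statistical stage, not the imaging
chain. Image-chain and cohort-chain claims are therefore tested
separately.

The labeling rule is the guideline criterion: CTRCD iff the maximum
LVEF drop from baseline exceeds 10 points *and* the nadir is below 50%.
Boundary cases (drop exactly 10; nadir exactly 50) are stable by strict
inequality; near-misses on exactly one arm of the rule are labeled
stable but flagged for review.

## Statistical stage

* Univariate comparisons are gated on Shapiro–Wilk normality in *both*
  groups (α = 0.05): Welch's t test when compatible with normality (the
  historical description says only "unpaired t test"; unequal variances
  are the safe default at 166 vs 11), otherwise the two-sided
  Mann–Whitney rank-sum test. The historical description names the
  signed-rank test, which is undefined for independent unequal groups;
  reading it as rank-sum is a deliberate correction.
* Hotelling's T² uses the pooled-covariance two-sample form with the
  exact F conversion; the Henze–Zirkler statistic (lognormal
  approximation for the p-value) gates multivariate normality in the
  report.
* Logistic models: *full* = ApEn + LVEF + ApEn×LVEF + synchrony +
  entropy + phase SD; *reduced* = ApEn × LVEF. Wald p-values per
  coefficient, likelihood-ratio χ² for the model, and in-sample AUC
  (cross-validated AUC is reported only for the classifiers, matching
  how the two kinds of models are conventionally summarized).
  Separation or non-convergence raises an error — with ~11 events,
  silent quasi-separation would otherwise produce meaningless
  coefficients.
* Classifiers: random forest and Gaussian naive Bayes under stratified
  10-fold × 3-repeat cross-validation (stratification is essential: with
  11 events unstratified folds frequently contain none), per-resample
  held-out AUC via the Mann–Whitney formulation. No forest or NB
  implementation is available in the deployment environment, so compact
  in-package versions are used: bagged Gini-grown trees (default 100
  trees, mtry = ⌊√p⌋ = 2, nodes grown to purity, depth cap 25) and
  Gaussian NB with an SD floor of 10⁻⁶. These are deliberately plain
  defaults in the spirit of the standard libraries; AUCs are
  seed-reproducible by construction.
* `exclude_baseline()` reproduces the intake filter: records with
  baseline LVEF < 55% or any quality flag are removed with a per-category
  accounting.

## Numerical and interface choices

* Phase is stored in degrees in [0, 360), images 0-based, row-major,
  origin top-left in the on-disk CSV convention; a floating-point wrap
  artifact at the 0/360 seam is folded to 0.
* The portable study format is a CSV frame directory
  (`frame_000.csv…`, `mask.csv`, optional `meta.dcf`); DICOM reading is
  declared but unsupported in this build because no R DICOM parser is
  available in the deployment environment.
* Floats are written with 17 significant digits, so every writer/reader
  pair round-trips integers bit-compatibly and floats far below the
  1e-6 contract.
* Config files are DCF `key: value` (no YAML parser in the
  environment); CLI flags override config keys.
* All generators take an explicit `seed` and restore the caller's RNG
  stream; identical seeds give bit-identical outputs, which the pipeline
  determinism test checks end-to-end at the file-byte level.

## Known limitations

* ApEn is computed on valid-amplitude ROI pixels only; whether clinical
  systems include low-amplitude pixels in the series is unknown, so
  series lengths may differ slightly from historical software.
* The maximal-margin `recommend_r()` rule is advisory and can recommend
  the grid boundary; it reports clearances so the analyst can apply
  their own margin.
* The cohort generator's truncations (LVEF floor, probability bounds)
  slightly bias sample moments relative to the nominal normal
  parameters; moment-recovery tests bound this at 3 standard errors
  plus a small truncation allowance.
* Henze–Zirkler's lognormal p-value is an approximation; it is used as
  a gate/report, never as a primary endpoint.
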