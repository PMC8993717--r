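# rnvgphase

Phase analysis of gated blood-pool ventriculography (RNVG/MUGA) for
quantifying left-ventricular (LV) dyssynchrony and stratifying the risk of
cancer-therapy-related cardiac dysfunction (CTRCD).

Patients on cardiotoxic chemotherapy (anthracyclines, trastuzumab) are
monitored by serial LV ejection-fraction (LVEF) measurement, but an LVEF
decline is a late phenomenon. The phase image — the per-pixel timing of
contraction extracted from a gated blood-pool study — carries information
about sub-clinical contraction abnormalities that precede the LVEF drop.
This package implements the full analysis chain:

1. **Phase extraction.** Each pixel's time–activity curve over one averaged
   cardiac cycle is fitted with its first Fourier harmonic,
   `c_k = a0 − A·cos(2πk/F − 2πφ/360)`, giving a phase image φ (degrees;
   larger = later contraction) and an amplitude image A. Count-based LVEF
   comes from background-corrected ED/ES ROI counts.
2. **Phase parameters.** From the LV ROI: **approximate entropy** (ApEn) of
   the serpentine-ordered pixel series
   `ApEn = −(N−m)⁻¹ Σᵢ ln[cᵢ^{m+1}(r)/cᵢ^m(r)]` (self-matches included,
   Chebyshev template distance, defaults m = 2, r = 7°), **synchrony**
   `|Σ Aⱼ e^{iφⱼ}| / Σ Aⱼ`, normalized **phase-histogram entropy**, and
   **phase SD**.
3. **(m, r) optimization.** ApEn sweeps over m ∈ {1..5}, r ∈ [0.25, 21] on
   simulated normal/abnormal phase-image pairs, with detection of the
   *flip point* — the tolerance where normal and abnormal ApEn cross and
   the statistic loses discrimination.
4. **Synthetic data.** Radial-segment phase-image simulator (normal, MI,
   LBBB, aneurysm presets), Poisson gated-study simulator (inverse of the
   extraction), and a two-group cohort generator with serial LVEFs whose
   defaults are calibrated to a published stable (n = 166) vs CTRCD
   (n = 11) breast-cancer cohort.
5. **Cohort statistics.** Shapiro–Wilk-gated t / rank-sum comparisons,
   Henze–Zirkler multivariate normality, two-sample Hotelling T², logistic
   models with the ApEn×LVEF interaction, and random-forest / naive-Bayes
   classifiers under 10-fold × 3-repeat stratified cross-validation with
   AUC.

## Worked example

```r
library(rnvgphase)

roi    <- make_lv_roi()                               # 437-pixel elliptical LV
mi     <- preset_phase_image("mi", roi, seed = 2)     # apical-infarct pattern
study  <- make_gated_study(mi, roi, seed = 3)         # 24-frame, 5M-count Poisson study
compute_features(study)
#> phase features: ApEn 0.9274 | synchrony 0.9445 | entropy 0.5075 | phase SD 19.75 deg | LVEF 62.1%
```

The infarcted ventricle shows high ApEn (irregular serpentine series),
depressed synchrony and a wide phase histogram. Flip-point analysis against
a normal image shows why the tolerance must be chosen away from the
crossover:

```r
normal <- preset_phase_image("normal", roi, seed = 1)
sn <- serpentine_series(normal, roi)
sa <- serpentine_series(extract_phase_amplitude(study), study$roi)
find_flip_points(sn, sa, m = 2)
#>     r_star r_lo r_hi sign_before sign_after
#> 1 3.122366    3 3.25          -1          1
```

Below r ≈ 3.1° the *normal* image scores higher; above it the abnormal one
does — at the r = 7° operating point the ordering is the clinically useful
one. Cohort-level risk stratification:

```r
co  <- make_cohort(cohort_spec(seed = 4))             # 166 stable + 11 CTRCD
compare_feature(co, "apen")[, c("feature", "test", "p")]
#>   feature test         p
#> 1    apen    t 0.0443323
fit_logistic(co, "reduced")
#> logistic model 'reduced': LR chi-sq 21.05 (df 3, p 0.000103), in-sample AUC 0.846
cv <- cv_classifiers(co, seed = 5)
#> rf: mean AUC 0.751 over 30 resamples; nb: mean AUC 0.933
```

The same pipeline is scriptable via the CLI (`inst/exec/rnvgphase` or
`rnvg_cli()`): `simulate`, `extract-phase`, `features`, `sweep`,
`cohort-stats`, each with `--seed`, `--config` (DCF key: value) and `--out`.

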