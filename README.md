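# collat4d

Assessment of cerebral collateral circulation from dynamic whole-brain CT
angiography (4D-CTA), as a fully synthetic, end-to-end testable pipeline.

In acute ischemic stroke with large vessel occlusion, collateral vessels
keep the tissue behind the blockage alive; their quality — graded 0–4 on
dynamic multiphase CTA and dichotomized *good* (3–4) vs *poor* (0–2) —
drives reperfusion-therapy decisions. Manual grading is slow and
rater-dependent. This package implements the automated alternative:

1. **Synthetic dynamic studies** (`generate_study`, `generate_cohort`):
   a 19-volume acquisition (baseline non-contrast scan, 2-s arterial-window
   frames at 11–36 s, 5-s venous-window frames at 40–60 s), gamma-variate
   bolus hemodynamics
   `C(t) = A ((t−t₀)/(αβ))^α exp(α − (t−t₀)/β)` (peak `A` at `t₀ + αβ`),
   bone shell, noisy parenchyma, vessel trees, and an occluded territory
   whose collateral filling fractions encode a known 0–4 grade.
2. **Phase landmarks** (`landmarks`): quality-checked arterial/venous
   time–density curves yield the arterial-peak, artery–vein-crossing,
   venous-peak, and late-venous-plateau frames.
3. **Preprocessing** (`build_phase_set`, `build_montage`): NCCT
   subtraction with bone removal, window normalisation, axial maximum
   intensity projection, and a lossless 2×2 four-phase montage.
4. **Classifiers** (`network_config`, `train_classifier`, `predict`): a
   residual CNN ((3, 4, 6, 3) blocks behind a 3×3 stem) on the stitched
   montage, and a four-branch variant fusing per-phase probabilities by
   averaging; Adam, lr 1e-4, batch 16, ≤ 10 epochs with early stopping.
5. **Evaluation** (`mc_splits`, `roc_auc`, `aggregate_metrics`,
   `run_experiment`): five stratified 70/30 Monte Carlo splits, accuracy /
   precision / recall / F1 / trapezoidal AUC, mean ± SD and vertically
   averaged ROC curves.
6. **Cohort statistics** (`table1_report`, `chi_square`, `ttest_pooled`,
   `mann_whitney`, `kruskal_wallis`, `anova_oneway`): the two-group
   baseline comparison with normal/non-normal routing.

## Worked example

```r
library(collat4d)

study <- generate_study("good", seed = 7)
arterial <- extract_tdc(study, study$ground_truth$artery_roi, "artery")
venous   <- extract_tdc(study, study$ground_truth$vein_roi, "vein")
landmarks(arterial, venous)
#> <phase_landmarks>
#>   arterial       t =  21.0 s  (frame 6)
#>   arteriovenous  t =  33.0 s  (frame 12)
#>   venous         t =  45.0 s  (frame 15)
#>   late_venous    t =  60.0 s  (frame 18)
```

The detected frames sit on the acquired samples nearest the analytic
landmarks of the generating curves (arterial peak 20.2 s, crossing
32.9 s, venous peak 44.6 s, plateau 57.8 s for this seed). A full
cross-validated experiment — 80 studies, strongly contrasted classes,
single-input variant:

```r
ex <- run_experiment(40, 40, variant = "single", seed = 1, contrast = "strong")
ex$report
#> <metrics_report> 5 Monte Carlo iterations
#>   accuracy   1.000 ± 0.000
#>   precision  1.000 ± 0.000
#>   recall     1.000 ± 0.000
#>   f1         1.000 ± 0.000
#>   auc        1.000 ± 0.000
```

Each line is the mean ± sample SD over the five 56/24 train/test
iterations. The `"strong"` setting draws grade-4 against grade-0 studies
with near-extreme collateral filling, so the montages are designed to be
cleanly separable and a correct pipeline should score at or near 1.0
(other seeds give e.g. AUC 0.997 ± 0.006); clinical data would not
behave this way. `plot_mean_roc(ex$report,
ex$report$rocs, "roc.png")` draws the per-iteration (dashed), mean
(solid), and ±1 SD band ROC figure; `write_metrics_csv(ex$report, dir)`
exports the tables.

A thin command-line wrapper over the same functions lives at
`inst/scripts/collat4d.R` (subcommands `simulate`, `preprocess`,
`stats`, `evaluate`).

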