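# petromics

Baseline FDG-PET radiomics for early-stage mediastinal Hodgkin lymphoma:
can the pre-treatment scan identify, before any therapy is given, the small
minority of patients whose disease will prove primary refractory? The
package is aimed at imaging scientists and biostatisticians who want the
full analysis chain — segmentation, feature extraction, classification,
prognostic grouping — as tested, reusable, seeded code rather than a
one-off script.

## What it computes

* **Metabolic segmentation.** Inside each hand-contoured anatomic site,
  the tumor is delineated by the fixed body-weight threshold SUV ≥ 2.5;
  MTV (cc), SUVmean over the segmented voxels, SUVmax over the contour and
  TLG = MTV × SUVmean follow. Sites with MTV < 5 cc are excluded.
* **33 radiomic features** per site: 8 intensity-histogram features, 22
  gray-level co-occurrence (GLCM) features computed in 2.5D — per axial
  slice at distance 1 over the four in-plane directions, then averaged
  across slices — and 3 shape features. Entropies are in bits; the inverse
  variance is `2 Σ_i Σ_{j>i} p_ij/(i−j)²`, the information measures of
  correlation `IMC1 = (HXY − HXY1)/HX` and `IMC2 = √(1 − exp(−2(HXY2 −
  HXY)))`.
* **Outcome-stratified boosted-SVM classification.** Patients are split
  into G groups (G = number of refractory cases, one per group); an
  AdaBoost ensemble of linear SVMs is trained on G − 2 groups and scored
  on the held-out 2, rotating over group pairs. Pooled out-of-sample
  scores give the ROC: AUC (trapezoid ≡ Mann–Whitney), bootstrap
  percentile CI, and the pooled error rate at score 0 — compared against
  single-feature baselines (MTV, TLG, SUVmax).
* **Prognostic subgroups.** Complete-linkage hierarchical clustering of
  the five selected features (z-scored), cut at k = 5, with per-group
  refractory and death-from-lymphoma percentages.
* **Synthetic phantom cohorts.** Ellipsoidal lesions with Gaussian
  random-field texture on a clipped-noise background, with class-
  conditional SUVmax/volume/texture distributions — so the whole pipeline
  runs and is testable without any patient data.

## Worked example

```r
library(petromics)

# one synthetic lesion: 20 cc, SUVmax pinned at 8, textured
ph  <- generate_phantom(single_lesion_spec(volume_cc = 20, target_suv_max = 8,
                                           texture_corr_length = 6,
                                           texture_sd = 1, seed = 3))
seg <- threshold_segment(ph$vol, ph$mask, threshold = 2.5)
seg
#> <site_segmentation> 'mediastinum': 304 voxels, MTV 19.46 cc, SUVmean 6.16, SUVmax 8.00, TLG 119.78

fv <- extract_feature_vector(ph$vol, ph$mask)
round(fv[c("GlobalMax", "Volume", "InformationMeasureCorr1",
           "InformationMeasureCorr2", "InverseVariance")], 3)
#>               GlobalMax                  Volume InformationMeasureCorr1
#>                   8.000                  19.456                  -0.324
#> InformationMeasureCorr2         InverseVariance
#>                   0.948                   0.187
```

The voxelized 20 cc ellipsoid recovers 19.46 cc; the generator pins SUVmax
at exactly 8 by construction, so `GlobalMax` is a closed-form check. A full
synthetic cohort at the default study conditions (169 patients, refractory
prevalence 12/169) runs end to end in about half a minute:

```r
res <- run_pipeline(pipeline_config(seed = 7))
res$eval
#> <eval_result> AUC 0.907 (95% CI 0.866-0.942), total error rate 0.029, 2197 scored cases
sapply(res$baselines, function(b) b$auc)
#>       mtv       tlg   suv_max
#> 0.9190273 0.9343465 0.8854582
```

Under these synthetic conditions the boosted 5-feature model and the
volume-based baselines are all strongly predictive — by design, since the
default class model separates classes in SUVmax, volume *and* texture; the
numbers describe the phantoms, not any clinical cohort. The property tests
instead check the qualitative ordering on cohorts where only texture
differs between classes. `res$summary` holds the per-group outcome table
(n, refractory %, death % among refractory) for the k = 5 prognostic
groups.

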