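---
title: "Methods: PET radiomics modeling of refractory mediastinal Hodgkin lymphoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics modeling of refractory mediastinal Hodgkin lymphoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A small minority of patients with early-stage classical Hodgkin lymphoma
develop primary refractory disease — persistence during or within 90 days of
completing upfront therapy — and their outcomes are markedly worse than
those of patients who are cured or relapse late. Identifying them *before*
therapy, from the baseline FDG-PET scan alone, would allow treatment to be
intensified exactly where de-intensification is dangerous. `petromics`
implements the full analysis chain for that question: metabolic segmentation
of contoured disease sites, a 33-feature radiomic description of each site,
a boosted-SVM classifier of refractory status compared by ROC against the
classical single-number baselines (MTV, TLG, SUVmax), and unsupervised
grouping of patients into prognostic subgroups. Because no patient imaging
is distributed with the package, a synthetic phantom cohort generator with
controllable class structure stands in for the data and makes every stage
testable end to end.

# Segmentation and first-order volume metrics

Disease is assumed contoured per anatomic site (mediastinum, neck, axilla,
...) on a grid shared with the SUV volume; the package does not perform
contouring or registration. Within a contour, the metabolic tumor volume is
delineated by the fixed body-weight SUV threshold 2.5, read inclusively: a
voxel exactly at 2.5 is in. Then

* `MTV` (cc) = segmented voxel count × voxel volume; 0 when the site's
  SUVmax is below the threshold,
* `SUVmean` = mean SUV over the *segmented* voxels,
* `SUVmax` = maximum SUV over the full contour,
* `TLG` = `MTV × SUVmean`, an identity that holds to full float precision
  by construction.

Sites with MTV below 5 cc are excluded before feature extraction (features
from small lesions are poorly reproducible); the cut is strict, so exactly
5 cc survives. Voxel membership is whole-voxel — no partial-volume edge
weighting — which keeps the measure reproducible at the cost of a small
discretization bias for lesions a few voxels across. Whether SUVmean should
be taken over the thresholded set or the whole contour is genuinely
ambiguous in routine practice; this package uses the thresholded set for
the mean and the full contour for the max, and states so rather than
asserting it as the only convention.

# The 33-feature catalog

Eight first-order intensity features (histogram entropy and uniformity,
max, IQR, mean, kurtosis, sd, skewness), twenty-two gray-level
co-occurrence (GLCM) features, and three shape features (maximum 3-D
diameter, volume, roundness).

**Discretization.** GLCMs need discrete gray levels; the package uses 64
equal-width bins spanning the segmented region's `[min, max]` (a common
radiomics default; configurable). The binning is computed once per lesion —
all disconnected components and slices pooled — so levels are comparable
across slices, and the same histogram feeds the intensity entropy and
uniformity. A constant region collapses to a single level.

**GLCM geometry (2.5D).** Co-occurrences are counted per axial slice at
voxel distance 1 in the four in-plane directions (0°, 45°, 90°, 135°),
symmetrically, counting a pair only when both voxels are segmented. The
default pools the four directions into one matrix per slice before feature
computation (an `"average"` mode computing features per direction and
averaging is exposed as a flag, since published implementations differ and
exact bit-compatibility with any one of them is not claimed). The 22
features are computed per slice and combined into 2.5D features by
unweighted averaging across contributing slices; a slice with no valid
in-mask pair is skipped, and a lesion with *no* contributing slice is an
error ("too thin for texture analysis").

**Feature definitions.** The standard co-occurrence statistics over the
normalized symmetric matrix \(p_{ij}\), \(i,j = 1..N_g\), with marginals
\(p_x, p_y\) and entropies \(HX\), \(HXY\), \(HXY_1\), \(HXY_2\); all
logarithms are base 2, consistently, so entropy-family features are in
bits. Three that deserve spelling out:

\[
\mathrm{InverseVariance} = 2\sum_{i=1}^{N_g}\sum_{j>i}^{N_g}
\frac{p_{ij}}{(i-j)^2},\qquad
\mathrm{IMC_1} = \frac{HXY - HXY_1}{HX},\qquad
\mathrm{IMC_2} = \sqrt{1 - e^{-2(HXY_2 - HXY)}}.
\]

The inner sum of the inverse variance runs over \(j > i\): with the leading
factor 2 this is the standard symmetric off-diagonal form (a \(j > 1\)
variant with the same factor would double-count and disagrees with the
cited reference literature for this feature family).

**Degenerate conventions (never-NaN contract).** All 0/0-type expressions
return the constant-image limit: \(\mathrm{IMC_1} = 0\) when \(HX = 0\),
correlation 0 at zero marginal variance, inverse variance 0 when the
off-diagonal sum is empty. A uniform lesion therefore yields Contrast 0,
Entropy 0, Energy 1, Homogeneity 1, InverseVariance 0, \(\mathrm{IMC_2}\)
0 — closed-form values the tests assert.

**Numeric conventions.** IQR uses linear-interpolation quantiles (type 7);
sd uses the sample (n−1) denominator; skewness is \(m_3/m_2^{3/2}\) and
kurtosis the excess \(m_4/m_2^2 - 3\) on population moments; a single-voxel
or constant region sets all dispersion-dependent features to 0.
`Max3DDiameter` is the largest Euclidean distance between segmented voxel
centers (computed on the morphological boundary voxels, where the maximum
is necessarily attained). `Roundness` is the ratio of the lesion volume to
the volume of the sphere with diameter `Max3DDiameter` — a pinned,
sphere-referenced definition (voxelization can push tiny lesions slightly
above 1); no bit-compatibility with any commercial roundness is implied.

# The synthetic phantom cohort

Each phantom is a background of clipped Gaussian noise (mean SUV 1.0, sd
0.1 — typical mediastinal blood pool) holding one ellipsoidal lesion. The
lesion texture is a Gaussian random field: white noise smoothed with a
separable Gaussian kernel of width `texture_corr_length / spacing` voxels,
then affinely rescaled so the maximum equals `target_suv_max` *exactly*
(making `GlobalMax` a closed-form oracle) and the minimum stays above 2.6,
so every lesion voxel survives segmentation and MTV has an analytic
ellipsoid-volume oracle (recovered within 15% at the default 4 mm
spacing). The intensity spread is `min(target_suv_max − 2.65, 4 ×
texture_sd)`; `texture_sd = 0` gives a uniform lesion at the target.

Cohorts draw refractory labels at prevalence 12/169 (the mediastinal-subset
prevalence this analysis is modeled on), redrawing until both classes have
at least 2 members. Class-conditional lesion parameters are log-normal
around class medians chosen once as clinically plausible: refractory
lesions hotter (SUVmax median 10 vs 6), bulkier (35 vs 15 cc) and more
heterogeneous (texture correlation length 4 vs 8 mm, amplitude 1.2 vs 0.6
SUV); secondary outcomes use relapse rate 7/157 among non-refractory and
death rate 4/12 among refractory. Volumes are clamped to [7, 90] cc so
every synthetic lesion passes the 5 cc exclusion after voxelization.

What the phantoms *do not* emulate: scanner noise spectra, partial-volume
effects, respiratory blur, reconstruction differences, multi-site disease,
or any distributional fact about the real cohort beyond the headline
counts. Passing tests on phantoms therefore demonstrate the pipeline's
correctness and the qualitative behavior of the statistics, not clinical
performance; no synthetic AUC is claimed to equal any published AUC.

# Classification protocol

Patients are split into `G` groups, where `G` is the number of refractory
cases, each group holding exactly one refractory case and group sizes
differing by at most 1 (with 167 patients and 12 refractory cases this
gives 12 groups of 13–14). Training uses `G − 2` groups; the held-out 2
are scored out-of-sample. The default `"rotate"` mode cycles over all
unordered group pairs (cap configurable) and pools the out-of-sample
scores; `"single"` mode reproduces a one-shot 10-train/2-test split.

The classifier is discrete AdaBoost with linear-kernel SVM weak learners
(e1071/libsvm) fitted on weighted bootstrap resamples of the training rows;
stage weights \(\alpha_t = \tfrac12\ln((1-\epsilon_t)/\epsilon_t)\), early
stop at \(\epsilon_t = 0\) (capped large weight) or \(\epsilon_t \ge 0.5\).
Features are z-scored with training-fold parameters. Initial boosting
weights are uniform; no minority-class resampling is applied (configurable
via the cost parameter). The default feature set is the five most
predictive of refractory mediastinal disease — GlobalMax, Volume,
InformationMeasureCorr1, InformationMeasureCorr2, InverseVariance — taken
as configuration; how that quintet was originally selected is not on
record, so any automatic selector a user applies should be treated as a
reconstruction.

Pooled scores give the ROC. AUC is computed two independent ways —
trapezoidal integration of the tie-grouped ROC, and Mann–Whitney pair
counting with ties worth ½ — which agree to machine precision on every
input (a standing test). Confidence intervals are bootstrap percentile
(2000 resamples, seeded; the original analysis does not state its CI
method). The total error rate is the pooled misclassification fraction at
ensemble-score threshold 0. Baselines score patients by a single raw
feature (MTV, TLG, SUVmax); orientation is not auto-flipped, so an
anti-predictive feature reports an AUC below 0.5, and no error rate is
defined for a thresholdless raw feature.

# Prognostic grouping

The five selected features are z-scored (sample-sd convention — the
features live on SUV, cc and unitless scales, so clustering unscaled
values would let volume dominate; this deliberately differs from heatmap
tools whose default is no row/column scaling) and clustered
agglomeratively with Euclidean distance and complete linkage, cut at
k = 5 groups — k is a presentation choice, not an optimum. Group labels
are renumbered by increasing group mean of the first selected feature, so
labels are deterministic and row-order invariant (ties in merge distance
are measure-zero for continuous features; the test oracle pins a
lowest-index tie-break). Outcome summaries report per group: n, refractory
count and percent of the group, deaths from lymphoma among the group's
refractory cases and percent of those cases, with half-up integer rounding
(5/36 → 14%).

# Reproducibility and problem sizes

One base seed fans out by fixed offsets (+1 cohort, +2 model, +3
clustering) so stages can be re-run in isolation; two identically
configured runs produce byte-identical output files (a standing test —
logs carry no timestamps). Default problem sizes were chosen so a full
default run (169 phantoms, all 66 rotation rounds, 50 boosting stages,
2000 bootstrap resamples) completes in well under a minute per stage on a
single core; the statistical property tests use scaled-down cohorts
(n = 60–100 phantoms, 10–15 boosting stages, 12–15 rotation rounds, 20
replicates) — sizes picked as the smallest at which the permutation null
and the texture-signal ordering are statistically stable, and stated here
as the package's own test design.

Two statistical properties are asserted rather than any clinical number:
on cohorts whose classes differ only in texture (SUVmax and volume
distributions equalized), the cross-validated AUC of the 5-feature boosted
model exceeds the SUVmax-only baseline in at least 18 of 20 seeded
replicates — the qualitative ordering (model > single-feature baselines)
that motivates the method; and with permuted labels the cross-validated
AUC is within 3 Monte-Carlo standard errors of 0.5 over 20 replicates.

# Known limitations

* Whole-voxel segmentation membership and center-to-center diameters bias
  small-lesion metrics; no partial-volume modeling.
* The GLCM bin count (64) and direction pooling are defensible defaults,
  not a claim of numeric parity with any specific historical
  implementation.
* Masks and SUV volumes must share one grid; CT-contour resampling is out
  of scope.
* The phantom texture model is stationary Gaussian; real tumor
  heterogeneity (necrotic cores, rim uptake) is richer.
* Survival/time-to-event modeling and relapse prediction are out of scope;
  the classifier targets primary refractory status only.
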