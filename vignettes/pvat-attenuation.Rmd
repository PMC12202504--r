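---
title: "Quantifying perivascular adipose tissue attenuation around the aorta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular adipose tissue attenuation around the aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvatscope)
```

## The measurement problem

Perivascular adipose tissue (PVAT) is the fat immediately surrounding a
vessel wall. Its CT attenuation rises when the adjacent wall is inflamed:
lipid-rich, quiescent fat sits deep in the adipose Hounsfield range, while
inflamed, oedematous fat shifts toward water. Comparing fat attenuation
*near* the wall against fat *far* from the wall therefore gives a
self-normalised, per-patient readout of perivascular inflammation. In
patients treated with a thoracic stent graft for type B aortic dissection,
this readout is of interest as a non-invasive marker of whether the false
lumen around the graft will persist (a "residual false lumen") or close.

`pvatscope` implements that measurement and the cohort statistics built on
it. The inputs are a CT volume and a co-registered binary aortic mask, both
in NIfTI format with millimetre voxel spacing; the mask is consumed as
input (for instance from an automatic segmentation tool), never produced
here.

## The quantification model

For a vessel mask $M$ on a lattice with anisotropic spacing, define for
every voxel the Euclidean distance $d(v)$ from its center to the center of
the nearest mask voxel, in physical millimetres. Two perivascular rings are
thresholded from this distance field:

* the **close ring**: $2\,\mathrm{mm} \le d \le 5\,\mathrm{mm}$,
* the **distant ring**: $10\,\mathrm{mm} \le d \le 12\,\mathrm{mm}$.

Within each ring, adipose voxels are those with attenuation in the fat
window $[-180, -30]$ HU (both bounds inclusive). Writing
$\mathrm{HU}_{close}$ and $\mathrm{HU}_{distant}$ for the mean attenuation
of the fat voxels of each ring, the two indices are

$$\mathrm{HU}_\Delta = \mathrm{HU}_{close} - \mathrm{HU}_{distant},
\qquad
\mathrm{HU}_{ratio} = \mathrm{HU}_{close} / \mathrm{HU}_{distant}.$$

A warmer (less negative) close ring relative to the distant ring gives a
larger $\mathrm{HU}_\Delta$ and, because both means are negative, a
*smaller* $\mathrm{HU}_{ratio}$.

Subjects with too little perivascular fat for the means to be reliable are
flagged: the effective fat thickness of each ring is its fat volume
(mm^3^) divided by the exposed surface area of the vessel mask (mm^2^,
counted as exposed voxel faces weighted by physical face area), and the
quality check requires both thicknesses to be at least 3 mm (0.3 cm).

### Design choices in the quantification

Several aspects of the measurement are genuinely open and fixed here as
package policy:

* **Distance convention.** $d$ is the distance to the nearest mask voxel
  *center*, not to a sub-voxel surface model. This makes the transform
  exactly checkable against a brute-force all-pairs oracle (the test suite
  does this on lattices up to $16^3$) and is the convention under which a
  morphological "dilation by $r$ mm" has an unambiguous meaning. Voxels are
  wholly in or out of a ring by their center; partial-volume effects are
  ignored.
* **Interval inclusivity.** Both ring intervals are closed; the 5--10 mm
  gap is deliberately unassigned. If the intervals are configured to touch,
  a voxel exactly on the shared boundary belongs to the close ring only.
* **Fat-first averaging.** Ring means are computed over fat-filtered voxels
  only; non-adipose ring voxels (wall remnants, contrast, soft tissue)
  never contribute to $\mathrm{HU}_{close}$ or $\mathrm{HU}_{distant}$.
* **Thickness definition.** "PVAT thickness" has no standard definition on
  a curved, irregular ring, so the package defines it volumetrically
  (volume / surface area), reports both values per subject, and lets users
  re-filter at other thresholds. The comparison is `>=` for a pass.
* **Centerline.** The analysis range along the vessel is parameterised by
  arc-length on the polyline of per-slice mask centroids. This is a
  deliberate, documented approximation to dedicated centerline software;
  for near-tubular masks the centroid polyline is accurate, while for
  strongly curved or branching vessels it underestimates the true
  centerline curvature. The quantitative range is exposed as a parameter
  (`range_mm` of `measure_pvat()`) and defaults to the full mask extent,
  since no standard anatomical range exists.
* **Geometry.** Volumes are stored with 1-based array indices; the world
  coordinate of voxel $i$ is $\mathrm{origin} + (i-1)\cdot\mathrm{spacing}$
  per axis. Oblique affines (off-diagonal rotation above $10^{-3}$) are
  rejected rather than resampled. HU values are held as doubles even when
  the file is integer-typed, so ring means are not quantised. Exclusion
  boxes for artifact regions use half-open, 0-based index ranges, the
  convention of the common image-processing toolkits.

## Synthetic data: what it emulates and what it does not

Because patient imaging cannot be redistributed, the package ships two
generators that are first-class, tested code.

**Phantoms** (`make_phantom()`) build a contrast-filled vessel (lumen
about +300 HU, wall +40 HU) running straight or helically through the
volume, surrounded by two adipose shells at configurable radial offsets
with configurable mean HU inside the fat window, embedded in soft tissue
(+20 HU), with optional additive Gaussian noise. The shells are placed with
the same surface-distance geometry the pipeline measures with, so on a
noiseless phantom the configured shell means are recovered exactly (to
floating-point accumulation, bounded at $10^{-6}$ HU in the tests) and the
index identities hold exactly. With noise of SD $\sigma$ the shell-mean
recovery error shrinks as $\sigma/\sqrt{n}$, which the tests verify at
$\sigma = 10$ HU over shells of at least $10^4$ voxels (recovery within
0.3 HU). Phantoms do **not** emulate dissection flap geometry, stent metal,
beam hardening, or CT texture; passing phantom tests therefore validates
the geometry and arithmetic of the pipeline, not its robustness to
scanner artifacts.

**Cohorts** (`simulate_cohort()`) draw two outcome groups with the
covariate roster of a TEVAR cohort: demographics, comorbidities,
postoperative labs, the two attenuation indices, and procedural variables.
The built-in parameterisation (`default_cohort_spec()`) uses group sizes
56 (residual false lumen) and 76 (closed), group means and SDs such as
$\mathrm{HU}_\Delta$ 8.75 ± 3.29 vs 5.16 ± 2.84 and $\mathrm{HU}_{ratio}$
0.73 ± 0.13 vs 0.85 ± 0.11, and per-group category proportions.
Continuous variables are truncated Gaussians (physiologic floors: counts
and times at 0, ratio in (0, 2]); skewed labs such as D-dimer are still
simulated as truncated Gaussians because only mean ± SD summaries are
available — a documented limitation. Covariates are drawn independently
within group, since no within-group correlation structure is published;
simulated cohorts consequently understate the collinearity of real labs.
One roster detail: the published stent-graft-material row prints its two
group cells against columns where the counts exceed the group sizes; the
generator uses the only assignment consistent with the group sizes and
flags rather than hides the discrepancy. Generation is seed-deterministic
with no hidden global state.

The ratio index also carries a definitional wrinkle: one published summary
table footnote describes it as a false-to-true-lumen attenuation ratio.
This package follows the methodological definition used throughout —
close-ring over distant-ring fat attenuation — and records the conflict
here rather than silently choosing.

## The statistical cascade

`compare_groups()` gates each continuous variable through a Shapiro–Wilk
test in each group at $\alpha = 0.05$ (a conventional gate level; the gate
itself has no published level): both groups compatible with normality
gives an independent-samples $t$-test with pooled variance, otherwise a
Wilcoxon rank-sum test; categorical variables use a $\chi^2$ test. All
tests are two-sided; constants are flagged, not tested. No
multiple-testing correction is applied anywhere in the cascade, matching
standard practice for this kind of screening table.

`univariate_screen()` fits one logistic regression per candidate and
advances variables with Wald $p < 0.05$. Fits showing separation
(boundary fitted probabilities with exploding coefficients or standard
errors) are flagged non-converged and excluded from advancement with a
warning rather than advancing on a meaningless $p$-value.
`vif_filter()` computes each variable's variance inflation factor
$1/(1-R^2)$ and removes the worst offender iteratively until all VIFs are
at or below 10; an exact linear dependence has infinite VIF and is removed
first. `multivariate_logistic()` fits the joint model by maximum
likelihood (log-likelihood tolerance $10^{-8}$, at most 100 iterations)
and reports Wald 95% confidence intervals, matching the symmetric
intervals conventional in clinical tables.

`roc_analysis()` builds the empirical ROC curve with cut-points at
midpoints between adjacent distinct scores. The AUC is the pairwise
concordance probability with ties counted ½ (identical to the trapezoidal
area), computed through the rank-sum identity. The Youden cut-off
maximises sensitivity + specificity − 1; among ties the highest-specificity
threshold is reported — a tie-break that must be fixed by convention since
none is standard. Markers that fall in cases are handled by
`direction = "lesser"` (test positive when the score is at or below the
cut-off), the natural direction for $\mathrm{HU}_{ratio}$;
$\mathrm{HU}_\Delta$ uses greater-is-positive. `binormal_auc()` supplies
the closed form $\Phi\!\big((\mu_+-\mu_-)/\sqrt{\sigma_+^2+\sigma_-^2}\big)$
that bridges group summaries to an expected AUC when no patient-level data
exist; the suite verifies it against Monte-Carlo concordance.

`pooled_summary()` reconstructs an overall mean ± SD column from per-group
$(n, \bar x, s)$ via the size-weighted mean and the law of total variance
with the sample ($n-1$) denominator, so it agrees exactly with summarising
the concatenated raw sample.

## Numerical and testing choices

* The distance transform is the exact separable lower-envelope algorithm
  on squared distances, in compiled code; equality with the brute-force
  oracle is asserted to $10^{-9}$ mm.
* Geometry round-trips through NIfTI are asserted to $10^{-4}$ (float32
  storage); spacing equality in alignment checks uses the same tolerance.
* Simulation-based checks in the test suite use deliberately modest problem
  sizes chosen for statistical sufficiency: 200 replicate cohorts of
  56 + 76 for the AUC replicate (Monte-Carlo SE ≈ 0.003), 100 seeds for
  the marker-selection recovery, 500 null cohorts × 2 covariates for the
  screen's type-I calibration (binomial SE ≈ 0.7 percentage points), and
  noisy phantoms of 48 × 48 × 60 voxels giving > 10^4^ voxels per shell.
* Degenerate inputs fail loudly: empty masks (no distance map, no
  centerline), analysis ranges selecting no slice, out-of-lattice
  exclusion boxes, single-class ROC labels, truncation bounds excluding a
  group mean by more than 3 SD.

## Known limitations

* The centroid centerline is not a true medial axis; arc-length is
  slightly underestimated for tortuous vessels.
* Ring placement by voxel-center distance means ring volumes are quantised
  at the voxel scale; at 0.6--0.7 mm CT spacing this is negligible relative
  to the 2--3 mm ring widths.
* Simulated cohorts carry no covariate correlations and Gaussian shapes
  only; power and calibration results on them do not certify behaviour on
  heavy-tailed or correlated clinical data.
* The logistic cascade is the classical screen-then-adjust workflow; it
  inherits that workflow's known optimism about selected effects. Penalised
  or Firth regression is out of scope.
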