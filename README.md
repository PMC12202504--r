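# pvatscope

Quantifies **perivascular adipose tissue (PVAT) attenuation** around the
aorta from CT and runs the two-group biomarker statistics built on it.

Fat surrounding an inflamed vessel wall shifts its CT attenuation toward
water. Comparing fat attenuation near the wall against fat far from the
wall gives a self-normalised, per-patient inflammation readout that has
been studied as a predictor of residual false lumen after thoracic
endovascular aortic repair (TEVAR) of type B aortic dissection. This
package is for imaging researchers who have a CT volume and a
co-registered binary aortic mask (NIfTI, mm spacing) and want a tested,
scriptable implementation of that measurement and its downstream
statistics.

## The measurement

With `d(v)` the Euclidean distance (mm, anisotropic spacing) from voxel
`v` to the nearest aortic-mask voxel, two rings are thresholded:
**close** (2 mm ≤ d ≤ 5 mm) and **distant** (10 mm ≤ d ≤ 12 mm). Adipose
voxels are those in the fat window [−180, −30] HU. With HU_close and
HU_distant the mean fat attenuation of each ring:

    HU_Δ     = HU_close − HU_distant
    HU_ratio = HU_close / HU_distant

A volumetric thickness check (ring fat volume / vessel surface area,
both rings ≥ 3 mm) flags subjects with too little perivascular fat.
Downstream: normality-gated group comparisons, univariate logistic
screening (p < 0.05), VIF collinearity filtering (> 10 removed),
multivariate logistic regression with Wald intervals, and ROC analysis
with Youden cut-offs. Synthetic CT phantoms and two-group cohorts with
ground truth are included as first-class, tested generators.

## Worked example

```r
library(pvatscope)

# a noisy synthetic vessel phantom: shells at -70 / -80 HU, noise SD 5
ph <- make_phantom(phantom_spec(noise_sd = 5, seed = 3))
measure_pvat(ph$grid, ph$mask)
#> PVAT measurement
#>   hu_close    -69.979 HU  (n = 13920 fat voxels)
#>   hu_distant  -79.979 HU  (n = 13680 fat voxels)
#>   hu_delta     10.000 HU
#>   hu_ratio     0.8750
#>   thickness  close 3.79 mm, distant 3.73 mm, QC pass
```

The configured shell contrast (ΔHU = 10, ratio 0.875) is recovered to two
decimals despite the noise; both rings pass the 3 mm thickness check.

```r
# a simulated two-group cohort (56 residual / 76 closed false lumen)
co <- simulate_cohort(seed = 7)
sc <- univariate_screen(co)
keep <- vif_filter(co, sc$advancing)$retained
multivariate_logistic(co, keep)$coefficients[c("term", "estimate", "p_value")]
roc_analysis(co$hu_delta, co$outcome)
#> ROC (greater-is-positive): AUC = 0.779 (56 pos / 76 neg)
#> Youden cut-off: score > 5.071 (sens 0.911, spec 0.579)
```

In this realisation the attenuation difference discriminates residual
from closed false lumen with AUC 0.78; the Youden point trades
sensitivity 0.91 against specificity 0.58 at a cut-off of 5.1 HU.
A command-line wrapper covering the same steps
(`crop`, `quantify`, `phantom`, `simulate-cohort`, `analyze`, `render`)
is installed as `exec/pvatscope`.

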