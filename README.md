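# wetspr

Slice-wise water-equivalent thickness (WET) estimation and size-dependent
stopping-power-ratio (SPR) prediction from dual-energy CT, for
proton-therapy tissue characterization research.

Dual-energy CT predicts SPR directly: a calibrated linear blend of the
low- and high-kVp images gives the relative electron density ρe and
effective atomic number Z, Z is converted to a mean excitation energy I,
and the Bethe equation yields voxel-wise SPR.  Because beam hardening
makes CT numbers depend on patient size, the blending weights
α_RED(WET) and α_EAN3.1(WET) must be looked up at the scanned object's
water-equivalent thickness — so WET estimation quality propagates straight
into SPR accuracy.  `wetspr` implements and cross-validates three
slice-wise thickness estimation methods (TEMs) on the low-energy image
(μ: attenuation relative to water, a_x/a_y: pixel sizes):

| Method | Estimate |
|---|---|
| TEM-A  | √( max_i Σ_j μ·a_x · max_j Σ_i μ·a_y ) — geometric mean of the maximum attenuation extents |
| TEM-B1 | 2·√( Σ_ij μ·a_x·a_y / π ) — equal-area circle, linear weighting |
| TEM-B2 | 2·√( Σ_ij μ²·a_x·a_y / π ) — equal-area circle, squared weighting |

Around them the package provides the full chain: synthetic phantom
generation with analytic ground-truth WET (rotated ellipses,
cylindrical insert phantoms of 75–400 mm with a parametric beam-hardening
bias, patient couch, seeded HU noise), size-dependent calibration of the
blending weights from surrogate-insert measurements, voxel-wise SPR maps
via the Bethe equation, and a WET-perturbation sensitivity analysis that
propagates the disagreement between TEMs into SPR deviations per tissue.
Minimal readers/writers for single-frame CT DICOM series and a plain-text
matrix fixture format handle I/O.

## Worked example

```r
library(wetspr)

## a rotated 2:1 water ellipse: the area methods stay on the analytic
## ground truth, the max-extent method picks up the 45-degree chord
img <- rasterize(ellipsePhantom(semiA = 100, semiB = 50, rotationDeg = 45))
c(temA = temA(img), temB1 = temB1(img), temB2 = temB2(img),
  truth = groundTruthWet(ellipsePhantom(semiA = 100, semiB = 50)))
#>     temA    temB1    temB2    truth
#> 127.0000 141.4755 141.4755 141.4214

## simulate a calibration sweep, fit a TEM-specific curve, predict SPR
sweep <- phantomSweep(seq(100, 400, by = 50), seed = 1)
curve <- calibrateSweep(sweep, "tem-b1")
curve
#> CalibrationCurve (tem-b1): 7 knots, WET 106.7..422 mm
#>   alphaRed -0.50825..-0.497172, alphaEan 11.573..13.2596

demo <- sweep[[4]]   # the 250 mm phantom
pred <- predictInsertSpr(demo$measurements, curve,
                         unname(demo$wetByMethod["tem-b1"]))
pred[c(1, 6, 11), c("insert", "spr_pred", "spr_ref", "spr_err_pct")]
#>           insert spr_pred spr_ref spr_err_pct
#> 1    lung_inhale   0.2795  0.2794    0.010159
#> 6         muscle   1.0385  1.0384    0.012350
#> 11 cortical_bone   1.6154  1.6153    0.007382
```

TEM-A lands on 127.0 mm, the closed-form 45° central chord (126.5 mm,
−10.6 % versus the 141.4 mm ground truth), while TEM-B1/B2 stay within
0.04 % — the rotation-robustness contrast the package is built to study.
The fitted curve's weights drift with phantom size (that drift *is* the
beam-hardening compensation), and the predicted insert SPRs agree with
their reference-parameter values to better than 0.15 % across tissues in
the noise-free sweep.

A thin command-line front end with subcommands (`estimate-wet`,
`calibrate`, `predict-spr`, `sensitivity`, `run-all`) lives at
`inst/cli/wetspr.R`; `runPipeline()` is the equivalent in-R entry point
and writes provenance-stamped CSV/fixture artifacts for every stage.

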