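---
title: "Slice-wise WET estimation and size-dependent SPR prediction"
author: "wetspr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise WET estimation and size-dependent SPR prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetspr)
```

## The problem

Dual-energy CT (DECT) predicts the proton stopping-power ratio (SPR) of
tissue directly: a calibrated linear blend of the low- and high-kVp images
yields the relative electron density (RED, $\rho_e$) and effective atomic
number (EAN, $Z$), the EAN is converted heuristically to a mean excitation
energy $I$, and the Bethe equation turns $(\rho_e, I)$ into SPR.  The
blending weights are not universal: beam hardening makes measured CT
numbers depend on how much attenuating material the beam traverses, so the
weights must be chosen per patient size.  The size surrogate used for the
lookup is the slice-wise **water-equivalent thickness (WET)** — the
object's extent scaled by its attenuation relative to water.

Everything therefore hinges on estimating WET well.  `wetspr` implements
three slice-wise thickness estimation methods (TEMs) on the reconstructed
low-energy image (pixel values $\mu_{ij}$, attenuation relative to water;
pixel sizes $a_x, a_y$ in mm):

* **TEM-A** — geometric mean of the maximum attenuation-weighted extents
  along rows and columns,
  $\mathrm{WET} = \sqrt{\max_i \sum_j \mu_{ij} a_x \cdot
  \max_j \sum_i \mu_{ij} a_y}$.  Uses only two perpendicular profiles and
  implicitly assumes a centred, roughly elliptical, homogeneous object.
* **TEM-B1** — diameter of the circle whose area equals the slice's total
  attenuation-weighted area,
  $\mathrm{WET} = 2\sqrt{\sum_{ij} \mu_{ij} a_x a_y / \pi}$.
* **TEM-B2** — as B1 but each pixel contributes the product of its
  water-equivalent $x$ and $y$ dimensions,
  $\mathrm{WET} = 2\sqrt{\sum_{ij} \mu_{ij}^2 a_x a_y / \pi}$.
  For a uniform object of attenuation $\mu_m$ and diameter $D$ this is
  exactly $D\mu_m$; on binary images it coincides with B1.

No segmentation is applied: all pixels participate (air contributes
essentially nothing), and attenuation values are clamped at zero before
the sums so that noise cannot reduce an estimate.  The multi-slice case is
a thin wrapper (`estimateProfile()`) mapping one method over ordered
slices; the scalar summary is the median, which is robust against
end-of-scan slices (the per-scan vs per-slice lookup policy is a
configuration choice, per-slice being the default in `sprImage()`).

## Ground truth on synthetic objects

For generic geometry (a single, possibly rotated ellipse with fully
enclosed inhomogeneities) the ground-truth WET is the effective diameter
$2\sqrt{ab}$ — the geometric mean of the semi-axes — times the
area-weighted mean attenuation (`groundTruthWet()`).  For a uniform
cylinder it reduces to geometric diameter times material attenuation.
Both are closed-form, rotation-free definitions, which is what makes the
rotation and inhomogeneity experiments meaningful: TEM-A picks up the
45° central chord $L(\theta) = 2/\sqrt{\cos^2\theta/a^2 +
\sin^2\theta/b^2}$ of a rotated 2:1 ellipse (a −10.6 % deviation at 45°),
while the area methods are rotation-invariant by construction.

## What the synthetic generator emulates — and what it does not

`PhantomSpec` describes a pixel grid, a stack of ellipses (later shapes
overwrite earlier ones), optional tissue-surrogate insert disks, an
optional couch slab, Gaussian HU noise with a recorded seed, and a
parametric beam-hardening bias.  Design choices that matter:

* **Rasterization.**  Coverage of each pixel is evaluated with 4×4
  sub-pixel sampling and then *majority-rounded*, so uniform shapes
  rasterize piecewise-constant.  The alternative — area-weighted
  partial-volume edges (`antialias = TRUE`) — is available but not the
  default, because squaring anti-aliased boundary pixels makes TEM-B2
  under-count the water-equivalent area by roughly (perimeter × pixel)/6,
  about 0.2–0.3 % for the geometries used here at 1 mm pixels.  The
  idealized geometries the analytic oracles refer to are sharp-edged, and
  the piecewise-constant convention keeps all three closed forms exact up
  to discretization.  With either setting the total rasterized
  attenuation area stays within 0.2 % of the analytic $\pi a b \mu$.
* **Beam hardening.**  A deterministic multiplicative bias, not spectral
  physics: attenuation at energy $E$ is scaled by $1 + g_E (W - W_0)$,
  and for bone-class materials ($Z >$ 8.8) additionally by
  $1 + b_E (W - W_0)$, where $W$ is the phantom's ground-truth WET.
  Defaults $g_{low} = -5\times10^{-5}$, $g_{high} = -2\times10^{-5}$,
  $b_{low} = -8\times10^{-5}$, $b_{high} = -3\times10^{-5}$ per mm with
  $W_0 = 200$ mm produce calibration-factor curves that vary smoothly and
  monotonically with size, qualitatively like measured size-dependent
  factors.  At $W = W_0$ the bias is exactly zero, giving a clean
  zero-hardening control (the fitted factors are then identical across
  sizes to $10^{-9}$).
* **The couch** is a rectangular slab (defaults: 500 mm wide, 20 mm
  thick, $\mu = 0.3$, 5 mm below the object).  Its water-equivalent row
  extent is $500 \times 0.3 = 150$ mm, so it dominates the row maximum —
  the mechanism by which TEM-A is hit hardest — only for objects whose
  own row extent is below 150 mm water-equivalent (acrylic cylinders up
  to roughly 135 mm diameter).  For larger objects TEM-A's couch error
  collapses to the small column-sum contribution while the area methods
  still absorb the full couch area; the crossover is a property of the
  slab parameters, not of the estimation methods.  The slab is a
  stand-in: no claim is made that it matches any scanner's couch.
* **Tissue surrogates.**  The packaged catalogue
  (`surrogates_synthetic.csv`) lists plausible lung/soft/bone reference
  RED/EAN values; it is synthetic, not vendor data.  Nominal dual-energy
  attenuations come from a two-term forward model
  $\mu_E = \rho_e\,(1 - c_{1,E} + c_{1,E} (Z/Z_w)^{3.1})$ with
  $c_{1,low} = 0.12$, $c_{1,high} = 0.04$: a Compton-like density term
  plus a photoelectric-like $Z$ term, normalised so water maps to
  $\mu = 1$ at both energies.  Under this model exact blending weights
  exist in the bias-free limit ($\alpha_{RED} = -0.5$,
  $\alpha_{EAN} = 12$), which is what makes parameter-recovery testable
  against a closed form.
* **Not emulated:** polychromatic ray physics, scatter, reconstruction
  artifacts, noise correlation/texture, metal, FOV truncation.  Passing
  the test suite therefore demonstrates internal consistency of the
  estimation-calibration-prediction chain under controlled bias, not
  clinical accuracy on scanner data.

ROI statistics are taken over each insert disk eroded by one pixel, so
with zero noise the reported means equal the biased material CT numbers
exactly.

## Calibration

Per phantom size, the weights solve one-parameter weighted least squares
in closed form ($\mu_E = H_E/1000 + 1$):

$$\rho_e \approx \alpha\,\mu_L + (1-\alpha)\,\mu_H, \qquad
\rho_e (Z/Z_w)^{3.1} \approx \alpha_E\,\mu_L + (1-\alpha_E)\,\mu_H.$$

The EAN target uses the *reference* electron density so the two fits stay
decoupled linear problems.  The exponent 3.1 and $Z_w = 7.45$ follow the
EAN-3.1 convention (both configurable).  All surrogates get weight 1 by
default, with an option to upweight bone-class inserts, whose large
low/high CT-number differences carry most of the information.  A fit is
refused (error, not silent fallback) when all measurements have
$\mu_L = \mu_H$, since $\alpha$ is then unidentifiable.

Across sizes the per-size fits are joined into a `CalibrationCurve`
keyed by the WET *as estimated by the chosen TEM on that same phantom* —
this is what makes curves TEM-specific: on the same simulated sweep the
fitted weights coincide and only the WET axis differs.  Evaluation is
piecewise linear with constant (clamped) extrapolation outside the knot
range — the smoothest defensible choice given that only qualitative curve
shape is known; duplicate knots are rejected.

## The SPR chain

`sprImage()` runs voxel-wise: weights looked up at the slice WET, RED
from the blend, EAN from
$Z = Z_w [(\alpha_E \mu_L + (1-\alpha_E)\mu_H)/\rho_e]^{1/3.1}$, mean
excitation energy from a piecewise log-linear $I(Z)$ mapping, SPR from
the Bethe equation with energies in eV:

$$\mathrm{SPR} = \rho_e\,
\frac{\ln\!\left(\frac{2 m_e c^2 \beta^2}{I (1-\beta^2)}\right) - \beta^2}
     {\ln\!\left(\frac{2 m_e c^2 \beta^2}{I_w (1-\beta^2)}\right) - \beta^2}.$$

Numerical guard rails:

* voxels with $\rho_e \le 0.01$ are classified as air: EAN falls back to
  $Z_w$, SPR is set to 0 (avoiding log-domain failures); a negative blend
  numerator likewise falls back with a flag instead of an exception;
* the proton energy defaults to 100 MeV (SPR is only weakly
  energy-dependent over therapeutic energies) and $I_w$ to 75 eV;
  literature values span roughly 75–78 eV, so both are configuration;
* the packaged $I(Z)$ mapping — knots (6.0, 65 eV), (7.45, 75 eV),
  (13.8, 112 eV), clamped outside — is an editable synthetic stand-in
  anchored so water maps exactly to $I_w$.  Results must not be read as
  equivalent to any vendor implementation;
* an $I$ large enough to push the Bethe bracket non-positive is outside
  the equation's validity and raises an error.

Water is a fixed point of the whole chain for *any* calibration curve:
water CT numbers give $\rho_e = 1$ under every blend, $Z = Z_w$, $I =
I_w$, SPR $= 1$ — a strong invariant the tests exploit.

## Sensitivity analysis

`sensitivityTable()` reproduces the two-step procedure: nominal SPR with
factors at the host WET, perturbed SPR with factors at WET $\pm \delta$
while the CT numbers are held constant.  The default $\delta$ in the
pipeline is the maximum pairwise WET deviation between TEMs observed in
the couch-free phantom sweep; an explicit override (in mm, or as percent
of the host WET — both modes exist because either convention is
plausible) supports unit tests.  Tissue CT numbers at each host WET are
derived with the same hardening bias the scans would exhibit.  Expected
behaviour, verified by the suite: exactly zero deviation at $\delta = 0$,
magnitudes non-decreasing in $|\delta|$, sign symmetry to first order on
a locally linear curve segment (away from clamped knots of the $I(Z)$
mapping, where the chain is non-smooth), and bone affected more strongly
than lung and soft tissue.

## Problem sizes and reproducibility

The test suite and the acceptance script use: generic geometries up to
240 mm at 1 mm pixels; a 14-size calibration sweep (75–400 mm in 25 mm
steps, eleven inserts, zero noise); a 250 mm uniform soft-tissue phantom
for the end-to-end comparison; and a 150–450 mm WET grid for the
sensitivity table.  These sizes keep every check closed-form auditable
while spanning the clinically relevant size range.  Every stochastic step
(HU noise) derives from a recorded integer seed with a `seed + index`
policy across a sweep, so duplicate diameters get independent noise and
full runs are byte-reproducible; the pipeline stamps every artifact with
package version, configuration hash, seed and method tag.

## Known limitations

* WET is estimated per reconstructed slice; cross-slice effects (scatter,
  partial volume along $z$) and projection-domain implementations are out
  of scope.  TEM-B1 would transfer to the projection domain; TEM-B2
  inherently needs a reconstructed image.
* Behaviour under FOV truncation or CT numbers far outside the calibrated
  range is undefined and documented rather than handled.
* Crop boxes use 1-based inclusive pixel indices (R convention).
* The couch model, surrogate catalogue, hardening parameters and $I(Z)$
  mapping are synthetic defaults chosen for plausibility and
  testability — none are scanner- or vendor-accurate.
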