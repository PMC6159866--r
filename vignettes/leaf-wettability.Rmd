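---
title: "Modelling seasonal leaf wettability from surface morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal leaf wettability from surface morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafwet)
```

## The problem

Deciduous leaves such as Katsura (*Cercidiphyllum japonicum*) are
superhydrophobic in summer and become sticky and merely hydrophobic in fall.
The change is structural: the leaf surface carries a two-tier roughness —
microscale papillose epidermal cells forming convex bumps, covered by
nanoscale epicuticular wax tubules — and in fall the bumps deflate as turgor
pressure drops while the wax mat erodes. `leafwet` models how these
morphological quantities set the apparent contact angle, the contact-angle
hysteresis, and ultimately how much water a tilted leaf can hold.

## The wetting model

Three measurable parameters describe a leaf surface:

* `r_micro` ≥ 1 — microscale roughness, the ratio of actual to projected
  surface area of the epidermal bumps (dimensionless);
* `phi_nano` ∈ [0, 1] — the areal fraction of liquid/solid contact on top of
  the wax tubule tips (the droplet rests on tips and trapped air);
* `alpha` ∈ [0, 1] — the areal fraction of the surface where the wax mat is
  still intact (1 on green leaves, below 1 after erosion).

Droplets are taken to be in the Wenzel state at the microscale (the water
follows the bump contours) and in the Cassie-Baxter state at the nanoscale
wherever wax is intact. Over intact wax the solid/liquid fraction per
projected area is `r_micro * phi_nano`; over eroded regions the droplet wets
the bare rough surface. Weighting the two by `alpha` gives the apparent
contact angle `theta*`:

    cos(theta*) = alpha * r_micro * (phi_nano * (cos(theta) + 1) - 1)
                  + (1 - alpha) * r_micro * cos(theta)

where `theta` is the contact angle on a chemically identical flat wax
surface (mean 101 degrees in the bundled presets, with advancing/receding
117/86). The limits are the classical relations: `alpha = 0` is Wenzel
(`cos theta* = r cos theta`), `alpha = 1, r = 1` is Cassie-Baxter, and
`alpha = 1` gives the uniformly waxed form
`r * phi * cos(theta) - r * (1 - phi)`. When the right-hand side leaves
[-1, 1] the model has exited its physical regime; `combined_angle()` raises
a `leafwet_nonphysical` error rather than clamping, so parameter sweeps see
the breakdown explicitly.

```{r}
reproduce_table1()
```

### Contact-angle hysteresis: two readings

Propagating the flat-surface hysteresis `Δθ_flat = θ_adv − θ_rec` through
the model can be written two ways, and they differ by where the sine factors
sit:

* **as-printed form** (the default):
  `Δθ*_leaf = r (α(φ−1)+1) Δθ_flat · sin(θ*)/sin(θ_flat)`
* **derivative form**: differentiating the combined relation with respect
  to `θ` gives the reciprocal placement,
  `Δθ*_leaf = r (α(φ−1)+1) Δθ_flat · sin(θ_flat)/sin(θ*)`.

The available hysteresis observations are not precise enough to adjudicate
between the two, so `hysteresis_leaf()` implements both (argument `form`)
and every report carries both, labelled. No claim is made about which is
intended; the derivative form is the one that matches a finite-difference
propagation through `combined_angle()`, and the test suite checks exactly
that property. Predicted advancing/receding angles are reported as
`θ* ± Δθ*_leaf/2`; splitting the hysteresis symmetrically about the mean is
a convention of this package.

### Nanoscale state and meniscus penetration

Whether the nanoscale is Cassie-Baxter at all depends on how deep the
air/water meniscus sags between wax tubules. For tubules at half-gap
`d_wax` and a wall advancing angle `θ > 90°`, the meniscus radius is
`d_wax / sin(θ − 90°)` and the penetration depth is

    h = d_wax * (1/sin(θ−90°) − sqrt((1/sin(θ−90°))² − 1))

`classify_nano_state(h, tubule_height)` returns Cassie-Baxter when
`h < tubule_height` and Wenzel otherwise; the boundary case counts as
Wenzel (conservative — a meniscus that just reaches the floor is treated
as wetting). A caution on reported depths: published depth figures of
25 nm (green, tubules ~1 µm) and 277 nm (brown, tubules ~134 nm) are not
recoverable from this formula with the stated geometry (75 nm spacing and a
117° wall angle give ≈ 9 nm). `meniscus_depth()` therefore exposes the
geometry explicitly and such literature depths should be treated as inputs
to the classification, not as formula targets.

### Droplet retention on a tilted leaf

A droplet of volume `V` sitting as a spherical cap at the mean angle
`θ̄ = (θ_adv + θ_rec)/2` has cap radius `R` from
`V = π/3 R³ (1−cos θ̄)² (2+cos θ̄)` and contact radius `a = R sin θ̄`
(`cap_geometry()`). Pinning balances gravity at

    π a γ_LA (cos θ_rec − cos θ_adv) = V ρ g sin β

Eliminating `a` yields the critical (maximum pinned) volume
(`critical_volume()`), and solving for `β` at fixed `V` yields the roll-off
tilt (`rolloff_tilt()`). When the arcsine argument exceeds one the droplet
never rolls off; this is returned as the first-class `PINNED` value, not an
error, and serialised as the string `"PINNED"`. Default fluid constants are
water near room temperature: `γ_LA = 0.072 N/m`, `ρ = 1000 kg/m³`,
`g = 9.81 m/s²`; all overridable through `droplet_spec()`. The ratio of
critical volumes between two leaf states is independent of all of these
constants and of the tilt — they cancel exactly — which is why the
brown/green ratio (`volume_ratio()`, ≈ 16.5, i.e. ~17-fold) is a pure
function of the four measured angles.

```{r}
predict_leaf("brown", reference = "green")
```

## Morphometry: from micrographs to parameters

All angles at interfaces are degrees; images are row-major matrices with
the origin at the top-left, intensities normalised to [0, 1], and a
physical pixel size in µm (square pixels). Cross-section heights are
measured upward from the bottom image edge at pixel centres.

**`r_micro`** comes from a traced surface profile: global threshold (Otsu
by default, fixed threshold optional), removal of foreground specks below
`min_object_px`, per-column topmost foreground row, interpolation of empty
columns (at most 10%, otherwise an error), then the arc-length/chord ratio
`Σ √(dx² + dh²) / extent`. Two numerical choices matter. First, the traced
boundary is smoothed with a short moving average (default window 5
columns): a raw binarised boundary is a staircase whose quantisation adds
arc length in proportion to slope (about +8% at slope 0.5 at any
resolution), while over-smoothing shortcuts real curvature; window 5 at
0.1 µm/px keeps the net bias of the default bump geometry within about
0.5%. Second, the line-profile ratio is used directly as `r_micro` without
squaring for areal isotropy, matching how the parameter is calibrated from
cross-sections.

**`phi_nano`** uses the intensity histogram of a top view of the wax mat:
256 bins, moving-average smoothing (window 5), local maxima refined to the
raw-count argmax nearby (ties toward the brighter bin), a qualifying peak
must reach 5% of the dominant peak's height, and the two dominant peaks
must be at least 20 bins apart — otherwise a `leafwet_unimodal` error.
The estimate is the fraction of pixels strictly brighter than the upper
peak's bin centre: the droplet is assumed to touch only the tubule tips,
which image brighter than both the wax body (upper peak) and the leaf
floor (lower peak). None of the histogram constants is physically derived;
they are robustness choices exposed as arguments.

**`alpha`** segments intact (bright) from eroded (dark) wax by a global
threshold, then applies physical-unit area filters: intact patches below
5 µm² are reassigned to eroded, then eroded patches below 22.5 µm² are
reassigned to intact, in that order, using 4-connected components.
Reassignment (rather than deletion) keeps the total area fixed so the
denominator of `alpha` is stable, and makes the filter idempotent. If the
histogram is unimodal (a uniformly intact or uniformly eroded image) there
is no bimodal split to threshold; the image is assigned wholly to one class
by whether its mean lies above mid-gray, with a QA flag.

`morphometry_pipeline()` averages replicates per parameter (arithmetic
mean, sample standard deviation reported) and records per-image estimator
failures as QA flags instead of aborting, as long as each role retains one
valid image.

## What the synthetic generators emulate — and what they do not

The generators exist so the whole pipeline can be exercised with known
ground truth. Each is driven by one integer seed through a per-call random
state (the caller's RNG stream is untouched), and each records its ground
truth from the emitted object itself — mask pixel counts, or arc length at
10× the emitted sampling density — never from the request parameters.

* `gen_bump_profile()` tiles analytic bumps (default sinusoid, height 8 µm,
  width 25 µm — the observed summer epidermal cell scale) and renders a
  binary-ish raster with Gaussian intensity grain; the emitted profile is
  the clean analytic curve.
* `gen_waxtip_image()` places non-overlapping bright discs (tips) over a
  dark floor and mid-gray wax texture until the disc mask reaches the
  target fraction (default 0.25); unreachable packings fail loudly. The
  floor and wax textures are one-sided (mode pinned at the level's top
  edge, spread downward) and tips span a broad brightness band with no mode
  of their own, so the histogram shows exactly two material peaks with the
  contact area brighter than the upper one — the geometry the histogram
  estimator is designed for.
* `gen_erosion_image()` thresholds a smoothed random field at the quantile
  giving the target intact fraction (default 0.46, the characterised brown
  leaf), records the truth, then injects sub-threshold speckles of both
  polarities (intact flecks < 5 µm², eroded pinholes < 22.5 µm²) to
  exercise the area filters; the same seed's noise is drawn before speckle
  injection so speckled and clean renderings differ only at speckle pixels.
* `gen_goniometer_readings()` draws advancing/receding pairs with Gaussian
  scatter truncated to (0, 180) and advancing > receding.

These are *not* SEM simulations: there is no beam-interaction physics, no
charging, drift or depth-of-field effects, and the intensity textures are
constructed so each material class has a well-defined modal brightness.
Passing recovery tests on them demonstrates that the estimators invert the
generators' image-formation model at the stated tolerances (roughness
within 2%, `phi` within 0.03, `alpha` within 0.05 across 20 seeded
replicates); on real micrographs, where contrast drifts and the histogram
peaks broaden or merge, the estimators expose their thresholds and peak
parameters precisely because the automatic defaults cannot be guaranteed.

## Problem sizes and runtime choices

The validation suite uses 512² px top views at 0.02 µm/px for the wax-tip
images, 384² px erosion maps at 0.2 µm/px, and six-bump cross-sections at
0.1 µm/px — large enough that mask-counting ground truth is accurate to a
few parts per thousand, small enough that the full 20-replicate recovery
sweep runs in seconds. The end-to-end check uses a bump height of 6.73 µm
(within the observed 8 ± 5 µm spread), whose ground-truth roughness ≈ 1.16
matches the green-leaf preset.

## Known limitations

* The model is quasi-static: droplet impact, evaporation and temperature
  dependence of surface tension are out of scope.
* `r_micro` from a single profile direction assumes the bump field is
  statistically isotropic.
* The hysteresis prediction inherits the unresolved sine-placement
  ambiguity above; downstream users should carry both variants, as the
  reports do.
* The unimodal-image fallback for `alpha` uses a fixed mid-gray decision
  level of 0.5, which presumes roughly calibrated intensities.
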