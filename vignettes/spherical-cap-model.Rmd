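---
title: "The spherical-cap model of epidural hematomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spherical-cap model of epidural hematomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edhgeom)
```

## The model

An acute epidural hematoma (EDH) collects between the skull and the dura and
takes a characteristic biconvex, lens-like shape on CT. `edhgeom` models this
shape geometrically: the supratentorial brain is a half sphere of radius
$r$ (80 mm by default), the outer surface of the hematoma follows the inner
skull, so the part of the EDH outside its cut-off plane is a spherical cap,
and — because the dura is stiff enough that its deformed position mirrors its
original one — the inner part is the reflection of that cap across the base
plane. The whole hematoma is therefore two mirrored caps with total volume
$2V_{SC}$.

A cap on a sphere of radius $r$ with base-circle radius $a$ and height $h$
satisfies

$$r^2 = a^2 + (r - h)^2, \qquad V_{SC} = \frac{\pi}{3} h^2 (3r - h),$$

so on a fixed-radius skull a single measurement — the hematoma's largest
diameter $A = 2a$, which is always visible on some axial image — determines
$h = r - \sqrt{r^2 - a^2}$ and both volume estimates:

* the biconvex estimate $V_{SC2} = 2 V_{SC}$, and
* the classical ABC/ellipsoid estimate evaluated in-model,
  $V_{ABC} = \tfrac{4}{3}\pi a^2 h$ (exact $\pi$; the familiar "ABC/2" rule
  corresponds to $\pi \approx 3$).

Their ratio is $(4r - 2h)/(3r - h)$: close to $4/3$ for small caps, falling
to 1 only at the (clinically impossible) full hemisphere. The ellipsoid
method thus systematically overestimates biconvex hematomas by roughly 30%.

### Placement: latitude, apparent thickness, extent

A cap can sit anywhere under the skull convexity. Its *latitude* $\varphi$ is
the angle between the cap axis and the basal (equatorial) plane, recovered
from axial landmarks as
$\varphi = \arcsin\!\big((z_{centroid} - z_{basal})/(r - h)\big)$ with
$z_{centroid} = (z_{cranial} + z_{caudal})/2$; the hypotenuse is $r-h$, the
distance from the sphere centre to the base-circle centre. Negative latitudes
(temporal hematomas below the basal landmark plane) are accepted.

On the axial image with the largest hematoma area the apparent
half-thickness $b$ exceeds the true cap height once the axis tilts. In the
working plane (z-axis plus cap axis, origin at the base-circle centre) the
skull circle is $(u - (h-r))^2 + v^2 = r^2$ and the axial cut is the ray
$v = u\tan\varphi$; the positive root of the resulting quadratic gives

$$b = \frac{(h-r) + \sqrt{(h-r)^2 - (1+\tan^2\varphi)(h^2 - 2rh)}}
          {\sqrt{1+\tan^2\varphi}},$$

with closed-form branches $b = h$ at $\varphi = 0$ and $b = a$ at
$\varphi = \pm 90^\circ$ (where $\tan\varphi$ is singular). The
cranial-caudal half-extent is the projection $c = a\cos\varphi$ ($c = h$ at
the poles). The small-angle shortcut $\hat b = h/\cos\varphi$ is also
provided; it is accurate for low-lying hematomas and diverges near the
vertex, which is exactly why the exact solution matters.

Since $h \le b \le a$, the apparent thickness can overstate the true one by
up to $a/h$ — a factor of 15.9 for a 20 mm-diameter cap. `edhgeom` exposes
this as `thickness_ratio_bound()` and flags it in decision records: thickness
read off an axial image is a treacherous surgical criterion near the vertex,
whereas the largest diameter is always measurable. The worked example: the
cap with full thickness 15 mm ($h = 7.5$ mm, $A = 67.6$ mm) placed so the
skull vertex lies on its base-circle rim sits at $\varphi \approx 65^\circ$
and *appears* 30 mm thick ($b \approx 15$ mm).

```{r}
cap <- spherical_cap(r = 80, h = 7.5)
vertex_on_rim_latitude(cap)
thickness_exact(cap, 65)
```

### Two latitude models

The *native* model fixes $r = 80$ mm, so $z_{vertex} = z_{basal} + r$ needs
no measurement. Real heads vary: the *landmark-corrected* model replaces the
radius in the latitude formula with the measured vertex-to-basal distance
$r_L = z_{vertex} - z_{basal}$, i.e.
$\varphi_L = \arcsin\!\big((z_{centroid} - z_{basal})/(r_L - h)\big)$.
The cap geometry itself ($h$ from $a$, and the working-plane circle) stays on
the model sphere by default: the correction is to the *placement* angle, not
to the skull. Because the choice is defensible either way, `edh_predict()`
exposes `landmark_radius = "landmark"` to run the whole geometry on $r_L$
for sensitivity analysis; on our phantom cohorts the difference is well below
the measurement discretization.

## Thresholds and the lookup table

Guideline practice evacuates an EDH above 30 mL, or thicker than 15 mm.
In-model, 30 mL corresponds to a largest diameter of 64.7 mm (ABC) or
69.1 mm (biconvex) — a spread of only 4.4 mm — and 15 mm full thickness
($2h$) to 67.6 mm. All three fall just under 7 cm, which motivates the
single-parameter rule: *an EDH longer than 7 cm should be considered for
evacuation*. `edh_table()` regenerates the lookup table on a 10 mm grid with
those threshold diameters injected at full precision (plus the 65 mm
convenience row), truncated where the ABC estimate would exceed the
half-sphere model's own volume (beyond $A = 140$ mm at $r = 80$).
`evaluate_case()` turns a measured diameter into a decision record; the
thickness criterion is evaluated on the true model thickness $2h$, with a
separate flag for diameters whose *apparent* thickness $2b$ could cross the
threshold at some latitude — the overtreatment caveat made machine-readable.

Display rounding is deliberately a serialization concern
(`format_edh_table()`): lengths and volumes to 0.1, ratios to 0.01, volumes
under 0.05 mL to 0.01 mL so that the smallest caps do not round to zero. All
internal computation is unrounded; several printed cells (e.g. the biconvex
volume at the 64.7 mm anchor) only reproduce when the anchors are carried at
full precision and rounded last.

## The voxel phantom oracle

Closed-form geometry is verified against an implementation that shares none
of it: `build_phantom()` voxelizes the biconvex solid directly from its
set definition (inside the sphere and beyond the base plane, or the mirror
image thereof) on an isotropic grid aligned to a fixed world lattice, at any
latitude and azimuth. Azimuth is a free parameter — the volume must not
depend on it, and a test checks that it does not. Voxel counting converges
to $2V_{SC}$ at first order in the voxel size; at 0.5 mm voxels the error is
below 1% across the clinically relevant size range.

`measure_phantom()` then digitizes the manual CT protocol: axial slices
sampled at a fixed spacing (5 mm by default, typical of non-volumetric
trauma CT), the largest-area slice found, the length measured as the maximal
chord of the occupied region (convex-hull diameter), the thickness as the
maximal extent perpendicular to that chord, and the cranial-caudal extent as
slice count times spacing. `generate_cohort()` wraps this into a synthetic
measurement table with analytic ground truth attached.

The cohort generator's defaults emulate the validation cohort the model was
originally checked against: base radii uniform on 32.3–50.0 mm and native
latitudes on 5.1°–58.9° (that cohort's observed ranges), skull radius 80 mm,
0.5 mm voxels, 5 mm slices, measurement noise off. Per-patient raw data from
that cohort are not published, so the published per-patient regression slopes
are not reproducible; the phantom cohort is the in-silico analogue, and it is
labelled synthetic everywhere. What passing recovery tests show is that the
closed-form placement equations and the digitized measurement protocol agree
through the whole pipeline; they cannot show anything about dural mechanics,
active bleeding, non-spherical skulls or reader variability in real images.

A design choice worth recording: caps at low latitude routinely extend below
the basal landmark plane (crossing requires only
$\tan\varphi < a/(r-h)$), and real temporal EDHs do exactly that — the model
even admits $\varphi < 0$. The phantom therefore builds the full biconvex
solid by default and only *flags* basal-plane crossing
(`crosses_basal`); clipping to the half space is available as
`clip_basal = TRUE` for studying the half-sphere model's blind spot, but a
clipped solid no longer has volume $2V_{SC}$ and excluding all crossing
cases would empty the realistic latitude range.

## Validation statistics

`edh_validate()` reproduces the model-validation analysis for any
measurement table: per-case predictions of $b$ and $c$ from the length and
landmarks alone, then, per target and latitude model,

* regression through the origin, $\hat\beta = \sum xy / \sum x^2$ — the
  origin constraint is physical (thickness and extent vanish with the
  hematoma). $R^2$ uses the uncentered total sum of squares
  ($1 - \sum(y-\hat y)^2/\sum y^2$), the standard definition for
  no-intercept fits; a centered $R^2$ can be negative there and answers a
  different question.
* a two-sided paired t-test (`stats::t.test`), with a degeneracy flag when
  the differences have zero variance, and
* the mean and range of absolute differences.

Results come back `tidy()`/`glance()`-style, with an `autoplot()` scatter of
predicted against measured values. On a noiseless 14-case phantom cohort at
the defaults the through-origin slopes for both $b$ and $c$ land within a few
percent of 1 with $R^2 > 0.99$; with 5 mm slices the extent errors exceed the
thickness errors on average, since $c$ is quantized by the slice grid while
$b$ is measured in-plane at voxel resolution — the same asymmetry expected
from sparse z-sampling on real scanners.

## Numerical choices and limitations

* Lengths are mm, volumes mL, angles degrees at every interface (radians
  internally).
* Root finding (`diameter_for_volume`) is bracketed on $A \in (0, 2r)$ via
  `uniroot` at 1e-12 interval tolerance; monotonicity guarantees uniqueness.
  Targets above the model's capacity error out.
* Degenerate caps ($a = 0$) return zero volumes; only the ABC/SC *ratio* is
  an error there.
* $\varphi = \pm 90^\circ$ uses closed-form branches ($b = a$, $c = h$),
  not limits of the tangent-based formulas.
* Problem sizes in the test suite and acceptance runs: phantoms at 0.5 mm
  voxels for volume checks and the 14-case recovery cohort, 1-2 mm voxels
  for structural and convergence checks — sizes at which voxelization error
  is comfortably inside every asserted tolerance.
* The model is supratentorial and adult: posterior-fossa and pediatric
  geometry, skull asphericity, dural sag, brain compression, midline shift
  and CT intensity simulation are out of scope. Volumes assume a
  well-formed biconvex collection; actively bleeding, irregular hematomas
  violate the premise and were the largest outliers in the original
  validation.
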