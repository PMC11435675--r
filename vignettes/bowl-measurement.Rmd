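---
title: "Measuring dining bowls from a single photograph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dining bowls from a single photograph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowlruler)
```

## The measurement problem

In image-based dietary assessment the utensil is the volumetric
reference: knowing the geometry of the bowl someone eats from turns a
photograph of food into an estimate of how much food there is. A bowl's
rim radius and height are easy to measure with a ruler, but its
*shape* — how quickly the wall rises from the flat bottom — is not, and
shape drives volume. `bowlruler` recovers all three from one photograph
of a cheap adhesive paper ruler taped across the bowl's interior, taken
at an arbitrary angle with a camera of known intrinsics.

## The surface model

The bowl interior is modeled as a surface of revolution with profile

$$z = f(y) = \left(\frac{y}{R}\right)^{q} H, \qquad 0 \le y \le R,\ q > 1,$$

with rim radius $R$ (mm), height $H$ (mm) and dimensionless shape
exponent $q$. The constraint $q > 1$ makes $f'(0) = 0$, so the modeled
bowl has the flat, stable bottom real bowls need. Two derived
quantities have closed forms:

* **plumpness** $p = V_{\mathrm{bowl}} / V_{\mathrm{cylinder}} =
  q/(q+2)$, confined to the open interval $(1/3, 1)$ — the cone-like
  and cylinder-like limits are approached but never attained for finite
  $q > 1$, which is why `plumpness()` and `q_from_plumpness()` treat
  the bounds as open;
* **volume** $V = \frac{q}{q+2} \pi H R^2$, reported in cm³.

Inverting plumpness, $q = 2p/(1-p)$, is also how ground truth is
obtained for a physical bowl: measure $V$ by water filling, $H$ and $R$
with a ruler, then `q_from_measurements(V, H, R)`.

The rim-to-rim length of the interior meridian,
$L = 2\int_0^R \sqrt{1 + f'(y)^2}\,dy$, has no closed form. It is
evaluated by adaptive quadrature (relative tolerance $10^{-8}$), and
`build_arc_table()` tabulates the curve against arc length (default
$10^4$ samples per half-curve, monotone piecewise-cubic inversion) so
that positions *along the tape* can be mapped to 3D points on the
surface. Inside the estimator's inner loop the same table is rebuilt
for every candidate bowl, so there a plain cumulative-trapezoid table
with linear inversion is used; at the default resolutions the
difference is orders of magnitude below the landmark spacing.

## The virtual ruler

The simulator reproduces the physical measurement: a 5 mm-wide virtual
tape runs centrally across the bowl, its length $L$ divided into 20
equal segments (21 division points including both rim ends, i.e. 42
landmarks). At each division the two tape-edge landmarks sit on the
latitude circle through that point, separated by the tape width
*measured as arc length along that circle* ($\pm \alpha$ with
$\alpha = (w/2)/r$). Near the bottom the latitude circles degenerate;
when $\alpha > 0.3$ rad the pair is instead offset $\pm w/2$
horizontally and re-projected onto the surface (the small-angle circle
construction would err by more than ~1.5% there, and the planar offset
is exact at $r = 0$).

Landmarks are projected through an ideal pinhole camera,
$p' = Rp + t$, $\tilde c = (F x'/z' + c_x,\ F y'/z' + c_y)$. The Euler
convention is intrinsic Z–Y–X ($\psi$ about $z$, then $\theta$, then
$\phi$), in degrees; it is a documented constant shared by the
simulator and the estimator, so estimation is self-consistent
regardless of convention. Default intrinsics emulate a smartphone main
camera ($F = 3000$ px, $4000 \times 3000$ image); study scenarios draw
camera extrinsics uniformly from realistic ranges
($X, Y \in [-400, 400]$ mm, $Z \in [180, 500]$ mm,
$\theta \in [30, 90]°$, $\phi, \psi \in [-60, 60]°$), rejecting
draws in which any landmark leaves the frame (plus a 5% margin) or
falls behind the camera — study photographs always contain the whole
ruler. Projections are exact by default; `noise_sd` adds Gaussian pixel
noise for robustness experiments.

## The estimator

A one-step optimization over $(R, H, q, \text{pose})$ is impossible
because the 3D landmarks are themselves functions of $(R, H, q)$ with
no closed form. The estimator is therefore coarse-to-fine:

1. **Coarse grid.** $H \in \{10, 20, \dots, 130\}$,
   $R \in \{30, 40, \dots, 130\}$, $q \in \{2, \dots, 10\}$. For each
   candidate bowl the camera pose is fitted by Levenberg–Marquardt on
   the reprojection residuals (analytic Jacobian, 6 parameters),
   minimizing $J = \sum_i \lVert \tilde c_i - c_i \rVert^2$.
2. **Ranking.** Candidates are ranked by the selection score
   $e_n = e_c + e_l$: the mean width-normalized reprojection error
   $e_c$ plus the relative tape-length error
   $e_l = |L_{est} - L_{gt}|/L_{gt}$ ($L_{gt}$ is known — the physical
   tape is itself a ruler; a signed $e_l$ would reward undersized
   bowls, so the absolute value is used). The best $m = 10$ are kept.
3. **Refinement.** Rounds of Gaussian random search around each
   candidate ($\sigma_0 = (5\,\text{mm}, 5\,\text{mm}, 0.5)$ for
   $(H, R, q)$, halved each round, 50 samples per candidate per round)
   with warm-started pose refits, until the best $e_n$ drops below the
   stop threshold (default 0.02) or 10 rounds elapse. The best $e_n$ is
   non-increasing by construction; ties break on smaller $J$, then
   smaller volume, for determinism.

Two additions to the plain grid + local search proved necessary and are
deliberate design choices. At strongly oblique views the $e_n$
landscape develops narrow valleys and deceptive secondary minima in
which an inflated $H$ is compensated by a different camera depth; a
purely local, shrinking search that starts outside the true valley can
stall there. But the known tape length pins the true bowl to the 2D
surface $L(R, H, q) = L_{gt}$, so (a) the coarse pool is augmented with
one *length-matched* candidate per $(R, q)$ grid point ($H$ solved by
root finding so $e_l = 0$), and (b) every fifth refinement sample is a
long-range draw in $(R, q)$ at the initial scale with $H$
length-matched. The remaining samples follow the halved-sd schedule, so
the search stays coarse-to-fine while retaining global reach on the
physically admissible surface. Without this, roughly one scenario in
seven converged to a secondary valley with volume errors of 20–60%;
with it, none of the observed failures persist.

Pose fitting details that matter: the coarse sweep warm-starts each
grid bowl's fit from its predecessor's pose (the optimum varies
smoothly with candidate shape), seeded by a multi-start probe fit at
the grid center; kept candidates are re-polished with the full
multi-start set (tilts $\theta \in \{30, 60, 90\}°$,
$\psi \in \{0, \pm 30\}°$, translations back-projecting the observed
pixel centroid to 300 mm depth). Landmarks that fall behind the camera
during a pose step incur a large finite penalty (100 px per mm of depth
violation, depths clamped at 1 mm) rather than an exception, so LM can
recover.

### Degenerate inputs and numerical choices

Candidate bowls shorter than the tape clamp the overhanging arc
positions to the rim and count them (`n_clamped`). Observed pairs of
zero pixel width are excluded from $e_c$ with a warning. All RNG flows
from a single seed; `estimate_bowl()` is deterministic given its
config seed, and `run_simulation_study()` threads one stream through
scenario generation and estimation.

## Error propagation

Linearizing $V = \frac{q}{q+2}\pi H R^2$ at the truth gives

$$\frac{\Delta V}{V_0} \approx \frac{\Delta H}{H_0}
  + 2\frac{\Delta R}{R_0} + \frac{2\,\Delta q}{q_0(q_0+2)},$$

and, for uncorrelated zero-mean relative errors,

$$\sigma_V^2 \approx \sigma_H^2 + 4\sigma_R^2
  + \frac{4}{(q_0+2)^2}\sigma_q^2.$$

All sigmas here are *relative* standard deviations — the only reading
under which the closed form reproduces the reference volumetric-error
cells, and the one this package documents and tests. The factor 4 on
$\sigma_R$ is the amplification that makes volume estimates spread more
widely than the parameter estimates; the $q$ term fades as
$(q_0+2)^{-2}$. `monte_carlo_sigma_v()` verifies the closed form by
sampling exact volumes; agreement is within Monte-Carlo error for
sigmas up to ~0.1, beyond which second-order terms appear.
Experimental $\sigma_V$ in study reports is the sd of per-image
relative volume errors.

```{r sigma}
sigma_v(q0 = 5.2, sigma_H = 0.009, sigma_R = 0.009, sigma_q = 0.068)
```

## Labeled-landmark preprocessing

For real photographs, landmarks are clicked by hand at the tape's
printed half-inch divisions along both edges (rim-end pairs must be
labeled; nothing is extrapolated). The published procedure is shown by
example rather than stated in full; this package decomposes it into
three configurable steps, one faithful reading among several:

1. *vertical filter* — each pair is replaced by its midpoint (plus the
   half-width offset kept aside), cancelling antisymmetric click error;
2. *horizontal filter* — each interior midpoint is repositioned along
   the midpoint polyline so its two neighbor distances become their
   average $h = (\lVert OA\rVert + \lVert OB\rVert)/2$; border points
   are never moved;
3. *upsampling* — each edge polyline is re-interpolated at 4× the
   division density through the filtered points (natural cubic by
   default, linear available).

Equally spaced collinear labels are a fixed point of the pipeline,
which is how the tests anchor its behavior.

## Point-cloud validation

To check the power-law model against scanned bowls,
`extract_cross_section()` levels the rim plane (one robust RANSAC pass,
then iterated re-selection with plain least-squares plane fits — LS on
RANSAC inliers alone retains a tilt when the selected band covers only
part of the rim ring), centers the axis with a least-squares circle fit
to the rim band (top 2% of heights), keeps a thin slab through the
axis, and folds it into an $(r, z)$ profile. `fit_model_to_profile()`
then fits $z = (r/R)^q H$ on vertical residuals — vertical because the
profile is a function $z = f(r)$; normal-distance residuals would mix
the two axes' units of error. In `fixed_RH` mode the hand-measured $R$
and $H$ are kept and only $q$ is fitted; in `free` mode all three are
fitted, with $R$ bounded above by the observed radial extent: beyond
that bound the model depends on $(R, H, q)$ only through $H/R^q$ and
the fit is degenerate. Errors are reported as MAE and RMSE plus
relative versions normalized by the bowl height, in mm or inches per
the input flag (1 in = 25.4 mm). Bowls with trapezoid-like
cross-sections are the known failure mode of the model — the fit
reports them honestly with several-fold larger relative RMSE rather
than refusing.

## What the synthetic studies do and do not show

The simulator produces exact pinhole projections of an ideal tape:
no lens distortion, no tape wrinkling or tension effects, no labeling
error, no occlusion, and no outward rim bend (real bowls often flare at
the rim; the model does not). Passing the recovery studies therefore
demonstrates the correctness and conditioning of the geometry and the
optimizer, not field accuracy on photographs — on real images,
labeling noise and model mismatch dominate, and estimates degrade
accordingly. Synthetic point clouds are labeled as such; scanner jitter
is emulated at 0.3 mm sd, typical of consumer structured-light
scanners.

Problem sizes were chosen to keep the full studies comfortable on one
core: the reference accuracy study runs the five fixed study bowls ×
10 random cameras (the generator defaults to 25 images per bowl, the
full protocol), and Monte-Carlo checks use $10^5$ draws.

## Known limitations

* Bowls whose profiles are not power-law-like (trapezoidal
  cross-sections, rims narrower than the widest point, uneven rims) are
  outside the model class; the point-cloud fit flags them via large
  relative errors.
* Binary PLY files are not parsed; convert to ASCII PLY, XYZ or CSV.
* Camera intrinsics are assumed known (from calibration); lens
  distortion is not modeled.
* The estimator's accuracy depends on the full ruler being visible;
  occluded or clipped observations should be re-taken.
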