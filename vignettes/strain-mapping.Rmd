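---
title: "Mapping cyclic wall strains in the AAA from B-mode cine-loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cyclic wall strains in the AAA from B-mode cine-loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallstrain)
```

## The problem

Abdominal aortic aneurysm (AAA) surveillance rests on the maximum
antero-posterior (AP) diameter measured on 2D ultrasound, a criterion with
known limitations for rupture-risk prediction. The cyclic strain of the
aneurysm wall in response to the blood-pressure pulse is a direct window on
wall distensibility and hence on tissue degeneration, but estimating it
in vivo requires tracking a low-contrast, heterogeneous-quality B-mode
image sequence and differentiating the resulting sparse, noisy motion
field. `wallstrain` implements a fast, semi-automatic pipeline for this:
from a rough manual delineation of the inner wall on the first frame, it
maps circumferential, radial and shear strains over the wall cross-section
for every pressure cycle of a transverse cine-loop.

The design has two scientific pillars:

1. **Sparse demons-style tracking.** Wall motion is tracked only at a
   sparse set of points chosen where the image actually carries motion
   information (high gradient), instead of on a dense grid. This both cuts
   cost and avoids asking the tracker for answers in signal voids (the
   lateral walls, which run parallel to the beam and scatter weakly).
2. **Meshless strain computation.** The sparse displacement samples are
   interpolated with a cubic radial basis function (RBF) plus a linear
   polynomial, which is then differentiated *analytically*. No regular
   mesh is needed where the data are irregular, and the strain field is
   available anywhere — in particular on a regular output grid laid over
   the wall for display.

## Geometry: contour, region of interest, output grid

The inner wall is described by ordered landmarks in image coordinates
(x to the right, y downward/posterior, millimetres). `resample_contour()`
passes a periodic cubic spline through them and discretizes it into N
points equally spaced in arc length, rooted at the most posterior point
(maximum y) so that node numbering is reproducible across frames and
probes. Wall thickness cannot be measured on B-mode images, so a
homogeneous 2 mm is imposed: `build_wall_grid()` projects each inner node
outward along the local normal (the average of the two 90°-rotated
adjacent chords, oriented away from the centroid), re-resamples the outer
contour to N equal-spaced points keeping the posterior point fixed, and
fills two intermediate layers by linear partition, giving a 4-layer
lattice. N is chosen automatically so elements are roughly square
(circumferential spacing ≈ thickness / 3, rounded to an even integer,
at least 16). On strongly tortuous contours the projected outer contour
can self-intersect; the grid is still built, with a warning, since the
strain interpolation itself is meshless.

```{r geometry}
inner <- resample_contour(cbind(20 + 10 * cos(seq(0, 2 * pi, length.out = 73)[-73]),
                                20 + 10 * sin(seq(0, 2 * pi, length.out = 73)[-73])), 48)
grid <- build_wall_grid(inner)   # 2 mm thickness, 4 layers, auto density
grid
```

Each node also carries the angle θ of the local circumferential tangent to
the horizontal, computed by periodic central differences. The polar strain
rotation is π-periodic in θ, so angles are stored in (−π/2, π/2].

## Point selection and tracking

`sobel_gradient()` computes |Gx| + |Gy| of the frame at the start of the
first analyzed cycle; `select_points()` greedily accepts candidate pixels
inside the wall ring in descending gradient order, rejecting any candidate
within 1 mm of an accepted point. The 1 mm floor bounds the point count
(and thus cost) and avoids redundant clustered points; ties are broken in
row-major pixel order so selection is deterministic. The grid nodes are
always appended to the tracked set, because the strain output must be
supported there; where the image is weak their motion is effectively
carried by the smoothing and interpolation described next.

`track_points()` estimates each point's frame-to-frame increment by a
demons-style iteration: the update
u ← u + (I₀ − I₁(x+u))·∇I₀ / (‖∇I₀‖² + α (I₀ − I₁)²)
is averaged over a 9×9 px patch sampled with subpixel bilinear
interpolation, iterated (≤50 times) until the update falls below 0.01 px.
Frames are pre-filtered with a σ = 1 px Gaussian, and a two-level pyramid
(×1, ×1/2) captures motion beyond the patch scale. The per-point
increments are then smoothed across points with a Gaussian kernel in
space (σ = 2 mm) — the "Gaussian motion model" that makes the sparse field
inherently smooth. All of these are `tracking_params()` fields. The
tracker is deterministic; no seed is involved.

Each pressure cycle is tracked independently, once forward from its
end-diastolic start and once backward from its end (the wall returns to
its reference configuration at end-diastole, so the backward pass is
seeded with the same coordinates), and the two passes are merged with a
linear temporal blend — forward trusted near the cycle start, backward
near the end — which suppresses accumulated drift and enforces cyclic
closure.

## Cycle detection

The inner contour is tracked across the whole (optionally cropped)
sequence, and the AP diameter is read per frame at the intersection of the
contour with the vertical line through the contour centroid (recomputed
per frame, so the line follows the vessel; the alternative of freezing the
frame-1 line changes the diameter by at most the centroid drift, which is
negligible over a breath-hold). Minima (end-diastole) and maxima
(peak-systole) of the 3-frame-smoothed series delimit the cycles. Noise
extrema are pruned by a prominence filter — 25% of the series peak-to-peak
range — and a 0.3 s minimum peak separation, chosen to reject noise
without suppressing the shortest physiological cycles; durations outside
[0.3, 2.0] s are reported as warnings, never errors, since arrhythmia and
probe motion are for the reader to judge. The reference cycle is the one
whose systolic diameter increase is closest to the mean (ties to the
earliest).

## RBF interpolation and analytic differentiation

Given N sources (the tracked points at the cycle's first frame) with
cumulative displacements g, the displacement field is
u(x) = Σᵢ γᵢ ‖x − xᵢ‖³ + β₀ + β₁x + β₂y, with the coefficients solving
the symmetric (N+3)×(N+3) system [M P; Pᵀ 0][γ; β] = [g; 0], M_ij =
‖xᵢ − xⱼ‖³, P = [1 x y] — once per displacement component, by a dense
LAPACK solve. No kernel regularization is applied: exact interpolation at
the sources (residual ≤ 10⁻⁸ mm) is part of the contract, and the side
conditions Σγ = Σγx = Σγy = 0 guarantee the affine part lives entirely in
the polynomial. Near-coincident sources (< 10⁻⁶ mm) are deduplicated;
exactly collinear sources are a hard error, as the saddle-point system is
then singular.

The kernel differentiates in closed form, ∂ₓ‖r‖³ = 3‖r‖ r_x (zero in the
limit at a source), so the displacement gradient — and with it the
infinitesimal strains ε_x = ∂u_x/∂x, ε_y = ∂u_y/∂y and the engineering
shear γ_xy = ∂u_x/∂y + ∂u_y/∂x — is exact for the fitted field, with no
numerical differentiation step. Note the shear must be the symmetric
cross-derivative combination: a "shear" built from the diagonal terms
would merely duplicate the trace and could not satisfy the rotation
identities below. Strains are finally rotated into the local wall frame
with the tensor rotation T(θ) acting on (ε_x, ε_y, γ_xy/2); positive
ε_circ is circumferential stretch, positive ε_rad is wall thickening, and
the trace ε_circ + ε_rad = ε_x + ε_y is preserved exactly. Output-grid
nodes outside the convex hull of the sources (typically parts of the outer
layer) rely on the RBF's smooth extrapolation; the annulus benchmark below
exercises this case.

```{r rbf}
src <- cbind(runif(40, 0, 30), runif(40, 0, 30))
mod <- fit_rbf(src, cbind(0.01 * src[, 1], -0.005 * src[, 2]))
eval_gradient(mod, cbind(15, 15))   # recovers the affine gradient exactly
```

## The finite-element oracle

`bilinear_strain()` implements the classic 4-node isoparametric
quadrilateral with reduced integration: strain is evaluated at the single
Gauss point (ξ, η) = (0, 0) — the element centroid, where the bilinear
element is most accurate. It needs no material model (strain is purely
kinematic), replaces a commercial solver for this purpose, and provides an
independent route to strain from the same nodal displacements. A 2×2
full-integration variant is available and gives equivalent results. For
nodal strain maps, the centroid values are extrapolated to the nodes by
averaging over the elements sharing each node, the standard display step
for these elements.

`mesh_convergence()` rebuilds the wall grid at element sizes from 2 mm
down to the image resolution, evaluates the maximum of the nodal
maximum-principal-strain map by both routes, and normalizes each curve by
its finest-grid value. On the analytic annulus benchmark the meshless RBF
route converges essentially immediately (its nodal map is exact wherever
the fitted field is), while the FEM route approaches from below as the
centroids close in on the inner wall — the same qualitative ordering seen
when both are driven by tracked clinical displacements.

## The phantom: simulated cine-loops with known motion

Because no ground-truth wall motion exists for patient data, validation
uses `make_phantom_template()` + `analytic_inflation_motion()` +
`simulate_bmode()`:

* **Template.** An 8-bit image emulating the transverse scan: dark lumen
  (I ≈ 10) in a bright 2 mm annular wall (I ≈ 180), speckled mid-gray
  background (I ≈ 80) and a bright flat band below the annulus standing in
  for the spine interface. An optional angular sector of the wall can be
  rendered at near-background intensity to emulate the lateral-wall signal
  void. Defaults: 10 mm lumen radius, 0.22 × 0.22 mm pixels.
* **Motion.** Incompressible plane-strain inflation kinematics,
  u_r = A(t)·r_in/r with A(t) = A_peak·sin²(πt/T): zero at both cycle
  ends, one mid-cycle systolic peak. The closed forms ε_circ = A·r_in/r²,
  ε_rad = −A·r_in/r² are the strain oracle. Defaults: A_peak = 0.5 mm
  (a mid-range cyclic pulsation for AAA walls, whose AP diameter change
  spans roughly 0.2–2 mm) over a 33-frame cycle.
* **Imaging.** ~11,000 point scatterers are placed uniformly at random.
  Scatterers inside the wall ring form the *coherent* map: their
  backscatter coefficient BSC = (I/255)^0.2 is frozen from the frame-1
  template and their positions are advected by the analytic motion field.
  Background scatterers form the *incoherent* map: fixed positions, BSC
  re-read from the template each frame (the template is static here, a
  simplification of the patient-template original whose background also
  carried tissue motion). A 1 mm transition zone around the wall holds no
  scatterers. Frames are formed by bilinear splatting of BSC-weighted
  scatterers, convolution with a Gaussian-modulated axial cosine × lateral
  Gaussian point-spread function (σ_ax 0.2 mm, σ_lat 0.4 mm, carrier
  0.3 mm), envelope detection and 40 dB log-compression to 8 bits. The
  0.3 mm carrier sits near Nyquist at clinical pixel sizes, so the
  discrete kernel is de-meaned to preserve its bandpass character —
  without this the background envelope is not Rayleigh. At the default
  density the background envelope SNR (mean/sd) is ≈ 1.8–1.9, consistent
  with fully developed speckle (Rayleigh: 1.91), and it approaches 1.91
  as density grows.

What the phantom does *not* emulate: attenuation and depth-dependent gain,
beam geometry and anisotropic resolution, intraluminal thrombus,
out-of-plane motion, and coherent background motion. Passing the phantom
studies therefore demonstrates correctness of the tracking/strain
machinery under realistic speckle and motion, not robustness to every
clinical artifact.

## Validation studies

`run_validation()` reproduces the package's two validation instruments at
the study conditions above:

* **Tracking accuracy.** The wall grid nodes are tracked through the
  simulated cycle, seeded either on the regular grid alone or together
  with automatically selected points, and compared per frame to the
  imposed motion (RMSE over nodes). Both strategies stay well inside the
  B-mode pixel size; on the low-signal (masked-sector) variant the
  automatic selection is the better of the two, though on this small
  circular phantom the margin is modest because the 2 mm increment
  smoothing couples the two point sets.
* **Strain agreement and convergence.** On the peak-systole ground-truth
  displacements, the RBF and FEM routes agree at image-resolution element
  size to a mean absolute maximum-principal-strain difference orders of
  magnitude below the strains themselves, and the RBF convergence level
  exceeds 99% for every grid beyond 1000 elements.

`scripts/acceptance.R` re-runs exactly these four quantities from scratch
and writes them as JSON; the problem sizes are the defaults above
(376-node output grid, 33 frames, ~11,000 scatterers; finest element size
0.22 mm, 2538 elements).

## Numerical choices and limitations

* Dense saddle-point solves are unregularized; for the N ≈ 10²–10³
  sources of a clinical cycle this is fast and stable in double
  precision. Duplicated sources are removed, collinear clouds rejected.
* The demons iteration is a fixed-point scheme without line search;
  pre-filtering, the patch average, the pyramid and the spatial smoothing
  are what keep it in its basin. Points whose patch leaves the image
  freeze their displacement with a warning.
* Strain is purely kinematic: no mechanical equilibrium is enforced, no
  stresses are computed, and no material parameters exist anywhere in the
  package.
* The AP diameter line follows the per-frame centroid; cycle detection
  assumes at least one full end-diastole-to-end-diastole excursion.
* 2D only: out-of-plane motion appears as apparent in-plane strain and is
  not corrected.
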