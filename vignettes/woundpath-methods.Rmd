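---
title: "Methods: geometry, calibration and control in woundpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, calibration and control in woundpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundpath)
```

woundpath implements the computational side of a six-axis in situ
bioprinting robot for skin-wound repair: find the wound with a binocular
camera, reconstruct its surface and measure the missing volume, plan a
conformal deposition path that carries exactly that volume of bioink, and
keep tracking the wound while it moves. This vignette documents the models,
the conventions and defaults, the numerical choices, and what the synthetic
fixtures do and do not establish about real data.

## Conventions

Everything inside the package is millimetres and radians; degrees appear
only in files and at the CLI. Frames are right-handed. Euler angles are
intrinsic Z-Y-X (yaw–pitch–roll), the most common manipulator convention;
nothing in the hardware-facing formats pins a convention, so this one is
fixed explicitly and written into every serialized header. Waypoint
orientations encode the *surface frame* — z along the outward surface
normal, x along the travel direction — and the print head approaches along
−z of that frame, i.e. the tool axis is anti-parallel to the surface
normal. With that choice a flat horizontal surface yields zero pitch and
roll, and a normal-aligned head sees zero relative inclination everywhere,
which is exactly the printable-angle argument below.

## Vision

The pinhole model is linear: `Z (u,v,1)' = K [R|t] (X,1)'` with
`K = [[fx, s, x0], [0, fy, y0], [0, 0, 1]]`. Lens distortion beyond the
linear terms is out of scope. Pixels are (u, v) = (column, row), origin at
the top-left pixel centre, 0-based.

Segmentation exploits the colour contrast between wound and skin: linear
per-channel normalization (so the pipeline is exactly invariant to affine
brightness changes), RGB→HSV conversion and a hue/saturation/value band,
Gaussian blur at σ = 0.5 px, removal of margin pixels by a Sobel-magnitude
threshold and of components touching the image border, morphological
erosion, then connected components, ordered contours and area barycentres.
The HSV thresholds for real murine wounds are not derivable at the desk;
the defaults target the synthetic fixture palette (deep red on skin tone)
and every band is configuration-exposed.

Triangulation stacks the two projection equations into the homogeneous
linear system and takes the smallest right singular vector (DLT). A
nonlinear reprojection-minimizing refinement exists as
`triangulate_nonlinear()` but is deliberately *not* the production path: it
serves as the independent cross-check in the tests, and collapsing the two
would remove the check. Localization quality is summarized by the relative
range error and angular deviation

$$E_d = \frac{|l - l_0|}{l_0}, \qquad
  E_a = \arctan\!\left(\frac{dP \cdot \sin\theta}{l_0}\right),$$

with `l`/`l₀` the calculated/real camera–object distance, `dP` the planar
recognition error and θ the depression angle. `E_d` is reported as a
magnitude (the signed form carries no extra information for accuracy
grading and the invariant `E_d ≥ 0` keeps summaries one-sided).

## Eye-in-hand calibration

With the camera on the end-effector, each sampled pose obeys
`H_ew,i · H_ce = H_gw · H_cg,i`. Eliminating the two constants between
samples i and j gives `A X = X B` with
`A = inv(H_ew,j) H_ew,i` and `B = inv(H_cg,j) H_cg,i`; this pairing follows
directly from the frame definitions (end-effector in base; camera in grid)
and is pinned by a forward-construction test. The solver is closed-form
for determinism: rotation by quaternion linear least squares over all
informative pairs, translation by linear least squares, then a few
alternating-average sweeps (X → grid pose → X) that drive consistent data
to machine precision. The rotation metric everywhere is
`2 asin(‖R₁'R₂ − I‖_F / 2√2)`, which unlike the arccos-of-trace form does
not lose precision below ~2e−8 rad.

The problem is unobservable when all relative rotations share one axis, so
the solver refuses sets with fewer than 3 samples or a rotation-axis spread
under 5°, reporting the measured spread instead of returning an
ill-conditioned answer.

## Kinematics

Links follow the standard (distal) Denavit–Hartenberg convention; the
canonical matrix form is used. The physical arm's parameter table is not
publicly available, so a representative anthropomorphic 6R arm with a
spherical wrist and ≈600 mm reach ships as `default_chain()`; every
algorithm is parameter-generic and a YAML chain description overrides the
default. Chains of any length are accepted — planar 2R arms and single
rotary links are the analytic test cases.

Inverse kinematics is damped least squares (Levenberg adaptation: damping
shrinks while steps improve, grows when they stall) on the 6-vector pose
error, with rotation rows weighted at 100 mm/rad so millimetre and radian
residuals are balanced, joint-limit clamping, and a handful of
deterministic perturbed restarts for the rare configuration near a wrist
singularity. Targets beyond the chain's reach fail fast with the measured
distance.

The Monte Carlo workspace samples joints uniformly within limits (seed
mandatory), evaluates positions with a vectorized batch evaluator, and
voxelizes; volume is occupied voxels × voxel³. Voxel counting slightly
overestimates at the boundary (partial cells count whole), which is the
dominant bias at practical sample counts. For planar chains a planar area
is reported so closed forms (annulus `π((L1+L2)² − (L1−L2)²)`) can grade
the estimate. The kinematic-error map perturbs the D–H parameters with
Gaussian draws and maps mean end-effector displacement over a 5 mm grid,
summarizing the fraction of cells under 0.2 / 0.4 mm; it is a simulation
model of error accumulation, and no attempt is made to match any specific
hardware's measured percentage.

## Wound geometry

Scans are open surfaces, so the defect model is expressed as the region
between two height-field surfaces over one triangulation rather than a
Boolean of solids: the *bed* (scan inside the rim) and the *cap* (the
interpolated healthy surface across the rim). Reconstruction is a regular
grid at `grid_step`, each node fitted by a local least-squares plane over
its neighbourhood — this reproduces planar surfaces to machine precision
and gives O(h²) accuracy on smooth curvature. At a crater rim with a
vertical tangent the surface drops by the chord depth `sqrt(2 r h)` inside
one cell, so pointwise accuracy there is fundamentally limited for any
height field; the defect *volume*, the quantity the planner consumes, is
affected only at the percent level (graded at 2 % on the hemisphere
fixture).

Rim detection thresholds depth below a reference plane fitted to the
scan's outer boundary (default 0.1 mm), takes the largest connected
component and its surrounding ring of healthy nodes. A mean-curvature
detector was considered and rejected: on discrete noisy grids it flags the
crater bottom as readily as the rim, while a depth threshold has one
interpretable parameter. An explicit rim polygon overrides auto-detection
and keeps tests deterministic. The cap solves the Laplace equation on the
footprint with rim heights as Dirichlet data (harmonic interpolation —
the unique minimal-membrane continuation of the surrounding surface);
volume is the prismatic integral of cap minus bed over the shared
triangles. Volumes are invariant under rigid motion of the scan via
`orient = "auto"`, which rotates the total-least-squares plane normal to
+z first.

## Path planning and bioink allocation

Small wounds are filled point-to-point; large wounds get a planar
boustrophedon raster projected conformally onto the bed. The strategy
threshold defaults to 20 mm³, which sends 2 and 5 mm biopsy-punch defects
to point mode and a 10 mm defect (≈31 mm³) to the conformal path. Ties go
to conformal. The projection axis is the cap's mean normal (+z after
orientation); the projection resamples the raster at a fixed arc-length
step and interpolates position and normal barycentrically inside each
triangle. On a sphere centred at the origin the barycentric combination of
radial vertex normals is exactly radial, which is what lets the conformal
tests grade tool-axis accuracy at 1e−6 rad against the analytic sphere.

Bioink is incompressible and the deposited volume equals the defect volume
(1 mm³ = 1 µl). Allocation is proportional to segment arc length within a
layer, with the last element adjusted so the sum is *exactly* the total —
mass conservation is asserted at 1e−9 µl on every plan. Multi-layer fills
repeat the bed path offset along the projection axis at `layer_height`
until the cumulative layer volume reaches the defect volume; the last
layer's share is scaled down. Nozzle diameter and rheology are out of
scope; line spacing (1 mm), waypoint step (0.5 mm) and layer height
(0.5 mm) are defaults chosen at biopsy-punch scale and exposed in
configuration.

The printable-angle model captures thread skidding on inclines: threads
adhere up to a critical inclination (70° for the reference hydrogel), so a
fixed-vertical head prints `2 × 70° = 140°` symmetric about vertical,
while a normal-aligned head keeps the nozzle–surface inclination at zero
identically and the skid condition never triggers — a 360° printable
range.

## Tracking simulation

The loop is discrete-time with synchronized camera and control cycles
(defaults: 30 Hz camera, 90 Hz control, one camera frame of latency —
declared assumptions, no frame rates are published for the hardware).
Wound pose is measured from n ≥ 3 rigid markers: positions perturbed by
Gaussian noise, plane fitted for orientation, 2D registration in the plane
for the rest — the same plane-from-points capture used for static wounds.
Compensation is pure feed-forward of the latest measured displacement
composed with the preset path; a PID refinement was deliberately excluded
so the error budget stays analyzable: with a speed/acceleration-unlimited
arm and no latency the loop tracks any smooth trajectory to solver
tolerance, and with latency L the straight-line error is pinned near
(speed × L).

The end-effector model carries a velocity state under a speed cap
(500 mm/s) and an acceleration cap (400 mm/s², a gentle-handling value for
motion near a patient). The acceleration cap is what makes corners the
dominant error source: a square corner demands a discontinuous velocity
direction change, producing a transient the feed-forward loop cannot
remove, whereas pure kinematic compensation would actually *cut* corners
and err less there. Corner steps are labelled over the stale-measurement
window plus the re-acceleration time `speed·√2 / max_accel` after each
>45° turn. Simulated error magnitudes are properties of these declared
knobs, not predictions of any specific hardware's measured accuracy.

## Fixtures: what they do and do not show

Every module is graded against generators with known truth: anti-aliased
dot grids (10 × 8, 20 mm pitch, 4 mm dots) rendered through both cameras;
wound discs on textured skin whose per-channel extremes pin normalization;
crater clouds (hemisphere / half-ellipsoid / punch cylinder at biopsy-punch
scales) with closed-form volumes; hand-eye pose sets built from known
transforms with enforced axis diversity. Same parameters + seed give
byte-identical output.

These fixtures validate the *geometry and algebra* — projection,
triangulation, calibration, reconstruction, integration, allocation,
loop timing. They do not emulate lens distortion, specular skin, scanner
noise correlation, soft-tissue deformation, or extrusion physics; passing
tests therefore demonstrate correctness of the computational pipeline, not
field performance of a physical system.

## Problem sizes and tolerances

The test and acceptance runs use: 1000-point triangulation round trips
(<1e−6 px reprojection); 10-pose noiseless hand-eye recovery (<1e−8 rad,
<1e−8 mm) with noise scaling checked over one decade; 1000 random chains
against the homogeneous-matrix FK oracle (1e−12 relative) and 500 IK round
trips (<1e−6 mm, 100 % required); 1e6 workspace samples at 2 mm voxels
against the annulus area (3 %); hemisphere volume at 0.25 mm grid from a
0.125 mm cloud (2 %, plus a voxel-counting cross-check at 2 %); toolpath
conservation at 1e−9 µl and sphere conformality at 1e−6 mm / 1e−6 rad;
tracking at speeds {5, 10, 15, 20, 30} mm/s (strict monotonicity, corner
dominance on the square); segmentation centroids at 0.5 px. These sizes
keep the full suite around two minutes on one core while leaving each
estimate's Monte Carlo error well inside its tolerance.

## Known limitations

- Height-field reconstruction cannot represent overhanging or folded
  anatomy; such scans are rejected with a re-orientation hint.
- Rim ordering sorts by angle about the centroid, which assumes a
  star-shaped rim; strongly non-convex wounds would need a boundary walk.
- The linear camera model ignores radial distortion; real calibration
  residuals would fold into the recognition errors.
- The servo simulator is kinematic with first-order actuation caps; joint
  dynamics, flexibility and controller internals are out of scope.
- Hand-eye solving assumes the grid pose per sample is given (produced by
  the fixtures); estimating it from raw grid images is not implemented.
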