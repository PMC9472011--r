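# woundpath

Planning and tracking computations for an adaptive multi-degree-of-freedom
in situ bioprinting robot for skin-wound repair.

In situ bioprinting deposits cell-laden bioink directly into a tissue
defect. Doing that on a living animal requires a chain of computations that
this package implements end to end, on synthetic but ground-truthed data:

- **Vision** — HSV colour-filter wound segmentation (normalize → colour
  band → Gaussian blur σ = 0.5 px → gradient margin removal → erosion →
  contours and barycentres), the linear pinhole model
  `Z·(u,v,1)' = K [R|t] (X,1)'`, binocular triangulation (homogeneous DLT),
  and the recognition-error metrics
  `E_d = |l − l₀|/l₀`, `E_a = arctan(dP·sinθ / l₀)`
  evaluated on a 10 × 8 dot grid (20 mm pitch, 4 mm dots).
- **Calibration** — the eye-in-hand identity
  `H_ew,i · H_ce = H_gw · H_cg,i` solved for the camera-to-end-effector
  transform as a closed-form AX = XB problem (quaternion linear least
  squares, then translation least squares, then alternating refinement).
- **Kinematics** — standard Denavit–Hartenberg link transforms, forward
  kinematics `T = ∏ Tᵢ`, damped-least-squares inverse kinematics, Monte
  Carlo reachable workspace with voxel volume estimates, and simulated
  kinematic-error maps over a 5 mm grid (0.2 / 0.4 mm accuracy bands).
- **Wound geometry** — height-field surface reconstruction from scan point
  clouds, rim detection, harmonic (Laplace) cap interpolation over the
  defect, and defect volume by prismatic integration: the cap-minus-bed
  expression of the Boolean defect model for open scanned surfaces.
- **Path planning** — boustrophedon rasters projected conformally onto the
  reconstructed surface as six-coordinate waypoints (position + intrinsic
  Z-Y-X Euler angles of the local surface frame), volume-exact bioink
  allocation, the small/large wound strategy switch, and the printable-angle
  model (70° skid threshold → 140° for a fixed-vertical head; 360° for a
  normal-aligned head).
- **Servo simulation** — a discrete-time closed-loop visual tracking
  simulator (synchronized camera/control cycles, frame latency, marker-based
  pose measurement via plane fitting, feed-forward compensation,
  speed/acceleration limits) with square / circle / shaker trajectories.
- **Fixtures** — deterministic synthetic generators with machine-readable
  ground truth for every stage: stereo dot-grid and wound renders, crater
  clouds with closed-form volumes, hand-eye pose sets.

Units are millimetres and radians throughout; degrees appear only at file
and CLI boundaries.

## Worked example

```r
library(woundpath)

# a 5 mm hemispherical biopsy-punch defect, scanned as a point cloud
cr   <- gen_crater_cloud("hemisphere", radius = 5, sample_step = 0.125)
mesh <- reconstruct_surface(cr$cloud, grid_step = 0.25)
model <- extract_wound(mesh)
model
#> <wound_model> volume 258.535 mm^3, rim of 121 vertices, footprint ~92.9 mm^2

c(truth = cr$truth$volume_mm3, estimate = model$volume_mm3)
#>    truth estimate
#> 261.7994 258.5354          # 1.25 % low: rim smoothing of the reconstruction

tp <- plan_wound(model, line_spacing = 1, step = 0.5, layer_height = 0.5)
tp
#> <toolpath> conformal, 1050 waypoints, 6 layer(s), 258.535 ul total
sum(tp$extrude) - model$volume_mm3
#> [1] 0                       # bioink allocation conserves the defect volume

st <- error_stats(simulate_tracking(
  make_trajectory("square", speed = 15, duration = 12), servo_config(), seed = 1))
st
#> segment  max_mm mean_mm rms_mm    n
#> all       0.932   0.682  0.684 1035
#> corner    0.932   0.731  0.745   52
#> straight  0.833   0.679  0.681  983   # corners dominate the tracking error
```

The volume printed by `extract_wound()` is what drives both the strategy
switch (`choose_strategy()`: below 20 mm³ the wound is filled
point-to-point, above it a conformal raster is planned) and the exact
extrusion budget. The tracking table shows the feed-forward loop pinned at
the latency floor on straight segments and spiking at corners, where the
arm's acceleration limit bites.

A full pipeline run (`run_pipeline()`, or `Rscript inst/cli/woundpath.R run
--seed 4 --out out/`) chains fixtures → segmentation → stereo localization
→ reconstruction → planning → tracking and writes per-stage artifacts plus
a deterministic `report.json`.

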