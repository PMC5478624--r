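# seedbed3d

Depth-camera characterization of cultivated seedbed surface structure.

How finely a field is tilled — the size distribution of soil clods on the
surface — shapes seed–soil contact and hence crop emergence. `seedbed3d`
turns a single frame from a consumer structured-light depth camera
(Kinect-class, 640×480, mounted nadir at ~0.8 m) into:

* a metric 3D reconstruction (pinhole back-projection, hole masking,
  rasterization to a height field, optional Delaunay mesh export);
* a decomposition of the surface into a **basal soil surface** plus a
  **block residual** carrying the protruding clods,
  `G(r) = G(r)_basal + G(r)_block`, via a robust mask-aware Gaussian form
  filter (σ = 0.05 × image width);
* a per-clod inventory (area, extents, height, area-equivalent diameter)
  binned into the standard grain-size classes
  `<5, 5–15, 15–50, 50–80, 80–120, >120 mm`;
* the ISO 25178-2 areal height parameters on the detrended surface

  S<sub>a</sub> = (1/A)∬|z| dx dy, &nbsp;
  S<sub>q</sub> = √((1/A)∬z²), &nbsp;
  S<sub>sk</sub> = (1/S<sub>q</sub>³)(1/A)∬z³, &nbsp;
  S<sub>ku</sub> = (1/S<sub>q</sub>⁴)(1/A)∬z⁴;

* classification into ten reference tilth grades (nearest reference in
  standardized (S<sub>a</sub>, S<sub>q</sub>) space; the packaged reference
  tables give each grade's sieved size composition and characteristic
  texture values);
* validation statistics (R², RMSE, REP = 100·RMSE/mean(reference)) under a
  seeded, grade-stratified calibration/validation split, reported per
  parameter × grade group (1–3, 4–6, 7–10);
* emergence-rate and emergence-speed summaries of daily seedling counts;
* a fully seeded **synthetic seedbed simulator** (grade-faithful clod-size
  sampler, spherical-cap scenes, Kinect-like noise/quantization/hole
  rendering) with complete ground truth, so the entire pipeline is testable
  without field data.

## Worked example

```r
library(seedbed3d)

scene  <- build_seedbed(grade = 6, seed = 1)   # ground-truth scene
img    <- render_depth(scene, seed = 2)        # simulated 640x480 depth frame
report <- run_pipeline(img)                    # reconstruct -> detrend ->
                                               # decompose -> texture -> clods
report
#> <plot_report> plot: grade 3, Sa=6.05 mm, Sq=7.25 mm, 108 clods
report$texture
#> <texture_params> Sa=6.053 mm  Sq=7.255 mm  Ssk=1.169  Sku=3.058
scene$true_texture$Sa
#> [1] 6.141123
```

The pipeline recovers the scene's true S<sub>a</sub> (6.14 mm) to within
~1.4% despite 2 mm depth quantization, 1.5 mm range noise and 2% dropouts.
`report$distribution` holds the clod size-class fractions,
`report$blocks` the per-clod records, and `report$grade` the assigned
reference grade.

Real frames enter the same way from disk: a 16-bit grayscale PNG whose
pixel value is depth in mm (0 = hole) with a JSON/YAML intrinsics sidecar —
`run_pipeline("plot042.png", pipeline_config(), output_dir = "out/")`.

A thin command-line wrapper ships at
`system.file("cli", "seedbed3d.R", package = "seedbed3d")` with subcommands
`reconstruct`, `texture`, `blocks`, `grade`, `simulate`, `validate`.

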