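# stereotrack

3D particle tracking from two-photon stereo projection microscopy, in R.

## The problem

Video-rate two-photon laser scanning stereomicroscopy images a whole
~110 × 110 × 100 µm volume at 30 volumes/s by scanning two extended-focus
Gaussian beams tilted by a small parallax angle (≈28.1° full angle). Each
acquisition is a *stereo pair* of 2D projections; a fluorescent particle at
depth `z` from the focal mid-plane appears laterally shifted by
`±z·tan(θ/2)` in the two views, so its pixel disparity `d = x_L − x_R`
encodes depth linearly:

    z = d · p / (2·tan(θ/2)),     p = pixel pitch (110/512 ≈ 0.215 µm)

This package implements the computational side of that instrument for
people doing multiple-particle tracking in scattering media (intralipid,
tissue-engineered scaffolds): image restoration (frequency-domain low-pass
+ Richardson–Lucy deconvolution), adaptive-threshold segmentation with
circular-Hough particle detection, optimal (Hungarian) left↔right stereo
matching on position/size/encircled-energy features, disparity-to-depth 3D
reconstruction, frame-to-frame trajectory linking with gap closing, and
trajectory analytics (time-averaged MSD, drift velocity, localization
precision, depth-error statistics). A built-in synthetic stereo simulator
(parallel projection, disc ⊛ Gaussian-PSF blobs, Brownian motion + drift,
Poisson photon noise) provides ground truth so every stage is testable
without a microscope.

## Worked example

Render the 13-bead characterization scene (4.46 µm fluorescent beads,
non-overlapping, depths spread across the depth of field), run the full
reconstruction, and score depth errors against the simulator ground truth:

```r
library(stereotrack)

cfg <- optics_config()     # 28.1°, 110×110×100 µm, 512×512 px, 30 Hz
print(cfg)
#> <optics_config>
#>   parallax (full) : 28.10 deg
#>   field of view   : 110 x 110 um (512 x 512 px, 0.2148 um/px)
#>   depth of field  : 100 um (z in [-50, 50])
#>   volume rate     : 30 Hz

scene <- characterization_scene(seed = 42, cfg = cfg)
pair  <- render_stereo_pair(scene, cfg,
                            noise_model(background_photons = 10,
                                        read_noise_sd = 1, seed = 42))
res   <- run_pipeline(list(pair), pipeline_config())
print(res)
#> <pipeline_result> 1 frame(s), 13 matched particle(s), 13 trajectorie(s)

est <- pair_with_truth(res$particles, scene)
print(depth_error_report(est[, c("id", "z_um")], scene[, c("id", "z_um")]))
#> <depth_error_report> n = 13, mean |dz| = 0.004 um, <2 um: 100.0%, <5 um: 100.0%
```

All 13 beads are detected in both views, matched, and depth-resolved; on
this noise-clean synthetic scene the mean absolute depth error is ~4 nm —
far inside the few-µm errors measured on real data, which is the point:
the synthetic analogue bounds the algorithmic error, not the instrument's.

Time series work the same way: `simulate_sequence()` produces frames plus
a tidy ground-truth table, `run_pipeline()` returns per-frame 3D particles
and linked trajectories, and `compute_msd()` / `drift_velocity()` /
`localization_precision()` quantify them.

## Command line

```sh
inst/cli/stereotrack simulate    --config optics.yaml --n-particles 13 --frames 120 --seed 1 --out sim/
inst/cli/stereotrack run         --config optics.yaml --left sim/left.tif --right sim/right.tif --out out/
inst/cli/stereotrack analyze     --trajectories out/trajectories.csv --out out/
```

Formats: multi-page grayscale TIFF in (split `left.tif`/`right.tif` or a
single interleaved stack), CSV/JSON out, YAML config.

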