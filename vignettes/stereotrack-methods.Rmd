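---
title: "Methods: stereo projection reconstruction and particle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo projection reconstruction and particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stereotrack)
```

## The measurement model

A two-photon stereo projection microscope scans two Gaussian beams tilted by
a small full parallax angle $\theta$ (default $28.1^\circ$) through a volume
with an extended depth of field (EDF). Each acquisition produces a
*stereo pair*: two 2D images that are parallel projections of the same
volume along the two tilted axes. A fluorescent particle at depth $z$
(measured from the axial centre of the extended focus) appears laterally
displaced by $+z\tan(\theta/2)$ in the left view and $-z\tan(\theta/2)$ in
the right view, so its disparity $d = x_L - x_R$ in pixels encodes depth
linearly:

$$ z = \frac{d \, p}{2\tan(\theta/2)}, $$

with $p$ the pixel pitch in micrometres (`fov_x_um / frame_w_px`,
$110/512 \approx 0.215\,\mu m$ by default). With the default geometry one
pixel of disparity corresponds to $\approx 0.43\,\mu m$ of depth, which is
why axial precision is intrinsically $\sim\!2\times$ worse than lateral
precision *per pixel of centroid error*, and why the reconstruction is only
valid inside the depth of field ($\pm 50\,\mu m$ by default).

Three conventions had to be fixed where the instrument description leaves
them open, and all code follows them consistently:

* `parallax_angle_deg` is the **full** angle between the two view axes
  (each beam is tilted $\theta/2$ from the optical axis);
* disparity is $x_L - x_R$, and positive disparity means positive $z$;
* image row = y, column = x, origin top-left, 0-based pixel centres
  (pixel column $i$ sits at $i\,p$ micrometres).

## Pipeline

For each frame the pipeline runs, per view:

1. **Low-pass denoising** in the frequency domain with a Gaussian transfer
   function $H(f) = \exp(-2 (f/f_c)^2)$, $f_c$ = `cutoff` (cycles/pixel,
   default 0.3). A Gaussian response was chosen over an ideal brick-wall
   filter to avoid ringing around bright particles; the price is that the
   filter is only approximately idempotent.
2. **Richardson–Lucy deconvolution** (default 10 iterations, early stop at
   relative change $<10^{-4}$) with a synthetic Gaussian PSF of sd
   `psf_sigma_um` (default 0.4 µm). The division inside the iteration is
   guarded by $\epsilon = 10^{-12}$; convolutions use reflective padding.
   The instrument description does not say whether a measured or model PSF
   was used for deconvolution; the model PSF is the default and a measured
   kernel can be passed to `deconvolve_rl()` directly.
3. **Segmentation** by adaptive threshold: foreground iff pixel > local
   mean over a `block_size_px` window (default 31) + `offset` (default
   twice the robust noise sd, `2 * mad(img)`).
4. **Detection**: gradient-voting circular Hough transform over the radius
   range `r_min_px..r_max_px` (default 7–14 px, bracketing the 4.46 µm
   calibration bead whose radius is ≈10.4 px). Non-maximum suppression
   keeps centres at least `r_min_px` apart, with deterministic tie-breaks
   (score, then row, then column). For PSF-limited particles (e.g. 500 nm
   nanoparticles, well below the pixel pitch) the Hough radius estimate is
   ill-posed — the image is the PSF regardless of particle size — so a
   `mode: blob` detector (local maxima + the same feature extraction) is
   provided instead.
5. **Feature extraction**: iterated intensity-weighted centroid over a
   1.5 r window, background-subtracted photometry over a 2 r window, and
   encircled energy (fraction of total intensity within r). The frame
   background is the image median, robust against sparse bright particles.

Then, per frame:

6. **Stereo matching**: all feasible left/right pairs get a dimensionless
   cost $w_y |\Delta c_y|/s_y + w_r |\Delta r|/s_r + w_E |\Delta E|/s_E$
   (defaults $w = (0.5, 0.25, 0.25)$); a pair is infeasible when the rows
   differ by more than `row_tol_px` (default 2 px, allowing for resonant
   line jitter) or the implied depth leaves the DOF. The scales $s$ are
   per-frame MAD spreads of each feature pooled over both views, floored at
   (1 px, 0.5 px, 0.02) so that frames of identical features remain
   well-defined. The exact functional form of the combination factor is an
   engineering choice; any weighted sum monotone in each discrepancy
   satisfies the published description. The assignment is solved exactly
   with an in-package Hungarian (shortest augmenting path) solver rather
   than greedily, because the matching is described as globally best and
   the same solver is needed for tracking anyway.
7. **Reconstruction**: $x = p(c_{x,L}+c_{x,R})/2$, same for $y$; $z$ from
   the disparity. Matches implying $|z| > \mathrm{DOF}/2 + 1\,\mu m$ are
   dropped with a warning.

And over time:

8. **Tracking**: optimal frame-to-frame linking of 3D positions with a
   gate `max_link_dist_um` (default 5 µm), then gap closing between track
   ends and starts `1..max_gap_frames` frames later (default 2) within
   `max_gap_dist_um` (default 7 µm), again by optimal assignment. These
   gating defaults are engineering choices, not published values; they are
   all exposed in the config. The suggested anisotropic down-weighting of
   z in the link metric is implemented (`z_weight`) but ships **off**
   (`z_weight = 1`) because the documented invariant — direct links never
   exceed `max_link_dist_um` in plain Euclidean 3D distance — would
   otherwise silently change meaning. Trajectories shorter than
   `min_length` (default 3) are flagged, never deleted.

## The synthetic world

The simulator exists so that every stage is testable against ground truth
without a microscope. It emulates:

* uniform random 3D bead fields (`make_scene`), optionally with a minimum
  pairwise 3D distance and — for characterization scenes — a minimum
  pairwise distance in *each projected view*. The latter matters because
  two beads 12 µm apart in 3D can still overlap in projection when their
  separation is mostly axial (parallax moves a bead laterally by only
  $z\tan(\theta/2) \approx z/4$); the published characterization scene is
  explicitly a field of non-overlapping circular objects.
* parallel projection onto the two tilted views with a top-hat axial
  response: uniform sensitivity inside the DOF, nothing outside. The real
  axial profile of the extended focus is not published; the top-hat keeps
  blob photometry depth-invariant, which the matching stage assumes.
* blobs as a uniform disc of the particle's physical radius convolved with
  a Gaussian lateral PSF (sd 0.4 µm by default — plausible for a 0.8 NA
  two-photon system, an assumption rather than a measurement). The profile
  is evaluated analytically (a Rician integral with `besselI`) on a 4×
  oversampled grid and box-binned, keeping pixelisation centroid bias
  below ~0.05 px. Sub-resolution particles degenerate correctly to the
  PSF itself.
* Brownian motion with constant drift (`step_motion`): displacement
  $v\,\Delta t + \mathcal N(0, \sqrt{2D\Delta t})$ per axis, reflecting
  (default, conserves particle count) or absorbing boundaries.
* detection noise: optional view crosstalk $\epsilon$ (imperfect pulse
  demultiplexing: $(1-\epsilon)\cdot$own $+\,\epsilon\cdot$other, default
  0 — ideal demultiplexing), constant background (default 10
  photons/pixel), Poisson photon sampling, additive Gaussian read noise
  (default sd 1 count), clipped at zero. Default peak brightness is 1000
  expected photons.

What the simulator does **not** model: depth-dependent signal loss in
scattering media, scanner kinematics, pulse-level multiplexing timing, or
aberrations. A green synthetic test therefore establishes that the
*algorithms* recover what the stated optics encode — it does not establish
instrument-level performance in tissue. This is also why the synthetic
analogues of the characterization experiments are compared against the
published real-data numbers as *upper bounds*: the clean synthetic scene
should do at least as well (measured here: mean synthetic depth error
~0.005 µm versus the published real-data mean of ~2.5 µm, and stationary-
bead precision of a few nm versus the published 0.1/1.1 µm).

The settling velocity reported for the real nanoparticle experiments
(≈10 µm²/s, printed with area units) is ambiguous between a drift speed
and a squared-displacement rate; the simulator exposes both knobs
(`drift_um_per_s`, `diffusion_um2_per_s`) and no attempt is made to
reproduce that number.

### Fixture geometry choices (made once, not tuned)

* Characterization scene (`characterization_scene`): 13 beads, radius
  2.23 µm, brightness 1000, 3D and projected separation ≥ 12 µm, x inset
  by the maximum parallax shift ($\mathrm{DOF}/2 \cdot \tan(\theta/2)
  \approx 12.5\,\mu m$) plus the blob extent so every projection stays in
  frame, z inset 3 µm from the DOF edge so the reconstruction tolerance
  never clips a bead.
* Depth sweep (`depth_sweep_scene`): 21 beads on a fixed 5-column grid,
  z from $-50$ to $+50\,\mu m$ in 5 µm steps assigned column-wise in
  increasing order, so laterally adjacent projections never cross. Rows
  are additionally staggered in y by 2.2 µm per column: identical beads on
  a shared epipolar row in different columns would otherwise be exact cost
  ties for the stereo matcher (the correspondence features deliberately
  exclude x), and either labelling of a tie is optimal — the stagger makes
  the intended pairing uniquely feasible instead of relying on tie-break
  luck.

## Numerical details worth knowing

* The Hungarian solver works on a square-padded matrix; infeasible pairs
  get a sentinel cost chosen so the solver first maximises the number of
  feasible assignments, then minimises their total cost. Assignments that
  land on a sentinel or a dummy are reported as unmatched.
* TIFF I/O implements the uncompressed grayscale baseline subset
  (8/16-bit unsigned, 32/64-bit float, little-endian) in R, because the
  target environment has no R TIFF package. The default pixel type for
  simulated sequences is 64-bit float, which round-trips R doubles
  bit-exactly. The Python `tifffile` reader is used in the test suite as
  an independent format oracle.
* `compute_msd` uses the overlapping time-average estimator (all ordered
  pairs per lag; standard in single-particle tracking) with a
  non-overlapping variant behind a flag; displacement pairs that span a
  missing frame (including bridged gaps) are excluded.
* All randomness flows through R's RNG; `simulate_sequence` seeds once
  from the noise model's seed and the same seed reproduces a sequence
  bit-for-bit. The pipeline itself is deterministic.

## Known limitations

* Overlapping-particle splitting is out of scope (the method assumes
  sparse fluorophores); densely overlapping projections will merge or
  drop detections.
* The Hough detector assumes bright, roughly circular blobs on a darker
  background; `mode: blob` covers the PSF-limited case but non-circular
  shapes are not modelled.
* Scenes are rendered frame-by-frame under the EDF idealisation; motion
  blur within a volume scan is not simulated.
* Test-suite simulations are scaled down (small frames, short sequences)
  to stay within CI time budgets; the acceptance experiments run at the
  full 512×512, 60-frame scale.
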