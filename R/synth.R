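#' Create a random 3D particle scene
#'
#' Places `n_particles` fluorescent particles uniformly at random in a box
#' spanning the imaged volume. Positions are in micrometres with `z` measured
#' from the focal mid-plane (see [optics_config()]).
#'
#' @param n_particles Number of particles, >= 0.
#' @param radius_um Physical particle radius (single value recycled), > 0.
#' @param brightness Expected peak photon count per particle at the detector.
#' @param bounds List with elements `x`, `y`, `z`, each `c(lo, hi)` in um.
#'   Default: the full default imaged volume `[0,110] x [0,110] x [-50,50]`.
#' @param min_separation_um Optional minimum pairwise 3D distance. Placement
#'   is by rejection sampling; an infeasible packing fails with an error
#'   after bounded retries rather than looping forever.
#' @param min_projected_separation_um Optional minimum pairwise lateral
#'   distance in *each projected view* (x shifted by `+-z tan(theta/2)`).
#'   Particles well separated in 3D can still overlap in a projection when
#'   their separation is mostly axial; a characterization scene of
#'   non-overlapping circular objects needs this guarantee. Requires `cfg`.
#' @param cfg An [optics_config()]; only needed when
#'   `min_projected_separation_um > 0`.
#' @param seed RNG seed; the scene is reproducible given the seed.
#' @return A `data.frame` (class `particle_scene`) with columns
#'   `id, x_um, y_um, z_um, radius_um, brightness`.
#' @export
make_scene <- function(n_particles, radius_um = 2.23, brightness = 1000,
                       bounds = list(x = c(0, 110), y = c(0, 110),
                                     z = c(-50, 50)),
                       min_separation_um = 0,
                       min_projected_separation_um = 0, cfg = NULL,
                       seed = NULL) {
  stopifnot(n_particles >= 0, radius_um > 0, brightness > 0,
            min_separation_um >= 0, min_projected_separation_um >= 0)
  tan_half <- 0
  if (min_projected_separation_um > 0) {
    if (is.null(cfg))
      stop("min_projected_separation_um needs an optics_config 'cfg'")
    tan_half <- tan(cfg$parallax_angle_deg / 2 * pi / 180)
  }
  if (!all(c("x", "y", "z") %in% names(bounds)))
    stop("'bounds' must contain x, y and z ranges")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_particles)
  if (n == 0L) {
    return(empty_scene())
  }
  max_restarts <- 20L
  per_particle_tries <- 200L
  for (restart in seq_len(max_restarts)) {
    xs <- ys <- zs <- numeric(0)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(per_particle_tries)) {
        x <- stats::runif(1, bounds$x[1], bounds$x[2])
        y <- stats::runif(1, bounds$y[1], bounds$y[2])
        z <- stats::runif(1, bounds$z[1], bounds$z[2])
        sep_ok <- min_separation_um <= 0 || length(xs) == 0L ||
          min((xs - x)^2 + (ys - y)^2 + (zs - z)^2) >= min_separation_um^2
        proj_ok <- TRUE
        if (sep_ok && min_projected_separation_um > 0 && length(xs) > 0L) {
          for (s in c(+1, -1)) {
            dxv <- (xs + s * zs * tan_half) - (x + s * z * tan_half)
            if (min(dxv^2 + (ys - y)^2) < min_projected_separation_um^2) {
              proj_ok <- FALSE
              break
            }
          }
        }
        if (sep_ok && proj_ok) {
          xs <- c(xs, x); ys <- c(ys, y); zs <- c(zs, z)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      sc <- data.frame(id = seq_len(n), x_um = xs, y_um = ys, z_um = zs,
                       radius_um = radius_um, brightness = brightness)
      class(sc) <- c("particle_scene", "data.frame")
      return(sc)
    }
  }
  stop(sprintf(
    "could not place %d particles with min separation %g um in the given bounds",
    n, min_separation_um))
}

empty_scene <- function() {
  sc <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                   z_um = numeric(0), radius_um = numeric(0),
                   brightness = numeric(0))
  class(sc) <- c("particle_scene", "data.frame")
  sc
}

#' Characterization bead scene
#'
#' The standard system-characterization scene: 13 fluorescent beads of
#' 4.46 um diameter (radius 2.23 um), non-overlapping in both projected
#' views, with depths spread across the depth of field. Bounds are inset so
#' every projected blob stays fully inside the frame (x by the maximum
#' parallax shift plus the blob extent, z slightly inside the DOF edge so
#' boundary truncation never clips a bead).
#'
#' @param seed Scene RNG seed. Default 42.
#' @param cfg An [optics_config()].
#' @param brightness Expected peak photon count per bead. Default 1000.
#' @return A `particle_scene` of 13 beads.
#' @export
characterization_scene <- function(seed = 42, cfg = optics_config(),
                                   brightness = 1000) {
  margin_x <- cfg$dof_um / 2 *
    tan(cfg$parallax_angle_deg / 2 * pi / 180) + 6
  make_scene(13, radius_um = 2.23, brightness = brightness,
             bounds = list(x = c(margin_x, cfg$fov_x_um - margin_x),
                           y = c(10, cfg$fov_y_um - 10),
                           z = c(-cfg$dof_um / 2 + 3, cfg$dof_um / 2 - 3)),
             min_separation_um = 12, min_projected_separation_um = 12,
             cfg = cfg, seed = seed)
}

#' Deterministic depth-sweep scene
#'
#' 21 beads on a fixed 5-column lateral grid with depths stepping through
#' the full depth of field in 5 um increments (`-dof/2 ... +dof/2`). Depths
#' are assigned column-wise in increasing order so that the parallax shifts
#' of laterally adjacent beads never make their projections cross or
#' overlap, and each column's rows are staggered in y by more than the
#' epipolar row tolerance so that identical-looking beads in different
#' columns can never be cost ties in the stereo matcher. Used for
#' depth-recovery linearity checks.
#'
#' @param cfg An [optics_config()].
#' @param radius_um Bead radius. Default 2.23.
#' @param brightness Peak photon count. Default 1000.
#' @return A `particle_scene` of 21 beads spanning the DOF.
#' @export
depth_sweep_scene <- function(cfg = optics_config(), radius_um = 2.23,
                              brightness = 1000) {
  z <- seq(-cfg$dof_um / 2, cfg$dof_um / 2, length.out = 21)
  sx <- cfg$fov_x_um / 110; sy <- cfg$fov_y_um / 110
  xcols <- c(22, 38, 54, 70, 86) * sx
  yrows <- c(14, 35, 56, 77, 98) * sy
  idx <- seq_len(21)
  col_of <- ceiling(idx / 5)          # 5 rows per column, z increasing
  row_of <- ((idx - 1) %% 5) + 1
  sc <- data.frame(id = idx,
                   x_um = xcols[col_of],
                   y_um = yrows[row_of] - 2.2 * sy * (col_of - 1),
                   z_um = z,
                   radius_um = radius_um, brightness = brightness)
  class(sc) <- c("particle_scene", "data.frame")
  sc
}

#' Particle motion model
#'
#' Isotropic Brownian diffusion plus a constant drift (gravitational settling
#' is a negative-z drift). Over a step `dt` each coordinate is displaced by
#' `drift * dt + N(0, sqrt(2 D dt))`.
#'
#' @param diffusion_um2_per_s Diffusion coefficient D, um^2/s, >= 0.
#' @param drift_um_per_s Length-3 drift vector (x, y, z), um/s.
#' @param boundary `"reflect"` (positions fold back at the box walls, particle
#'   count conserved) or `"absorb"` (particles leaving the box are removed).
#' @param bounds Box the boundary rule applies to; same format as in
#'   [make_scene()].
#' @return A `motion_model` object.
#' @export
motion_model <- function(diffusion_um2_per_s = 0,
                         drift_um_per_s = c(0, 0, 0),
                         boundary = c("reflect", "absorb"),
                         bounds = list(x = c(0, 110), y = c(0, 110),
                                       z = c(-50, 50))) {
  boundary <- match.arg(boundary)
  stopifnot(diffusion_um2_per_s >= 0, length(drift_um_per_s) == 3L,
            all(is.finite(drift_um_per_s)))
  structure(list(diffusion_um2_per_s = diffusion_um2_per_s,
                 drift_um_per_s = as.numeric(drift_um_per_s),
                 boundary = boundary, bounds = bounds),
            class = "motion_model")
}

# fold a coordinate back into [lo, hi] (reflecting boundary)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Advance a scene by one time step
#'
#' Applies the motion model to every particle. Uses the current global RNG
#' stream (seed it, or let [simulate_sequence()] do so, for reproducibility).
#' Particle ids are preserved; with an absorbing boundary, particles that
#' leave the box are dropped.
#'
#' @param scene A `particle_scene`.
#' @param model A [motion_model()].
#' @param dt_s Time step, seconds, > 0.
#' @return The displaced scene.
#' @export
step_motion <- function(scene, model, dt_s) {
  stopifnot(inherits(model, "motion_model"), dt_s > 0)
  n <- nrow(scene)
  if (n == 0L) return(scene)
  sd_step <- sqrt(2 * model$diffusion_um2_per_s * dt_s)
  disp <- matrix(stats::rnorm(3L * n, mean = 0, sd = sd_step), ncol = 3L)
  disp <- sweep(disp, 2L, model$drift_um_per_s * dt_s, `+`)
  scene$x_um <- scene$x_um + disp[, 1L]
  scene$y_um <- scene$y_um + disp[, 2L]
  scene$z_um <- scene$z_um + disp[, 3L]
  b <- model$bounds
  if (model$boundary == "reflect") {
    scene$x_um <- reflect_into(scene$x_um, b$x[1], b$x[2])
    scene$y_um <- reflect_into(scene$y_um, b$y[1], b$y[2])
    scene$z_um <- reflect_into(scene$z_um, b$z[1], b$z[2])
  } else {
    keep <- scene$x_um >= b$x[1] & scene$x_um <= b$x[2] &
            scene$y_um >= b$y[1] & scene$y_um <= b$y[2] &
            scene$z_um >= b$z[1] & scene$z_um <= b$z[2]
    scene <- scene[keep, , drop = FALSE]
  }
  scene
}

#' Detector noise model
#'
#' @param background_photons Mean background level per pixel (photons).
#' @param read_noise_sd Additive Gaussian read noise sd (counts).
#' @param crosstalk_fraction Fraction of each view's particle signal leaking
#'   into the other view (imperfect pulse demultiplexing); in `[0, 0.5)`.
#' @param seed RNG seed used when an operation seeds itself; `NA` means
#'   "use the current RNG stream" (what [simulate_sequence()] passes after
#'   seeding once).
#' @param poisson If `FALSE`, skip Poisson photon sampling (ideal noiseless
#'   detector; useful with `background_photons = 0, read_noise_sd = 0` to
#'   render the noiseless expectation image).
#' @return A `noise_model` object.
#' @export
noise_model <- function(background_photons = 10, read_noise_sd = 1,
                        crosstalk_fraction = 0, seed = 1L, poisson = TRUE) {
  stopifnot(background_photons >= 0, read_noise_sd >= 0,
            crosstalk_fraction >= 0, crosstalk_fraction < 0.5)
  structure(list(background_photons = background_photons,
                 read_noise_sd = read_noise_sd,
                 crosstalk_fraction = crosstalk_fraction,
                 seed = seed, poisson = isTRUE(poisson)),
            class = "noise_model")
}

#' Noiseless ideal detector
#' @return A [noise_model()] with zero background, zero read noise, no
#'   crosstalk and Poisson sampling disabled.
#' @export
noiseless <- function() {
  noise_model(background_photons = 0, read_noise_sd = 0,
              crosstalk_fraction = 0, seed = NA_integer_, poisson = FALSE)
}

# Radial profile of a uniform disc of radius r convolved with an isotropic
# 2D Gaussian of sd sigma (all in pixels). This is the Rician integral
#   f(d) = int_0^r s/sigma^2 exp(-(s-d)^2/(2 sigma^2)) I0(s d/sigma^2)
#          * exp(s d/sigma^2 - s d/sigma^2) ds
# evaluated with the exponentially-scaled Bessel function for stability.
# f(d) -> 1 inside a large disc; f(0) = 1 - exp(-r^2/(2 sigma^2)).
blob_radial_profile <- function(r_px, sigma_px, d_max, d_step = 0.02) {
  d <- seq(0, d_max, by = d_step)
  ns <- 257L                       # odd, for composite Simpson
  s <- seq(0, r_px, length.out = ns)
  ds <- s[2] - s[1]
  w <- rep(2, ns)
  w[seq(2, ns - 1L, by = 2)] <- 4
  w[c(1, ns)] <- 1
  w <- w * ds / 3
  sd2 <- sigma_px^2
  # matrix of integrand values: rows = s, cols = d
  f <- vapply(d, function(dd) {
    arg <- s * dd / sd2
    val <- (s / sd2) * exp(-(s - dd)^2 / (2 * sd2)) *
      besselI(arg, 0, expon.scaled = TRUE)
    sum(w * val)
  }, numeric(1))
  list(d = d, f = f)
}

# profile cache keyed by (radius, sigma), filled lazily
.blob_cache <- new.env(parent = emptyenv())

get_blob_profile <- function(r_px, sigma_px) {
  key <- sprintf("%.6f_%.6f", r_px, sigma_px)
  if (!is.null(.blob_cache[[key]])) return(.blob_cache[[key]])
  d_max <- r_px + 6 * sigma_px + 1
  prof <- blob_radial_profile(r_px, sigma_px, d_max)
  .blob_cache[[key]] <- prof
  prof
}

# Render one view (side = +1 left, -1 right) of a scene as the noiseless
# expected-photon image. Pixel centres sit at integer multiples of the pixel
# pitch; images are matrices [row = y, col = x]. Blobs are evaluated on a
# 4x oversampled grid and box-binned to keep pixelisation centroid bias
# under ~0.05 px.
render_view <- function(scene, cfg, side, psf_sigma_um) {
  h <- cfg$frame_h_px; w <- cfg$frame_w_px
  img <- matrix(0, nrow = h, ncol = w)
  if (nrow(scene) == 0L) return(img)
  ps <- cfg$pixel_size_um
  tan_half <- tan(cfg$parallax_angle_deg / 2 * pi / 180)
  sigma_px <- psf_sigma_um / ps
  os <- 4L
  sub <- (seq_len(os) - 0.5) / os - 0.5   # sub-pixel offsets within a pixel
  for (k in seq_len(nrow(scene))) {
    z <- scene$z_um[k]
    if (abs(z) > cfg$dof_um / 2) next     # outside the extended focus
    cx <- (scene$x_um[k] + side * z * tan_half) / ps
    cy <- scene$y_um[k] / ps
    r_px <- scene$radius_um[k] / ps
    prof <- get_blob_profile(r_px, sigma_px)
    peak <- prof$f[1]
    amp <- scene$brightness[k] / peak
    hw <- ceiling(r_px + 5 * sigma_px + 2)
    x0 <- max(0L, floor(cx) - hw); x1 <- min(w - 1L, floor(cx) + hw)
    y0 <- max(0L, floor(cy) - hw); y1 <- min(h - 1L, floor(cy) + hw)
    if (x0 > x1 || y0 > y1) next
    px <- x0:x1; py <- y0:y1
    xs <- rep(px, each = os) + sub        # oversampled x coordinates
    ys <- rep(py, each = os) + sub
    dmat <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
    vals <- stats::approx(prof$d, prof$f, xout = pmin(dmat, max(prof$d)),
                          rule = 2)$y
    vmat <- matrix(vals, nrow = length(ys))
    # box-bin os x os
    a <- array(vmat, dim = c(os, length(py), os, length(px)))
    patch <- amp * colMeans(colMeans(aperm(a, c(1, 3, 2, 4))))
    img[py + 1L, px + 1L] <- img[py + 1L, px + 1L] + patch
  }
  img
}

#' Render a noisy stereo pair of a scene
#'
#' Projects every in-focus particle onto the left and right views along the
#' two tilted parallel-projection axes: a particle at `(x, y, z)` appears at
#' `x + z tan(theta/2)` in the left view and `x - z tan(theta/2)` in the
#' right (y unchanged), as a uniform disc of its physical radius convolved
#' with the lateral PSF. Particles outside the depth of field contribute
#' nothing (top-hat axial response of the extended focus). Detection noise:
#' optional view crosstalk, background, Poisson photon sampling, additive
#' Gaussian read noise, negative values clipped at zero.
#'
#' @param scene A `particle_scene` (positions um, z from the mid-plane).
#' @param cfg An [optics_config()].
#' @param noise A [noise_model()]. If its `seed` is not `NA`, the RNG is
#'   seeded here so the rendering is reproducible on its own; pass
#'   `seed = NA` to consume the current RNG stream (as
#'   [simulate_sequence()] does).
#' @param psf_sigma_um Lateral PSF Gaussian sd, um. Default 0.4 (plausible
#'   for a 0.8 NA two-photon system; an assumption, not a measured value).
#' @param frame_index Frame number stored in the output, 0-based.
#' @return A `stereo_pair`: list with `left`, `right` image matrices
#'   (rows = y, cols = x), `frame_index`, `time_s`.
#' @export
render_stereo_pair <- function(scene, cfg, noise = noise_model(),
                               psf_sigma_um = 0.4, frame_index = 0L) {
  assert_optics(cfg)
  stopifnot(inherits(noise, "noise_model"))
  if (psf_sigma_um <= 0) stop("psf_sigma_um must be > 0")
  if (!is.na(noise$seed)) set.seed(noise$seed)
  left <- render_view(scene, cfg, +1, psf_sigma_um)
  right <- render_view(scene, cfg, -1, psf_sigma_um)
  eps <- noise$crosstalk_fraction
  if (eps > 0) {
    l2 <- (1 - eps) * left + eps * right
    r2 <- (1 - eps) * right + eps * left
    left <- l2; right <- r2
  }
  left <- left + noise$background_photons
  right <- right + noise$background_photons
  if (noise$poisson) {
    left <- matrix(stats::rpois(length(left), left),
                   nrow = nrow(left))
    right <- matrix(stats::rpois(length(right), right),
                    nrow = nrow(right))
  }
  if (noise$read_noise_sd > 0) {
    left <- left + matrix(stats::rnorm(length(left), 0, noise$read_noise_sd),
                          nrow = nrow(left))
    right <- right + matrix(stats::rnorm(length(right), 0,
                                         noise$read_noise_sd),
                            nrow = nrow(right))
  }
  left[left < 0] <- 0
  right[right < 0] <- 0
  structure(list(left = left, right = right,
                 frame_index = as.integer(frame_index),
                 time_s = as.integer(frame_index) / cfg$volume_rate_hz),
            class = "stereo_pair")
}

#' Simulate a time sequence of stereo pairs with ground truth
#'
#' Seeds the RNG once from `noise$seed` (unless `NA`), then alternates
#' rendering and motion stepping, recording the true particle positions at
#' every frame. The same seed gives a bit-identical sequence.
#'
#' @param scene0 Initial `particle_scene`.
#' @param motion A [motion_model()].
#' @param cfg An [optics_config()]; the frame interval is
#'   `1 / cfg$volume_rate_hz`.
#' @param noise A [noise_model()].
#' @param n_frames Number of stereo volumes to simulate.
#' @param psf_sigma_um Lateral PSF sd, um (see [render_stereo_pair()]).
#' @return List with `pairs` (list of `stereo_pair`) and `truth`
#'   (`data.frame` with columns `frame, id, x_um, y_um, z_um`).
#' @export
simulate_sequence <- function(scene0, motion, cfg, noise = noise_model(),
                              n_frames = 1L, psf_sigma_um = 0.4) {
  assert_optics(cfg)
  stopifnot(n_frames >= 0)
  if (!is.na(noise$seed)) set.seed(noise$seed)
  noise_stream <- noise
  noise_stream$seed <- NA_integer_
  dt <- 1 / cfg$volume_rate_hz
  pairs <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  scene <- scene0
  for (f in seq_len(n_frames)) {
    pairs[[f]] <- render_stereo_pair(scene, cfg, noise_stream,
                                     psf_sigma_um, frame_index = f - 1L)
    if (nrow(scene)) {
      truth[[f]] <- data.frame(frame = f - 1L, id = scene$id,
                               x_um = scene$x_um, y_um = scene$y_um,
                               z_um = scene$z_um)
    }
    if (f < n_frames) scene <- step_motion(scene, motion, dt)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (is.null(truth))
    truth <- data.frame(frame = integer(0), id = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        z_um = numeric(0))
  list(pairs = pairs, truth = truth)
}
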