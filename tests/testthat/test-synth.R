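test_that("make_scene places particles reproducibly within bounds", {
  expect_identical(nrow(make_scene(0)), 0L)

  b <- list(x = c(0, 110), y = c(0, 110), z = c(-50, 50))
  sc <- make_scene(40, bounds = b, seed = 3)
  expect_identical(nrow(sc), 40L)
  expect_true(all(sc$x_um >= 0 & sc$x_um <= 110))
  expect_true(all(sc$y_um >= 0 & sc$y_um <= 110))
  expect_true(all(sc$z_um >= -50 & sc$z_um <= 50))

  sc2 <- make_scene(40, bounds = b, seed = 3)
  expect_identical(sc, sc2)
})

test_that("min separation is honoured (exhaustive pairwise check) and infeasible packings fail", {
  sc <- make_scene(13, radius_um = 2.23, min_separation_um = 12, seed = 101)
  d <- as.matrix(dist(sc[, c("x_um", "y_um", "z_um")]))
  diag(d) <- Inf
  expect_identical(nrow(sc), 13L)
  expect_true(all(d >= 12))

  expect_error(
    make_scene(50, bounds = list(x = c(0, 20), y = c(0, 20), z = c(0, 20)),
               min_separation_um = 15, seed = 1),
    "could not place")
})

test_that("projected-separation option also separates the tilted views", {
  cfg <- optics_config()
  sc <- characterization_scene(42, cfg)
  expect_identical(nrow(sc), 13L)
  th <- tan(cfg$parallax_angle_deg / 2 * pi / 180)
  for (s in c(1, -1)) {
    xv <- sc$x_um + s * sc$z_um * th
    d <- as.matrix(dist(cbind(xv, sc$y_um)))
    diag(d) <- Inf
    expect_true(all(d >= 12))
  }
})

test_that("step_motion: drift is exact, diffusion variance matches 2 D dt", {
  sc <- make_scene(5, seed = 8)
  still <- motion_model(0, c(0, 0, 0))
  expect_equal(step_motion(sc, still, 1 / 30), sc)

  drift <- motion_model(0, c(0, 0, -3))
  moved <- step_motion(sc, drift, 1 / 30)
  expect_equal(moved$z_um, sc$z_um - 0.1, tolerance = 1e-12)
  expect_identical(moved$id, sc$id)

  # Monte-Carlo variance check against the closed form
  set.seed(5)
  D <- 1; dt <- 1 / 30
  p <- one_particle_scene(55, 55, 0)
  mm <- motion_model(D, c(0, 0, 0),
                     bounds = list(x = c(-1e6, 1e6), y = c(-1e6, 1e6),
                                   z = c(-1e6, 1e6)))
  steps <- t(replicate(10000, {
    p2 <- step_motion(p, mm, dt)
    c(p2$x_um - p$x_um, p2$y_um - p$y_um, p2$z_um - p$z_um)
  }))
  v <- apply(steps, 2, var)
  expect_equal(unname(v), rep(2 * D * dt, 3), tolerance = 0.05)
})

test_that("boundary rules conserve (reflect) or remove (absorb) particles", {
  b <- list(x = c(0, 10), y = c(0, 10), z = c(-5, 5))
  sc <- make_scene(20, bounds = b, seed = 2)
  mm_r <- motion_model(5, c(0, 0, 0), "reflect", b)
  mm_a <- motion_model(5, c(0, 0, -50), "absorb", b)
  set.seed(1)
  r <- step_motion(sc, mm_r, 1)
  expect_identical(nrow(r), 20L)
  expect_true(all(r$x_um >= 0 & r$x_um <= 10 & r$z_um >= -5 & r$z_um <= 5))
  set.seed(1)
  a <- step_motion(sc, mm_a, 1)
  expect_lt(nrow(a), 20L)
})

test_that("rendered disparity follows the linear depth map to sub-pixel accuracy", {
  cfg <- small_optics()
  # sweep depths across the DOF; centroid-of-rendered-blob oracle
  for (z in seq(-30, 30, by = 10)) {
    sp <- render_stereo_pair(one_particle_scene(13.75, 13.75, z), cfg,
                             noiseless())
    cl <- image_centroid(sp$left); cr <- image_centroid(sp$right)
    expect_equal(unname(cl["x"] - cr["x"]), depth_to_disparity(z, cfg),
                 tolerance = 0.1)
    expect_equal(unname(cl["y"] - cr["y"]), 0, tolerance = 0.05)
  }
})

test_that("zero-depth particles project identically; out-of-DOF particles vanish", {
  cfg <- small_optics()
  sp0 <- render_stereo_pair(one_particle_scene(13.75, 13.75, 0), cfg,
                            noiseless())
  expect_equal(sp0$left, sp0$right)
  expect_gt(max(sp0$left), 0)

  sp_out <- render_stereo_pair(one_particle_scene(13.75, 13.75, 51), cfg,
                               noiseless())
  expect_identical(max(sp_out$left), 0)
  expect_identical(max(sp_out$right), 0)

  # z = +10 um: measured centroid separation equals the configured disparity
  sp10 <- render_stereo_pair(one_particle_scene(13.75, 13.75, 10), cfg,
                             noiseless())
  d <- image_centroid(sp10$left)["x"] - image_centroid(sp10$right)["x"]
  expect_equal(unname(d), depth_to_disparity(10, cfg), tolerance = 0.2)
})

test_that("photon flux per particle is conserved across depth within the DOF", {
  cfg <- small_optics()
  sums <- vapply(c(-30, -15, 0, 15, 30), function(z)
    sum(render_stereo_pair(one_particle_scene(13.75, 13.75, z), cfg,
                           noiseless())$left), numeric(1))
  expect_lt(diff(range(sums)) / mean(sums), 1e-6)
})

test_that("crosstalk mixes the views as (1-eps) own + eps other", {
  cfg <- small_optics()
  sc <- one_particle_scene(13.75, 13.75, 20)
  clean <- render_stereo_pair(sc, cfg, noiseless())
  nz <- noiseless(); nz$crosstalk_fraction <- 0.2
  mixed <- render_stereo_pair(sc, cfg, nz)
  expect_equal(mixed$left, 0.8 * clean$left + 0.2 * clean$right,
               tolerance = 1e-12)
  expect_equal(mixed$right, 0.8 * clean$right + 0.2 * clean$left,
               tolerance = 1e-12)
})

test_that("simulate_sequence is deterministic and spans the right time", {
  cfg <- small_optics()
  sc <- make_scene(3, bounds = list(x = c(5, 22), y = c(5, 22),
                                    z = c(-30, 30)), seed = 4)
  one <- simulate_sequence(sc, motion_model(0), cfg, noiseless(), 1)
  expect_length(one$pairs, 1L)
  expect_equal(one$truth$x_um, sc$x_um)

  # 120 frames at 30 Hz = 4 s
  expect_identical(frames_in_duration(4, cfg), 120L)
  seq5 <- simulate_sequence(sc, motion_model(0), cfg, noiseless(), 5)
  expect_equal(seq5$pairs[[5]]$time_s, 4 / 30)

  # static noiseless scene: frames bit-identical
  expect_identical(seq5$pairs[[1]]$left, seq5$pairs[[5]]$left)

  # same seed -> bit-identical noisy sequences
  nm <- noise_model(seed = 77)
  s1 <- simulate_sequence(sc, motion_model(2), cfg, nm, 3)
  s2 <- simulate_sequence(sc, motion_model(2), cfg, nm, 3)
  expect_identical(s1$pairs[[3]]$right, s2$pairs[[3]]$right)
  expect_identical(s1$truth, s2$truth)
})
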