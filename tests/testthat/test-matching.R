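make_det <- function(view, cx, cy, r = 10, ee = 0.87, frame = 0L) {
  data.frame(view = view, frame_index = frame, cx_px = cx, cy_px = cy,
             radius_px = r, total_intensity = 1000, encircled_energy = ee)
}

test_that("correspondence cost: zero for identical features, epipolar gate, monotone in row offset", {
  cfg <- optics_config()
  a <- make_det("left", 250, 100)
  b <- make_det("right", 250, 100)
  expect_equal(correspondence_cost(a, b, cfg), 0)

  # row offset beyond tolerance is infeasible whatever the other features
  b_far <- make_det("right", 250, 103.1)
  expect_identical(correspondence_cost(a, b_far, cfg, row_tol_px = 3), Inf)
  b_gate <- make_det("right", 250, 104)
  expect_identical(correspondence_cost(a, b_gate, cfg, row_tol_px = 2), Inf)

  # implied depth outside the DOF is infeasible
  b_deep <- make_det("right", 250 - 260, 100)   # disparity 260 px -> z > 55 um
  expect_identical(correspondence_cost(a, b_deep, cfg), Inf)

  # strictly increasing with |dcy| at fixed radius/energy difference
  costs <- vapply(c(0, 0.5, 1, 1.5), function(dy)
    correspondence_cost(a, make_det("right", 250, 100 + dy), cfg),
    numeric(1))
  expect_true(all(diff(costs) > 0))

  expect_error(correspondence_cost(a, b, cfg, weights = c(0.5, 0.25, 0.3)),
               "sum to 1")
  expect_error(correspondence_cost(a, b, cfg, weights = c(-0.5, 1, 0.5)),
               "non-negative")
  expect_error(correspondence_cost(b, a, cfg), "left-view")
})

test_that("stereo matching equals brute force on small random instances", {
  cfg <- optics_config()
  set.seed(31)
  for (trial in 1:40) {
    n <- sample(2:6, 1)
    # all pairs feasible: same rows, disparities inside the DOF
    left <- make_det("left", runif(n, 200, 260), rep(100, n),
                     r = runif(n, 9, 11), ee = runif(n, 0.8, 0.9))
    right <- make_det("right", runif(n, 200, 260), rep(100, n),
                      r = runif(n, 9, 11), ee = runif(n, 0.8, 0.9))
    scales <- c(1, 1, 0.05)
    res <- match_stereo(left, right, cfg, scales = scales)
    expect_identical(nrow(res$matches), n)
    cost <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      cost[i, j] <- correspondence_cost(left[i, ], right[j, ], cfg,
                                        scales = scales)
    expect_equal(sum(res$matches$cost), brute_force_assignment_cost(cost),
                 tolerance = 1e-10)
  }
})

test_that("empty and singleton inputs", {
  cfg <- optics_config()
  l1 <- make_det("left", 250, 100)
  r1 <- make_det("right", 248, 100)
  res <- match_stereo(l1, r1, cfg)
  expect_identical(nrow(res$matches), 1L)

  res0 <- match_stereo(l1[0, ], r1, cfg)
  expect_identical(nrow(res0$matches), 0L)
  expect_identical(res0$unmatched_right, 1L)
})

test_that("reconstruction formulas and DOF filtering", {
  cfg <- optics_config()
  l <- make_det("left", 250, 100)
  r <- make_det("right", 250, 100)
  res <- match_stereo(l, r, cfg)
  p <- reconstruct_3d(res, l, r, cfg)
  expect_equal(p$z_um, 0)
  expect_equal(p$x_um, cfg$pixel_size_um * 250)
  expect_equal(p$y_um, cfg$pixel_size_um * 100)

  # a match whose implied depth exceeds DOF + 1 um is dropped with warning
  fake <- list(matches = data.frame(left_id = 1L, right_id = 1L, cost = 0))
  l2 <- make_det("left", 350, 100)
  r2 <- make_det("right", 100, 100)   # disparity 250 px -> z ~ 107 um
  expect_warning(p2 <- reconstruct_3d(fake, l2, r2, cfg), "outside the DOF")
  expect_identical(nrow(p2), 0L)
})

test_that("matching is symmetric under left/right swap with negated disparity", {
  cfg <- optics_config()
  set.seed(8)
  n <- 5
  left <- make_det("left", runif(n, 220, 280), runif(n, 90, 110),
                   r = runif(n, 9, 11), ee = runif(n, 0.8, 0.9))
  right <- left
  right$view <- "right"
  right$cx_px <- left$cx_px - depth_to_disparity(runif(n, -30, 30), cfg)
  fwd <- reconstruct_3d(match_stereo(left, right, cfg), left, right, cfg)
  sw_l <- right; sw_l$view <- "left"
  sw_r <- left; sw_r$view <- "right"
  rev <- reconstruct_3d(match_stereo(sw_l, sw_r, cfg), sw_l, sw_r, cfg)
  expect_equal(sort(fwd$x_um), sort(rev$x_um), tolerance = 1e-9)
  expect_equal(sort(fwd$z_um), sort(-rev$z_um), tolerance = 1e-9)
})

test_that("13-bead synthetic scene matches perfectly against ground truth", {
  cfg <- optics_config()
  sc <- characterization_scene(seed = 5, cfg = cfg)
  sp <- render_stereo_pair(sc, cfg, noiseless())
  config <- pipeline_config()
  ld <- stereotrack:::process_view(sp$left, config, 0L, "left")
  rd <- stereotrack:::process_view(sp$right, config, 0L, "right")
  res <- match_stereo(ld, rd, cfg)
  expect_identical(nrow(res$matches), 13L)
  p3 <- reconstruct_3d(res, ld, rd, cfg)
  # every reconstructed particle sits on a distinct ground-truth bead
  hit <- vapply(seq_len(nrow(p3)), function(i) {
    d <- sqrt((sc$x_um - p3$x_um[i])^2 + (sc$y_um - p3$y_um[i])^2 +
                (sc$z_um - p3$z_um[i])^2)
    which.min(d)
  }, integer(1))
  expect_identical(sort(hit), 1:13)
  dz <- abs(p3$z_um - sc$z_um[hit])
  expect_lt(max(dz), 1)
})
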