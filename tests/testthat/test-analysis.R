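make_track <- function(frames, x, y, z, rate = 30) {
  data.frame(track_id = 1L, frame = frames, time_s = frames / rate,
             x_um = x, y_um = y, z_um = z)
}

test_that("MSD: stationary, pure drift, and Brownian closed forms", {
  fr <- 0:99
  still <- make_track(fr, 5, 5, 5)
  m0 <- compute_msd(still)
  expect_true(all(m0$msd_um2 == 0))
  expect_equal(m0$msd_um2[m0$lag_s == 0], 0)

  # pure drift: msd(tau) = |v|^2 tau^2 exactly
  v <- c(1, -2, 0.5)
  dr <- make_track(fr, v[1] * fr / 30, v[2] * fr / 30, v[3] * fr / 30)
  md <- compute_msd(dr)
  expect_equal(md$msd_um2, sum(v^2) * md$lag_s^2, tolerance = 1e-10)

  # n_pairs non-increasing with lag
  expect_true(all(diff(md$n_pairs[-1]) <= 0))

  # simulated 3D Brownian motion: fitted slope ~ 6 D within 15%
  set.seed(55)
  D <- 1; dt <- 1 / 30
  n <- 1000L
  steps <- matrix(rnorm(3 * n, 0, sqrt(2 * D * dt)), ncol = 3)
  pos <- apply(steps, 2, cumsum)
  br <- make_track(seq_len(n) - 1L, pos[, 1], pos[, 2], pos[, 3])
  mb <- compute_msd(br)
  fit <- fit_msd_diffusion(mb, n_lags = 10)
  expect_equal(fit$slope_um2_per_s, 6 * D, tolerance = 0.15)
  expect_equal(fit$D_um2_per_s, D, tolerance = 0.15)
})

test_that("MSD is additive over dimensions and gap-aware", {
  set.seed(6)
  fr <- 0:49
  tr <- make_track(fr, cumsum(rnorm(50)), cumsum(rnorm(50)),
                   cumsum(rnorm(50)))
  mx <- compute_msd(tr, dims = "x")
  my <- compute_msd(tr, dims = "y")
  mz <- compute_msd(tr, dims = "z")
  mxyz <- compute_msd(tr, dims = c("x", "y", "z"))
  expect_equal(mxyz$msd_um2, mx$msd_um2 + my$msd_um2 + mz$msd_um2,
               tolerance = 1e-10)

  # pairs spanning a missing frame are excluded
  gap <- tr[tr$frame != 10L, ]
  mg <- compute_msd(gap, max_lag_fraction = 0.1)
  lag1 <- mg[mg$lag_s > 0, ][1, ]
  expect_equal(lag1$n_pairs, 47)   # 49 transitions minus the two crossing f=10

  # non-overlapping estimator uses disjoint windows
  mno <- compute_msd(tr, max_lag_fraction = 0.2, overlapping = FALSE)
  m5 <- mno[abs(mno$lag_s - 5 / 30) < 1e-9, ]
  expect_equal(m5$n_pairs, floor(49 / 5))
})

test_that("localization precision: sds, sample-size guard, noise monotonicity", {
  set.seed(2)
  tr <- make_track(0:59, rnorm(60, 50, 0.1), rnorm(60, 50, 0.08),
                   rnorm(60, 10, 1))
  pr <- localization_precision(tr)
  expect_equal(pr$sd_x_um, sd(tr$x_um))
  expect_equal(pr$sd_z_um, sd(tr$z_um))
  expect_identical(pr$n_frames, 60L)
  expect_error(localization_precision(tr[1:5, ]), "at least 10")
})

test_that("depth error report: hand arithmetic, CDF validity, id pairing", {
  est <- data.frame(id = 1:2, z_um = c(1, 3))
  gt <- data.frame(id = 1:2, z_um = c(0, 0))
  rep <- depth_error_report(est, gt)
  expect_equal(rep$mean_um, 2)
  expect_equal(rep$fraction_below(2), 0.5)
  expect_equal(rep$fraction_below(100), 1)

  # estimates = truth
  perfect <- depth_error_report(gt, gt)
  expect_equal(perfect$mean_um, 0)
  expect_equal(perfect$fraction_below(1e-9), 1)

  # fraction_below is a valid CDF: monotone in [0, 1], reaching 1
  set.seed(14)
  r2 <- depth_error_report(data.frame(id = 1:50, z_um = rnorm(50)),
                           data.frame(id = 1:50, z_um = rnorm(50)))
  th <- seq(0, 10, by = 0.25)
  fb <- vapply(th, r2$fraction_below, numeric(1))
  expect_true(all(diff(fb) >= 0))
  expect_true(all(fb >= 0 & fb <= 1))
  expect_equal(fb[length(fb)], 1)

  expect_error(depth_error_report(data.frame(id = 3, z_um = 1), gt),
               "missing from the ground truth")
})

test_that("drift velocity: exact on pure drift, unbiased under diffusion", {
  fr <- 0:59
  tr <- make_track(fr, 5, 5, 20 - 3 * fr / 30)
  expect_equal(drift_velocity(tr, "z"), -3, tolerance = 1e-10)

  # zero-drift ensemble: |mean| within 2 standard errors of 0
  set.seed(91)
  D <- 1; dt <- 1 / 30; nf <- 100L
  tracks <- do.call(rbind, lapply(1:50, function(k) {
    pos <- apply(matrix(rnorm(3 * nf, 0, sqrt(2 * D * dt)), ncol = 3),
                 2, cumsum)
    data.frame(track_id = k, frame = seq_len(nf) - 1L,
               time_s = (seq_len(nf) - 1L) / 30,
               x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  }))
  v_hat <- drift_velocity(tracks, "z")
  # per-track slope sd for pure diffusion over T = nf*dt is about
  # sqrt(12 D / T) / sqrt(nf) ... use the empirical spread instead
  slopes <- vapply(split(tracks, tracks$track_id), function(tr) {
    t <- tr$time_s - mean(tr$time_s)
    sum(t * (tr$z_um - mean(tr$z_um))) / sum(t^2)
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(v_hat), 2.5 * se + 1e-12)

  # drift + diffusion: unbiased at v = -2
  set.seed(17)
  tracks2 <- do.call(rbind, lapply(1:200, function(k) {
    steps <- matrix(rnorm(3 * 60, 0, sqrt(2 * 1 * dt)), ncol = 3)
    steps[, 3] <- steps[, 3] - 2 * dt
    pos <- apply(steps, 2, cumsum)
    data.frame(track_id = k, frame = 0:59, time_s = (0:59) / 30,
               x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  }))
  expect_equal(drift_velocity(tracks2, "z"), -2, tolerance = 0.15)
})
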