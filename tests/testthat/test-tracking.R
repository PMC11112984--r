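particles_at <- function(frame, xyz) {
  data.frame(frame = frame, x_um = xyz[, 1], y_um = xyz[, 2],
             z_um = xyz[, 3])
}

test_that("frame-pair linking: gating, brute-force optimality, deterministic ties", {
  p0 <- particles_at(0L, cbind(10, 10, 0))
  p1 <- particles_at(1L, cbind(12, 10, 0))
  expect_identical(link_frame_pair(p0, p1, 5)$from, 1L)
  expect_identical(nrow(link_frame_pair(p0, p1, 1)), 0L)

  set.seed(19)
  for (trial in 1:40) {
    n <- sample(2:6, 1)
    a <- particles_at(0L, matrix(runif(3 * n, 0, 20), ncol = 3))
    b <- particles_at(1L, as.matrix(a[, c("x_um", "y_um", "z_um")]) +
                        matrix(rnorm(3 * n, 0, 1), ncol = 3))
    links <- link_frame_pair(a, b, max_link_dist_um = 100)
    expect_identical(nrow(links), n)
    d <- stereotrack:::particle_dist_matrix(a, b)
    expect_equal(sum(links$dist_um), brute_force_assignment_cost(d),
                 tolerance = 1e-10)
  }

  # exact symmetric crossing: either labelling has equal cost; the solver
  # must still return a complete, deterministic assignment
  a <- particles_at(0L, rbind(c(0, 0, 0), c(2, 0, 0)))
  b <- particles_at(1L, rbind(c(2, 0, 0), c(0, 0, 0)))
  l1 <- link_frame_pair(a, b, 10)
  l2 <- link_frame_pair(a, b, 10)
  expect_identical(l1, l2)
  expect_identical(nrow(l1), 2L)
})

test_that("gap closing bridges a single-frame dropout into one trajectory", {
  # 10-frame track with frame 5 missing
  frames <- setdiff(0:9, 5L)
  obs <- data.frame(frame = frames, x_um = 10 + 0.1 * frames, y_um = 20,
                    z_um = 5)
  traj <- build_trajectories(obs, tracking_params(max_link_dist_um = 2,
                                                  max_gap_frames = 2,
                                                  max_gap_dist_um = 3))
  expect_identical(length(unique(traj$tracks$track_id)), 1L)
  expect_identical(nrow(traj$gap_links), 1L)
  expect_equal(traj$gap_links$frame_end, 4)
  expect_equal(traj$gap_links$frame_start, 6)
  expect_identical(sum(traj$tracks$gap_flag), 1L)

  # a gap longer than max_gap_frames stays split
  frames2 <- setdiff(0:9, 4:6)
  obs2 <- data.frame(frame = frames2, x_um = 10, y_um = 20, z_um = 5)
  traj2 <- build_trajectories(obs2, tracking_params(max_gap_frames = 2))
  expect_identical(length(unique(traj2$tracks$track_id)), 2L)

  # no dropouts: gap closing is a no-op
  obs3 <- data.frame(frame = 0:9, x_um = 10, y_um = 20, z_um = 5)
  traj3 <- build_trajectories(obs3)
  expect_identical(nrow(traj3$gap_links), 0L)
  expect_identical(length(unique(traj3$tracks$track_id)), 1L)
})

test_that("trajectory building conserves observations and recovers identities", {
  expect_identical(nrow(build_trajectories(
    data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
               z_um = numeric(0)))$tracks), 0L)

  # 40 Brownian particles, ground truth fed straight to the linker
  cfg <- optics_config()
  set.seed(23)
  sc <- make_scene(40, min_separation_um = 12, seed = 23)
  mm <- motion_model(0.5, c(0, 0, 0))
  n_frames <- 30L
  frames <- list()
  scene <- sc
  for (f in seq_len(n_frames)) {
    frames[[f]] <- data.frame(frame = f - 1L, id = scene$id,
                              x_um = scene$x_um, y_um = scene$y_um,
                              z_um = scene$z_um)
    scene <- step_motion(scene, mm, 1 / 30)
  }
  truth <- do.call(rbind, frames)
  traj <- build_trajectories(truth[, c("frame", "x_um", "y_um", "z_um")],
                             tracking_params(max_link_dist_um = 5))
  expect_identical(nrow(traj$tracks), nrow(truth))        # conservation
  expect_identical(length(unique(traj$tracks$track_id)), 40L)

  # identity purity: every track follows exactly one ground-truth id
  merged <- merge(traj$tracks, truth, by = c("frame", "x_um", "y_um", "z_um"))
  purity <- tapply(merged$id, merged$track_id,
                   function(ids) length(unique(ids)))
  expect_true(all(purity == 1L))
})

test_that("link success rate meets the diffusion-gating bound", {
  # pure diffusion with max_link_dist >= 4 sqrt(6 D dt) and spacing >= 5x
  D <- 0.5; dt <- 1 / 30
  gate <- 4 * sqrt(6 * D * dt)
  set.seed(77)
  n_correct <- 0L; n_total <- 0L
  sc <- make_scene(20, bounds = list(x = c(0, 200), y = c(0, 200),
                                     z = c(-50, 50)),
                   min_separation_um = 5 * gate, seed = 31)
  mm <- motion_model(D, c(0, 0, 0),
                     bounds = list(x = c(0, 200), y = c(0, 200),
                                   z = c(-50, 50)))
  scene <- sc
  for (f in 1:50) {
    nxt <- step_motion(scene, mm, dt)
    links <- link_frame_pair(scene, nxt, gate)
    n_total <- n_total + nrow(scene)
    n_correct <- n_correct +
      sum(scene$id[links$from] == nxt$id[links$to])
    scene <- nxt
  }
  expect_gte(n_correct / n_total, 0.99)
})

test_that("single particle over 120 frames yields one full-length trajectory", {
  set.seed(41)
  pos <- matrix(0, 120, 3)
  pos[1, ] <- c(50, 50, 0)
  for (f in 2:120) pos[f, ] <- pos[f - 1, ] + rnorm(3, 0, 0.2)
  obs <- data.frame(frame = 0:119, x_um = pos[, 1], y_um = pos[, 2],
                    z_um = pos[, 3])
  traj <- build_trajectories(obs)
  expect_identical(length(unique(traj$tracks$track_id)), 1L)
  expect_identical(nrow(traj$tracks), 120L)
  expect_false(any(traj$tracks$short))
})
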