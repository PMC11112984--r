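# Shared fixtures: a small-frame optics config (same pixel pitch and
# parallax as the default 512 px instrument, 16x fewer pixels -> fast
# rendering), a brute-force assignment oracle, and blob helpers.

small_optics <- function() {
  optics_config(parallax_angle_deg = 28.1,
                fov_x_um = 110 * 128 / 512, fov_y_um = 110 * 128 / 512,
                dof_um = 100, frame_w_px = 128L, frame_h_px = 128L,
                volume_rate_hz = 30)
}

# all permutations of 1..n (n small), memoised
.perm_cache <- new.env(parent = emptyenv())
perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- if (n == 1L) matrix(1L) else {
    q <- perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
      cbind(i, ifelse(q >= i, q + 1L, q))))
  }
  .perm_cache[[key]] <- p
  p
}

# brute-force minimum assignment cost over all permutations (square matrix)
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost)
  P <- perms(n)
  min(apply(P, 1L, function(pp) sum(cost[cbind(seq_len(n), pp)])))
}

# total cost of a solve_assignment() result
assignment_cost <- function(cost, assign) {
  i <- which(!is.na(assign))
  sum(cost[cbind(i, assign[i])])
}

# render a centred Gaussian blob on an n x n image (0-based centre cx, cy)
gaussian_blob <- function(n, cx, cy, sigma, amplitude = 1) {
  xs <- 0:(n - 1)
  amplitude * exp(-outer((xs - cy)^2, (xs - cx)^2, `+`) / (2 * sigma^2))
}

# intensity centroid of an image (0-based pixel coordinates)
image_centroid <- function(img) {
  tot <- sum(img)
  c(x = sum(col(img) * img) / tot - 1, y = sum(row(img) * img) / tot - 1)
}

# single-particle scene helper
one_particle_scene <- function(x, y, z, radius_um = 2.23, brightness = 1000) {
  sc <- data.frame(id = 1L, x_um = x, y_um = y, z_um = z,
                   radius_um = radius_um, brightness = brightness)
  class(sc) <- c("particle_scene", "data.frame")
  sc
}
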