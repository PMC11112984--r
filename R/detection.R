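# Particle detection: adaptive-threshold segmentation, circular Hough
# transform (for resolved beads) or local-maximum blob detection (for
# PSF-limited nanoparticles), and per-detection feature extraction.

# local mean over a block x block window via integral image; windows are
# clipped at the borders so the mean is always over in-frame pixels
local_mean <- function(img, block) {
  h <- nrow(img); w <- ncol(img)
  r <- (block - 1L) %/% 2L
  # integral image with a leading zero row/col
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()
  y0 <- pmax(0L, seq_len(h) - 1L - r); y1 <- pmin(h, seq_len(h) + r)
  x0 <- pmax(0L, seq_len(w) - 1L - r); x1 <- pmin(w, seq_len(w) + r)
  sums <- S[y1 + 1L, x1 + 1L] - S[y0 + 1L, x1 + 1L] -
          S[y1 + 1L, x0 + 1L] + S[y0 + 1L, x0 + 1L]
  area <- outer(y1 - y0, x1 - x0)
  sums / area
}

#' Adaptive-threshold segmentation
#'
#' A pixel is foreground iff its value exceeds the local mean over a
#' `block_size_px` square window by more than `offset`. Window means are
#' computed over in-frame pixels only (clipped at the borders).
#'
#' @param img Numeric matrix.
#' @param block_size_px Odd window size, >= 3. Default 31.
#' @param offset Threshold offset above the local mean; `NULL` (default)
#'   uses twice the robust noise sd, `2 * mad(img)`.
#' @return Logical mask, same shape as `img`.
#' @export
segment_adaptive <- function(img, block_size_px = 31L, offset = NULL) {
  if (!is.matrix(img)) stop("'img' must be a matrix")
  block_size_px <- as.integer(block_size_px)
  if (block_size_px < 3L || block_size_px %% 2L == 0L)
    stop("'block_size_px' must be odd and >= 3")
  if (is.null(offset)) offset <- 2 * stats::mad(img)
  img > local_mean(img, block_size_px) + offset
}

# Sobel gradients; returns list(gx, gy, mag). Border rows/cols are zeroed.
sobel_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  z <- matrix(0, h, w)
  if (h < 3L || w < 3L) return(list(gx = z, gy = z, mag = z))
  i <- 2:(h - 1L); j <- 2:(w - 1L)
  gx <- z; gy <- z
  gx[i, j] <- (img[i - 1, j + 1] + 2 * img[i, j + 1] + img[i + 1, j + 1]) -
              (img[i - 1, j - 1] + 2 * img[i, j - 1] + img[i + 1, j - 1])
  gy[i, j] <- (img[i + 1, j - 1] + 2 * img[i + 1, j] + img[i + 1, j + 1]) -
              (img[i - 1, j - 1] + 2 * img[i - 1, j] + img[i - 1, j + 1])
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Circular Hough transform particle detection
#'
#' Gradient-voting circular Hough transform: edge pixels (gradient magnitude
#' above `edge_frac` of the maximum, optionally restricted to a foreground
#' mask) vote along their gradient direction (which points toward the centre
#' of a bright disc) at every candidate radius. Accumulators are smoothed,
#' normalised by the circle circumference `2 pi r`, and peaks above
#' `1 - sensitivity` are returned after non-maximum suppression: no two
#' returned centres lie closer than `r_min_px`. Ties are broken by higher
#' score, then smaller `cy`, then smaller `cx` (deterministic ordering).
#'
#' @param img Restored image (numeric matrix).
#' @param mask Optional logical foreground mask (e.g. from
#'   [segment_adaptive()]); votes come only from edge pixels within 2 px of
#'   the mask.
#' @param r_min_px,r_max_px Radius search range in pixels, `0 < r_min <=
#'   r_max`.
#' @param sensitivity In (0, 1); higher accepts weaker circles. A perfect
#'   circle scores about 0.5 after accumulator smoothing; the acceptance
#'   threshold is `1 - sensitivity`. Default 0.85.
#' @param edge_frac Gradient-magnitude threshold as a fraction of the image
#'   maximum gradient. Default 0.15.
#' @return `data.frame` with columns `cx_px, cy_px, r_px, score` (0-based
#'   pixel centre coordinates), strongest first; zero rows if nothing found.
#' @export
hough_circles <- function(img, mask = NULL, r_min_px, r_max_px,
                          sensitivity = 0.85, edge_frac = 0.15) {
  if (r_min_px <= 0 || r_min_px > r_max_px)
    stop("radius range invalid: need 0 < r_min_px <= r_max_px")
  if (sensitivity <= 0 || sensitivity >= 1)
    stop("'sensitivity' must lie in (0, 1)")
  h <- nrow(img); w <- ncol(img)
  g <- sobel_gradients(img)
  thr <- edge_frac * max(g$mag)
  sel <- g$mag > thr & g$mag > 0
  if (!is.null(mask)) {
    near <- mask | segment_dilate(mask, 2L)
    sel <- sel & near
  }
  idx <- which(sel)
  empty <- data.frame(cx_px = numeric(0), cy_px = numeric(0),
                      r_px = numeric(0), score = numeric(0))
  if (!length(idx)) return(empty)
  ey <- ((idx - 1L) %% h)          # 0-based row (y)
  ex <- ((idx - 1L) %/% h)         # 0-based col (x)
  ux <- g$gx[idx] / g$mag[idx]
  uy <- g$gy[idx] / g$mag[idx]
  radii <- seq(ceiling(r_min_px), floor(r_max_px))
  if (!length(radii)) radii <- round((r_min_px + r_max_px) / 2)
  sm <- gaussian_kernel(1, 2L)
  acc_best <- matrix(-Inf, h, w)
  r_best <- matrix(radii[1], h, w)
  for (r in radii) {
    # gradient of a bright disc points inward, toward the centre
    cx <- round(ex + r * ux); cy <- round(ey + r * uy)
    ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
    acc <- matrix(tabulate(cy[ok] + cx[ok] * h + 1L, nbins = h * w), h, w)
    acc <- conv2_reflect(acc, sm) / (2 * pi * r)
    better <- acc > acc_best
    acc_best[better] <- acc[better]
    r_best[better] <- r
  }
  accept <- 1 - sensitivity
  cand <- which(acc_best >= accept)
  if (!length(cand)) return(empty)
  cy <- (cand - 1L) %% h
  cx <- (cand - 1L) %/% h
  sc <- acc_best[cand]
  rr <- r_best[cand]
  ord <- order(-sc, cy, cx)
  cy <- cy[ord]; cx <- cx[ord]; sc <- sc[ord]; rr <- rr[ord]
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    if (!any(keep) ||
        min((cx[keep] - cx[k])^2 + (cy[keep] - cy[k])^2) >= r_min_px^2)
      keep[k] <- TRUE
  }
  data.frame(cx_px = as.numeric(cx[keep]), cy_px = as.numeric(cy[keep]),
             r_px = as.numeric(rr[keep]), score = sc[keep])
}

# binary dilation of a mask by a square of half-width r (cheap, loop-based)
segment_dilate <- function(mask, r) {
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0L && dx == 0L) next
    ys <- pmin(pmax(seq_len(h) + dy, 1L), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1L), w)
    out <- out | mask[ys, xs]
  }
  out
}

#' Local-maximum blob detection for PSF-limited particles
#'
#' For sub-resolution particles the circular Hough transform is ill-posed
#' (the image is the PSF itself regardless of particle size), so this
#' detector finds local maxima of the (already restored) image above
#' `median + k * mad`, applies the same non-maximum suppression and returns
#' the same record shape as [hough_circles()] with a nominal radius.
#'
#' @param img Restored image.
#' @param radius_px Nominal radius to attach to each blob (used by feature
#'   extraction windows), > 0.
#' @param k_mad Threshold in robust noise sds above the median. Default 8.
#' @param min_sep_px Non-maximum suppression distance; default `2 *
#'   radius_px`.
#' @return `data.frame` with `cx_px, cy_px, r_px, score`.
#' @export
detect_blobs <- function(img, radius_px, k_mad = 8, min_sep_px = 2 * radius_px) {
  stopifnot(radius_px > 0)
  h <- nrow(img); w <- ncol(img)
  thr <- stats::median(img) + k_mad * stats::mad(img)
  if (h < 3L || w < 3L)
    return(data.frame(cx_px = numeric(0), cy_px = numeric(0),
                      r_px = numeric(0), score = numeric(0)))
  i <- 2:(h - 1L); j <- 2:(w - 1L)
  ctr <- img[i, j]
  ismax <- ctr > thr &
    ctr >= img[i - 1, j] & ctr >= img[i + 1, j] &
    ctr >= img[i, j - 1] & ctr >= img[i, j + 1] &
    ctr >= img[i - 1, j - 1] & ctr >= img[i - 1, j + 1] &
    ctr >= img[i + 1, j - 1] & ctr >= img[i + 1, j + 1]
  hit <- which(ismax, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(cx_px = numeric(0), cy_px = numeric(0),
                      r_px = numeric(0), score = numeric(0)))
  cy <- hit[, 1L]; cx <- hit[, 2L]          # 0-based after offset below
  sc <- ctr[ismax]
  ord <- order(-sc, cy, cx)
  cy <- cy[ord]; cx <- cx[ord]; sc <- sc[ord]
  keep <- logical(length(sc))
  for (k in seq_along(sc)) {
    if (!any(keep) ||
        min((cx[keep] - cx[k])^2 + (cy[keep] - cy[k])^2) >= min_sep_px^2)
      keep[k] <- TRUE
  }
  data.frame(cx_px = as.numeric(cx[keep]), cy_px = as.numeric(cy[keep]),
             r_px = radius_px, score = sc[keep])
}

#' Extract stereo-matching features for detected circles
#'
#' For each candidate circle the centroid is refined by three iterations of
#' intensity-weighted centre of mass over a window of half-width `1.5 r`
#' (background-subtracted, negatives clipped); `total_intensity` is the
#' background-subtracted sum over a `2 r` window around the refined centroid
#' and `encircled_energy` the fraction of it within `r` of the centroid.
#' The frame background is estimated as the image median (robust against
#' sparse bright particles). Degenerate detections (zero net intensity, or
#' refinement window fully outside the frame) are dropped with a warning.
#'
#' @param img Restored image.
#' @param circles `data.frame` from [hough_circles()] or [detect_blobs()].
#' @param frame_index Frame number recorded in the output.
#' @param view `"left"` or `"right"`.
#' @return `data.frame` (one row per surviving detection) with columns
#'   `view, frame_index, cx_px, cy_px, radius_px, total_intensity,
#'   encircled_energy` (0-based sub-pixel centres).
#' @export
extract_features <- function(img, circles, frame_index = 0L,
                             view = c("left", "right")) {
  view <- match.arg(view)
  h <- nrow(img); w <- ncol(img)
  bg <- stats::median(img)
  out <- vector("list", nrow(circles))
  dropped <- 0L
  for (k in seq_len(nrow(circles))) {
    cx <- circles$cx_px[k]; cy <- circles$cy_px[k]; r <- circles$r_px[k]
    # centroid refinement
    ok <- TRUE
    for (iter in 1:3) {
      hw <- ceiling(1.5 * r)
      x0 <- round(cx) - hw; x1 <- round(cx) + hw
      y0 <- round(cy) - hw; y1 <- round(cy) + hw
      if (x1 < 0L || y1 < 0L || x0 > w - 1L || y0 > h - 1L) { ok <- FALSE; break }
      xs <- max(0L, x0):min(w - 1L, x1)
      ys <- max(0L, y0):min(h - 1L, y1)
      sub <- img[ys + 1L, xs + 1L, drop = FALSE] - bg
      sub[sub < 0] <- 0
      tot <- sum(sub)
      if (tot <= 0) { ok <- FALSE; break }
      cy <- sum(outer(ys, rep(1, length(xs))) * sub) / tot
      cx <- sum(outer(rep(1, length(ys)), xs) * sub) / tot
    }
    if (!ok) { dropped <- dropped + 1L; next }
    # photometry over a 2r window around the refined centroid
    hw2 <- ceiling(2 * r)
    xs <- max(0L, round(cx) - hw2):min(w - 1L, round(cx) + hw2)
    ys <- max(0L, round(cy) - hw2):min(h - 1L, round(cy) + hw2)
    sub <- img[ys + 1L, xs + 1L, drop = FALSE] - bg
    sub[sub < 0] <- 0
    tot <- sum(sub)
    if (tot <= 0) { dropped <- dropped + 1L; next }
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    ee <- sum(sub[d2 <= r^2]) / tot
    out[[k]] <- data.frame(view = view, frame_index = as.integer(frame_index),
                           cx_px = cx, cy_px = cy, radius_px = r,
                           total_intensity = tot, encircled_energy = ee)
  }
  if (dropped > 0L)
    warning(sprintf("%d detection(s) dropped (degenerate window or intensity)",
                    dropped))
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(view = character(0), frame_index = integer(0),
                      cx_px = numeric(0), cy_px = numeric(0),
                      radius_px = numeric(0), total_intensity = numeric(0),
                      encircled_energy = numeric(0))
  res
}
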