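# Left/right correspondence: feature-based cost, optimal one-to-one
# matching per frame, and disparity-to-depth 3D reconstruction.

#' Stereo correspondence cost between two detections
#'
#' Dimensionless weighted combination of the row offset, radius difference
#' and encircled-energy difference between a left-view and a right-view
#' detection:
#' `cost = w_y |dcy|/s_y + w_r |dr|/s_r + w_E |dE|/s_E`.
#' A pair is infeasible (`Inf`) when the rows differ by more than
#' `row_tol_px` (views share epipolar rows up to line jitter) or when the
#' implied depth `disparity_to_depth(cx_L - cx_R)` falls outside the depth
#' of field (+1 um tolerance).
#'
#' @param a Left-view detection (one row of [extract_features()] output).
#' @param b Right-view detection, same frame.
#' @param cfg An [optics_config()] (for the depth-of-field gate).
#' @param weights Non-negative weights `c(y, r, e)` summing to 1.
#'   Default `c(0.5, 0.25, 0.25)`.
#' @param scales Positive feature scales `c(y, r, e)` making the terms
#'   dimensionless. Default `c(1, 1, 0.05)`.
#' @param row_tol_px Epipolar row tolerance in pixels. Default 2.
#' @return Non-negative cost, or `Inf` if infeasible.
#' @export
correspondence_cost <- function(a, b, cfg, weights = c(0.5, 0.25, 0.25),
                                scales = c(1, 1, 0.05), row_tol_px = 2) {
  check_match_weights(weights, scales)
  if (!identical(as.character(a$view), "left") ||
      !identical(as.character(b$view), "right"))
    stop("'a' must be a left-view and 'b' a right-view detection")
  if (a$frame_index != b$frame_index)
    stop("detections must come from the same frame")
  dy <- abs(a$cy_px - b$cy_px)
  if (dy > row_tol_px) return(Inf)
  z <- disparity_to_depth(a$cx_px - b$cx_px, cfg)
  if (abs(z) > cfg$dof_um / 2 + 1) return(Inf)
  weights[1] * dy / scales[1] +
    weights[2] * abs(a$radius_px - b$radius_px) / scales[2] +
    weights[3] * abs(a$encircled_energy - b$encircled_energy) / scales[3]
}

check_match_weights <- function(weights, scales) {
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0))
    stop("'weights' must be three non-negative numbers")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must sum to 1")
  if (length(scales) != 3L || any(!is.finite(scales)) || any(scales <= 0))
    stop("'scales' must be three positive numbers")
  invisible(TRUE)
}

# robust per-frame feature scales: MAD spread of each feature pooled over
# both views, floored so a frame of identical features stays well-defined
match_feature_scales <- function(left, right,
                                 floors = c(y = 1, r = 0.5, e = 0.02)) {
  pool <- rbind(left[c("cy_px", "radius_px", "encircled_energy")],
                right[c("cy_px", "radius_px", "encircled_energy")])
  c(max(stats::mad(pool$cy_px), floors[["y"]]),
    max(stats::mad(pool$radius_px), floors[["r"]]),
    max(stats::mad(pool$encircled_energy), floors[["e"]]))
}

#' Match left and right detections of one frame
#'
#' Builds the full feasible-pair cost matrix with [correspondence_cost()]
#' and solves the optimal one-to-one assignment with [solve_assignment()]
#' (Hungarian). Feature scales default to robust (MAD) spreads pooled over
#' both views so the cost terms are dimensionless and comparable across
#' frames.
#'
#' @param left_dets,right_dets Detection tables from [extract_features()]
#'   for the two views of one frame.
#' @param cfg An [optics_config()].
#' @param weights,row_tol_px See [correspondence_cost()].
#' @param scales Feature scales; `NULL` (default) uses per-frame MAD spreads.
#' @return List with `matches` (`data.frame`: `left_id, right_id, cost`,
#'   row indices into the two input tables), `unmatched_left`,
#'   `unmatched_right` (integer indices).
#' @export
match_stereo <- function(left_dets, right_dets, cfg,
                         weights = c(0.5, 0.25, 0.25), row_tol_px = 2,
                         scales = NULL) {
  assert_optics(cfg)
  nl <- nrow(left_dets); nr <- nrow(right_dets)
  empty <- data.frame(left_id = integer(0), right_id = integer(0),
                      cost = numeric(0))
  if (nl == 0L || nr == 0L)
    return(list(matches = empty, unmatched_left = seq_len(nl),
                unmatched_right = seq_len(nr)))
  if (is.null(scales)) scales <- match_feature_scales(left_dets, right_dets)
  check_match_weights(weights, scales)
  cost <- matrix(Inf, nl, nr)
  for (i in seq_len(nl)) for (j in seq_len(nr)) {
    cost[i, j] <- correspondence_cost(left_dets[i, ], right_dets[j, ], cfg,
                                      weights, scales, row_tol_px)
  }
  assign <- solve_assignment(cost)
  mi <- which(!is.na(assign))
  matches <- if (length(mi)) {
    data.frame(left_id = mi, right_id = assign[mi],
               cost = cost[cbind(mi, assign[mi])])
  } else empty
  list(matches = matches,
       unmatched_left = setdiff(seq_len(nl), matches$left_id),
       unmatched_right = setdiff(seq_len(nr), matches$right_id))
}

#' Reconstruct 3D particle positions from stereo matches
#'
#' Converts each matched pair to micrometres: lateral position is the mean
#' of the two views' centroids (`x_um = pixel_size (cx_L + cx_R)/2`, same
#' for y), depth comes from the disparity via [disparity_to_depth()].
#' Matches whose depth falls outside the depth of field (+1 um tolerance)
#' are dropped with a warning.
#'
#' @param match_result Output of [match_stereo()].
#' @param left_dets,right_dets The detection tables that were matched.
#' @param cfg An [optics_config()].
#' @return `data.frame` with columns `frame, x_um, y_um, z_um, disparity_px,
#'   match_cost, left_id, right_id`.
#' @export
reconstruct_3d <- function(match_result, left_dets, right_dets, cfg) {
  assert_optics(cfg)
  m <- match_result$matches
  if (nrow(m) == 0L)
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      disparity_px = numeric(0), match_cost = numeric(0),
                      left_id = integer(0), right_id = integer(0)))
  L <- left_dets[m$left_id, ]
  R <- right_dets[m$right_id, ]
  ps <- cfg$pixel_size_um
  disparity <- L$cx_px - R$cx_px
  z <- disparity_to_depth(disparity, cfg)
  out <- data.frame(frame = L$frame_index,
                    x_um = ps * (L$cx_px + R$cx_px) / 2,
                    y_um = ps * (L$cy_px + R$cy_px) / 2,
                    z_um = z,
                    disparity_px = disparity,
                    match_cost = m$cost,
                    left_id = m$left_id, right_id = m$right_id)
  keep <- abs(out$z_um) <= cfg$dof_um / 2 + 1
  if (any(!keep))
    warning(sprintf("%d match(es) dropped: implied depth outside the DOF",
                    sum(!keep)))
  out[keep, , drop = FALSE]
}
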