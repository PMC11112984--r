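# End-to-end orchestration: configuration, stereo-sequence file I/O,
# the per-frame reconstruction pipeline, and CSV export.

#' Full pipeline configuration
#'
#' Validates and bundles the parameters of every stage. Unknown keys in any
#' block are rejected (strict parsing), so a typo in a config file fails
#' loudly instead of silently using a default.
#'
#' @param optics An [optics_config()] or a named list of its arguments.
#' @param restoration List: `cutoff` (low-pass, cycles/px), `rl_iterations`,
#'   `psf_sigma_um` (deconvolution PSF width).
#' @param detection List: `mode` ("hough" or "blob"), `r_min_px`, `r_max_px`,
#'   `sensitivity`, `block_size_px`, `offset` (NULL = auto),
#'   `blob_radius_px` (blob mode only).
#' @param matching List: `weights` (length 3, sums to 1), `row_tol_px`.
#' @param tracking A [tracking_params()] or named list of its arguments.
#' @param seed Simulation seed recorded in the config.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(optics = optics_config(),
                            restoration = list(),
                            detection = list(),
                            matching = list(),
                            tracking = list(),
                            seed = 1L) {
  if (!is_optics_config(optics)) optics <- do.call(optics_config, optics)
  restoration <- merge_block("restoration", restoration,
    list(cutoff = 0.3, rl_iterations = 10L, psf_sigma_um = 0.4))
  detection <- merge_block("detection", detection,
    list(mode = "hough", r_min_px = 7, r_max_px = 14, sensitivity = 0.85,
         block_size_px = 31L, offset = NULL, blob_radius_px = 2))
  matching <- merge_block("matching", matching,
    list(weights = c(0.5, 0.25, 0.25), row_tol_px = 2))
  if (inherits(tracking, "tracking_params")) {
    trk <- tracking
  } else {
    trk_args <- merge_block("tracking", tracking,
      list(max_link_dist_um = 5, max_gap_frames = 2L, max_gap_dist_um = 7,
           z_weight = 1, min_length = 3L))
    trk <- do.call(tracking_params, trk_args)
  }
  stopifnot(restoration$cutoff > 0, restoration$cutoff <= 0.5,
            restoration$rl_iterations >= 0, restoration$psf_sigma_um > 0,
            detection$mode %in% c("hough", "blob"))
  check_match_weights(matching$weights, c(1, 1, 1))
  structure(list(optics = optics, restoration = restoration,
                 detection = detection, matching = matching,
                 tracking = trk, seed = as.integer(seed)),
            class = "pipeline_config")
}

merge_block <- function(name, given, defaults) {
  if (length(given) == 0L) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown key(s) in '%s' config block: %s",
                 name, paste(unknown, collapse = ", ")))
  defaults[names(given)] <- given
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' Expects top-level blocks `optics`, and optionally `restoration`,
#' `detection`, `matching`, `tracking`, `seed`. Unknown keys anywhere are
#' rejected.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("optics", "restoration", "detection", "matching", "tracking",
             "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  args <- list(
    optics = if (is.null(y$optics)) optics_config() else y$optics,
    restoration = y$restoration %||% list(),
    detection = y$detection %||% list(),
    matching = y$matching %||% list(),
    tracking = y$tracking %||% list(),
    seed = y$seed %||% 1L
  )
  # lists from YAML may carry weights as a list
  if (!is.null(args$matching$weights))
    args$matching$weights <- as.numeric(unlist(args$matching$weights))
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  o <- config$optics
  yaml::write_yaml(list(
    optics = list(parallax_angle_deg = o$parallax_angle_deg,
                  fov_x_um = o$fov_x_um, fov_y_um = o$fov_y_um,
                  dof_um = o$dof_um, frame_w_px = o$frame_w_px,
                  frame_h_px = o$frame_h_px,
                  volume_rate_hz = o$volume_rate_hz),
    restoration = config$restoration,
    detection = config$detection[!vapply(config$detection, is.null,
                                         logical(1))],
    matching = list(weights = as.numeric(config$matching$weights),
                    row_tol_px = config$matching$row_tol_px),
    tracking = unclass(config$tracking),
    seed = config$seed
  ), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a stereo time sequence from TIFF stacks
#'
#' Two dialects: `"split"` (two files, left and right, equal page counts)
#' or `"interleaved"` (one file, even page count; even pages 0, 2, ... are
#' left views, odd pages right views).
#'
#' @param path Left-view stack (split) or the interleaved stack.
#' @param right_path Right-view stack (split dialect only).
#' @param dialect `"split"` or `"interleaved"`.
#' @param volume_rate_hz Frame rate used for timestamps. Default 30.
#' @return List of `stereo_pair` objects with consecutive frame indices.
#' @export
read_stereo_sequence <- function(path, right_path = NULL,
                                 dialect = c("split", "interleaved"),
                                 volume_rate_hz = 30) {
  dialect <- match.arg(dialect)
  if (dialect == "split") {
    if (is.null(right_path))
      stop("split dialect needs both a left and a right stack")
    left <- read_tiff_stack(path)
    right <- read_tiff_stack(right_path)
    if (length(left) != length(right))
      stop(sprintf("page count mismatch: %s has %d pages, %s has %d",
                   path, length(left), right_path, length(right)))
  } else {
    pages <- read_tiff_stack(path)
    if (length(pages) %% 2L != 0L)
      stop(sprintf("interleaved stack %s has an odd page count (%d)",
                   path, length(pages)))
    left <- pages[seq(1L, length(pages), by = 2L)]
    right <- pages[seq(2L, length(pages), by = 2L)]
  }
  lapply(seq_along(left), function(i) {
    if (!identical(dim(left[[i]]), dim(right[[i]])))
      stop(sprintf("page %d: left/right shape mismatch", i))
    structure(list(left = left[[i]], right = right[[i]],
                   frame_index = i - 1L,
                   time_s = (i - 1L) / volume_rate_hz),
              class = "stereo_pair")
  })
}

#' Write a stereo time sequence as TIFF stacks
#'
#' @param pairs List of `stereo_pair` objects.
#' @param dir Output directory (created if needed). Split dialect writes
#'   `left.tif` and `right.tif`; interleaved writes `stereo.tif`.
#' @param dialect `"split"` or `"interleaved"`.
#' @param type Pixel type passed to [write_tiff_stack()].
#' @return Invisibly, the file path(s) written.
#' @export
write_stereo_sequence <- function(pairs, dir,
                                  dialect = c("split", "interleaved"),
                                  type = "float64") {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (dialect == "split") {
    lp <- file.path(dir, "left.tif"); rp <- file.path(dir, "right.tif")
    write_tiff_stack(lapply(pairs, `[[`, "left"), lp, type)
    write_tiff_stack(lapply(pairs, `[[`, "right"), rp, type)
    invisible(c(lp, rp))
  } else {
    sp <- file.path(dir, "stereo.tif")
    inter <- vector("list", 2L * length(pairs))
    inter[seq(1L, length(inter), 2L)] <- lapply(pairs, `[[`, "left")
    inter[seq(2L, length(inter), 2L)] <- lapply(pairs, `[[`, "right")
    write_tiff_stack(inter, sp, type)
    invisible(sp)
  }
}

# restore + detect + feature-extract a single view image
process_view <- function(img, config, frame_index, view) {
  r <- config$restoration
  d <- config$detection
  img <- lowpass_denoise(img, r$cutoff)
  if (r$rl_iterations > 0L) {
    sigma_px <- r$psf_sigma_um / config$optics$pixel_size_um
    img <- deconvolve_rl(img, gaussian_kernel(sigma_px), r$rl_iterations)
  }
  circles <- if (d$mode == "hough") {
    mask <- segment_adaptive(img, d$block_size_px, d$offset)
    hough_circles(img, mask, d$r_min_px, d$r_max_px, d$sensitivity)
  } else {
    detect_blobs(img, d$blob_radius_px)
  }
  extract_features(img, circles, frame_index, view)
}

#' Run the full reconstruction pipeline on a stereo sequence
#'
#' Per frame: restore both views (low-pass + Richardson-Lucy), detect
#' particles, extract features, match left/right by optimal assignment and
#' reconstruct 3D positions; then link all frames into trajectories with
#' gap closing. Fully deterministic given inputs and config.
#'
#' @param pairs List of `stereo_pair` objects (e.g. from
#'   [simulate_sequence()] or [read_stereo_sequence()]).
#' @param config A [pipeline_config()].
#' @param verbose Print per-frame stage counts.
#' @return List (class `pipeline_result`): `particles` (tidy table over all
#'   frames), `trajectories` (a `trajectory_set`), `detections` (per-view
#'   feature table), `counts` (per-frame bookkeeping: detections L/R,
#'   matches).
#' @export
run_pipeline <- function(pairs, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$optics
  all_parts <- list(); all_dets <- list(); counts <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    fi <- pr$frame_index
    ld <- process_view(pr$left, config, fi, "left")
    rd <- process_view(pr$right, config, fi, "right")
    mt <- match_stereo(ld, rd, cfg, config$matching$weights,
                       config$matching$row_tol_px)
    p3 <- reconstruct_3d(mt, ld, rd, cfg)
    all_parts[[i]] <- p3
    all_dets[[i]] <- rbind(ld, rd)
    counts[[i]] <- data.frame(frame = fi, detections_left = nrow(ld),
                              detections_right = nrow(rd),
                              matches = nrow(p3))
    if (verbose)
      message(sprintf("frame %d: %d left, %d right, %d matched",
                      fi, nrow(ld), nrow(rd), nrow(p3)))
  }
  particles <- do.call(rbind, all_parts)
  if (is.null(particles))
    particles <- data.frame(frame = integer(0), x_um = numeric(0),
                            y_um = numeric(0), z_um = numeric(0),
                            disparity_px = numeric(0),
                            match_cost = numeric(0),
                            left_id = integer(0), right_id = integer(0))
  traj <- build_trajectories(particles, config$tracking,
                             volume_rate_hz = cfg$volume_rate_hz)
  structure(list(particles = particles, trajectories = traj,
                 detections = do.call(rbind, all_dets),
                 counts = do.call(rbind, counts)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d frame(s), %d matched particle(s), %d trajectorie(s)\n",
              NROW(x$counts), nrow(x$particles),
              length(unique(x$trajectories$tracks$track_id))))
  invisible(x)
}

csv_header_comment <- paste(
  "# coordinates: micrometres; z relative to the mid-plane of the depth",
  "of field; pixel columns are 0-based pixel centres")

write_commented_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header_comment, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export tables as CSV (with a coordinate-convention header comment)
#'
#' `write_detections_csv` writes per-view detections, `write_particles_csv`
#' the reconstructed per-frame 3D particles, `write_trajectories_csv` the
#' linked trajectories (`track_id, frame, time_s, x_um, y_um, z_um,
#' gap_flag`), and `write_ground_truth_csv` a simulator truth table
#' (`frame, id, x_um, y_um, z_um`). Read them back with
#' [read_csv_table()].
#'
#' @param x The corresponding table (or `trajectory_set` /
#'   `pipeline_result` component).
#' @param path Output path.
#' @return The path, invisibly.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_detections_csv <- function(x, path) {
  write_commented_csv(x[, c("view", "frame_index", "cx_px", "cy_px",
                            "radius_px", "total_intensity",
                            "encircled_energy")], path)
}

#' @rdname csv_io
#' @export
write_particles_csv <- function(x, path) {
  write_commented_csv(x[, c("frame", "x_um", "y_um", "z_um", "disparity_px",
                            "match_cost")], path)
}

#' @rdname csv_io
#' @export
write_trajectories_csv <- function(x, path) {
  if (inherits(x, "trajectory_set")) x <- x$tracks
  write_commented_csv(x[, c("track_id", "frame", "time_s", "x_um", "y_um",
                            "z_um", "gap_flag")], path)
}

#' @rdname csv_io
#' @export
write_ground_truth_csv <- function(x, path) {
  write_commented_csv(x[, c("frame", "id", "x_um", "y_um", "z_um")], path)
}

#' Read a CSV written by the `write_*_csv` helpers
#' @param path CSV path (leading `#` comment lines are skipped).
#' @return `data.frame`.
#' @export
read_csv_table <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
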