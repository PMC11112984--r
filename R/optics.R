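#' Imaging geometry of a stereo projection microscope
#'
#' Bundles the parallax geometry, field of view, depth of field and frame
#' timing of an extended-depth-of-field (EDF) two-photon stereo microscope.
#' All conversions between pixels, micrometres, disparity and depth go
#' through this object, so it is the single source of truth for coordinates.
#'
#' Conventions: image row = y, column = x, origin top-left, 0-based pixel
#' centres (pixel column `i` sits at `i * pixel_size_um` micrometres);
#' depth `z = 0` at the axial centre of the extended focus, valid
#' reconstruction range `[-dof_um/2, +dof_um/2]`; `parallax_angle_deg` is the
#' FULL angle between the two view axes (each beam tilted by half of it).
#'
#' @param parallax_angle_deg Full angle between left and right view axes,
#'   degrees, in (0, 90). Default 28.1.
#' @param fov_x_um,fov_y_um Lateral field of view, micrometres. Default 110.
#' @param dof_um Depth of field (axial extent of the EDF), micrometres.
#'   Default 100.
#' @param frame_w_px,frame_h_px Frame size in pixels. Default 512.
#' @param volume_rate_hz Stereo volumes acquired per second. Default 30.
#'
#' @return An object of class `optics_config` with the above fields plus the
#'   derived `pixel_size_um = fov_x_um / frame_w_px`.
#' @examples
#' cfg <- optics_config()
#' cfg$pixel_size_um            # 110/512 ~ 0.215 um
#' disparity_to_depth(5, cfg)
#' @export
optics_config <- function(parallax_angle_deg = 28.1,
                          fov_x_um = 110, fov_y_um = 110,
                          dof_um = 100,
                          frame_w_px = 512L, frame_h_px = 512L,
                          volume_rate_hz = 30) {
  stopifnot(
    is.numeric(parallax_angle_deg), length(parallax_angle_deg) == 1L,
    is.finite(parallax_angle_deg)
  )
  if (parallax_angle_deg <= 0 || parallax_angle_deg >= 90)
    stop("parallax_angle_deg must lie strictly between 0 and 90 degrees")
  for (nm in c("fov_x_um", "fov_y_um", "dof_um", "frame_w_px", "frame_h_px",
               "volume_rate_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single strictly positive finite number", nm))
  }
  cfg <- list(
    parallax_angle_deg = parallax_angle_deg,
    fov_x_um = fov_x_um, fov_y_um = fov_y_um,
    dof_um = dof_um,
    frame_w_px = as.integer(frame_w_px), frame_h_px = as.integer(frame_h_px),
    volume_rate_hz = volume_rate_hz,
    pixel_size_um = fov_x_um / frame_w_px
  )
  class(cfg) <- "optics_config"
  cfg
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  parallax (full) : %.2f deg\n", x$parallax_angle_deg))
  cat(sprintf("  field of view   : %g x %g um (%d x %d px, %.4f um/px)\n",
              x$fov_x_um, x$fov_y_um, x$frame_w_px, x$frame_h_px,
              x$pixel_size_um))
  cat(sprintf("  depth of field  : %g um (z in [%g, %g])\n",
              x$dof_um, -x$dof_um / 2, x$dof_um / 2))
  cat(sprintf("  volume rate     : %g Hz\n", x$volume_rate_hz))
  invisible(x)
}

is_optics_config <- function(x) inherits(x, "optics_config")

assert_optics <- function(cfg) {
  if (!is_optics_config(cfg)) stop("'cfg' must be an optics_config object")
  if (abs(cfg$pixel_size_um - cfg$fov_x_um / cfg$frame_w_px) > 1e-9)
    stop("inconsistent optics_config: pixel_size_um != fov_x_um / frame_w_px")
  invisible(cfg)
}

# disparity (px) per micrometre of depth; the slope of the linear depth map
disparity_slope_px_per_um <- function(cfg) {
  2 * tan(cfg$parallax_angle_deg / 2 * pi / 180) / cfg$pixel_size_um
}

#' Convert stereo disparity to depth
#'
#' Under parallel projection along two axes tilted by the full parallax angle
#' theta, a particle at depth `z` from the focal mid-plane appears displaced
#' by `+z tan(theta/2)` in the left view and `-z tan(theta/2)` in the right
#' view, so its disparity `d = x_left - x_right` (in pixels) maps linearly to
#' depth: `z = d * pixel_size / (2 tan(theta/2))`.
#'
#' @param disparity_px Signed disparity, pixels (`x_left - x_right`).
#'   Vectorised.
#' @param cfg An [optics_config()].
#' @return Depth in micrometres relative to the focal mid-plane; positive
#'   disparity gives positive depth.
#' @seealso [depth_to_disparity()] for the exact inverse.
#' @export
disparity_to_depth <- function(disparity_px, cfg) {
  assert_optics(cfg)
  if (!is.numeric(disparity_px) || any(!is.finite(disparity_px)))
    stop("'disparity_px' must be finite numeric (got non-finite values)")
  disparity_px / disparity_slope_px_per_um(cfg)
}

#' Convert depth to stereo disparity
#'
#' Exact algebraic inverse of [disparity_to_depth()]:
#' `d = z * 2 tan(theta/2) / pixel_size`.
#'
#' @param depth_um Depth in micrometres from the focal mid-plane. Vectorised.
#' @param cfg An [optics_config()].
#' @return Signed disparity in pixels.
#' @export
depth_to_disparity <- function(depth_um, cfg) {
  assert_optics(cfg)
  if (!is.numeric(depth_um) || any(!is.finite(depth_um)))
    stop("'depth_um' must be finite numeric (got non-finite values)")
  depth_um * disparity_slope_px_per_um(cfg)
}

#' Scattering medium descriptor
#'
#' @param mu_s_per_mm Scattering coefficient, 1/mm, > 0.
#' @param mu_s_prime_per_mm Reduced scattering coefficient, 1/mm, > 0 and
#'   not exceeding `mu_s_per_mm`.
#' @return An object of class `scattering_medium`.
#' @examples
#' m <- scattering_medium(3, 0.85)  # 1% intralipid at 864 nm
#' penetration_depths(m)
#' @export
scattering_medium <- function(mu_s_per_mm, mu_s_prime_per_mm) {
  if (!is.numeric(mu_s_per_mm) || length(mu_s_per_mm) != 1L ||
      !is.finite(mu_s_per_mm) || mu_s_per_mm <= 0)
    stop("mu_s_per_mm must be a single strictly positive number")
  if (!is.numeric(mu_s_prime_per_mm) || length(mu_s_prime_per_mm) != 1L ||
      !is.finite(mu_s_prime_per_mm) || mu_s_prime_per_mm <= 0)
    stop("mu_s_prime_per_mm must be a single strictly positive number")
  if (mu_s_prime_per_mm > mu_s_per_mm)
    stop("mu_s_prime_per_mm cannot exceed mu_s_per_mm")
  structure(list(mu_s_per_mm = mu_s_per_mm,
                 mu_s_prime_per_mm = mu_s_prime_per_mm),
            class = "scattering_medium")
}

#' Characteristic penetration depths of a scattering medium
#'
#' Mean free path MFP = 1/mu_s bounds camera-based imaging depth; transport
#' mean free path TMFP = 1/mu_s' bounds point-scanning two-photon imaging
#' depth. Both in millimetres.
#'
#' @param medium A [scattering_medium()].
#' @return Named list with `mfp_mm` and `tmfp_mm`; always `tmfp_mm >= mfp_mm`.
#' @export
penetration_depths <- function(medium) {
  if (!inherits(medium, "scattering_medium"))
    stop("'medium' must be a scattering_medium object")
  list(mfp_mm = 1 / medium$mu_s_per_mm,
       tmfp_mm = 1 / medium$mu_s_prime_per_mm)
}

#' Number of stereo volumes acquired in a time span
#'
#' Counts frames whose acquisition start falls in the half-open interval
#' `[0, duration_s)` at the configured volume rate.
#'
#' @param duration_s Recording duration, seconds, >= 0.
#' @param cfg An [optics_config()].
#' @return Integer frame count, `floor(duration_s * volume_rate_hz)`.
#' @export
frames_in_duration <- function(duration_s, cfg) {
  assert_optics(cfg)
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s < 0)
    stop("'duration_s' must be a single finite non-negative number")
  as.integer(floor(duration_s * cfg$volume_rate_hz + 1e-9))
}
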