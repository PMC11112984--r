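# Trajectory building: optimal frame-to-frame linking followed by gap
# closing between track ends and later track starts.

#' Tracking parameters
#'
#' @param max_link_dist_um Maximum 3D displacement for a direct
#'   frame-to-frame link, um. Default 5.
#' @param max_gap_frames Maximum frame span bridgeable by gap closing.
#'   Default 2 (a single missed frame gives a span of 2).
#' @param max_gap_dist_um Maximum 3D distance for a bridged link, um.
#'   Default 7.
#' @param z_weight Multiplier applied to the z component in the link metric.
#'   1 (default) is plain Euclidean distance, which keeps the gating
#'   distances interpretable; values < 1 down-weight the noisier axial
#'   coordinate.
#' @param min_length Trajectories shorter than this are flagged
#'   (`short = TRUE`), never deleted. Default 3.
#' @return A `tracking_params` object.
#' @export
tracking_params <- function(max_link_dist_um = 5, max_gap_frames = 2L,
                            max_gap_dist_um = 7, z_weight = 1,
                            min_length = 3L) {
  stopifnot(max_link_dist_um > 0, max_gap_frames >= 0,
            max_gap_dist_um > 0, z_weight > 0, min_length >= 1)
  structure(list(max_link_dist_um = max_link_dist_um,
                 max_gap_frames = as.integer(max_gap_frames),
                 max_gap_dist_um = max_gap_dist_um,
                 z_weight = z_weight, min_length = as.integer(min_length)),
            class = "tracking_params")
}

# pairwise (weighted) Euclidean distance matrix between two particle tables
particle_dist_matrix <- function(p0, p1, z_weight = 1) {
  dx <- outer(p0$x_um, p1$x_um, `-`)
  dy <- outer(p0$y_um, p1$y_um, `-`)
  dz <- outer(p0$z_um, p1$z_um, `-`) * z_weight
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Link particles between two consecutive frames
#'
#' Optimal one-to-one assignment minimising summed 3D distance; pairs
#' further apart than `max_link_dist_um` are infeasible and stay unlinked
#' (track death / birth). Ties are resolved deterministically by the
#' solver's stable scan order (lowest source index first).
#'
#' @param particles_t,particles_t1 `data.frame`s with `x_um, y_um, z_um`
#'   for two consecutive frames.
#' @param max_link_dist_um Gating distance, um.
#' @param z_weight Axial weight in the metric (see [tracking_params()]).
#' @return `data.frame` with `from, to, dist_um`: row indices into the two
#'   inputs for every accepted link.
#' @export
link_frame_pair <- function(particles_t, particles_t1, max_link_dist_um = 5,
                            z_weight = 1) {
  n0 <- nrow(particles_t); n1 <- nrow(particles_t1)
  empty <- data.frame(from = integer(0), to = integer(0), dist_um = numeric(0))
  if (n0 == 0L || n1 == 0L) return(empty)
  d <- particle_dist_matrix(particles_t, particles_t1, z_weight)
  cost <- d
  cost[cost > max_link_dist_um] <- Inf
  assign <- solve_assignment(cost)
  i <- which(!is.na(assign))
  if (!length(i)) return(empty)
  data.frame(from = i, to = assign[i], dist_um = d[cbind(i, assign[i])])
}

#' Close gaps between track ends and later track starts
#'
#' Candidate bridges connect the end of one track to the start of another
#' `1..max_gap_frames` frames later and within `max_gap_dist_um`; the
#' optimal set of bridges (minimum summed distance) is chosen by the same
#' assignment solver, and bridged tracks are merged. Chains of bridges are
#' resolved transitively.
#'
#' @param tracks `data.frame` of observations with columns `track_id, frame,
#'   x_um, y_um, z_um` (from frame-to-frame linking).
#' @param max_gap_frames,max_gap_dist_um,z_weight See [tracking_params()].
#' @return List with `tracks` (same shape, merged ids, renumbered 1..n) and
#'   `gap_links` (`data.frame`: `track_id, frame_end, frame_start`).
#' @export
close_gaps <- function(tracks, max_gap_frames = 2L, max_gap_dist_um = 7,
                       z_weight = 1) {
  gap_links <- data.frame(track_id = integer(0), frame_end = integer(0),
                          frame_start = integer(0))
  if (nrow(tracks) == 0L || max_gap_frames < 1L)
    return(list(tracks = renumber_tracks(tracks)$tracks, gap_links = gap_links))
  ids <- sort(unique(tracks$track_id))
  ends <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr[which.max(tr$frame), ]
  }))
  starts <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr[which.min(tr$frame), ]
  }))
  span <- outer(ends$frame, starts$frame, function(fe, fs) fs - fe)
  d <- particle_dist_matrix(ends, starts, z_weight)
  cost <- d
  cost[span < 1L | span > max_gap_frames] <- Inf
  cost[d > max_gap_dist_um] <- Inf
  diag(cost) <- Inf                       # a track cannot bridge to itself
  assign <- solve_assignment(cost)
  take <- which(!is.na(assign))
  if (!length(take))
    return(list(tracks = renumber_tracks(tracks)$tracks, gap_links = gap_links))
  # merge: track ids[to] is appended to track ids[from]; resolve chains
  parent <- stats::setNames(ids, ids)
  find_root <- function(id) { while (parent[[as.character(id)]] != id)
    id <- parent[[as.character(id)]]; id }
  bridges <- data.frame(from = ids[take], to = ids[assign[take]],
                        frame_end = ends$frame[take],
                        frame_start = starts$frame[assign[take]])
  for (b in seq_len(nrow(bridges)))
    parent[[as.character(bridges$to[b])]] <- bridges$from[b]
  root <- vapply(tracks$track_id, find_root, numeric(1))
  tracks$track_id <- root
  gap_links <- data.frame(
    track_id = vapply(bridges$from, find_root, numeric(1)),
    frame_end = bridges$frame_end,
    frame_start = bridges$frame_start)
  res <- renumber_tracks(tracks)
  gap_links$track_id <- res$map[as.character(gap_links$track_id)]
  list(tracks = res$tracks, gap_links = gap_links)
}

renumber_tracks <- function(tracks) {
  if (nrow(tracks) == 0L)
    return(list(tracks = tracks, map = integer(0)))
  old <- sort(unique(tracks$track_id))
  map <- stats::setNames(seq_along(old), old)
  tracks$track_id <- as.integer(map[as.character(tracks$track_id)])
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  list(tracks = tracks, map = map)
}

#' Build 3D trajectories from per-frame particle tables
#'
#' Composition of optimal frame-to-frame linking over all consecutive frame
#' pairs followed by gap closing. Every input particle appears in exactly
#' one trajectory (singletons allowed). The result is a tidy observation
#' table plus the gap-link record, wrapped as a `trajectory_set`.
#'
#' @param particles `data.frame` of reconstructed particles with columns
#'   `frame, x_um, y_um, z_um` (e.g. from [reconstruct_3d()], concatenated
#'   over frames), or a list of per-frame tables.
#' @param params A [tracking_params()].
#' @param volume_rate_hz Frame rate used to fill the `time_s` column.
#'   Default 30.
#' @return A `trajectory_set`: list with `tracks` (`data.frame`: `track_id,
#'   frame, time_s, x_um, y_um, z_um, gap_flag, short`) and `gap_links`.
#'   `gap_flag` marks the first observation after a bridged gap.
#' @export
build_trajectories <- function(particles, params = tracking_params(),
                               volume_rate_hz = 30) {
  stopifnot(inherits(params, "tracking_params"))
  if (is.list(particles) && !is.data.frame(particles))
    particles <- do.call(rbind, particles)
  cols <- c("frame", "x_um", "y_um", "z_um")
  if (nrow(particles) == 0L || is.null(particles)) {
    tracks <- data.frame(track_id = integer(0), frame = integer(0),
                         time_s = numeric(0), x_um = numeric(0),
                         y_um = numeric(0), z_um = numeric(0),
                         gap_flag = logical(0), short = logical(0))
    return(structure(list(tracks = tracks,
                          gap_links = data.frame(track_id = integer(0),
                                                 frame_end = integer(0),
                                                 frame_start = integer(0))),
                     class = "trajectory_set"))
  }
  stopifnot(all(cols %in% names(particles)))
  particles <- particles[order(particles$frame), cols, drop = FALSE]
  frames <- sort(unique(particles$frame))
  per_frame <- lapply(frames, function(f)
    particles[particles$frame == f, , drop = FALSE])
  # frame-to-frame linking; track id carried on each particle row
  next_id <- 1L
  track_of <- vector("list", length(frames))
  track_of[[1L]] <- seq_len(nrow(per_frame[[1L]])) - 1L + next_id
  next_id <- next_id + nrow(per_frame[[1L]])
  if (length(frames) > 1L) {
    for (k in seq_len(length(frames) - 1L)) {
      p0 <- per_frame[[k]]; p1 <- per_frame[[k + 1L]]
      links <- if (frames[k + 1L] - frames[k] == 1L) {
        link_frame_pair(p0, p1, params$max_link_dist_um, params$z_weight)
      } else {
        data.frame(from = integer(0), to = integer(0), dist_um = numeric(0))
      }
      ids1 <- rep(NA_integer_, nrow(p1))
      if (nrow(links)) ids1[links$to] <- track_of[[k]][links$from]
      born <- which(is.na(ids1))
      if (length(born)) {
        ids1[born] <- seq_along(born) - 1L + next_id
        next_id <- next_id + length(born)
      }
      track_of[[k + 1L]] <- ids1
    }
  }
  obs <- do.call(rbind, lapply(seq_along(frames), function(k) {
    p <- per_frame[[k]]
    data.frame(track_id = track_of[[k]], frame = p$frame,
               x_um = p$x_um, y_um = p$y_um, z_um = p$z_um)
  }))
  closed <- close_gaps(obs, params$max_gap_frames, params$max_gap_dist_um,
                       params$z_weight)
  tracks <- closed$tracks
  tracks$time_s <- tracks$frame / volume_rate_hz
  tracks$gap_flag <- FALSE
  gl <- closed$gap_links
  for (b in seq_len(nrow(gl))) {
    hit <- tracks$track_id == gl$track_id[b] & tracks$frame == gl$frame_start[b]
    tracks$gap_flag[hit] <- TRUE
  }
  len <- table(tracks$track_id)
  tracks$short <- as.integer(len[as.character(tracks$track_id)]) <
    params$min_length
  tracks <- tracks[, c("track_id", "frame", "time_s", "x_um", "y_um",
                       "z_um", "gap_flag", "short")]
  structure(list(tracks = tracks, gap_links = gl),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- length(unique(x$tracks$track_id))
  cat(sprintf("<trajectory_set> %d trajectories, %d observations, %d bridged gap(s)\n",
              n, nrow(x$tracks), nrow(x$gap_links)))
  invisible(x)
}
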