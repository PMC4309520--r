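# Migration metrics for the agarose-spot chemotactic-invasion assay.
# Tracks are data.frames with one row per sample: columns t_s (seconds,
# strictly increasing), x_um, y_um, and optionally width_um / length_um.

.check_track <- function(track, min_samples = 2L) {
  stopifnot(is.data.frame(track),
            all(c("t_s", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < min_samples) {
    stop("track has ", nrow(track), " sample(s); at least ", min_samples,
         " required for this metric")
  }
  if (is.unsorted(track$t_s, strictly = TRUE)) {
    stop("track times must be strictly increasing")
  }
  invisible(track)
}

# Split a long-format track table (id column) into a list of per-track
# data.frames, preserving sample order.
.split_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks), "id" %in% names(tracks))
  split(tracks, tracks$id)
}

#' Total path length of a cell track
#'
#' Sum of Euclidean step distances between consecutive samples.
#'
#' @param track Data.frame with columns `t_s`, `x_um`, `y_um`.
#' @return Path length in µm.
#' @examples
#' tr <- data.frame(t_s = c(0, 60), x_um = c(0, 3), y_um = c(0, 4))
#' path_length(tr)  # 5
#' @export
path_length <- function(track) {
  .check_track(track)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Net distance from origin
#'
#' Euclidean distance between the first and last sample of a track; always
#' at most the total path length.
#'
#' @inheritParams path_length
#' @return Distance in µm.
#' @export
distance_from_origin <- function(track) {
  .check_track(track)
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

#' Average velocity of a cell track
#'
#' By default the total path length divided by elapsed time (the
#' convention of cell-tracking software that reports path length
#' alongside); set `mode = "displacement"` for net displacement over
#' elapsed time.
#'
#' @inheritParams path_length
#' @param mode `"path"` (default) or `"displacement"`.
#' @return Velocity in µm/h.
#' @export
average_velocity <- function(track, mode = c("path", "displacement")) {
  mode <- match.arg(mode)
  .check_track(track)
  dt_h <- (track$t_s[nrow(track)] - track$t_s[1]) / 3600
  if (dt_h <= 0) stop("track has zero duration; velocity undefined")
  d <- if (mode == "path") path_length(track) else distance_from_origin(track)
  d / dt_h
}

#' Elliptical factor (cell shape polarity index)
#'
#' Cell width divided by cell length, a number in (0, 1]; 1 for a circular
#' cell, small values for elongated cells. Width is the minor axis by
#' convention: if `width > length` the two are swapped with a warning.
#'
#' @param width Cell width, µm.
#' @param length Cell length, µm.
#' @return Ratio in (0, 1]; vectorised.
#' @export
elliptical_factor <- function(width, length) {
  stopifnot(all(width > 0), all(length > 0))
  if (any(width > length)) {
    warning("width > length for some cells; swapping (width = minor axis)")
    swap <- width > length
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  width / length
}

#' Migration angle relative to the spot perpendicular
#'
#' Unsigned angle between a track's origin-to-endpoint displacement and the
#' line perpendicular to the agarose-spot edge (the expected migration
#' direction). 0 degrees is migration straight along the perpendicular;
#' 90 degrees is along the edge.
#'
#' @inheritParams path_length
#' @param spot A [spot_geometry()].
#' @return Angle in degrees, \[0, 180\].
#' @export
migration_angle <- function(track, spot) {
  .check_track(track)
  n <- nrow(track)
  v <- c(track$x_um[n] - track$x_um[1], track$y_um[n] - track$y_um[1])
  angle_to_perpendicular(spot, v)
}

#' Count cells that migrated into the spot
#'
#' A track counts as migrated when its final position lies inside the spot
#' and the track crossed the spot edge during the recording (cells seeded
#' inside never count). Tracks without samples are rejected with their ids
#' reported.
#'
#' @param tracks Long-format track table (columns `id`, `t_s`, `x_um`,
#'   `y_um`) or a list of per-track data.frames.
#' @param spot A [spot_geometry()].
#' @return Integer count; attribute `"ids"` holds the migrated track ids.
#' @export
count_migrated <- function(tracks, spot) {
  trl <- if (is.data.frame(tracks)) .split_tracks(tracks) else tracks
  if (length(trl) == 0) stop("no tracks supplied")
  empty <- names(trl)[vapply(trl, nrow, integer(1)) < 1L]
  if (length(empty) > 0) {
    stop("tracks without samples rejected: ", paste(empty, collapse = ", "))
  }
  mig <- vapply(trl, function(tr) {
    s <- spot_signed_distance(spot, cbind(tr$x_um, tr$y_um))
    n <- length(s)
    s[n] > 0 && any(s[seq_len(n - 1)] <= 0)
  }, logical(1))
  ids <- names(trl)[mig]
  structure(sum(mig), ids = ids)
}

#' Percent decrease of a treated mean relative to control
#'
#' `100 * (control - treated) / control`; negative when the treated mean
#' exceeds control. Invariant to rescaling both means by the same positive
#' constant.
#'
#' @param control_mean Control-condition mean (> 0).
#' @param treated_mean Treated-condition mean.
#' @return Percent decrease.
#' @examples
#' percent_decrease(100, 40)  # 60
#' @export
percent_decrease <- function(control_mean, treated_mean) {
  if (any(control_mean <= 0)) {
    stop("control mean must be positive for a percent decrease")
  }
  100 * (control_mean - treated_mean) / control_mean
}

#' Wound-healing distance
#'
#' Mean distance advanced by the wound edge between two time points,
#' measured at paired points along the wound. Each pair contributes the
#' component of its displacement along the wound normal.
#'
#' @param edge_t0,edge_t1 Matrices or data.frames of paired points (x, y)
#'   in µm along the wound edge at the two time points; same row count.
#' @param normal Unit vector perpendicular to the wound (direction of
#'   closure); defaults to the mean displacement direction.
#' @return Mean advance in µm.
#' @export
wound_distance <- function(edge_t0, edge_t1, normal = NULL) {
  e0 <- as.matrix(edge_t0)[, 1:2, drop = FALSE]
  e1 <- as.matrix(edge_t1)[, 1:2, drop = FALSE]
  if (nrow(e0) != nrow(e1)) {
    stop("edge traces must have the same number of measurement points")
  }
  d <- e1 - e0
  if (is.null(normal)) {
    m <- colMeans(d)
    if (sqrt(sum(m^2)) == 0) return(0)
    normal <- .unit(m)
  } else {
    normal <- .unit(as.numeric(normal))
  }
  mean(abs(d %*% normal))
}

#' Per-track migration metric table
#'
#' Computes path length, distance from origin, average velocity, migration
#' angle and (when shape columns are present) the mean elliptical factor
#' for every track in a field.
#'
#' @param tracks Long-format track table (columns `id`, `t_s`, `x_um`,
#'   `y_um`, optionally `width_um`, `length_um`).
#' @param spot A [spot_geometry()].
#' @return Data.frame with one row per track: `id`, `path_um`,
#'   `distance_um`, `velocity_um_h`, `angle_deg`, `elliptical_factor`,
#'   `migrated`.
#' @export
track_metrics <- function(tracks, spot) {
  trl <- .split_tracks(tracks)
  mig_ids <- attr(count_migrated(tracks, spot), "ids")
  out <- lapply(names(trl), function(id) {
    tr <- trl[[id]]
    ef <- if (all(c("width_um", "length_um") %in% names(tr))) {
      mean(elliptical_factor(tr$width_um, tr$length_um))
    } else NA_real_
    disp <- distance_from_origin(tr)
    data.frame(
      id = id,
      path_um = path_length(tr),
      distance_um = disp,
      velocity_um_h = average_velocity(tr),
      angle_deg = if (disp > 0) migration_angle(tr, spot) else NA_real_,
      elliptical_factor = ef,
      migrated = id %in% mig_ids
    )
  })
  do.call(rbind, out)
}
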