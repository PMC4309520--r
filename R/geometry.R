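#' Agarose-spot edge geometry
#'
#' Describes the edge of the chemoattractant (agarose) spot as a straight
#' line in micrometre coordinates, together with the unit vector
#' perpendicular to the edge pointing into the spot interior. The
#' perpendicular defines the expected direction of chemotactic migration
#' and the front/middle/back polarity axis.
#'
#' @param edge_point Numeric length-2, a point (x, y) in µm on the spot edge.
#' @param perpendicular Numeric length-2, vector from the edge into the spot
#'   interior; normalised internally.
#' @return An object of class `spot_geometry` with elements `edge_point`,
#'   `perpendicular` (unit length) and `tangent` (unit vector along the edge).
#' @examples
#' sp <- spot_geometry(c(0, 0), c(1, 0))  # spot occupies x > 0
#' spot_inside(sp, c(5, 3))
#' @export
spot_geometry <- function(edge_point = c(0, 0), perpendicular = c(1, 0)) {
  stopifnot(length(edge_point) == 2, length(perpendicular) == 2)
  u <- .unit(as.numeric(perpendicular))
  structure(
    list(
      edge_point = as.numeric(edge_point),
      perpendicular = u,
      tangent = c(-u[2], u[1])
    ),
    class = "spot_geometry"
  )
}

#' @export
print.spot_geometry <- function(x, ...) {
  cat(sprintf(
    "spot edge through (%.1f, %.1f) um, interior direction (%.3f, %.3f)\n",
    x$edge_point[1], x$edge_point[2], x$perpendicular[1], x$perpendicular[2]
  ))
  invisible(x)
}

#' Signed distance from the spot edge
#'
#' Positive inside the spot (in the direction of the perpendicular),
#' negative outside.
#'
#' @param spot A [spot_geometry()].
#' @param xy Numeric length-2 point or an n x 2 matrix of points (µm).
#' @return Numeric vector of signed distances (µm).
#' @export
spot_signed_distance <- function(spot, xy) {
  stopifnot(inherits(spot, "spot_geometry"))
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  (xy[, 1] - spot$edge_point[1]) * spot$perpendicular[1] +
    (xy[, 2] - spot$edge_point[2]) * spot$perpendicular[2]
}

#' Is a point inside the spot?
#'
#' @inheritParams spot_signed_distance
#' @return Logical vector.
#' @export
spot_inside <- function(spot, xy) spot_signed_distance(spot, xy) > 0

#' Unsigned angle between a displacement vector and the spot perpendicular
#'
#' @param spot A [spot_geometry()].
#' @param v Numeric length-2 displacement vector (µm); need not be unit.
#' @return Angle in degrees in \[0, 180\].
#' @export
angle_to_perpendicular <- function(spot, v) {
  stopifnot(inherits(spot, "spot_geometry"), length(v) == 2)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero net displacement: migration angle undefined")
  ca <- sum(.unit(as.numeric(v)) * spot$perpendicular)
  .rad2deg(acos(pmin(1, pmax(-1, ca))))
}
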