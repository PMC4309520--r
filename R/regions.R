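# Front/middle/back polarity partition of a migrating cell. The migration
# axis is the line perpendicular to the agarose-spot edge; the cell-mask
# extent along this axis is divided into three equal lengths, with the
# front band nearest the spot interior. Counts are area-normalised
# downstream because the three bands generally differ in area.

#' Partition a cell mask into front/middle/back bands
#'
#' Projects the cell-mask pixels onto the migration axis (the spot
#' perpendicular), splits the projected extent into three equal-length
#' bands, and labels every mask pixel with its band. The front band is the
#' one nearest the spot interior. Points exactly on a band boundary are
#' assigned frontward.
#'
#' @param mask Logical or 0/1 matrix (rows = y, cols = x), non-empty. If
#'   the mask is disconnected the largest connected component is used, with
#'   a warning.
#' @param pixel_size_um Pixel size, µm/px.
#' @param spot A [spot_geometry()] giving the migration axis. Its
#'   perpendicular is interpreted in image coordinates (x = column,
#'   y = row, µm = (px - 1) * pixel_size).
#' @param bounded_by One of `"mask"` (default: band extent from the mask's
#'   own projected extent) or `"bbox"` (extent of the mask's bounding box
#'   projected onto the axis; differs from `"mask"` only for oblique axes).
#' @return An object of class `region_partition`: list with `axis` (unit
#'   vector, front direction), `extent` (projected min/max, µm),
#'   `boundaries` (back/middle and middle/front cut positions, µm),
#'   `labels` (integer matrix: 0 outside, 1 front, 2 middle, 3 back),
#'   `areas` (named µm² per region), `pixel_size_um`.
#' @export
partition_cell <- function(mask, pixel_size_um, spot,
                           bounded_by = c("mask", "bbox")) {
  bounded_by <- match.arg(bounded_by)
  stopifnot(is.matrix(mask), pixel_size_um > 0,
            inherits(spot, "spot_geometry"))
  m <- mask > 0
  if (!any(m)) stop("empty cell mask")
  lab <- EBImage::bwlabel(m + 0)
  ncomp <- max(lab)
  if (ncomp > 1) {
    warning("mask has ", ncomp, " components; using the largest")
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    m <- lab == which.max(sizes)
  }
  idx <- which(m, arr.ind = TRUE) # row, col
  x_um <- (idx[, 2] - 1) * pixel_size_um
  y_um <- (idx[, 1] - 1) * pixel_size_um
  u <- spot$perpendicular
  proj <- x_um * u[1] + y_um * u[2]
  extent <- if (bounded_by == "mask") {
    range(proj)
  } else {
    cx <- range(x_um); cy <- range(y_um)
    corners <- cbind(cx[c(1, 1, 2, 2)], cy[c(1, 2, 1, 2)])
    range(corners %*% u)
  }
  third <- diff(extent) / 3
  b1 <- extent[1] + third      # back/middle boundary
  b2 <- extent[1] + 2 * third  # middle/front boundary
  lab_img <- matrix(0L, nrow(mask), ncol(mask))
  band <- ifelse(proj >= b2, 1L, ifelse(proj >= b1, 2L, 3L))
  lab_img[idx] <- band
  areas <- c(front = sum(band == 1L), middle = sum(band == 2L),
             back = sum(band == 3L)) * pixel_size_um^2
  structure(
    list(axis = u, extent = extent, boundaries = c(b1, b2),
         labels = lab_img, areas = areas, pixel_size_um = pixel_size_um),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "region_partition: axis (%.2f, %.2f); areas F/M/B = %.1f/%.1f/%.1f um^2\n",
    x$axis[1], x$axis[2], x$areas["front"], x$areas["middle"],
    x$areas["back"]
  ))
  invisible(x)
}

#' Assign points to polarity regions
#'
#' Labels points by the band containing their projection onto the
#' migration axis; boundary points are assigned to the more frontward
#' band. Points outside the cell mask are labelled `"outside"` and should
#' be excluded from counts.
#'
#' @param xy_um Length-2 point or n x 2 matrix of (x, y) positions in µm.
#' @param partition A [partition_cell()] result.
#' @return Character vector of labels among `"front"`, `"middle"`,
#'   `"back"`, `"outside"`.
#' @export
assign_region <- function(xy_um, partition) {
  stopifnot(inherits(partition, "region_partition"))
  if (!is.matrix(xy_um)) xy_um <- matrix(xy_um, ncol = 2)
  psz <- partition$pixel_size_um
  col <- as.integer(round(xy_um[, 1] / psz + 1))
  row <- as.integer(round(xy_um[, 2] / psz + 1))
  inbounds <- col >= 1L & col <= ncol(partition$labels) &
    row >= 1L & row <= nrow(partition$labels)
  inside <- inbounds
  inside[inbounds] <- partition$labels[cbind(row[inbounds],
                                             col[inbounds])] > 0L
  proj <- xy_um %*% partition$axis
  b <- partition$boundaries
  band <- ifelse(proj >= b[2], "front", ifelse(proj >= b[1], "middle",
                                               "back"))
  ifelse(inside, band, "outside")
}

#' Area-normalised counts per polarity region
#'
#' Divides per-region object counts by the region areas, keeping the raw
#' counts alongside, as the three equal-length bands generally have
#' different areas.
#'
#' @param counts Named (front/middle/back) or length-3 numeric counts.
#' @param partition A [partition_cell()] result.
#' @return Data.frame with columns `region`, `count`, `area_um2`,
#'   `density_per_um2`.
#' @export
density_per_region <- function(counts, partition) {
  stopifnot(inherits(partition, "region_partition"))
  regions <- c("front", "middle", "back")
  if (is.null(names(counts))) {
    stopifnot(length(counts) == 3)
    names(counts) <- regions
  }
  counts <- counts[regions]
  counts[is.na(counts)] <- 0
  areas <- partition$areas[regions]
  if (any(areas <= 0)) stop("zero-area region; cannot normalise")
  data.frame(
    region = regions,
    count = as.numeric(counts),
    area_um2 = as.numeric(areas),
    density_per_um2 = as.numeric(counts) / as.numeric(areas),
    row.names = NULL
  )
}
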