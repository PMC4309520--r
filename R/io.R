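# Reading and writing the pipeline's interchange formats: track CSVs,
# multi-page TIFF stacks (with a JSON calibration sidecar), spot-geometry
# YAML and result JSON.

#' Write cell tracks to CSV
#'
#' Columns: id, frame, t_s, x_um, y_um and, when present, width_um /
#' length_um.
#'
#' @param tracks Long-format track table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(all(c("id", "frame", "t_s", "x_um", "y_um") %in% names(tracks)))
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Read cell tracks from CSV
#' @param path CSV written by [write_tracks_csv()] (columns id, frame,
#'   t_s, x_um, y_um, optionally width_um, length_um).
#' @return Long-format track data.frame ordered by id then frame.
#' @export
read_tracks_csv <- function(path) {
  tr <- read.csv(path)
  need <- c("id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tr))) {
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  }
  tr[order(tr$id, tr$frame), ]
}

#' Write a timelapse stack as multi-page TIFF
#'
#' One 32-bit float TIFF per channel (frames as pages) plus a JSON sidecar
#' (`<stem>_meta.json`) carrying pixel size, frame interval and channel
#' names.
#'
#' @param stack A [timelapse_stack()].
#' @param stem Output path stem; files are `<stem>_<channel>.tif`.
#' @return Invisibly, the paths written.
#' @export
write_stack_tiff <- function(stack, stem) {
  stopifnot(inherits(stack, "timelapse_stack"))
  chn <- names(stack$channels)
  if (is.null(chn)) chn <- paste0("ch", seq_along(stack$channels))
  paths <- character(0)
  ranges <- list()
  for (k in seq_along(stack$channels)) {
    ch <- stack$channels[[k]]
    rg <- range(ch)
    if (diff(rg) == 0) rg[2] <- rg[1] + 1
    ranges[[chn[k]]] <- rg
    # TIFF samples must lie in [0, 1]; the grey-value range is recorded in
    # the sidecar and restored on read
    pages <- lapply(seq_len(dim(ch)[3]),
                    function(f) (ch[, , f] - rg[1]) / diff(rg))
    p <- paste0(stem, "_", chn[k], ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 32L)
    paths <- c(paths, p)
  }
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               channels = chn, ranges = ranges)
  mp <- paste0(stem, "_meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read a timelapse stack written by [write_stack_tiff()]
#' @param stem The path stem used when writing.
#' @return A [timelapse_stack()].
#' @export
read_stack_tiff <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(chn) {
    pages <- tiff::readTIFF(paste0(stem, "_", chn, ".tif"), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    rg <- meta$ranges[[chn]]
    arr <- array(NA_real_, dim = c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * diff(rg) + rg[1]
    arr
  })
  names(channels) <- meta$channels
  timelapse_stack(channels, meta$pixel_size_um, meta$frame_interval_s,
                  channel_names = meta$channels)
}

#' Read spot geometry from a YAML config
#'
#' Expected keys: `edge_point` (x, y in µm) and `perpendicular` (vector
#' into the spot interior).
#'
#' @param path YAML file.
#' @return A [spot_geometry()].
#' @export
read_spot_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$edge_point) || is.null(y$perpendicular)) {
    stop("spot YAML needs keys 'edge_point' and 'perpendicular'")
  }
  spot_geometry(as.numeric(y$edge_point), as.numeric(y$perpendicular))
}

#' Write spot geometry to YAML
#' @param spot A [spot_geometry()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_spot_yaml <- function(spot, path) {
  stopifnot(inherits(spot, "spot_geometry"))
  yaml::write_yaml(list(edge_point = spot$edge_point,
                        perpendicular = spot$perpendicular), path)
  invisible(path)
}

#' Write the tracks and events of a synthetic field as ground-truth CSVs
#'
#' Tracks as (id, frame, x_um, y_um) plus a JSON echo of the preset and
#' seed, mirroring the run-manifest convention.
#'
#' @param field A [make_spot_field()] result.
#' @param out_dir Output directory.
#' @param seed The seed used to generate the field (echoed).
#' @return Invisibly, the paths written.
#' @export
write_field_truth <- function(field, out_dir, seed = NULL) {
  stopifnot(inherits(field, "field_ground_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tp <- file.path(out_dir, "tracks.csv")
  write.csv(field$tracks, tp, row.names = FALSE)
  mp <- file.path(out_dir, "field.json")
  jsonlite::write_json(
    list(preset = field$preset$name, seed = seed,
         migrated_ids = field$migrated_ids,
         spot = list(edge_point = field$spot$edge_point,
                     perpendicular = field$spot$perpendicular)),
    mp, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tp, mp))
}
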