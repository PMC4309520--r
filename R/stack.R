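#' Calibrated timelapse image stack
#'
#' Container for a one- or multi-channel grayscale timelapse. Each channel
#' is a numeric array of dimension (rows, cols, frames); all channels share
#' the same geometry and calibration. Pixel (i, j) has its centre at
#' x = j, y = i in pixel units and at `(px - 1) * pixel_size_um` in µm.
#'
#' @param channels A numeric 3d array, a matrix (single frame) or a list of
#'   such arrays (one per channel).
#' @param pixel_size_um Pixel size, µm per pixel.
#' @param frame_interval_s Frame interval, seconds.
#' @param channel_names Optional character vector naming the channels.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(channels, pixel_size_um, frame_interval_s,
                            channel_names = NULL) {
  if (!is.list(channels)) channels <- list(channels)
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    stopifnot(length(dim(ch)) == 3)
    ch
  })
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d))
  stopifnot(pixel_size_um > 0, frame_interval_s > 0)
  if (!is.null(channel_names)) names(channels) <- channel_names
  structure(
    list(
      channels = channels,
      pixel_size_um = pixel_size_um,
      frame_interval_s = frame_interval_s
    ),
    class = "timelapse_stack"
  )
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "timelapse_stack: %d channel(s), %d x %d px, %d frame(s), %.3g um/px, %.3g s/frame\n",
    length(x$channels), d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s
  ))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [timelapse_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$channels[[1]])[3]

#' Extract one frame of one channel as a matrix
#' @param stack A [timelapse_stack()].
#' @param frame Frame index (1-based).
#' @param channel Channel index or name.
#' @return Numeric matrix (rows x cols).
#' @export
get_frame <- function(stack, frame, channel = 1L) {
  stopifnot(inherits(stack, "timelapse_stack"))
  stack$channels[[channel]][, , frame]
}
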