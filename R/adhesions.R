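# Focal-adhesion detection, per-region counts, disassembly timing from
# intensity traces, and the clathrin-recruitment test.

#' Detect focal adhesions in one frame
#'
#' Background-subtracted threshold segmentation followed by connected-
#' component labelling and a size filter. The default threshold adapts to
#' the frame: background plus half the (99.9th-percentile) object
#' amplitude, floored at `k_sigma` noise SDs so blank frames yield nothing.
#' Shape is summarised by the intensity-weighted second moments (fitted
#' ellipse: centroid, major/minor semi-axes, orientation, elongation).
#'
#' @param img Numeric matrix (rows = y, cols = x).
#' @param pixel_size_um Pixel size, µm/px.
#' @param size_range_um2 Accepted object area range, µm² (default
#'   0.25–15).
#' @param k_sigma Noise floor of the threshold, in robust noise SDs.
#' @param halfmax Use the half-amplitude component of the threshold
#'   (default TRUE; recovers the object outline of plateau-like objects).
#' @return An object of class `fa_set`: list with `table` (data.frame:
#'   id, x_px, y_px, area_px, area_um2, major_px, minor_px, elongation,
#'   theta) and `labels` (integer label matrix matching `table$id`).
#' @export
detect_fas <- function(img, pixel_size_um, size_range_um2 = c(0.25, 15),
                       k_sigma = 4, halfmax = TRUE) {
  stopifnot(is.matrix(img), pixel_size_um > 0)
  bg <- median(img)
  noise <- mad(img)
  thr <- bg + k_sigma * noise
  if (halfmax) {
    hi <- quantile(img, 0.999, names = FALSE)
    thr <- max(thr, bg + 0.5 * (hi - bg))
  }
  bw <- img > thr
  lab <- EBImage::bwlabel(bw + 0)
  nlab <- max(lab)
  empty <- list(
    table = data.frame(id = integer(0), x_px = numeric(0),
                       y_px = numeric(0), area_px = numeric(0),
                       area_um2 = numeric(0), major_px = numeric(0),
                       minor_px = numeric(0), elongation = numeric(0),
                       theta = numeric(0)),
    labels = matrix(0L, nrow(img), ncol(img))
  )
  if (nlab == 0) return(structure(empty, class = "fa_set"))
  px_area <- pixel_size_um^2
  rows <- vector("list", nlab)
  newlab <- matrix(0L, nrow(img), ncol(img))
  next_id <- 0L
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    area_um2 <- nrow(idx) * px_area
    if (area_um2 < size_range_um2[1] || area_um2 > size_range_um2[2]) next
    w <- img[idx] - bg
    w <- pmax(w, 0)
    sw <- sum(w)
    cx <- sum(idx[, 2] * w) / sw
    cy <- sum(idx[, 1] * w) / sw
    mxx <- sum((idx[, 2] - cx)^2 * w) / sw
    myy <- sum((idx[, 1] - cy)^2 * w) / sw
    mxy <- sum((idx[, 2] - cx) * (idx[, 1] - cy) * w) / sw
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)
    major <- 2 * sqrt(max(ev$values[1], 1e-12))
    minor <- 2 * sqrt(max(ev$values[2], 1e-12))
    theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
    next_id <- next_id + 1L
    newlab[idx] <- next_id
    rows[[next_id]] <- data.frame(
      id = next_id, x_px = cx, y_px = cy, area_px = nrow(idx),
      area_um2 = area_um2, major_px = major, minor_px = minor,
      elongation = major / minor, theta = theta
    )
  }
  if (next_id == 0L) return(structure(empty, class = "fa_set"))
  structure(list(table = do.call(rbind, rows[seq_len(next_id)]),
                 labels = newlab),
            class = "fa_set")
}

#' @export
print.fa_set <- function(x, ...) {
  cat(sprintf("fa_set: %d focal adhesions\n", nrow(x$table)))
  invisible(x)
}

#' Count focal adhesions per polarity region
#'
#' Counts detected adhesions by the region containing their centroid and
#' normalises by region area.
#'
#' @param fas An [detect_fas()] result (or its `table`).
#' @param partition A [partition_cell()] result.
#' @param pixel_size_um Pixel size, µm/px.
#' @return Data.frame as [density_per_region()].
#' @export
count_fas_per_region <- function(fas, partition, pixel_size_um) {
  tab <- if (inherits(fas, "fa_set")) fas$table else fas
  regions <- c("front", "middle", "back")
  if (nrow(tab) > 0) {
    xy <- cbind((tab$x_px - 1) * pixel_size_um,
                (tab$y_px - 1) * pixel_size_um)
    lab <- assign_region(xy, partition)
    counts <- vapply(regions, function(r) sum(lab == r), numeric(1))
  } else {
    counts <- setNames(rep(0, 3), regions)
  }
  density_per_region(counts, partition)
}

#' Integrated intensity traces of focal adhesions across a stack
#'
#' Measures, for every detected adhesion, the background-subtracted
#' integrated intensity within its (reference-frame) mask in every frame.
#' Adhesions in this assay are positionally stable over the disassembly
#' window, so a fixed mask tracks each object.
#'
#' @param stack A [timelapse_stack()].
#' @param fas An [detect_fas()] result from the reference frame.
#' @param channel Channel index or name.
#' @return Matrix (frames x adhesions) of integrated intensities.
#' @export
fa_traces <- function(stack, fas, channel = 1L) {
  stopifnot(inherits(stack, "timelapse_stack"), inherits(fas, "fa_set"))
  ids <- fas$table$id
  nf <- n_frames(stack)
  out <- matrix(NA_real_, nf, length(ids),
                dimnames = list(NULL, as.character(ids)))
  masks <- lapply(ids, function(i) fas$labels == i)
  for (f in seq_len(nf)) {
    img <- get_frame(stack, f, channel)
    bg <- median(img)
    for (k in seq_along(ids)) {
      out[f, k] <- sum(img[masks[[k]]] - bg)
    }
  }
  out
}

#' Disassembly time from an adhesion intensity trace
#'
#' Onset is the last frame at or above 90% of the pre-decline plateau
#' (plateau = median of the frames near the trace's upper level); end is
#' the first subsequent frame at or below background + 2 noise SDs. The
#' disassembly time is `(end - onset) * frame_interval` in minutes. A
#' trace that never declines below the end threshold is censored
#' (returns NULL). The measurement is invariant to rescaling the whole
#' trace by a positive constant.
#'
#' @param trace Numeric vector of background-subtracted integrated
#'   intensities, one per frame.
#' @param frame_interval_s Frame interval, seconds.
#' @param noise_sd Noise SD of the trace; estimated from first differences
#'   (`mad(diff(trace)) / sqrt(2)`) when NULL.
#' @param plateau_frac Onset threshold as a fraction of the plateau.
#' @return A one-row data.frame (`onset_frame`, `end_frame`,
#'   `disassembly_min`) or NULL when censored.
#' @export
disassembly_time <- function(trace, frame_interval_s, noise_sd = NULL,
                             plateau_frac = 0.9) {
  stopifnot(length(trace) >= 3, frame_interval_s > 0)
  if (is.null(noise_sd)) noise_sd <- mad(diff(trace)) / sqrt(2)
  plateau <- median(trace[trace >= 0.75 * quantile(trace, 0.95,
                                                   names = FALSE)])
  if (plateau <= 2 * noise_sd) return(NULL) # never above background
  end_thr <- max(2 * noise_sd, 0.05 * plateau)
  onset <- max(which(trace >= plateau_frac * plateau))
  below <- which(seq_along(trace) > onset & trace <= end_thr)
  if (length(below) == 0) return(NULL) # censored: decline incomplete
  end <- min(below)
  data.frame(onset_frame = onset, end_frame = end,
             disassembly_min = (end - onset) * frame_interval_s / 60)
}

#' Fraction of focal adhesions containing a punctum
#'
#' An adhesion is positive when any punctum centroid falls within its mask
#' dilated by `dilate_px` (disc structuring element). When a disassembly
#' window and frame-resolved puncta are supplied, a per-adhesion
#' recruitment flag records whether positivity occurred during the window.
#'
#' @param fas An [detect_fas()] result.
#' @param puncta Data.frame of punctum detections (`x_px`, `y_px`,
#'   optionally `frame`).
#' @param dilate_px Dilation radius, px.
#' @param windows Optional data.frame (`id`, `onset_frame`, `end_frame`)
#'   of disassembly windows per adhesion id.
#' @return List with `fraction` (positive adhesions / total), `positive`
#'   (logical per adhesion) and, when windows are given, `recruited`
#'   (logical per adhesion: positive during its disassembly window).
#' @export
clathrin_at_fa <- function(fas, puncta, dilate_px = 3, windows = NULL) {
  stopifnot(inherits(fas, "fa_set"))
  tab <- fas$table
  if (nrow(tab) == 0) return(list(fraction = NA_real_,
                                  positive = logical(0)))
  brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "disc")
  n <- nrow(fas$labels); m <- ncol(fas$labels)
  pr <- pmax(1L, pmin(n, as.integer(round(puncta$y_px))))
  pc <- pmax(1L, pmin(m, as.integer(round(puncta$x_px))))
  positive <- logical(nrow(tab))
  recruited <- if (!is.null(windows)) logical(nrow(tab)) else NULL
  for (k in seq_len(nrow(tab))) {
    md <- EBImage::dilate((fas$labels == tab$id[k]) + 0, brush) > 0
    inmask <- md[cbind(pr, pc)]
    positive[k] <- any(inmask)
    if (!is.null(windows) && "frame" %in% names(puncta)) {
      w <- windows[windows$id == tab$id[k], ]
      if (nrow(w) == 1 && !is.na(w$onset_frame)) {
        recruited[k] <- any(inmask & puncta$frame >= w$onset_frame &
                              puncta$frame <= w$end_frame)
      }
    }
  }
  out <- list(fraction = mean(positive), positive = positive)
  if (!is.null(recruited)) out$recruited <- recruited
  out
}

#' Compare disassembly-time groups
#'
#' Group means, standard errors and a two-sample test of each group
#' against the first. The default test is Mann–Whitney U (rank-based,
#' robust to the skewed time distributions typical of these assays); a
#' Welch t-test is available by flag.
#'
#' @param groups Named list of numeric vectors of disassembly times
#'   (minutes); at least 2 groups of at least 3 measurements each.
#' @param test `"wilcox"` (default) or `"welch"`.
#' @return List with `summary` (data.frame: group, n, mean, se) and
#'   `tests` (data.frame: group, p_value vs the first group).
#' @export
compare_disassembly <- function(groups, test = c("wilcox", "welch")) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop("each group needs at least 3 measurements")
  }
  summ <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    se = vapply(groups, function(g) sd(g) / sqrt(length(g)), numeric(1)),
    row.names = NULL
  )
  ref <- groups[[1]]
  tests <- lapply(names(groups)[-1], function(g) {
    p <- if (test == "wilcox") {
      suppressWarnings(wilcox.test(ref, groups[[g]])$p.value)
    } else {
      t.test(ref, groups[[g]])$p.value
    }
    data.frame(group = g, p_value = p)
  })
  list(summary = summ, tests = do.call(rbind, tests))
}
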