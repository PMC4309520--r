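# Detection, linking and event calling for diffraction-limited TIRF
# puncta. Detection is scale-space (Laplacian-of-Gaussian) blob detection
# with sub-pixel refinement; linking is greedy nearest-neighbour with gap
# closing; endocytic disappearance events require all three criteria: the
# drop is rapid (within the frame window), the punctum does not reappear
# nearby within the window, and the drop is not attributable to global
# photobleaching.

# Mean-subtracted inverted-LoG kernel: positive centre, negative ring,
# zero total weight so a flat background contributes nothing.
.log_kernel <- function(sigma) {
  w <- ceiling(4 * sigma)
  d <- (-w):w
  r2 <- outer(d^2, d^2, "+")
  k <- (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

# Robust global background and noise-SD estimates for one frame.
.frame_bg <- function(img) {
  c(bg = median(img), noise = mad(img))
}

#' Detect diffraction-limited puncta in one frame
#'
#' Laplacian-of-Gaussian blob detection at the configured scale: the frame
#' is convolved with a zero-mean inverted-LoG kernel, local maxima of the
#' response above `k_sigma` times the robust response noise are kept, and
#' centres are refined to sub-pixel precision by an intensity-weighted
#' centroid of the response in a 5x5 window.
#'
#' @param img Numeric matrix (one frame, rows = y, cols = x).
#' @param sigma_px Blob scale (Gaussian sigma), px.
#' @param k_sigma Detection threshold in units of the robust (MAD) noise of
#'   the LoG response; the default 5 gives well under one false positive
#'   per frame on pure noise.
#' @param saturation_level Optional grey level at which the detector warns
#'   about saturation (detection still proceeds).
#' @return Data.frame with columns `x_px`, `y_px` (sub-pixel), `intensity`
#'   (peak minus background), `bg` (background estimate), `response`.
#' @export
detect_puncta <- function(img, sigma_px = 1.5, k_sigma = 5,
                          saturation_level = NULL) {
  stopifnot(is.matrix(img))
  if (!is.null(saturation_level) && any(img >= saturation_level)) {
    warning("frame contains saturated pixels; detection proceeds")
  }
  K <- .log_kernel(sigma_px)
  resp <- EBImage::filter2(img, K)
  thr <- k_sigma * mad(resp)
  n <- nrow(img); m <- ncol(img)
  # 8-neighbour local maxima strictly inside a 2 px border
  cand <- which(resp > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 2 & cand[, 1] < n - 1 &
                 cand[, 2] > 2 & cand[, 2] < m - 1, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    v <- resp[i, j]
    nb <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
    keep[k] <- v >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  bgst <- .frame_bg(img)
  if (nrow(cand) == 0) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), bg = numeric(0),
                      response = numeric(0)))
  }
  out <- matrix(NA_real_, nrow(cand), 3L)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    r0 <- max(1L, i - 2L):min(n, i + 2L)
    c0 <- max(1L, j - 2L):min(m, j + 2L)
    w <- pmax(resp[r0, c0], 0)
    sw <- sum(w)
    out[k, 1] <- sum(rep(c0, each = length(r0)) * w) / sw # x
    out[k, 2] <- sum(rep(r0, times = length(c0)) * w) / sw # y
    out[k, 3] <- img[i, j] - bgst["bg"]
  }
  data.frame(x_px = out[, 1], y_px = out[, 2], intensity = out[, 3],
             bg = as.numeric(bgst["bg"]), response = as.numeric(resp[cand]))
}

#' Detect puncta in every frame of a stack
#'
#' @param stack A [timelapse_stack()].
#' @param channel Channel index or name.
#' @inheritParams detect_puncta
#' @return Data.frame as [detect_puncta()] with an added `frame` column.
#' @export
detect_puncta_stack <- function(stack, channel = 1L, sigma_px = 1.5,
                                k_sigma = 5) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nf <- n_frames(stack)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- detect_puncta(get_frame(stack, f, channel), sigma_px, k_sigma)
    if (nrow(d) > 0) d$frame <- f
    out[[f]] <- d
  }
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
  if (is.null(out)) {
    out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), bg = numeric(0),
                      response = numeric(0), frame = integer(0))
  }
  out
}

#' Link per-frame detections into punctum tracks
#'
#' Greedy nearest-neighbour linking: within each frame, candidate matches
#' between open tracks and detections are assigned in order of increasing
#' distance (ties broken by lowest track id), accepting only matches
#' within `max_step_px`. Tracks missing a detection stay open for up to
#' `max_gap` frames, then close.
#'
#' @param detections Data.frame from [detect_puncta_stack()] (columns
#'   `frame`, `x_px`, `y_px`, `intensity`).
#' @param max_step_px Maximum link distance per step, px.
#' @param max_gap Maximum number of consecutive missed frames bridged.
#' @return Data.frame of linked detections with a `track_id` column,
#'   ordered by track then frame.
#' @export
link_puncta <- function(detections, max_step_px = 2, max_gap = 2) {
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  if (nrow(detections) == 0) {
    return(cbind(detections, track_id = integer(0)))
  }
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2) {
    detections$track_id <- seq_len(nrow(detections))
    return(detections)
  }
  detections$track_id <- NA_integer_
  next_id <- 1L
  # open tracks: id, last frame, last x, last y
  open <- data.frame(id = integer(0), frame = integer(0),
                     x = numeric(0), y = numeric(0))
  for (f in frames) {
    di <- which(detections$frame == f)
    open <- open[f - open$frame - 1L <= max_gap, , drop = FALSE]
    if (nrow(open) > 0 && length(di) > 0) {
      dd <- expand.grid(oi = seq_len(nrow(open)), ki = seq_along(di))
      dd$dist <- sqrt(
        (open$x[dd$oi] - detections$x_px[di[dd$ki]])^2 +
          (open$y[dd$oi] - detections$y_px[di[dd$ki]])^2
      )
      dd <- dd[dd$dist <= max_step_px, , drop = FALSE]
      dd <- dd[order(dd$dist, open$id[dd$oi]), , drop = FALSE]
      used_o <- logical(nrow(open)); used_k <- logical(length(di))
      for (r in seq_len(nrow(dd))) {
        oi <- dd$oi[r]; ki <- dd$ki[r]
        if (!used_o[oi] && !used_k[ki]) {
          used_o[oi] <- TRUE; used_k[ki] <- TRUE
          id <- open$id[oi]
          detections$track_id[di[ki]] <- id
          open$frame[oi] <- f
          open$x[oi] <- detections$x_px[di[ki]]
          open$y[oi] <- detections$y_px[di[ki]]
        }
      }
      di_new <- di[!used_k]
    } else {
      di_new <- di
    }
    for (ki in di_new) {
      detections$track_id[ki] <- next_id
      open <- rbind(open, data.frame(id = next_id, frame = f,
                                     x = detections$x_px[ki],
                                     y = detections$y_px[ki]))
      next_id <- next_id + 1L
    }
  }
  detections[order(detections$track_id, detections$frame), ]
}

# Background-subtracted punctum intensity measured in the stack: mean of
# the 3x3 neighbourhood of (x, y) minus the frame's robust background.
.measure_punctum <- function(img, x, y, bg = NULL) {
  if (is.null(bg)) bg <- median(img)
  i <- max(2L, min(nrow(img) - 1L, round(y)))
  j <- max(2L, min(ncol(img) - 1L, round(x)))
  mean(img[(i - 1):(i + 1), (j - 1):(j + 1)]) - bg
}

#' Classify punctum-track fates
#'
#' Each linked track gets one fate: `lateral` if its net displacement is at
#' least `lateral_threshold_um`; otherwise `disappearing` if the track ends
#' before the end of the stack and the intensity at its terminal position
#' falls to background; `static` if it survives to the final frame; and
#' `censored` if it ends early without a clean drop to background (for
#' example a detection dropout).
#'
#' @param tracks Linked detections from [link_puncta()].
#' @param stack The [timelapse_stack()] the detections came from.
#' @param channel Channel index or name.
#' @param lateral_threshold_um Net-displacement threshold for the lateral
#'   fate, µm.
#' @return Data.frame with one row per track: `track_id`, `fate`,
#'   `net_disp_um`, `first_frame`, `last_frame`, `x_end_px`, `y_end_px`,
#'   `x0_px`, `y0_px`.
#' @export
classify_fates <- function(tracks, stack, channel = 1L,
                           lateral_threshold_um = 0.5) {
  stopifnot(inherits(stack, "timelapse_stack"))
  nf <- n_frames(stack)
  psz <- stack$pixel_size_um
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    nlast <- nrow(tr)
    disp <- sqrt((tr$x_px[nlast] - tr$x_px[1])^2 +
                   (tr$y_px[nlast] - tr$y_px[1])^2) * psz
    last <- tr$frame[nlast]
    fate <- if (disp >= lateral_threshold_um) {
      "lateral"
    } else if (last >= nf) {
      "static"
    } else {
      # ended early: at background at the terminal position? Check the two
      # frames after the track end (the drop may span a half-intensity
      # frame) and take the dimmer one.
      v <- vapply(seq.int(last + 1L, min(nf, last + 2L)), function(f) {
        img <- get_frame(stack, f, channel)
        st <- .frame_bg(img)
        .measure_punctum(img, tr$x_px[nlast], tr$y_px[nlast], st["bg"]) /
          st["noise"]
      }, numeric(1))
      if (min(v) <= 2) "disappearing" else "censored"
    }
    data.frame(track_id = id, fate = fate, net_disp_um = disp,
               first_frame = tr$frame[1], last_frame = last,
               x_end_px = tr$x_px[nlast], y_end_px = tr$y_px[nlast],
               x0_px = tr$x_px[1], y0_px = tr$y_px[1])
  })
  do.call(rbind, out)
}

#' Call an endocytic disappearance event for one track
#'
#' A punctum leaving the evanescent field counts as an internalisation
#' event only when all three criteria hold: (1) *rapid* — the intensity at
#' the track position falls from its pre-event plateau (last frame at or
#' above 90% of the plateau) to at most background plus twice the noise SD
#' within `window` frames, counted inclusively; (2) *no reappearance* — no
#' detection occurs within `reappear_radius_px` of the terminal position
#' during the `window` frames after the track ends; (3) *not
#' photobleaching* — the cell-wide mean intensity declines by less than
#' `bleach_tolerance` over the event window. Tracks ending within `window`
#' frames of the end of the stack are censored (reappearance cannot be
#' evaluated) and yield no event.
#'
#' @param track One track's rows from [link_puncta()] (a single
#'   `track_id`).
#' @param stack The [timelapse_stack()].
#' @param detections All detections in the stack (for the reappearance
#'   test), e.g. the full [link_puncta()] output.
#' @param channel Channel index or name.
#' @param window Event window, frames (default 10).
#' @param reappear_radius_px Radius for the reappearance test, px.
#' @param bleach_tolerance Maximum tolerated fractional decline of the
#'   cell-wide mean over the event window (default 0.1).
#' @param mask Optional logical cell mask restricting the cell-wide mean.
#' @return A one-row data.frame (`track_id`, `frame`, `x_px`, `y_px`, and
#'   logical criteria columns `rapid`, `no_reappearance`,
#'   `not_photobleaching`) when an event is emitted, otherwise `NULL`.
#' @export
call_disappearance <- function(track, stack, detections, channel = 1L,
                               window = 10L, reappear_radius_px = 3,
                               bleach_tolerance = 0.1, mask = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"))
  track <- track[order(track$frame), ]
  nf <- n_frames(stack)
  end <- track$frame[nrow(track)]
  if (end + window > nf) return(NULL) # censored: cannot assess reappearance
  xe <- track$x_px[nrow(track)]; ye <- track$y_px[nrow(track)]

  # intensity trace at the track (then terminal) position
  f0 <- max(1L, end - window)
  fr <- f0:min(nf, end + window)
  trace <- vapply(fr, function(f) {
    img <- get_frame(stack, f, channel)
    row <- track[track$frame == f, ]
    if (nrow(row) == 1) {
      .measure_punctum(img, row$x_px, row$y_px)
    } else {
      .measure_punctum(img, xe, ye)
    }
  }, numeric(1))
  img_end <- get_frame(stack, end, channel)
  noise <- .frame_bg(img_end)["noise"]

  pre <- trace[fr <= end]
  # robust plateau: median of the upper half of the pre-event trace, so a
  # decline already under way does not drag the plateau (and with it the
  # last-bright frame) downward
  plateau <- median(pre[pre >= median(pre)])
  if (plateau <= 2 * noise) return(NULL) # never bright: nothing to call
  last_bright <- max(fr[fr <= end & trace >= 0.9 * plateau])
  dropped <- fr > last_bright & trace <= 2 * noise
  if (!any(dropped)) return(NULL) # never reaches background
  f_drop <- min(fr[dropped])
  rapid <- (f_drop - last_bright) <= window

  post <- detections[detections$frame > end &
                       detections$frame <= end + window, , drop = FALSE]
  reappeared <- nrow(post) > 0 &&
    any(sqrt((post$x_px - xe)^2 + (post$y_px - ye)^2) <= reappear_radius_px)
  no_reappearance <- !reappeared

  mean_at <- function(f) {
    img <- get_frame(stack, f, channel)
    if (is.null(mask)) mean(img) else mean(img[mask])
  }
  w0 <- max(1L, end - window); w1 <- min(nf, end + window)
  decline <- 1 - mean_at(w1) / mean_at(w0)
  not_photobleaching <- decline < bleach_tolerance

  if (rapid && no_reappearance && not_photobleaching) {
    data.frame(track_id = track$track_id[1], frame = end,
               x_px = xe, y_px = ye, rapid = rapid,
               no_reappearance = no_reappearance,
               not_photobleaching = not_photobleaching)
  } else {
    NULL
  }
}

#' Call disappearance events for all tracks in a stack
#'
#' Runs [call_disappearance()] over every track whose fate is
#' `disappearing` (per [classify_fates()]).
#'
#' @inheritParams call_disappearance
#' @param tracks Linked detections from [link_puncta()].
#' @param fates Optional precomputed [classify_fates()] table.
#' @param lateral_threshold_um Passed to [classify_fates()].
#' @return Data.frame of events (possibly 0 rows).
#' @export
call_disappearance_all <- function(tracks, stack, channel = 1L,
                                   window = 10L, reappear_radius_px = 3,
                                   bleach_tolerance = 0.1, mask = NULL,
                                   fates = NULL,
                                   lateral_threshold_um = 0.5) {
  if (is.null(fates)) {
    fates <- classify_fates(tracks, stack, channel, lateral_threshold_um)
  }
  cand <- fates$track_id[fates$fate == "disappearing"]
  ev <- lapply(cand, function(id) {
    call_disappearance(tracks[tracks$track_id == id, ], stack, tracks,
                       channel, window, reappear_radius_px,
                       bleach_tolerance, mask)
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) {
    ev <- data.frame(track_id = integer(0), frame = integer(0),
                     x_px = numeric(0), y_px = numeric(0),
                     rapid = logical(0), no_reappearance = logical(0),
                     not_photobleaching = logical(0))
  }
  ev
}

#' Per-region disappearance-event counts and densities
#'
#' Counts events by polarity region and normalises by region area; when
#' per-region spot totals are supplied, also reports events as a fraction
#' of total spots in each region.
#'
#' @param events Event table from [call_disappearance_all()] (columns
#'   `x_px`, `y_px`).
#' @param partition A [partition_cell()] result.
#' @param pixel_size_um Pixel size used to convert event positions to µm.
#' @param total_spots Optional named (front/middle/back) spot totals.
#' @return Data.frame with columns `region`, `count`, `area_um2`,
#'   `density_per_um2` and, when `total_spots` is given,
#'   `fraction_of_spots`.
#' @export
events_per_region <- function(events, partition, pixel_size_um,
                              total_spots = NULL) {
  regions <- c("front", "middle", "back")
  if (nrow(events) > 0) {
    xy <- cbind((events$x_px - 1) * pixel_size_um,
                (events$y_px - 1) * pixel_size_um)
    lab <- assign_region(xy, partition)
    counts <- vapply(regions, function(r) sum(lab == r), numeric(1))
  } else {
    counts <- setNames(rep(0, 3), regions)
  }
  out <- density_per_region(counts, partition)
  if (!is.null(total_spots)) {
    tot <- total_spots[regions]
    out$fraction_of_spots <- ifelse(tot > 0, out$count / as.numeric(tot),
                                    NA_real_)
  }
  out
}

#' Per-region dynamic fraction of puncta
#'
#' Fraction of punctum tracks per polarity region whose fate is dynamic
#' (lateral or disappearing), optionally restricted to spots present in
#' the first frame of the video; also reports the per-area dynamic counts.
#'
#' @param tracks Linked detections from [link_puncta()].
#' @param fates A [classify_fates()] table.
#' @param partition A [partition_cell()] result.
#' @param pixel_size_um Pixel size, µm/px.
#' @param first_frame_only Restrict to tracks whose first detection is in
#'   frame 1 (default TRUE: follow every spot present in the first image).
#' @return Data.frame with columns `region`, `n_spots`, `n_dynamic`,
#'   `fraction` (NA where a region has no spots), `area_um2`,
#'   `dynamic_per_um2`.
#' @export
dynamic_fraction <- function(tracks, fates, partition, pixel_size_um,
                             first_frame_only = TRUE) {
  regions <- c("front", "middle", "back")
  f <- fates
  if (first_frame_only) f <- f[f$first_frame == 1L, , drop = FALSE]
  if (nrow(f) > 0) {
    xy <- cbind((f$x0_px - 1) * pixel_size_um,
                (f$y0_px - 1) * pixel_size_um)
    lab <- assign_region(xy, partition)
  } else {
    lab <- character(0)
  }
  dyn <- f$fate %in% c("lateral", "disappearing")
  n_spots <- vapply(regions, function(r) sum(lab == r), numeric(1))
  n_dyn <- vapply(regions, function(r) sum(lab == r & dyn), numeric(1))
  areas <- partition$areas[regions]
  data.frame(
    region = regions,
    n_spots = n_spots,
    n_dynamic = n_dyn,
    fraction = ifelse(n_spots > 0, n_dyn / n_spots, NA_real_),
    area_um2 = as.numeric(areas),
    dynamic_per_um2 = n_dyn / as.numeric(areas),
    row.names = NULL
  )
}
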