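# Synthetic-data generator: spot-assay migration fields and TIRF-like
# timelapses with planted ground truth. The generator defines the study
# conditions for the whole package: treatment presets are frozen constants
# encoding the printed effect sizes, and the per-step angular-noise constant
# is a one-time calibration chosen so the control ensemble's mean unsigned
# migration angle is 2.80 degrees.

# ---------------------------------------------------------------------------
# Treatment presets (frozen, versioned constants)

# Calibrated per-step heading-noise SD (degrees) for the biased-persistent
# walk; fixed by bisection so that control-preset migrating tracks have a
# mean unsigned displacement angle of 2.80 degrees to the spot perpendicular
# (persistence 0.7, 84 steps of 10 min).
.ANGLE_NOISE_SD_DEG <- 9.72

.PRESET_TABLE <- local({
  ctl <- list(
    name = "control",
    migration_probability = 0.5,
    speed_scale = 1,
    persistence = 0.7
  )
  list(
    control = ctl,
    # non-silencing control siRNA: identical to control in expectation
    nsc_sirna = modifyList(ctl, list(name = "nsc_sirna")),
    # caveolin1 knock-down: no effect on migration
    cav1_sirna = modifyList(ctl, list(name = "cav1_sirna")),
    # dynamin inhibition: 60% fewer migrated cells, half speed
    dynasore = modifyList(ctl, list(
      name = "dynasore",
      migration_probability = 0.4 * ctl$migration_probability,
      speed_scale = 0.5
    )),
    # AP2 (alpha-adaptin) knock-down: 65% fewer migrated cells
    alpha_adaptin_sirna = modifyList(ctl, list(
      name = "alpha_adaptin_sirna",
      migration_probability = 0.35 * ctl$migration_probability
    ))
  )
})

#' Treatment presets for the synthetic migration field
#'
#' Returns the frozen parameter set for a named treatment condition. The
#' presets encode the relative effect sizes of dynamin inhibition (Dynasore:
#' migration probability 0.4x control, speed 0.5x control), AP2/alpha-adaptin
#' knock-down (migration probability 0.35x control) and caveolin1 knock-down
#' (identical to control), with the non-silencing control siRNA also
#' identical to control. Presets are versioned constants, not silently
#' user-tunable.
#'
#' @param name One of `"control"`, `"dynasore"`, `"nsc_sirna"`,
#'   `"alpha_adaptin_sirna"`, `"cav1_sirna"`.
#' @return An object of class `treatment_preset`: a list with fields
#'   `name`, `migration_probability`, `speed_scale` and `persistence`.
#' @examples
#' treatment_preset("dynasore")$migration_probability  # 0.4 x control
#' @export
treatment_preset <- function(name) {
  if (inherits(name, "treatment_preset")) return(name)
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.PRESET_TABLE)) {
    stop(
      "unknown treatment preset: ", deparse(substitute(name)),
      "; available: ", paste(names(.PRESET_TABLE), collapse = ", ")
    )
  }
  structure(.PRESET_TABLE[[name]], class = "treatment_preset")
}

#' @export
print.treatment_preset <- function(x, ...) {
  cat(sprintf(
    "treatment_preset '%s': P(migrate)=%.3f, speed x%.2f, persistence %.2f\n",
    x$name, x$migration_probability, x$speed_scale, x$persistence
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Spot-assay migration fields

#' Configuration for synthetic spot-assay migration fields
#'
#' Parameters of the biased-persistent random walk used to emulate cells
#' migrating under an agarose spot over an overnight timelapse.
#'
#' @param n_cells Cells per field of view.
#' @param duration_h Timelapse duration, hours (overnight assay window).
#' @param interval_s Sampling interval of the track, seconds.
#' @param speed_um_min Baseline instantaneous cell speed, µm/min (scaled by
#'   the preset's `speed_scale`).
#' @param angle_noise_sd_deg Per-step heading-noise SD in degrees. The
#'   default is the packaged calibration under which control-preset
#'   migrating tracks average 2.80 degrees of unsigned deviation from the
#'   spot perpendicular.
#' @param step_sdlog Log-SD of the lognormal per-step speed multiplier.
#' @param start_dist_um Range (min, max) of initial distance from the spot
#'   edge, µm; cells always start outside the spot.
#' @param field_halfwidth_um Half-extent of the seeded band along the edge.
#' @param spot A [spot_geometry()].
#' @return A list of class `field_config`.
#' @export
field_config <- function(n_cells = 25,
                         duration_h = 14,
                         interval_s = 600,
                         speed_um_min = 0.8,
                         angle_noise_sd_deg = .ANGLE_NOISE_SD_DEG,
                         step_sdlog = 0.3,
                         start_dist_um = c(80, 200),
                         field_halfwidth_um = 400,
                         spot = spot_geometry()) {
  stopifnot(
    n_cells >= 0, duration_h > 0, interval_s > 0, speed_um_min > 0,
    angle_noise_sd_deg >= 0, step_sdlog >= 0,
    length(start_dist_um) == 2, all(start_dist_um > 0),
    inherits(spot, "spot_geometry")
  )
  structure(
    list(
      n_cells = as.integer(n_cells), duration_h = duration_h,
      interval_s = interval_s, speed_um_min = speed_um_min,
      angle_noise_sd_deg = angle_noise_sd_deg, step_sdlog = step_sdlog,
      start_dist_um = start_dist_um,
      field_halfwidth_um = field_halfwidth_um, spot = spot
    ),
    class = "field_config"
  )
}

# One biased-persistent random walk. `target` is the unit direction the
# heading is persistently pulled toward; headings are blended
# (persistence * previous + (1 - persistence) * target), renormalised, then
# rotated by wrapped-Gaussian noise. Step lengths are lognormal about the
# nominal speed. Returns an (n_steps + 1) x 2 matrix of positions in µm.
.bp_walk <- function(start, target, n_steps, step_um, persistence,
                     angle_sd_rad, step_sdlog) {
  pos <- matrix(NA_real_, n_steps + 1L, 2L)
  pos[1L, ] <- start
  h <- target
  for (k in seq_len(n_steps)) {
    h <- .unit(persistence * h + (1 - persistence) * target)
    if (angle_sd_rad > 0) h <- .rotate2(h, rnorm(1L, 0, angle_sd_rad))
    len <- step_um *
      (if (step_sdlog > 0) rlnorm(1L, -step_sdlog^2 / 2, step_sdlog) else 1)
    pos[k + 1L, ] <- pos[k, ] + h * len
  }
  pos
}

#' Simulate a spot-assay migration field with known ground truth
#'
#' Generates `n_cells` biased-persistent random-walk tracks sampled at the
#' configured interval over the assay window. Each cell is independently a
#' "migrator" with the preset's `migration_probability`: migrators head
#' toward the spot interior (perpendicular to the edge) and cross into the
#' spot, non-migrators take a persistent walk about a random outward
#' direction and stay outside. Track headings concentrate about the
#' perpendicular with angular spread set by the calibrated per-step noise
#' and the preset's persistence.
#'
#' @param config A [field_config()].
#' @param preset A [treatment_preset()] or preset name.
#' @param seed Optional integer seed; if given, the field is reproducible.
#' @return A list of class `field_ground_truth` with elements `tracks`
#'   (data.frame: id, frame, t_s, x_um, y_um, width_um, length_um), `spot`,
#'   `migrated_ids` (ids of tracks whose final centroid lies inside the
#'   spot), `migrator` (planted per-track indicator) and `preset`.
#' @examples
#' fg <- make_spot_field(field_config(n_cells = 10), "control", seed = 1)
#' length(fg$migrated_ids)
#' @export
make_spot_field <- function(config = field_config(), preset = "control",
                            seed = NULL) {
  stopifnot(inherits(config, "field_config"))
  preset <- treatment_preset(preset)
  if (!is.null(seed)) set.seed(seed)
  sp <- config$spot
  n_steps <- round(config$duration_h * 3600 / config$interval_s)
  step_um <- config$speed_um_min * (config$interval_s / 60) *
    preset$speed_scale
  ang_sd <- .deg2rad(config$angle_noise_sd_deg)

  tracks <- vector("list", config$n_cells)
  migrator <- logical(config$n_cells)
  for (i in seq_len(config$n_cells)) {
    migrator[i] <- runif(1L) < preset$migration_probability
    lat <- runif(1L, -config$field_halfwidth_um, config$field_halfwidth_um)
    d0 <- runif(1L, config$start_dist_um[1], config$start_dist_um[2])
    start <- sp$edge_point + sp$tangent * lat - sp$perpendicular * d0
    target <- if (migrator[i]) {
      sp$perpendicular
    } else {
      # outward semicircle: never directed into the spot
      .rotate2(-sp$perpendicular, .deg2rad(runif(1L, -75, 75)))
    }
    pos <- .bp_walk(start, target, n_steps, step_um, preset$persistence,
                    ang_sd, config$step_sdlog)
    len_um <- max(20, rnorm(1L, 45, 5))
    ef <- if (migrator[i]) runif(1L, 0.35, 0.55) else runif(1L, 0.6, 0.9)
    tracks[[i]] <- data.frame(
      id = i,
      frame = seq_len(n_steps + 1L),
      t_s = (seq_len(n_steps + 1L) - 1) * config$interval_s,
      x_um = pos[, 1], y_um = pos[, 2],
      width_um = ef * len_um, length_um = len_um
    )
  }
  tracks <- do.call(rbind, tracks)
  finals <- tracks[tracks$frame == n_steps + 1L, ]
  migrated_ids <- finals$id[spot_inside(sp, cbind(finals$x_um, finals$y_um))]
  structure(
    list(
      tracks = tracks, spot = sp, migrated_ids = migrated_ids,
      migrator = migrator, preset = preset, config = config
    ),
    class = "field_ground_truth"
  )
}

#' @export
print.field_ground_truth <- function(x, ...) {
  cat(sprintf(
    "field_ground_truth: preset '%s', %d tracks, %d migrated\n",
    x$preset$name, length(unique(x$tracks$id)), length(x$migrated_ids)
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# TIRF-like timelapses

#' Configuration for synthetic TIRF timelapses
#'
#' Parameters of the rendered field: one elliptical adherent cell whose
#' front (migration direction) points along +x, containing diffraction-
#' limited puncta with planted fates and optionally a second punctum channel
#' with a planted colocalisation fraction and/or elongated focal-adhesion
#' objects with planted disassembly profiles.
#'
#' @param img_size Square image side, px.
#' @param pixel_size_um Pixel size, µm/px (TIRF scale, default 0.1).
#' @param frame_interval_s Frame interval, s.
#' @param n_frames Frames in the timelapse (default 30, a 1 min video at
#'   2 s/frame).
#' @param cell_semiaxes_px Semi-axes (along x, along y) of the elliptical
#'   cell mask, px.
#' @param n_puncta Puncta planted in channel 1.
#' @param punctum_sigma_px Isotropic Gaussian PSF sigma, px.
#' @param snr Punctum peak amplitude / noise SD; must be > 0.
#' @param noise_sd Additive Gaussian noise SD (grey values).
#' @param background Constant background level (grey values).
#' @param fate_probs Named probabilities for fates `static`, `lateral`,
#'   `disappearing`; must sum to 1.
#' @param front_bias Length-3 relative rates (front, middle, back) at which
#'   planted disappearance events fall in each polarity region.
#' @param reappear_fraction Fraction of disappearing puncta that reappear at
#'   the same spot after `reappear_delay_frames` (planted negatives for the
#'   event caller).
#' @param reappear_delay_frames Frames between disappearance and reappearance.
#' @param lateral_disp_um Range (min, max) of net displacement for lateral
#'   puncta over the video, µm.
#' @param bleach_rate Per-frame fractional intensity decay applied
#'   multiplicatively to all pixels (0 disables bleaching).
#' @param coloc_fraction Fraction of channel-1 puncta given a co-positioned
#'   partner in channel 2 (exact count `round(fraction * n_puncta)` per
#'   cell). Set > 0 (or `n_distractors` > 0) to render channel 2.
#' @param n_distractors Independent channel-2-only puncta (uniform in the
#'   cell mask).
#' @param n_fas Focal adhesions planted in a dedicated channel (0 disables).
#' @param fa_semiaxes_um FA ellipse semi-axes (major, minor), µm.
#' @param fa_snr FA amplitude / noise SD.
#' @param fa_min_sep_um Minimum FA centre separation, µm.
#' @param fa_onset_frac Range of the planted disassembly-onset frame as a
#'   fraction of `n_frames` (ignored when `n_frames == 1`).
#' @param fa_fall_frames Range of the planted decline duration, frames.
#' @param fa_disassemble_fraction Fraction of FAs that disassemble during
#'   the video (the rest stay at plateau).
#' @param chance_overlap If non-NULL and `n_fas > 0`, plant an independent
#'   punctum channel as a spatial Poisson process whose density is tuned
#'   analytically so the probability that an FA mask dilated by
#'   `fa_dilate_px` contains at least one punctum equals this value.
#' @param fa_dilate_px Dilation radius used for the chance-overlap tuning
#'   (matches the default measurement radius).
#' @return A list of class `tirf_config`.
#' @export
tirf_config <- function(img_size = 200,
                        pixel_size_um = 0.1,
                        frame_interval_s = 2,
                        n_frames = 30,
                        cell_semiaxes_px = c(85, 55),
                        n_puncta = 60,
                        punctum_sigma_px = 1.5,
                        snr = 10,
                        noise_sd = 10,
                        background = 100,
                        fate_probs = c(static = 0.6, lateral = 0.2,
                                       disappearing = 0.2),
                        front_bias = c(1, 1, 1),
                        reappear_fraction = 0,
                        reappear_delay_frames = 5,
                        lateral_disp_um = c(0.8, 1.6),
                        bleach_rate = 0,
                        coloc_fraction = 0,
                        n_distractors = 0,
                        n_fas = 0,
                        fa_semiaxes_um = c(1.0, 0.25),
                        fa_snr = 10,
                        fa_min_sep_um = 2.6,
                        fa_onset_frac = c(0.2, 0.4),
                        fa_fall_frames = c(10, 25),
                        fa_disassemble_fraction = 1,
                        chance_overlap = NULL,
                        fa_dilate_px = 3) {
  if (snr <= 0) stop("snr must be > 0")
  stopifnot(
    img_size >= 32, pixel_size_um > 0, frame_interval_s > 0, n_frames >= 1,
    length(cell_semiaxes_px) == 2, all(cell_semiaxes_px > 0),
    n_puncta >= 0, punctum_sigma_px > 0, noise_sd > 0,
    length(front_bias) == 3, all(front_bias >= 0), sum(front_bias) > 0,
    reappear_fraction >= 0, reappear_fraction <= 1,
    coloc_fraction >= 0, coloc_fraction <= 1,
    n_distractors >= 0, n_fas >= 0, bleach_rate >= 0, bleach_rate < 1
  )
  stopifnot(abs(sum(fate_probs) - 1) < 1e-8,
            all(c("static", "lateral", "disappearing") %in%
                  names(fate_probs)))
  structure(as.list(environment()), class = "tirf_config")
}

# Elliptical cell mask (logical matrix [row, col]); shrink_px pulls the
# boundary inward (analytic erosion of the ellipse).
.cell_mask <- function(config, shrink_px = 0) {
  n <- config$img_size
  cx <- (n + 1) / 2
  a <- config$cell_semiaxes_px[1] - shrink_px
  b <- config$cell_semiaxes_px[2] - shrink_px
  stopifnot(a > 0, b > 0)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE) # x = column
  ys <- matrix(seq_len(n), n, n)               # y = row
  ((xs - cx) / a)^2 + ((ys - cx) / b)^2 <= 1
}

# Sample n points uniformly inside a predicate region of the image by
# rejection; pred(x, y) vectorised over continuous pixel coords.
.sample_in <- function(n, img_size, pred, max_tries = 200L) {
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  for (tr in seq_len(max_tries)) {
    if (got >= n) break
    m <- (n - got) * 4L
    x <- runif(m, 1, img_size)
    y <- runif(m, 1, img_size)
    ok <- pred(x, y)
    k <- min(sum(ok), n - got)
    if (k > 0) {
      out[(got + 1):(got + k), ] <- cbind(x[ok][seq_len(k)],
                                          y[ok][seq_len(k)])
      got <- got + k
    }
  }
  if (got < n) stop("could not place points inside the requested region")
  out
}

# Region index (1=front, 2=middle, 3=back) of points by thirds of the mask
# extent along +x (front toward larger x); boundary points go frontward.
.region_of_x <- function(x, xr) {
  b2 <- xr[1] + (xr[2] - xr[1]) * 2 / 3 # front/middle boundary
  b1 <- xr[1] + (xr[2] - xr[1]) / 3     # middle/back boundary
  ifelse(x >= b2, 1L, ifelse(x >= b1, 2L, 3L))
}

# Add a Gaussian punctum of amplitude A at continuous position (x, y) to
# image `img` in place (window of +/- 4 sigma).
.render_punctum <- function(img, x, y, A, sigma) {
  n <- nrow(img)
  w <- ceiling(4 * sigma)
  r0 <- max(1L, floor(y) - w); r1 <- min(n, ceiling(y) + w)
  c0 <- max(1L, floor(x) - w); c1 <- min(n, ceiling(x) + w)
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  g <- A * exp(-(outer((rr - y)^2, (cc - x)^2, "+")) / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + g
  img
}

# Binary ellipse mask for an FA at centre (x, y), semi-axes (a, b) px,
# orientation theta (radians from +x axis), on an img_size canvas.
.ellipse_mask <- function(img_size, x, y, a, b, theta) {
  w <- ceiling(max(a, b)) + 2L
  r0 <- max(1L, floor(y) - w); r1 <- min(img_size, ceiling(y) + w)
  c0 <- max(1L, floor(x) - w); c1 <- min(img_size, ceiling(x) + w)
  rr <- r0:r1; cc <- c0:c1
  X <- matrix(cc, length(rr), length(cc), byrow = TRUE) - x
  Y <- matrix(rr, length(rr), length(cc)) - y
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  m <- matrix(FALSE, img_size, img_size)
  m[rr, cc] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Pixel count of an ellipse mask dilated by a disc of radius r (discrete, as
# used by the measurement side); used to tune the chance-overlap density.
.dilated_ellipse_area <- function(img_size, a, b, theta, r) {
  cx <- (img_size + 1) / 2
  m <- .ellipse_mask(img_size, cx, cx, a, b, theta)
  md <- EBImage::dilate(m + 0, EBImage::makeBrush(2L * r + 1L, "disc"))
  sum(md > 0)
}

#' Render a synthetic TIRF timelapse with planted ground truth
#'
#' Renders Gaussian puncta on a noisy constant background inside an
#' elliptical cell mask whose front points along +x. Punctum fates are
#' planted: static puncta jitter in place, lateral puncta drift by a net
#' displacement above the lateral threshold, disappearing puncta drop to
#' background within two frames at their planted event frame (positions of
#' disappearing puncta are drawn by region with relative rates
#' `front_bias`). Optionally a fraction of disappearing puncta reappear at
#' the same position (planted negatives), global exponential photobleaching
#' multiplies all pixels, a second punctum channel is rendered with a
#' planted colocalisation fraction plus independent distractors, and
#' elongated focal-adhesion objects with planted disassembly intensity
#' profiles are rendered in a dedicated channel (with an optional
#' chance-overlap punctum channel for colocalisation nulls).
#'
#' @param config A [tirf_config()].
#' @param seed Optional integer seed.
#' @return A list of class `tirf_ground_truth` with elements:
#'   `stack` (a [timelapse_stack()]; channels named among `"puncta"`,
#'   `"partner"`, `"adhesion"`), `mask` (logical cell mask), `puncta`
#'   (per-punctum data.frame: id, fate, x0_px, y0_px, event_frame,
#'   reappears, reappear_frame, coloc, region), `tracks` (planted
#'   per-frame positions and intensity scales), `adhesions` (per-FA
#'   data.frame: id, x_px, y_px, major_px, minor_px, theta, onset_frame,
#'   end_frame), `partner_truth` (planted channel-2 positions) and
#'   `bleach_rate`.
#' @examples
#' tg <- make_tirf_timelapse(tirf_config(n_puncta = 20, n_frames = 5),
#'                           seed = 1)
#' table(tg$puncta$fate)
#' @export
make_tirf_timelapse <- function(config = tirf_config(), seed = NULL) {
  stopifnot(inherits(config, "tirf_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$img_size
  nf <- config$n_frames
  psz <- config$pixel_size_um
  mask <- .cell_mask(config)
  xr <- range(which(apply(mask, 2, any))) # mask extent along x (columns)
  margin <- 8
  a_in <- config$cell_semiaxes_px[1] - margin
  b_in <- config$cell_semiaxes_px[2] - margin
  cx <- (n + 1) / 2
  in_cell <- function(x, y, ax = a_in, bx = b_in) {
    ((x - cx) / ax)^2 + ((y - cx) / bx)^2 <= 1
  }

  # --- plant channel-1 puncta -------------------------------------------
  np <- config$n_puncta
  puncta <- NULL
  tracks <- NULL
  if (np > 0) {
    fates <- sample(c("static", "lateral", "disappearing"), np,
                    replace = TRUE,
                    prob = config$fate_probs[c("static", "lateral",
                                               "disappearing")])
    # enforce a minimum separation: planted spots closer than ~3 sigma are
    # unresolvable (one diffraction-limited spot)
    min_sep <- 3 * config$punctum_sigma_px + 1
    pos <- matrix(NA_real_, np, 2L)
    placed <- 0L
    for (tr in seq_len(400L * np)) {
      if (placed >= np) break
      p <- .sample_in(1L, n, in_cell)
      if (placed == 0L ||
          min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE],
                                 2, p)^2))) >= min_sep) {
        placed <- placed + 1L
        pos[placed, ] <- p
      }
    }
    if (placed < np) stop("could not place ", np, " puncta; enlarge cell")
    # disappearing puncta: resample position by region with front_bias
    dis <- which(fates == "disappearing")
    if (length(dis) > 0 && stats::var(config$front_bias) > 0) {
      regs <- sample(1:3, length(dis), replace = TRUE,
                     prob = config$front_bias)
      for (k in seq_along(dis)) {
        for (tr in seq_len(400L)) {
          p <- .sample_in(1L, n, function(x, y) {
            in_cell(x, y) & .region_of_x(x, xr) == regs[k]
          })
          if (min(sqrt(rowSums(sweep(pos[-dis[k], , drop = FALSE],
                                     2, p)^2))) >= min_sep) {
            pos[dis[k], ] <- p
            break
          }
        }
      }
    }
    event_frame <- rep(NA_integer_, np)
    if (length(dis) > 0) {
      hi <- max(4L, nf - 12L)
      event_frame[dis] <- if (nf >= 6) {
        sample(3:hi, length(dis), replace = TRUE)
      } else rep(2L, length(dis))
    }
    reappears <- rep(FALSE, np)
    if (length(dis) > 0 && config$reappear_fraction > 0) {
      nr <- round(config$reappear_fraction * length(dis))
      reappears[sample(dis, nr)] <- TRUE
    }
    reappear_frame <- ifelse(reappears,
                             event_frame + config$reappear_delay_frames,
                             NA_integer_)
    coloc <- rep(FALSE, np)
    if (config$coloc_fraction > 0) {
      coloc[sample.int(np, round(config$coloc_fraction * np))] <- TRUE
    }
    puncta <- data.frame(
      id = seq_len(np), fate = fates,
      x0_px = pos[, 1], y0_px = pos[, 2],
      event_frame = event_frame, reappears = reappears,
      reappear_frame = reappear_frame, coloc = coloc,
      region = c("front", "middle", "back")[.region_of_x(pos[, 1], xr)]
    )

    # per-frame planted positions and intensity scales
    tracks <- vector("list", np)
    for (i in seq_len(np)) {
      xy <- matrix(rep(pos[i, ], each = nf), nf, 2L)
      if (fates[i] == "static" || fates[i] == "disappearing") {
        xy <- xy + matrix(rnorm(2L * nf, 0, 0.05), nf, 2L)
      } else { # lateral: linear drift, endpoint kept inside the cell
        disp_px <- runif(1L, config$lateral_disp_um[1],
                         config$lateral_disp_um[2]) / psz
        for (tr in 1:50) {
          th <- runif(1L, 0, 2 * pi)
          end <- pos[i, ] + disp_px * c(cos(th), sin(th))
          if (in_cell(end[1], end[2])) break
        }
        f01 <- (seq_len(nf) - 1) / max(1L, nf - 1L)
        xy <- cbind(pos[i, 1] + f01 * (end[1] - pos[i, 1]),
                    pos[i, 2] + f01 * (end[2] - pos[i, 2])) +
          matrix(rnorm(2L * nf, 0, 0.05), nf, 2L)
      }
      sc <- rep(1, nf)
      if (fates[i] == "disappearing") {
        ef <- event_frame[i]
        sc[seq_len(nf) == ef] <- 0.3
        sc[seq_len(nf) > ef] <- 0
        if (reappears[i]) sc[seq_len(nf) >= reappear_frame[i]] <- 1
      }
      tracks[[i]] <- data.frame(id = i, frame = seq_len(nf),
                                x_px = xy[, 1], y_px = xy[, 2], scale = sc)
    }
    tracks <- do.call(rbind, tracks)
  }

  # --- plant focal adhesions --------------------------------------------
  adhesions <- NULL
  if (config$n_fas > 0) {
    fa_a <- config$fa_semiaxes_um[1] / psz
    fa_b <- config$fa_semiaxes_um[2] / psz
    fa_margin <- fa_a + config$fa_dilate_px + 3
    min_sep <- config$fa_min_sep_um / psz
    centres <- matrix(NA_real_, config$n_fas, 2L)
    placed <- 0L
    for (tr in seq_len(20000L)) {
      if (placed >= config$n_fas) break
      p <- .sample_in(1L, n, function(x, y) {
        in_cell(x, y, config$cell_semiaxes_px[1] - fa_margin,
                config$cell_semiaxes_px[2] - fa_margin)
      })
      if (placed == 0L ||
          min(sqrt(rowSums(sweep(centres[seq_len(placed), , drop = FALSE],
                                 2, p)^2))) >= min_sep) {
        placed <- placed + 1L
        centres[placed, ] <- p
      }
    }
    if (placed < config$n_fas) {
      stop("could not place ", config$n_fas, " focal adhesions with ",
           "min separation ", config$fa_min_sep_um, " um; enlarge the cell")
    }
    theta <- runif(config$n_fas, 0, pi)
    onset <- end <- rep(NA_integer_, config$n_fas)
    if (nf > 1) {
      dis <- runif(config$n_fas) < config$fa_disassemble_fraction
      onset[dis] <- round(runif(sum(dis), config$fa_onset_frac[1] * nf,
                                config$fa_onset_frac[2] * nf))
      fall <- round(runif(sum(dis), config$fa_fall_frames[1],
                          config$fa_fall_frames[2]))
      end[dis] <- pmin(nf, onset[dis] + fall)
    }
    adhesions <- data.frame(
      id = seq_len(config$n_fas),
      x_px = centres[, 1], y_px = centres[, 2],
      major_px = fa_a, minor_px = fa_b, theta = theta,
      onset_frame = onset, end_frame = end
    )
  }

  # --- chance-overlap punctum channel for FA fields ----------------------
  overlap_pts <- NULL
  if (!is.null(config$chance_overlap) && config$n_fas > 0) {
    stopifnot(config$chance_overlap > 0, config$chance_overlap < 1)
    fa_a <- config$fa_semiaxes_um[1] / psz
    fa_b <- config$fa_semiaxes_um[2] / psz
    # mean discrete dilated area over a few orientations
    A_dil <- mean(vapply(seq(0, pi * 0.45, length.out = 4), function(th) {
      .dilated_ellipse_area(n, fa_a, fa_b, th, config$fa_dilate_px)
    }, numeric(1)))
    lambda <- -log(1 - config$chance_overlap) / A_dil # puncta per px^2
    n_extra <- rpois(1L, lambda * sum(mask))
    if (n_extra > 0) {
      overlap_pts <- .sample_in(n_extra, n, function(x, y) {
        mask[cbind(pmax(1, pmin(n, round(y))), pmax(1, pmin(n, round(x))))]
      })
    }
  }

  # --- channel-2 partners and distractors -------------------------------
  partner_truth <- NULL
  render_ch2 <- config$coloc_fraction > 0 || config$n_distractors > 0
  if (render_ch2) {
    pts <- list()
    if (!is.null(puncta) && any(puncta$coloc)) {
      ids <- puncta$id[puncta$coloc]
      jit <- matrix(runif(2L * length(ids), -0.5, 0.5), ncol = 2L)
      pts$partner <- data.frame(
        partner_of = ids,
        dx = jit[, 1], dy = jit[, 2]
      )
    }
    if (config$n_distractors > 0) {
      dp <- .sample_in(config$n_distractors, n, in_cell)
      pts$distractor <- data.frame(x_px = dp[, 1], y_px = dp[, 2])
    }
    partner_truth <- pts
  }

  # --- render ------------------------------------------------------------
  amp <- config$snr * config$noise_sd
  bfac <- (1 - config$bleach_rate)^(seq_len(nf) - 1L)
  ch1 <- array(0, dim = c(n, n, nf))
  ch2 <- if (render_ch2) array(0, dim = c(n, n, nf)) else NULL
  chfa <- if (config$n_fas > 0) array(0, dim = c(n, n, nf)) else NULL

  fa_masks <- NULL
  if (config$n_fas > 0) {
    fa_a <- config$fa_semiaxes_um[1] / psz
    fa_b <- config$fa_semiaxes_um[2] / psz
    fa_masks <- lapply(seq_len(config$n_fas), function(i) {
      m <- .ellipse_mask(n, adhesions$x_px[i], adhesions$y_px[i],
                         fa_a, fa_b, adhesions$theta[i])
      # smooth edge: convolve indicator with a 1 px Gaussian
      EBImage::gblur(m + 0, sigma = 1)
    })
  }

  for (f in seq_len(nf)) {
    img <- matrix(config$background, n, n)
    if (!is.null(tracks)) {
      tf <- tracks[tracks$frame == f & tracks$scale > 0, ]
      for (k in seq_len(nrow(tf))) {
        img <- .render_punctum(img, tf$x_px[k], tf$y_px[k],
                               amp * tf$scale[k], config$punctum_sigma_px)
      }
    }
    ch1[, , f] <- img * bfac[f] + rnorm(n * n, 0, config$noise_sd)

    if (render_ch2) {
      img2 <- matrix(config$background, n, n)
      if (!is.null(partner_truth$partner)) {
        pt <- partner_truth$partner
        tf <- tracks[tracks$frame == f & tracks$id %in% pt$partner_of, ]
        for (k in seq_len(nrow(tf))) {
          off <- pt[pt$partner_of == tf$id[k], ]
          if (tf$scale[k] > 0) {
            img2 <- .render_punctum(img2, tf$x_px[k] + off$dx,
                                    tf$y_px[k] + off$dy,
                                    amp * tf$scale[k],
                                    config$punctum_sigma_px)
          }
        }
      }
      if (!is.null(partner_truth$distractor)) {
        dd <- partner_truth$distractor
        for (k in seq_len(nrow(dd))) {
          img2 <- .render_punctum(img2, dd$x_px[k], dd$y_px[k], amp,
                                  config$punctum_sigma_px)
        }
      }
      ch2[, , f] <- img2 * bfac[f] + rnorm(n * n, 0, config$noise_sd)
    }

    if (config$n_fas > 0) {
      imgf <- matrix(config$background, n, n)
      fa_amp <- config$fa_snr * config$noise_sd
      for (i in seq_len(config$n_fas)) {
        sc <- 1
        if (nf > 1 && !is.na(adhesions$onset_frame[i])) {
          o <- adhesions$onset_frame[i]; e <- adhesions$end_frame[i]
          sc <- if (f <= o) 1 else if (f >= e) 0 else (e - f) / (e - o)
        }
        if (sc > 0) imgf <- imgf + fa_amp * sc * fa_masks[[i]]
      }
      chfa[, , f] <- imgf * bfac[f] + rnorm(n * n, 0, config$noise_sd)
    }
  }

  # chance-overlap puncta live in their own channel (e.g. clathrin imaged
  # alongside an adhesion marker)
  chov <- NULL
  if (!is.null(overlap_pts)) {
    chov <- array(0, dim = c(n, n, nf))
    for (f in seq_len(nf)) {
      img <- matrix(config$background, n, n)
      for (k in seq_len(nrow(overlap_pts))) {
        img <- .render_punctum(img, overlap_pts[k, 1], overlap_pts[k, 2],
                               amp, config$punctum_sigma_px)
      }
      chov[, , f] <- img * bfac[f] + rnorm(n * n, 0, config$noise_sd)
    }
  }

  channels <- list()
  if (np > 0 || is.null(chfa)) channels$puncta <- ch1
  if (!is.null(ch2)) channels$partner <- ch2
  if (!is.null(chfa)) channels$adhesion <- chfa
  if (!is.null(chov)) channels$overlap <- chov

  stack <- timelapse_stack(channels, psz, config$frame_interval_s,
                           channel_names = names(channels))
  structure(
    list(
      stack = stack, mask = mask, puncta = puncta, tracks = tracks,
      adhesions = adhesions, partner_truth = partner_truth,
      overlap_points = overlap_pts, bleach_rate = config$bleach_rate,
      config = config
    ),
    class = "tirf_ground_truth"
  )
}

#' @export
print.tirf_ground_truth <- function(x, ...) {
  cat(sprintf(
    "tirf_ground_truth: %d puncta, %d adhesions, bleach %.3g/frame\n",
    if (is.null(x$puncta)) 0L else nrow(x$puncta),
    if (is.null(x$adhesions)) 0L else nrow(x$adhesions),
    x$bleach_rate
  ))
  print(x$stack)
  invisible(x)
}
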