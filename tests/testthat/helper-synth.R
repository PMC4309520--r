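# Shared fixtures, built in code.

# Render a Gaussian punctum of amplitude `amp` at (x, y) onto a noisy
# background frame (independent of the package's internal renderer).
render_frame <- function(size = 64, puncta = NULL, bg = 100, noise = 10,
                         sigma = 1.5) {
  img <- matrix(bg + rnorm(size * size, 0, noise), size, size)
  if (!is.null(puncta)) {
    xs <- matrix(seq_len(size), size, size, byrow = TRUE)
    ys <- matrix(seq_len(size), size, size)
    for (k in seq_len(nrow(puncta))) {
      img <- img + puncta$amp[k] *
        exp(-((xs - puncta$x[k])^2 + (ys - puncta$y[k])^2) / (2 * sigma^2))
    }
  }
  img
}

# Build a small stack with per-frame punctum tables:
# puncta_by_frame[[f]] = data.frame(x, y, amp). `bleach` multiplies frame f
# by bleach^(f-1) (applied to background + signal, before noise).
render_stack <- function(n_frames, puncta_by_frame, size = 64, bg = 100,
                         noise = 10, sigma = 1.5, bleach = 1,
                         pixel_size_um = 0.1, frame_interval_s = 2) {
  arr <- array(NA_real_, c(size, size, n_frames))
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  for (f in seq_len(n_frames)) {
    img <- matrix(bg, size, size)
    pf <- puncta_by_frame[[f]]
    if (!is.null(pf) && nrow(pf) > 0) {
      for (k in seq_len(nrow(pf))) {
        img <- img + pf$amp[k] *
          exp(-((xs - pf$x[k])^2 + (ys - pf$y[k])^2) / (2 * sigma^2))
      }
    }
    arr[, , f] <- img * bleach^(f - 1) + rnorm(size * size, 0, noise)
  }
  timelapse_stack(arr, pixel_size_um, frame_interval_s)
}

# Detections/track table for a punctum present in frames `frames` at fixed
# (x, y) — used to drive the event caller directly.
planted_track <- function(id, frames, x, y, intensity = 75) {
  data.frame(track_id = id, frame = frames, x_px = x, y_px = y,
             intensity = intensity)
}

# A random cell track in long format.
random_track <- function(n = 50, id = 1, step_sd = 2, dt = 60) {
  data.frame(
    id = id, frame = seq_len(n), t_s = (seq_len(n) - 1) * dt,
    x_um = cumsum(c(0, rnorm(n - 1, 0, step_sd))),
    y_um = cumsum(c(0, rnorm(n - 1, 0, step_sd)))
  )
}
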