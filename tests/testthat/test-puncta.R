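test_that("detection is quiet on noise and sub-pixel accurate on planted spots", {
  set.seed(41)
  # false positives: < 1 per frame on pure noise at the 5-sigma threshold
  fp <- vapply(seq_len(20), function(k) {
    nrow(detect_puncta(render_frame(64, NULL)))
  }, numeric(1))
  expect_lt(mean(fp), 1)

  # single punctum at SNR 10 localised within 0.5 px
  errs <- vapply(seq_len(20), function(k) {
    x <- runif(1, 20, 44); y <- runif(1, 20, 44)
    d <- detect_puncta(render_frame(64, data.frame(x = x, y = y, amp = 100)))
    expect_equal(nrow(d), 1)
    sqrt((d$x_px - x)^2 + (d$y_px - y)^2)
  }, numeric(1))
  expect_lt(max(errs), 0.5)

  # two well-separated puncta
  d2 <- detect_puncta(render_frame(
    64, data.frame(x = c(20, 30), y = c(32, 32), amp = 100)
  ))
  expect_equal(nrow(d2), 2)
})

test_that("saturation warns but detection proceeds", {
  set.seed(43)
  img <- render_frame(64, data.frame(x = 32, y = 32, amp = 100))
  img[32, 32] <- 4095
  expect_warning(d <- detect_puncta(img, saturation_level = 4095),
                 "saturated")
  expect_gte(nrow(d), 1)
})

test_that("linking follows puncta through gaps without identity swaps", {
  # stationary punctum over 20 frames -> one track of length 20
  det <- data.frame(frame = 1:20, x_px = 10 + rnorm(20, 0, 0.1),
                    y_px = 10 + rnorm(20, 0, 0.1), intensity = 80)
  lk <- link_puncta(det, max_step_px = 2, max_gap = 2)
  expect_equal(length(unique(lk$track_id)), 1)
  expect_equal(nrow(lk), 20)

  # 1-frame dropout bridged at max_gap = 2
  det_gap <- det[det$frame != 10, ]
  lk <- link_puncta(det_gap, max_step_px = 2, max_gap = 2)
  expect_equal(length(unique(lk$track_id)), 1)
  # but not at max_gap = 0
  lk0 <- link_puncta(det_gap, max_step_px = 2, max_gap = 0)
  expect_equal(length(unique(lk0$track_id)), 2)

  # two paths crossing in x while separated in y: no swap
  a <- data.frame(frame = 1:21, x_px = seq(5, 25, by = 1), y_px = 10,
                  intensity = 80)
  b <- data.frame(frame = 1:21, x_px = seq(25, 5, by = -1), y_px = 13,
                  intensity = 80)
  lk <- link_puncta(rbind(a, b), max_step_px = 2, max_gap = 1)
  expect_equal(length(unique(lk$track_id)), 2)
  ya <- lk$y_px[lk$track_id == lk$track_id[1]]
  expect_true(all(ya == ya[1])) # each track keeps its own y
})

test_that("fates are classified from displacement and terminal intensity", {
  cfg <- tirf_config(n_puncta = 40, n_frames = 25, img_size = 160,
                     cell_semiaxes_px = c(65, 45),
                     fate_probs = c(static = 0.4, lateral = 0.3,
                                    disappearing = 0.3))
  tg <- make_tirf_timelapse(cfg, seed = 47)
  det <- detect_puncta_stack(tg$stack, "puncta")
  lk <- link_puncta(det)
  fates <- classify_fates(lk, tg$stack, "puncta")
  # match each truth punctum to the nearest track start
  acc <- vapply(seq_len(nrow(tg$puncta)), function(i) {
    d <- sqrt((fates$x0_px - tg$puncta$x0_px[i])^2 +
                (fates$y0_px - tg$puncta$y0_px[i])^2)
    j <- which.min(d)
    if (d[j] > 2) return(NA_character_)
    fates$fate[j]
  }, character(1))
  ok <- !is.na(acc)
  expect_gt(mean(ok), 0.9)
  agree <- acc[ok] == tg$puncta$fate[ok]
  expect_gt(mean(agree), 0.8)
})

test_that("the three event criteria each veto their designed negatives", {
  set.seed(53)
  mk_frames <- function(scales, x = 32, y = 32, extra = NULL) {
    lapply(scales, function(s) {
      p <- if (s > 0) data.frame(x = x, y = y, amp = 100 * s) else NULL
      rbind(p, extra)
    })
  }
  nf <- 30
  # clean step disappearance at frame 12
  sc <- c(rep(1, 11), 0.3, rep(0, nf - 12))
  st <- render_stack(nf, mk_frames(sc))
  trk <- planted_track(1, 1:12, 32, 32)
  ev <- call_disappearance(trk, st, trk)
  expect_equal(nrow(ev), 1)
  expect_true(ev$rapid && ev$no_reappearance && ev$not_photobleaching)

  # reappearance 5 frames later within the radius -> vetoed
  sc_re <- sc; sc_re[17:nf] <- 1
  st_re <- render_stack(nf, mk_frames(sc_re))
  det_re <- rbind(planted_track(1, 1:12, 32, 32),
                  planted_track(2, 17:nf, 32, 32))
  ev_re <- call_disappearance(det_re[det_re$track_id == 1, ], st_re, det_re)
  expect_null(ev_re)

  # rapid step drop inside a strongly bleaching field -> vetoed
  st_bl <- render_stack(nf, mk_frames(sc), bleach = 0.98)
  ev_bl <- call_disappearance(trk, st_bl, trk)
  expect_null(ev_bl)

  # gradual linear fade over 15 frames -> not rapid, vetoed (low noise so
  # the background crossing is resolved cleanly)
  nf_gr <- 36
  sc_gr <- c(rep(1, 8), seq(1, 0, length.out = 16), rep(0, nf_gr - 24))
  frames_gr <- lapply(sc_gr, function(s) {
    if (s > 0) data.frame(x = 32, y = 32, amp = 100 * s) else NULL
  })
  st_gr <- render_stack(nf_gr, frames_gr, noise = 5)
  # detectable roughly while above half amplitude
  trk_gr <- planted_track(1, 1:15, 32, 32)
  ev_gr <- call_disappearance(trk_gr, st_gr, trk_gr)
  expect_null(ev_gr)

  # track ending too close to the stack end is censored
  sc_late <- c(rep(1, 25), rep(0, nf - 25))
  st_late <- render_stack(nf, mk_frames(sc_late))
  trk_late <- planted_track(1, 1:25, 32, 32)
  expect_null(call_disappearance(trk_late, st_late, trk_late))
})

test_that("event calling is monotone in the photobleaching tolerance", {
  set.seed(59)
  nf <- 30
  sc <- c(rep(1, 11), 0.3, rep(0, nf - 12))
  frames <- lapply(sc, function(s) {
    if (s > 0) data.frame(x = 32, y = 32, amp = 100 * s) else NULL
  })
  st <- render_stack(nf, frames, bleach = 0.997) # ~6% decline over window
  trk <- planted_track(1, 1:12, 32, 32)
  got <- vapply(c(0.02, 0.05, 0.1, 0.2), function(tol) {
    !is.null(call_disappearance(trk, st, trk, bleach_tolerance = tol))
  }, logical(1))
  expect_true(all(diff(got) >= 0)) # relaxing never removes an event
  expect_false(got[1])
  expect_true(got[4])
})

test_that("per-region event counts conserve totals and respect planting", {
  mask <- matrix(TRUE, 100, 300)
  part <- partition_cell(mask, 0.1, spot_geometry(c(0, 0), c(1, 0)))
  # all events in the front third (x_px >= 201)
  ev <- data.frame(x_px = runif(15, 220, 290), y_px = runif(15, 10, 90))
  d <- events_per_region(ev, part, 0.1)
  expect_equal(d$count, c(15, 0, 0))
  expect_equal(sum(d$count), nrow(ev))
  tot <- c(front = 30, middle = 40, back = 0)
  d2 <- events_per_region(ev, part, 0.1, total_spots = tot)
  expect_equal(d2$fraction_of_spots[1], 0.5)
  expect_true(is.na(d2$fraction_of_spots[3]))
})

test_that("dynamic fraction hits its trivial extremes per region", {
  mask <- matrix(TRUE, 100, 300)
  part <- partition_cell(mask, 0.1, spot_geometry(c(0, 0), c(1, 0)))
  fates <- data.frame(
    track_id = 1:30, fate = "static", net_disp_um = 0, first_frame = 1,
    last_frame = 20,
    x_end_px = runif(30, 5, 295), y_end_px = runif(30, 5, 95),
    x0_px = runif(30, 5, 295), y0_px = runif(30, 5, 95)
  )
  tracks <- NULL # not used by the fraction computation
  d_all_static <- dynamic_fraction(tracks, fates, part, 0.1)
  expect_true(all(d_all_static$fraction == 0, na.rm = TRUE))
  fates$fate <- rep(c("lateral", "disappearing"), 15)
  d_all_dyn <- dynamic_fraction(tracks, fates, part, 0.1)
  expect_true(all(d_all_dyn$fraction == 1, na.rm = TRUE))
  # restricting to first-frame spots drops later arrivals
  fates$first_frame <- c(rep(1, 10), rep(5, 20))
  d_ff <- dynamic_fraction(tracks, fates, part, 0.1, first_frame_only = TRUE)
  expect_equal(sum(d_ff$n_spots), 10)
})
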