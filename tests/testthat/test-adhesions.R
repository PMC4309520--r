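test_that("adhesion segmentation finds planted ellipses and nothing else", {
  set.seed(79)
  blank <- matrix(rnorm(128 * 128, 100, 10), 128, 128)
  expect_equal(nrow(detect_fas(blank, 0.1)$table), 0)

  cfg <- tirf_config(img_size = 200, n_puncta = 0, n_frames = 1, n_fas = 1,
                     cell_semiaxes_px = c(85, 55))
  tg <- make_tirf_timelapse(cfg, seed = 83)
  fas <- detect_fas(get_frame(tg$stack, 1, "adhesion"), 0.1)
  expect_equal(nrow(fas$table), 1)
  err <- sqrt((fas$table$x_px - tg$adhesions$x_px)^2 +
                (fas$table$y_px - tg$adhesions$y_px)^2)
  expect_lt(err, 1)
  expect_gt(fas$table$elongation, 1) # elongated by construction
  expect_gt(fas$table$area_um2, 0.25)
  expect_lt(fas$table$area_um2, 15)

  cfg2 <- tirf_config(img_size = 200, n_puncta = 0, n_frames = 1, n_fas = 2,
                      cell_semiaxes_px = c(85, 55), fa_min_sep_um = 5)
  tg2 <- make_tirf_timelapse(cfg2, seed = 89)
  expect_equal(nrow(detect_fas(get_frame(tg2$stack, 1, "adhesion"),
                               0.1)$table), 2)
})

test_that("per-region adhesion counts follow the planted layout", {
  mask <- matrix(TRUE, 100, 300)
  part <- partition_cell(mask, 0.1, spot_geometry(c(0, 0), c(1, 0)))
  tab <- data.frame(x_px = runif(12, 5, 95), y_px = runif(12, 10, 90))
  d <- count_fas_per_region(tab, part, 0.1) # all in the back third
  expect_equal(d$count, c(0, 0, 12))
  expect_equal(sum(d$count), 12)
})

test_that("disassembly time follows its onset/end definition", {
  # plateau 100 through frame 11, linear decline to 0 at frame 21,
  # 1 min frames: onset = last frame >= 90 -> 12, end = first at or below
  # the end threshold (max(2 sd, 5% plateau) = 5) -> frame 21
  trace <- c(rep(100, 10), 100 * (10:0) / 10)
  m <- disassembly_time(trace, frame_interval_s = 60, noise_sd = 1)
  expect_equal(m$onset_frame, 12)
  expect_equal(m$end_frame, 21)
  expect_equal(m$disassembly_min, 9)

  # censored cases: constant trace, or decline that never completes
  expect_null(disassembly_time(rep(100, 20), 60, noise_sd = 1))
  expect_null(disassembly_time(c(rep(100, 10), rep(60, 10)), 60,
                               noise_sd = 1))

  # invariant to rescaling the trace
  m2 <- disassembly_time(trace * 37, 60, noise_sd = 37)
  expect_equal(m2$disassembly_min, m$disassembly_min)
})

test_that("planted disassembly profiles are recovered from rendered stacks", {
  cfg <- tirf_config(img_size = 256, n_puncta = 0, n_frames = 50,
                     frame_interval_s = 30, n_fas = 12,
                     cell_semiaxes_px = c(110, 70),
                     fa_onset_frac = c(0.2, 0.35), fa_fall_frames = c(10, 20))
  tg <- make_tirf_timelapse(cfg, seed = 97)
  fas <- detect_fas(get_frame(tg$stack, 1, "adhesion"), 0.1)
  expect_equal(nrow(fas$table), 12)
  traces <- fa_traces(tg$stack, fas, "adhesion")
  errs <- c()
  for (k in seq_len(nrow(fas$table))) {
    m <- disassembly_time(traces[, k], 30)
    expect_false(is.null(m))
    # match to the nearest planted adhesion
    d <- sqrt((tg$adhesions$x_px - fas$table$x_px[k])^2 +
                (tg$adhesions$y_px - fas$table$y_px[k])^2)
    fa <- tg$adhesions[which.min(d), ]
    fall <- fa$end_frame - fa$onset_frame
    # with a linear ramp the measured window spans the 90% and
    # background-crossing points: expected (0.95 - 0.1) * fall frames
    expected_min <- 0.85 * fall * 30 / 60
    errs <- c(errs, abs(m$disassembly_min - expected_min))
  }
  expect_lt(mean(errs), 1) # within ~2 frames on average
})

test_that("chance-level puncta hit adhesions at the planted rate extremes", {
  cfg <- tirf_config(img_size = 200, n_puncta = 0, n_frames = 1, n_fas = 6,
                     cell_semiaxes_px = c(85, 55), fa_min_sep_um = 3)
  tg <- make_tirf_timelapse(cfg, seed = 101)
  fas <- detect_fas(get_frame(tg$stack, 1, "adhesion"), 0.1)
  inside <- data.frame(x_px = fas$table$x_px, y_px = fas$table$y_px)
  expect_equal(clathrin_at_fa(fas, inside)$fraction, 1)
  outside <- data.frame(x_px = rep(2, 6), y_px = seq(2, 12, by = 2))
  expect_equal(clathrin_at_fa(fas, outside)$fraction, 0)
})

test_that("group comparison is calibrated under the null and powered", {
  same <- list(a = rep(c(9, 10, 11, 10.5), 5), b = rep(c(9, 10, 11, 10.5), 5))
  cmp <- compare_disassembly(same)
  expect_equal(cmp$summary$mean[1], cmp$summary$mean[2])
  expect_gt(cmp$tests$p_value, 0.9)

  set.seed(103)
  # type-I calibration at alpha = 0.05
  rej <- vapply(seq_len(200), function(k) {
    g <- list(a = rnorm(10, 10, 2), b = rnorm(10, 10, 2))
    compare_disassembly(g)$tests$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.1)

  # a 2x slower group at n = 100 is detected essentially always
  pw <- vapply(seq_len(20), function(k) {
    g <- list(a = rnorm(100, 10, 2), b = rnorm(100, 20, 4))
    compare_disassembly(g)$tests$p_value < 0.01
  }, logical(1))
  expect_gt(mean(pw), 0.9)

  expect_error(compare_disassembly(list(a = 1:5)), "2")
  expect_error(compare_disassembly(list(a = 1:5, b = 1:2)), "at least 3")
})
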