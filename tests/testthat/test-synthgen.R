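test_that("treatment presets encode the frozen effect sizes", {
  ctl <- treatment_preset("control")
  expect_equal(treatment_preset("dynasore")$migration_probability,
               0.4 * ctl$migration_probability)
  expect_equal(treatment_preset("dynasore")$speed_scale,
               0.5 * ctl$speed_scale)
  expect_equal(treatment_preset("alpha_adaptin_sirna")$migration_probability,
               0.35 * ctl$migration_probability)
  for (nm in c("nsc_sirna", "cav1_sirna")) {
    p <- treatment_preset(nm)
    expect_equal(p$migration_probability, ctl$migration_probability)
    expect_equal(p$speed_scale, ctl$speed_scale)
    expect_equal(p$persistence, ctl$persistence)
  }
  expect_error(treatment_preset("mystery_drug"), "unknown treatment preset")
})

test_that("identical seeds reproduce fields and stacks exactly", {
  f1 <- make_spot_field(field_config(n_cells = 8), "control", seed = 99)
  f2 <- make_spot_field(field_config(n_cells = 8), "control", seed = 99)
  expect_identical(f1$tracks, f2$tracks)
  expect_identical(f1$migrated_ids, f2$migrated_ids)

  cfg <- tirf_config(n_puncta = 15, n_frames = 4, img_size = 128,
                     cell_semiaxes_px = c(55, 40))
  t1 <- make_tirf_timelapse(cfg, seed = 5)
  t2 <- make_tirf_timelapse(cfg, seed = 5)
  expect_identical(t1$stack$channels, t2$stack$channels)
  expect_identical(t1$puncta, t2$puncta)
})

test_that("migrated fraction estimates the preset migration probability", {
  fg <- make_spot_field(field_config(n_cells = 400), "control", seed = 21)
  p <- treatment_preset("control")$migration_probability
  frac <- length(fg$migrated_ids) / 400
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 400))
  # every migrated id really ends inside the spot
  finals <- fg$tracks[fg$tracks$frame == max(fg$tracks$frame), ]
  inside <- finals$id[spot_inside(fg$spot, cbind(finals$x_um, finals$y_um))]
  expect_setequal(fg$migrated_ids, inside)
})

test_that("degenerate bias gives straight perpendicular tracks", {
  det_preset <- structure(
    list(name = "control", migration_probability = 1, speed_scale = 1,
         persistence = 1),
    class = "treatment_preset"
  )
  cfg <- field_config(n_cells = 5, angle_noise_sd_deg = 0, step_sdlog = 0)
  fg <- make_spot_field(cfg, det_preset, seed = 2)
  for (tr in split(fg$tracks, fg$tracks$id)) {
    expect_equal(var(tr$y_um), 0, tolerance = 1e-20)
    expect_true(all(diff(tr$x_um) > 0))
    expect_equal(migration_angle(tr, cfg$spot), 0, tolerance = 1e-10)
  }
})

test_that("global bleaching decays total intensity at the configured rate", {
  rate <- 0.03
  cfg <- tirf_config(n_puncta = 20, n_frames = 25, bleach_rate = rate,
                     fate_probs = c(static = 1, lateral = 0,
                                    disappearing = 0))
  tg <- make_tirf_timelapse(cfg, seed = 8)
  means <- vapply(seq_len(25), function(f) mean(get_frame(tg$stack, f)),
                  numeric(1))
  fit <- lm(log(means) ~ seq_len(25))
  rate_hat <- 1 - exp(coef(fit)[2])
  expect_lt(abs(rate_hat - rate) / rate, 0.05)
})

test_that("static fates without bleaching give constant intensity traces", {
  cfg <- tirf_config(n_puncta = 15, n_frames = 20, img_size = 128,
                     cell_semiaxes_px = c(55, 40),
                     fate_probs = c(static = 1, lateral = 0,
                                    disappearing = 0))
  tg <- make_tirf_timelapse(cfg, seed = 12)
  for (i in seq_len(5)) {
    tr <- tg$tracks[tg$tracks$id == i, ]
    vals <- vapply(seq_len(20), function(f) {
      img <- get_frame(tg$stack, f)
      img[round(tr$y_px[f]), round(tr$x_px[f])]
    }, numeric(1))
    expect_lt(sd(vals) / mean(vals), 0.1)
  }
})

test_that("planted disappearance events recover the front-bias ratio", {
  set.seed(31)
  regions <- character(0)
  for (s in c(101, 102)) {
    cfg <- tirf_config(img_size = 256, cell_semiaxes_px = c(110, 70),
                       n_puncta = 150, n_frames = 16,
                       fate_probs = c(static = 0, lateral = 0,
                                      disappearing = 1),
                       front_bias = c(2, 1, 1))
    tg <- make_tirf_timelapse(cfg, seed = s)
    regions <- c(regions, tg$puncta$region)
  }
  counts <- table(factor(regions, levels = c("front", "middle", "back")))
  chi <- suppressWarnings(
    stats::chisq.test(counts, p = c(2, 1, 1) / 4)
  )
  expect_gt(chi$p.value, 0.001)
  expect_gt(counts["front"], counts["middle"])
  expect_gt(counts["front"], counts["back"])
})

test_that("full planted colocalisation puts a partner within 1 px of every punctum", {
  cfg <- tirf_config(n_puncta = 30, n_frames = 1, coloc_fraction = 1,
                     n_distractors = 0)
  tg <- make_tirf_timelapse(cfg, seed = 4)
  expect_true(all(tg$puncta$coloc))
  pt <- tg$partner_truth$partner
  expect_equal(nrow(pt), 30)
  expect_true(all(sqrt(pt$dx^2 + pt$dy^2) < 1))
  # and the rendered channels agree at the default radius
  q <- detect_puncta(get_frame(tg$stack, 1, "puncta"))
  t2 <- detect_puncta(get_frame(tg$stack, 1, "partner"))
  cc <- circle_colocalisation(q, t2, radius_px = 3, n = 50, seed = 1)
  expect_equal(cc$fraction, 1)
})

test_that("generator rejects invalid configurations", {
  expect_error(tirf_config(snr = 0), "snr")
  expect_error(tirf_config(coloc_fraction = 1.5))
  expect_error(field_config(n_cells = 5, start_dist_um = c(-10, 50)))
})
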