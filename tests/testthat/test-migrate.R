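test_that("path length matches hand values and a brute-force oracle", {
  tr <- data.frame(t_s = c(0, 60), x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(path_length(tr), 5)
  still <- data.frame(t_s = c(0, 60, 120), x_um = rep(1, 3),
                      y_um = rep(2, 3))
  expect_equal(path_length(still), 0)

  set.seed(7)
  tr <- random_track(n = 1001)
  brute <- 0
  for (k in 2:nrow(tr)) {
    brute <- brute + sqrt((tr$x_um[k] - tr$x_um[k - 1])^2 +
                            (tr$y_um[k] - tr$y_um[k - 1])^2)
  }
  expect_equal(path_length(tr), brute, tolerance = 1e-9)
  expect_error(path_length(tr[1, ]), "at least 2")
})

test_that("displacement never exceeds path length", {
  set.seed(11)
  for (k in seq_len(200)) {
    tr <- random_track(n = sample(3:60, 1))
    expect_lte(distance_from_origin(tr), path_length(tr) + 1e-12)
  }
  loop <- data.frame(t_s = 0:4 * 60, x_um = c(0, 1, 1, 0, 0),
                     y_um = c(0, 0, 1, 1, 0))
  expect_equal(distance_from_origin(loop), 0)
  straight <- data.frame(t_s = 0:3 * 60, x_um = 0:3, y_um = rep(0, 4))
  expect_equal(distance_from_origin(straight), path_length(straight))
})

test_that("average velocity is path over time and consistent by construction", {
  tr <- data.frame(t_s = c(0, 1800), x_um = c(0, 5), y_um = c(0, 0))
  expect_equal(average_velocity(tr), 10) # 5 um in 0.5 h
  set.seed(3)
  for (k in seq_len(20)) {
    tr <- random_track(n = sample(5:50, 1))
    dur_h <- (tr$t_s[nrow(tr)] - tr$t_s[1]) / 3600
    expect_equal(average_velocity(tr) * dur_h, path_length(tr))
    expect_equal(average_velocity(tr, "displacement") * dur_h,
                 distance_from_origin(tr))
  }
  zerodur <- data.frame(t_s = c(0, 0), x_um = c(0, 1), y_um = c(0, 0))
  expect_error(average_velocity(zerodur))
})

test_that("elliptical factor lies in (0, 1] with the width convention", {
  expect_equal(elliptical_factor(10, 20), 0.5)
  expect_equal(elliptical_factor(15, 15), 1)
  expect_warning(ef <- elliptical_factor(20, 10), "swap")
  expect_equal(ef, 0.5)
  set.seed(9)
  w <- runif(100, 1, 50)
  l <- w + runif(100, 0, 50)
  ef <- elliptical_factor(w, l)
  expect_true(all(ef > 0 & ef <= 1))
})

test_that("migration angle measures deviation from the spot perpendicular", {
  sp <- spot_geometry(c(0, 0), c(1, 0))
  along <- data.frame(t_s = c(0, 60), x_um = c(-10, 10), y_um = c(0, 0))
  expect_equal(migration_angle(along, sp), 0)
  tangent <- data.frame(t_s = c(0, 60), x_um = c(0, 0), y_um = c(0, 10))
  expect_equal(migration_angle(tangent, sp), 90)
  backward <- data.frame(t_s = c(0, 60), x_um = c(10, -10), y_um = c(0, 0))
  expect_equal(migration_angle(backward, sp), 180)
  still <- data.frame(t_s = c(0, 60), x_um = c(1, 1), y_um = c(1, 1))
  expect_error(migration_angle(still, sp), "undefined")
})

test_that("migrated-cell counting requires crossing and final position inside", {
  sp <- spot_geometry(c(0, 0), c(1, 0))
  outside <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(id = i, t_s = 0:3 * 60, x_um = -50 - i + 0:3, y_um = 0)
  }))
  expect_equal(as.integer(count_migrated(outside, sp)), 0)
  crossing <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(id = i, t_s = 0:3 * 60, x_um = c(-5, -1, 2, 6), y_um = i)
  }))
  expect_equal(as.integer(count_migrated(crossing, sp)), 10)
  # seeded-inside tracks never count
  seeded <- data.frame(id = 1, t_s = 0:3 * 60, x_um = c(5, 6, 7, 8),
                       y_um = 0)
  expect_equal(as.integer(count_migrated(seeded, sp)), 0)

  fg <- make_spot_field(field_config(n_cells = 60), "control", seed = 14)
  cnt <- count_migrated(fg$tracks, fg$spot)
  expect_equal(as.integer(cnt), length(fg$migrated_ids))
  expect_setequal(attr(cnt, "ids"), as.character(fg$migrated_ids))
})

test_that("percent decrease behaves and is scale invariant", {
  expect_equal(percent_decrease(100, 40), 60)
  expect_equal(percent_decrease(7.3, 7.3), 0)
  expect_equal(percent_decrease(10, 13), -30)
  set.seed(5)
  for (k in seq_len(20)) {
    a <- runif(1, 1, 100); b <- runif(1, 0, 150); s <- runif(1, 0.01, 50)
    expect_equal(percent_decrease(a, b), percent_decrease(s * a, s * b))
  }
  expect_error(percent_decrease(0, 5), "positive")
})

test_that("wound distance averages paired edge advances", {
  x <- seq(0, 500, by = 50)
  e0 <- cbind(x, rep(0, length(x)))
  e1 <- cbind(x, rep(50, length(x)))
  expect_equal(wound_distance(e0, e1), 50)
  expect_equal(wound_distance(e0, e0), 0)
  set.seed(8)
  adv <- runif(length(x), 20, 80)
  e1 <- cbind(x, adv)
  # brute-force oracle: mean of per-point advances along the normal (0, 1)
  expect_equal(wound_distance(e0, e1, normal = c(0, 1)), mean(adv))
  expect_error(wound_distance(e0, e1[1:3, ]), "same number")
})

test_that("track metric table flags migrated tracks and carries shape", {
  fg <- make_spot_field(field_config(n_cells = 30), "control", seed = 17)
  tm <- track_metrics(fg$tracks, fg$spot)
  expect_equal(nrow(tm), 30)
  expect_setequal(tm$id[tm$migrated], as.character(fg$migrated_ids))
  expect_true(all(tm$distance_um <= tm$path_um + 1e-9))
  expect_true(all(tm$elliptical_factor > 0 & tm$elliptical_factor <= 1))
})
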