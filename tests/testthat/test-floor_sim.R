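test_that("floor model orders modes by frequency and validates inputs", {
  fm <- floor_model()
  expect_true(all(diff(fm$modes$f_hz) >= 0))
  expect_equal(fm$modes$f_hz[1], 16.7)
  expect_equal(nrow(fm$modes), 25)
  expect_error(floor_model(zeta = 0.5), "zeta")
  expect_error(fallvibe:::mode_shape(fm, c(-1, 2)), "outside")
})

test_that("plate response is linear in the force and zero for zero force", {
  fm <- tiny_floor()
  fs <- 200
  t <- (0:399) / fs
  F <- fallvibe:::half_sine(t, 0.2, 0.05, 800)
  sens <- rbind(c(1, 1), c(3, 4))
  zero <- floor_response(fm, force_profile(t, 0 * F), c(2, 2.5), sens, fs)
  expect_true(all(zero$channels == 0))
  a1 <- floor_response(fm, force_profile(t, F), c(2, 2.5), sens, fs)
  a2 <- floor_response(fm, force_profile(t, 2 * F), c(2, 2.5), sens, fs)
  expect_equal(a2$channels, 2 * a1$channels)
})

test_that("single-mode impulse response matches the closed-form sinusoid", {
  fm <- floor_model(n_modes_x = 1, n_modes_y = 1, f11 = 12, zeta = 0.05)
  fs <- 500
  n <- 1000
  F <- numeric(n); F[1] <- 1000
  src <- c(1.3, 2.1); sen <- rbind(c(2.6, 3.4))
  a <- fallvibe:::floor_accel(fm, F, src, sen, fs)
  w <- 2 * pi * 12; z <- 0.05; wd <- w * sqrt(1 - z^2)
  t <- (0:(n - 1)) / fs
  phi <- function(xy) sin(pi * xy[1] / 4) * sin(pi * xy[2] / 5) /
    sqrt(fm$modal_mass)
  amp <- phi(src) * phi(sen[1, ]) * 1000 / fs
  hdd <- exp(-z * w * t) * ((z^2 * w^2 - wd^2) * sin(wd * t) / wd -
                              2 * z * w * cos(wd * t))
  expected <- amp * hdd / 9.81
  rel <- max(abs(a[-1] - expected[-1])) / max(abs(expected))
  expect_lt(rel, 1e-6)
})

test_that("rhythmic jumping places impulses at the metronome rate", {
  fp <- activity_force("rhythmic_jump", list(mass_kg = 70), fs = 1652,
                       duration = 10)
  peaks <- which(diff(sign(diff(fp$F))) == -2) + 1
  big <- peaks[fp$F[peaks] > 0.5 * max(fp$F)]
  expect_equal(diff(fp$t[big]), rep(2 / 3, length(big) - 1),
               tolerance = 1e-2)
})

test_that("drop impulse peaks scale linearly with mass", {
  f1 <- activity_force("ball_drop",
                       list(mass_kg = 0.6, drop_height_m = 1.45),
                       fs = 400, duration = 2)
  f2 <- activity_force("ball_drop",
                       list(mass_kg = 5, drop_height_m = 1.45),
                       fs = 400, duration = 2)
  expect_equal(max(f2$F) / max(f1$F), 5 / 0.6)
})

test_that("ball drops bounce with decaying restitution peaks", {
  fp <- activity_force("ball_drop",
                       list(mass_kg = 0.6, drop_height_m = 2.10),
                       fs = 1000, duration = 3)
  peaks <- which(diff(sign(diff(fp$F))) == -2) + 1
  peaks <- peaks[fp$F[peaks] > 0.01 * max(fp$F)]
  expect_gte(length(peaks), 3)
  expect_true(all(diff(fp$F[peaks]) < 0))
})

test_that("walking with zero steps produces zero force", {
  fp <- activity_force("walk", list(mass_kg = 70, n_steps = 0),
                       fs = 200, duration = 2)
  expect_true(all(fp$F == 0))
  expect_error(activity_force("handstand", list(), 200, 2))
})

test_that("fall activity force pads the resting weight beyond the schedule", {
  fp <- activity_force("fall", list(mass_kg = 70), fs = 200, duration = 3)
  expect_length(fp$F, 600)
  expect_equal(tail(fp$F, 1), 70 * 9.81)
})

test_that("scenario generation is deterministic and respects the inventory", {
  d <- small_design(seed = 31)
  fm <- floor_model()
  ds1 <- generate_scenario(d, fm)
  ds2 <- generate_scenario(d, fm)
  expect_equal(length(ds1), sum(vapply(d$inventory, `[[`, numeric(1),
                                       "count")))
  expect_identical(lapply(ds1$records, `[[`, "channels"),
                   lapply(ds2$records, `[[`, "channels"))
  expect_equal(table(event_labels(ds1))[["fall"]], 20)
  # a different seed changes the data
  ds3 <- generate_scenario(small_design(seed = 32), fm)
  expect_false(identical(ds1$records[[1]]$channels,
                         ds3$records[[1]]$channels))
})

test_that("fall events carry more peak signal than walking events", {
  ds <- small_dataset()
  v <- extract_views(ds)
  acts <- event_labels(ds)
  expect_gt(mean(v$peak$matrix[acts == "fall", 1]),
            mean(v$peak$matrix[acts == "walk", 1]))
})

test_that("preset designs replicate the study inventories", {
  lab <- preset_designs("lab_table1")
  counts <- vapply(lab$inventory, `[[`, numeric(1), "count")
  acts <- vapply(lab$inventory, `[[`, character(1), "activity")
  expect_equal(sum(counts), 1690)
  expect_equal(sum(counts[acts == "fall"]), 520)
  expect_equal(sum(counts[acts != "fall"]), 1170)
  expect_equal(lab$fs, 1652)
  expect_equal(sum(counts[acts == "walk"]), 130)
  bench <- preset_designs("benchmark_table8")
  bcounts <- vapply(bench$inventory, `[[`, numeric(1), "count")
  bacts <- vapply(bench$inventory, `[[`, character(1), "activity")
  expect_equal(sum(bcounts[bacts == "fall"]), 1725)
  expect_equal(sum(bcounts[bacts != "fall"]), 7475)
  masses <- unique(vapply(bench$inventory[bacts == "fall"],
                          function(e) e$params$mass_kg, numeric(1)))
  expect_setequal(masses, c(60, 70, 80))
  expect_error(preset_designs("lab_table9"))
})
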