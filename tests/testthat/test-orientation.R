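# tilt angles, histograms, order parameter, surface slope, corrected tilt

test_that("tilt of cardinal axis vectors", {
  base <- matrix(c(1, 1, 5), 1)
  expect_equal(tilt_angles(axis_frame(base, matrix(c(0, 0, -1), 1)))$alpha,
               180)
  expect_equal(tilt_angles(axis_frame(base, matrix(c(0, 1, 0), 1)))$alpha,
               90)
  expect_equal(tilt_angles(axis_frame(base, matrix(c(0, 0, 1), 1)))$alpha,
               0)
  expect_error(tilt_angles(axis_frame(base, matrix(c(0, 0, 0), 1))),
               "zero-length")
})

test_that("flat layer with zero tilt reads 180 degrees everywhere", {
  sp <- layer_spec(n_molecules = 100, wave = c(A = 0, B = 5, C = 0, y0 = 8),
                   tilt_mean = 0, tilt_sd = 0, z_noise = 0,
                   water_thickness = 0, seed = 4)
  ta <- tilt_angles(generate_layer(sp)$frame)
  expect_equal(ta$alpha, rep(180, 100), tolerance = 1e-8)
})

test_that("tilt histogram fractions, boundaries, and validation", {
  rec <- data.frame(time = 0, mol = 1:3, alpha = c(130, 130, 130))
  expect_equal(unname(tilt_histogram(rec, c(90, 120, 150, 180))),
               c(0, 1, 0))
  # half-open bins: 120 belongs to [120, 150)
  rec2 <- data.frame(time = 0, mol = 1, alpha = 120)
  expect_equal(unname(tilt_histogram(rec2, c(90, 120, 150, 180))),
               c(0, 1, 0))
  # uniform samples populate bins in proportion to width
  set.seed(11)
  recu <- data.frame(time = 0, mol = seq_len(20000),
                     alpha = runif(20000, 90, 180))
  h <- tilt_histogram(recu, c(90, 120, 150, 180))
  se <- sqrt((1 / 3) * (2 / 3) / 20000)
  expect_true(all(abs(h - 1 / 3) < 3 * se))
  expect_error(tilt_histogram(rec, c(120, 90)), "increasing")
  expect_error(tilt_histogram(rec[0, ], c(90, 180)), "empty")
})

test_that("order parameter identities", {
  mk <- function(a) data.frame(time = 0, mol = seq_along(a), alpha = a)
  expect_equal(order_parameter(mk(rep(180, 5)))$mean, 1)
  expect_equal(order_parameter(mk(rep(90, 5)))$mean, 0, tolerance = 1e-12)
  expect_equal(order_parameter(mk(rep(120, 5)))$mean, 0.5)
  set.seed(2)
  opv <- order_parameter(mk(runif(100, 90, 180)))$mean
  expect_true(opv >= -1 && opv <= 1)
})

test_that("per-block OP averages equal the global OP for equal blocks", {
  set.seed(3)
  rec <- do.call(rbind, lapply(0:99, function(t)
    data.frame(time = t, mol = 1:20, alpha = runif(20, 90, 180))))
  bs <- order_parameter(rec, mode = "per_block", block = 25)
  expect_equal(nrow(bs), 4L)
  global <- mean(cos((180 - rec$alpha) * pi / 180))
  expect_equal(mean(bs$mean), global, tolerance = 1e-12)
})

test_that("per-molecule OP respects the time window", {
  rec <- rbind(data.frame(time = 0, mol = 1:2, alpha = c(180, 90)),
               data.frame(time = 10, mol = 1:2, alpha = c(90, 90)))
  pm <- order_parameter(rec, mode = "per_molecule", window = c(0, 5))
  expect_equal(pm$op, c(1, 0), tolerance = 1e-12)
  expect_error(order_parameter(rec, mode = "per_molecule",
                               window = c(100, 200)), "window")
})

test_that("surface slope of exact lines", {
  pts45 <- data.frame(y = seq(0, 5, 0.1), z = seq(0, 5, 0.1))
  attr(pts45, "Ly") <- 5
  s <- surface_slope(pts45, window = c(0, 5.1))
  expect_equal(s$angle, 45, tolerance = 1e-9)
  pts0 <- data.frame(y = seq(0, 5, 0.1), z = rep(2, 51))
  attr(pts0, "Ly") <- 5
  expect_equal(surface_slope(pts0, window = c(0, 5.1))$angle, 0)
})

test_that("slope in the central window approaches the inflection slope", {
  sp <- layer_spec(tilt_mean = 0, tilt_sd = 0, z_noise = 0,
                   xy_jitter = 0.02, water_thickness = 0,
                   hbond_fraction = 0, seed = 7)
  lay <- generate_layer(sp)
  pts <- extract_surface_points(lay$frame)
  fit <- fit_sine(smooth_profile(pts, 50))
  sl <- surface_slope(pts, fit)
  expected <- atan(2 * pi * sp$wave[["A"]] / sp$wave[["B"]]) * 180 / pi
  expect_true(all(abs(sl$angle - expected) < 2))
  # a window spanning an extremum is refused; the segment's lower extremum
  # sits half a window-length below y_lo (windows are central halves)
  ex <- sl$y_lo[1] - (sl$y_hi[1] - sl$y_lo[1]) / 2
  expect_error(surface_slope(pts, fit, window = c(ex - 0.5, ex + 0.5)),
               "extremum")
})

test_that("scalar slope correction reproduces the subtraction arithmetic", {
  ct <- corrected_tilt(142, 37)
  expect_equal(ct$corrected, 105)
  expect_equal(corrected_tilt(142, 0)$corrected, 142)
  # aligned sense folds back into [0, 180]
  expect_equal(corrected_tilt(150, 40, sense = "aligned")$corrected, 170)
  expect_equal(corrected_tilt(170, 40, sense = "aligned")$corrected, 150)
})

test_that("corrected tilt SD combines tilt SD and slope SE in quadrature", {
  rec <- data.frame(time = 0, mol = 1:4, alpha = c(140, 142, 144, 142))
  sl <- data.frame(y_lo = 0, y_hi = 1, n = 10, slope = 0.75,
                   angle = 37, se_angle = 1)
  ct <- corrected_tilt(rec, sl)
  expect_equal(ct$corrected, mean(rec$alpha) - 37)
  expect_equal(ct$corrected_sd, sqrt(sd(rec$alpha)^2 + 1))
})

test_that("molecules along the local normal correct back to upright", {
  # multi-segment wave so the correction can be checked per segment
  sp <- layer_spec(wave = c(A = 1.2, B = 7, C = 0.3, y0 = 8),
                   tilt_mean = 0, tilt_sd = 0, z_noise = 0,
                   xy_jitter = 0.02, water_thickness = 0,
                   hbond_fraction = 0, seed = 19)
  lay <- generate_layer(sp)
  fr <- lay$frame
  pts <- extract_surface_points(fr)
  fit <- fit_sine(smooth_profile(pts, 50))
  sl <- surface_slope(pts, fit)
  expect_gte(nrow(sl), 2L)
  ta <- tilt_angles(fr)
  corr <- vapply(seq_len(nrow(sl)), function(i) {
    sel <- pts$y >= sl$y_lo[i] & pts$y < sl$y_hi[i]
    corrected_tilt(ta$alpha[ta$mol %in% pts$mol[sel]], sl[i, ],
                   sense = "aligned")$corrected
  }, 0)
  expect_true(all(abs(corr - 180) < 3))
  expect_lt(sd(corr), 3)
  # while the raw tilt varies strongly along the wave
  expect_gt(max(ta$alpha) - min(ta$alpha), 20)
})

test_that("per-molecule local tilt against the analytic wave is exact", {
  sp <- layer_spec(wave = c(A = 1.5, B = 8, C = -0.2, y0 = 8),
                   tilt_mean = 0, tilt_sd = 0, z_noise = 0,
                   water_thickness = 0, hbond_fraction = 0, seed = 23)
  lay <- generate_layer(sp)
  lt <- local_tilt_angles(lay$frame, sp$wave)
  expect_equal(lt$alpha_local, rep(180, sp$n_molecules), tolerance = 1e-6)
  # with sampled tilt, the local angles recover the generator's draws
  sp2 <- layer_spec(wave = c(A = 1.5, B = 8, C = -0.2, y0 = 8),
                    tilt_mean = 60, tilt_sd = 10, z_noise = 0,
                    water_thickness = 0, hbond_fraction = 0, seed = 23)
  lay2 <- generate_layer(sp2)
  lt2 <- local_tilt_angles(lay2$frame, sp2$wave)
  expect_equal(lt2$alpha_local, 180 - abs(lay2$truth$tilt_deg),
               tolerance = 1e-6)
})
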