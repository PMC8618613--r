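# geometric hydrogen-bond detection, categories, invariances, plateau

# a two-molecule frame with donor/H of molecule 1 and acceptor of molecule 2
# at a prescribed separation and H-D-A angle
dha_frame <- function(sep, ang_deg, box = c(10, 10, 20)) {
  ang <- ang_deg * pi / 180
  atoms <- rbind(
    data.frame(id = 1, mol = 1, resname = "ESC", name = "DON",
               role = "donor", mass = 16, x = 1, y = 1, z = 5),
    data.frame(id = 2, mol = 1, resname = "ESC", name = "HD1",
               role = "hydrogen", mass = 1,
               x = 1 + 0.1 * cos(ang), y = 1 + 0.1 * sin(ang), z = 5),
    data.frame(id = 3, mol = 2, resname = "ESC", name = "ACC",
               role = "acceptor", mass = 16, x = 1 + sep, y = 1, z = 5))
  monolayer_frame(atoms, box)
}

test_that("collinear pair at 0.28 nm is one bond; 0.40 nm is none", {
  expect_equal(nrow(detect_hbonds(dha_frame(0.28, 0))), 1L)
  expect_equal(nrow(detect_hbonds(dha_frame(0.40, 0))), 0L)
  # angle gate
  expect_equal(nrow(detect_hbonds(dha_frame(0.28, 45))), 0L)
  expect_equal(nrow(detect_hbonds(dha_frame(0.28, 29))), 1L)
})

test_that("criterion validation and donor-without-hydrogen are errors", {
  expect_error(hbond_criterion(dist = 0), "distance")
  expect_error(hbond_criterion(angle = 95), "angle")
  fr <- dha_frame(0.28, 0)
  fr$atoms <- fr$atoms[fr$atoms$role != "hydrogen", ]
  expect_error(detect_hbonds(fr), "role error")
})

test_that("detector matches the brute-force all-pairs oracle on noisy frames", {
  for (seed in c(21, 22, 23)) {
    sp <- layer_spec(n_molecules = 150, hbond_fraction = 0.4,
                     water_thickness = 0, n_frames = 2, frame_jitter = 0.04,
                     seed = seed)
    frs <- generate_trajectory(sp)$frames
    for (f in frs) {
      got <- detect_hbonds(f)
      want <- brute_force_hbonds(f)
      expect_equal(got[, c("donor", "hydrogen", "acceptor", "category")],
                   want)
    }
  }
})

test_that("oracle equivalence holds with 3-site water present", {
  sp <- layer_spec(n_molecules = 40, hbond_fraction = 0.3,
                   water_thickness = 1.5, water_model = "3site", seed = 31)
  f <- generate_layer(sp)$frame
  got <- detect_hbonds(f)
  want <- brute_force_hbonds(f)
  expect_equal(got[, c("donor", "hydrogen", "acceptor", "category")], want)
  expect_true(any(got$category == "ww"))
})

test_that("counts are invariant under rigid translation and lateral shift", {
  sp <- layer_spec(n_molecules = 120, hbond_fraction = 0.5,
                   water_thickness = 0, frame_jitter = 0.03, n_frames = 2,
                   seed = 8)
  f <- generate_trajectory(sp)$frames[[2]]
  ref <- detect_hbonds(f)
  shift <- f
  shift$atoms$x <- shift$atoms$x + 3.17
  shift$atoms$y <- shift$atoms$y - 1.4
  shift$atoms$z <- shift$atoms$z + 12
  expect_equal(detect_hbonds(shift)[, 1:3], ref[, 1:3])
  wrap <- f
  wrap$atoms$x <- (wrap$atoms$x + f$box[1] / 3) %% f$box[1]
  expect_equal(detect_hbonds(wrap)[, 1:3], ref[, 1:3])
})

test_that("tightening either cutoff never increases the count", {
  sp <- layer_spec(n_molecules = 150, hbond_fraction = 0.6,
                   water_thickness = 0, n_frames = 2, frame_jitter = 0.06,
                   seed = 13)
  f <- generate_trajectory(sp)$frames[[2]]
  n <- function(d, a) nrow(detect_hbonds(f, hbond_criterion(d, a)))
  base <- n(0.35, 30)
  for (d in c(0.32, 0.30, 0.27, 0.22))
    expect_lte(n(d, 30), base)
  for (a in c(25, 15, 8, 3))
    expect_lte(n(0.35, a), base)
  # and jointly, as a chain
  chain <- c(n(0.35, 30), n(0.30, 25), n(0.28, 15), n(0.25, 8))
  expect_true(all(diff(chain) <= 0))
})

test_that("intramolecular bonds are excluded by default, reported on request", {
  atoms <- rbind(
    data.frame(id = 1, mol = 1, resname = "ESC", name = "DON",
               role = "donor", mass = 16, x = 1, y = 1, z = 5),
    data.frame(id = 2, mol = 1, resname = "ESC", name = "HD1",
               role = "hydrogen", mass = 1, x = 1.1, y = 1, z = 5),
    data.frame(id = 3, mol = 1, resname = "ESC", name = "ACC",
               role = "acceptor", mass = 16, x = 1.3, y = 1, z = 5))
  fr <- monolayer_frame(atoms, c(10, 10, 10))
  expect_equal(nrow(detect_hbonds(fr)), 0L)
  hb <- detect_hbonds(fr, include_intra = TRUE)
  expect_equal(hb$category, "intra")
})

test_that("time series counts per frame and single-frame series work", {
  sp <- layer_spec(n_molecules = 80, hbond_fraction = 0.5,
                   water_thickness = 0, seed = 2)
  f <- generate_layer(sp)$frame
  hs <- hbond_timeseries(f)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_ss, nrow(detect_hbonds(f)))
  expect_equal(hs$per_molecule_ss, hs$n_ss / 80)
})

test_that("plateau detection: constant, ramp, and saturating exponential", {
  const <- block_average(0:299, rep(2, 300), 50)
  expect_equal(detect_plateau(const), 0)
  ramp <- block_average(0:999, (0:999) / 100, 50)
  expect_true(is.na(detect_plateau(ramp, rel_tol = 0.001)))
  # saturating exponential toward 15.3 per molecule, tau = 150 ns:
  # analytic 95% settling time is tau * ln(20) ~ 449 ns
  t <- 0:999
  v <- 15.3 - 5.3 * exp(-t / 150)
  onset <- detect_plateau(block_average(t, v, 50))
  t95 <- 150 * log(20)
  expect_lt(abs(onset - t95), 2 * 150)
  expect_error(detect_plateau(const, rel_tol = 0), "rel_tol")
  expect_error(detect_plateau(const[1:2, ]), "3 blocks")
})

test_that("plateau onset on a drifting synthetic trajectory is near settling", {
  sp <- layer_spec(n_molecules = 100, water_thickness = 0, n_frames = 40,
                   frame_dt = 25, frame_jitter = 0.01, seed = 5)
  tr <- generate_trajectory(sp, drift = list(start = 0.1, plateau = 0.9,
                                             tau = 150))
  hs <- hbond_timeseries(tr$frames, block = 100)
  onset <- detect_plateau(attr(hs, "blocks")$ss, rel_tol = 0.05)
  expect_false(is.na(onset))
  t95 <- 150 * log(20)
  expect_lt(abs(onset - t95), 2 * 150)
})
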