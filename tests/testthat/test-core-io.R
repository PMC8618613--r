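# frame container, coordinate formats, role maps, block averaging

test_that("round trips preserve coordinates to format precision", {
  lay <- generate_layer(layer_spec(n_molecules = 441, water_thickness = 0,
                                   seed = 2))
  fr <- lay$frame
  tol <- c(gro = 5.1e-4, pdb = 5.1e-5, xyz = 1e-8)
  for (fmt in names(tol)) {
    p <- file.path(tempdir(), paste0("rt.", fmt))
    write_frames(fr, p)
    back <- read_frames(p)
    expect_length(back, 1L)
    b <- back[[1]]
    expect_equal(nrow(b$atoms), nrow(fr$atoms))
    expect_lt(max(abs(b$atoms$x - fr$atoms$x), abs(b$atoms$y - fr$atoms$y),
                  abs(b$atoms$z - fr$atoms$z)), tol[[fmt]])
    expect_identical(b$atoms$role, fr$atoms$role)
    expect_equal(b$box, fr$box, tolerance = 1e-4)
  }
})

test_that("multi-frame files come back in time order with times", {
  frs <- generate_trajectory(layer_spec(n_molecules = 30,
                                        water_thickness = 0, n_frames = 3,
                                        frame_dt = 2, frame_jitter = 0.05,
                                        seed = 9))$frames
  for (fmt in c("gro", "pdb", "xyz")) {
    p <- file.path(tempdir(), paste0("mf.", fmt))
    write_frames(frs, p)
    back <- read_frames(p, dt = 2)
    expect_length(back, 3L)
    expect_equal(vapply(back, function(f) f$time, 0), c(0, 2, 4))
    expect_lt(max(abs(back[[3]]$atoms$z - frs[[3]]$atoms$z)), 6e-4)
  }
})

test_that("GRO carries the box from the file", {
  p <- file.path(tempdir(), "box.gro")
  writeLines(c("t= 0.0", "    2",
               "    1ESC    BAS    1   1.000   2.000   3.000",
               "    1ESC    TIP    2   1.000   2.000   2.000",
               "  14.70000  14.70000  17.18000"), p)
  fr <- read_frames(p)[[1]]
  expect_equal(fr$box, c(14.70, 14.70, 17.18))
  expect_equal(fr$atoms$x, c(1.0, 1.0))
})

test_that("format errors name the offending input", {
  p <- file.path(tempdir(), "empty.gro")
  file.create(p)
  expect_error(read_frames(p), "empty file")
  p2 <- file.path(tempdir(), "bad.gro")
  writeLines(c("title", "    1",
               "    1ESC    BAS    1   1.000   xxxxx   3.000",
               "  10.0 10.0 10.0"), p2)
  expect_error(read_frames(p2), "line 3")
  expect_error(read_frames(file.path(tempdir(), "nope.gro")), "not found")
})

test_that("writing an empty frame is refused", {
  fr <- monolayer_frame(
    data.frame(id = integer(0), mol = integer(0), resname = character(0),
               name = character(0), role = character(0), mass = numeric(0),
               x = numeric(0), y = numeric(0), z = numeric(0)),
    box = c(1, 1, 1))
  expect_error(write_frames(fr, file.path(tempdir(), "e.gro")), "0 atoms")
})

test_that("role assignment is deterministic and strict mode errors", {
  map <- default_rolemap()
  r1 <- assign_roles(c("ESC", "W"), c("BAS", "W"), map)
  r2 <- assign_roles(c("ESC", "W"), c("BAS", "W"), map)
  expect_identical(r1, r2)
  expect_equal(r1$role, c("aglycone_base", "water_O"))
  expect_error(assign_roles("XXX", "QQ", map, fallback = FALSE),
               "role error")
  fb <- assign_roles("XXX", "C1", map, fallback = TRUE)
  expect_equal(fb$role, "other")
  expect_equal(fb$mass, 12.011)
})

test_that("rolemap refuses duplicate keys and reads YAML", {
  expect_error(rolemap(data.frame(residue = c("A", "A"), atom = c("X", "X"),
                                  role = "donor", mass = 1)),
               "duplicate")
  p <- file.path(tempdir(), "rm.yaml")
  writeLines(c("roles:",
               "  - {residue: ESC, atom: BAS, role: aglycone_base, mass: 12.011}",
               "  - {residue: ESC, atom: TIP, role: aglycone_tip, mass: 12.011}"),
             p)
  rm_ <- read_rolemap(p)
  expect_s3_class(rm_, "rolemap")
  expect_equal(assign_roles("ESC", "TIP", rm_)$role, "aglycone_tip")
  # the shipped config matches the built-in map
  shipped <- read_rolemap(system.file("extdata", "synthetic_rolemap.yaml",
                                      package = "undulayer"))
  m <- merge(default_rolemap()$entries, shipped$entries,
             by = c("residue", "atom"))
  expect_equal(nrow(m), nrow(default_rolemap()$entries))
  expect_equal(m$role.x, m$role.y)
  expect_equal(m$mass.x, m$mass.y, tolerance = 1e-3)
})

test_that("frame invariants are enforced", {
  a <- data.frame(id = 1:2, mol = 1L, resname = "ESC",
                  name = c("BAS", "BAS"),
                  role = c("aglycone_base", "aglycone_base"), mass = 12,
                  x = 0, y = 0, z = 0:1)
  expect_error(monolayer_frame(a, c(10, 10, 10)), "exactly one aglycone")
  a$role <- c("aglycone_base", "aglycone_tip")
  expect_silent(monolayer_frame(a, c(10, 10, 10)))
  expect_error(monolayer_frame(a, c(-1, 10, 10)), "positive")
  a$x[1] <- NaN
  expect_error(monolayer_frame(a, c(10, 10, 10)), "finite")
})

test_that("block_average: anchored blocks, trailing partial dropped", {
  # constant series
  bs <- block_average(0:99, rep(3.5, 100), 25)
  expect_equal(bs$mean, rep(3.5, 4))
  expect_equal(bs$sd, rep(0, 4))
  # 1000 ns at 1 ns sampling, 50 ns blocks -> 20 blocks
  bs2 <- block_average(0:999, rnorm(1000), 50)
  expect_equal(nrow(bs2), 20L)
  # alternating +-1, even samples per block -> zero means
  bs3 <- block_average(0:99, rep(c(1, -1), 50), 10)
  expect_equal(bs3$mean, rep(0, 10))
  # trailing partial block dropped
  bs4 <- block_average(0:74, rep(1, 75), 50)
  expect_equal(nrow(bs4), 1L)
  expect_error(block_average(0:9, 1:10, 0), "positive")
  expect_error(block_average(c(0, 0, 1), 1:3, 1), "strictly increasing")
})

test_that("block_average is invariant to chunk concatenation", {
  set.seed(4)
  t <- 0:499
  v <- cumsum(rnorm(500))
  full <- block_average(t, v, 50)
  parts <- rbind(
    block_average(t[t < 250], v[t < 250], 50),
    block_average(t[t >= 250], v[t >= 250], 50))
  expect_equal(full$mean, parts$mean)
  expect_equal(full$t_start, parts$t_start)
})

test_that("block means stay inside the raw range", {
  set.seed(5)
  v <- rnorm(400)
  bs <- block_average(0:399, v, 37)
  expect_true(all(bs$mean >= min(v) & bs$mean <= max(v)))
})
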