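# synthetic undulated monolayer + water slab with analytic ground truth

#' Specification of a synthetic monolayer
#'
#' Defines the study conditions for a generated configuration: a square
#' lateral box holding `n_molecules` surfactant proxies at
#' `area_per_molecule`, a sinusoidal surface undulation
#' `z(y) = y0 + A*sin(2*pi*y/B + C)` along y, molecular axes at a sampled
#' angle to the local surface normal of the analytic wave, a water slab
#' below the surface, and a fraction of molecules placed within
#' hydrogen-bond geometry of a lattice neighbour.
#'
#' Defaults are the conditions of the dense escin layer they emulate:
#' 441 molecules at 0.49 nm2 (box 14.70 nm), wave A = 2.1 nm, B = 16.6 nm,
#' C = -0.5, y0 = 8.0 nm, tilt to the local normal 75 +/- 20 degrees,
#' water at 997 kg/m3.
#'
#' @param n_molecules number of surfactant molecules.
#' @param area_per_molecule nm2 per molecule; sets `Lx = Ly =
#'   sqrt(n_molecules * area_per_molecule)`.
#' @param wave named numeric `(A, B, C, y0)`: amplitude (nm), period (nm),
#'   horizontal phase (rad), vertical offset (nm).
#' @param tilt_mean,tilt_sd mean and SD (degrees) of the molecular-axis
#'   angle to the local surface normal.
#' @param z_noise Gaussian SD (nm) added to base-atom z.
#' @param xy_jitter Gaussian SD (nm) of lattice-position jitter.
#' @param water_thickness water-slab thickness (nm); 0 disables water.
#' @param water_density slab density, kg/m3.
#' @param water_model `"bead"` (single 18-amu bead) or `"3site"`
#'   (O + 2 H, for surfactant-water H-bond work).
#' @param hbond_fraction fraction of molecules given a donor placed within
#'   H-bond geometry of a neighbour's acceptor.
#' @param n_frames,frame_dt,frame_jitter trajectory length, frame stride
#'   (ns) and per-frame coordinate jitter SD (nm).
#' @param axis_length aglycone axis length, nm.
#' @param seed integer seed; independent RNG streams are derived from it for
#'   placement, tilt, z-noise, bond selection, water and frame jitter, so
#'   changing one knob does not shift unrelated draws.
#' @return Object of class `layer_spec`.
#' @export
layer_spec <- function(n_molecules = 441, area_per_molecule = 0.49,
                       wave = c(A = 2.1, B = 16.6, C = -0.5, y0 = 8.0),
                       tilt_mean = 75, tilt_sd = 20,
                       z_noise = 0.30, xy_jitter = 0.05,
                       water_thickness = 6, water_density = 997,
                       water_model = c("bead", "3site"),
                       hbond_fraction = 0.5,
                       n_frames = 1, frame_dt = 1, frame_jitter = 0.02,
                       axis_length = 1.0, seed = 1) {
  water_model <- match.arg(water_model)
  wave <- wave[c("A", "B", "C", "y0")]
  if (anyNA(wave)) .stopf("wave must name A, B, C, y0")
  if (n_molecules < 1) .stopf("parameter error: n_molecules must be >= 1")
  if (area_per_molecule <= 0)
    .stopf("parameter error: area_per_molecule must be > 0")
  if (wave["A"] < 0 || wave["B"] <= 0)
    .stopf("parameter error: need A >= 0 and B > 0")
  if (hbond_fraction < 0 || hbond_fraction > 1)
    .stopf("parameter error: hbond_fraction must be in [0, 1]")
  if (water_thickness > 0 && water_density <= 0)
    .stopf("parameter error: water density must be > 0")
  if (n_frames < 1) .stopf("parameter error: n_frames must be >= 1")
  L <- sqrt(n_molecules * area_per_molecule)
  if (wave["B"] > 10 * L)
    warning("wave period exceeds 10x the box length; fit unidentifiable",
            call. = FALSE)
  structure(list(
    n_molecules = as.integer(n_molecules),
    area_per_molecule = area_per_molecule, wave = wave,
    tilt_mean = tilt_mean, tilt_sd = tilt_sd, z_noise = z_noise,
    xy_jitter = xy_jitter, water_thickness = water_thickness,
    water_density = water_density, water_model = water_model,
    hbond_fraction = hbond_fraction, n_frames = as.integer(n_frames),
    frame_dt = frame_dt, frame_jitter = frame_jitter,
    axis_length = axis_length, seed = as.integer(seed), L = L),
    class = "layer_spec")
}

# analytic wave and its derivative
.wave_z <- function(y, w) unname(w["y0"] + w["A"] * sin(2 * pi * y / w["B"] + w["C"]))
.wave_dz <- function(y, w) unname(w["A"] * (2 * pi / w["B"]) *
                                    cos(2 * pi * y / w["B"] + w["C"]))

#' Generate one synthetic monolayer frame with ground truth
#'
#' Molecules sit on a jittered square lattice; the base atom follows the
#' analytic wave plus Gaussian z-noise; the aglycone axis (base to tip,
#' pointing into the water so an upright molecule reads a tilt near 180
#' degrees) is rotated away from the local inward surface normal by the
#' sampled tilt, leaning azimuthally *with* the surface slope; five inert
#' beads along the axis carry the remaining molecular mass; donor/hydrogen/
#' acceptor sites sit in the head-group region, and for a fraction of
#' molecules the donor is moved into ideal H-bond geometry (0.28 nm,
#' collinear hydrogen) with a lattice neighbour's acceptor.  Water beads
#' fill a slab of the requested thickness below the local surface.
#'
#' @param spec a [layer_spec()].
#' @param time frame time label, ns.
#' @param hbond_fraction optional override of `spec$hbond_fraction`
#'   (used by [generate_trajectory()] drift).
#' @return Object of class `synthetic_layer`: list with `frame`
#'   (a [monolayer_frame()]) and `truth` (wave parameters, per-molecule true
#'   tilt to the local normal, true H-bond triples, box).
#' @export
generate_layer <- function(spec, time = 0, hbond_fraction = NULL) {
  stopifnot(inherits(spec, "layer_spec"))
  n <- spec$n_molecules
  L <- spec$L
  w <- spec$wave
  fb <- hbond_fraction %||% spec$hbond_fraction

  # placement stream
  set.seed(spec$seed + 101L)
  ns <- ceiling(sqrt(n))
  sp <- L / ns
  i0 <- seq_len(n) - 1L
  gx <- (i0 %% ns + 0.5) * sp
  gy <- (i0 %/% ns + 0.5) * sp
  x <- .wrap(gx + rnorm(n, 0, spec$xy_jitter), L)
  y <- .wrap(gy + rnorm(n, 0, spec$xy_jitter), L)

  # z-noise stream
  set.seed(spec$seed + 202L)
  zb <- .wave_z(y, w) + rnorm(n, 0, spec$z_noise)

  # tilt stream: axis at sampled angle to the local inward normal (-n),
  # leaning in the y-z plane with the slope (azimuth 0 = slope direction)
  set.seed(spec$seed + 303L)
  theta <- rnorm(n, spec$tilt_mean, spec$tilt_sd) * pi / 180
  fp <- .wave_dz(y, w)
  nn <- sqrt(1 + fp^2)
  nvec <- cbind(0, -fp / nn, 1 / nn)           # outward local normal
  uvec <- cbind(1, 0, 0)                        # in-surface, lateral
  vvec <- cbind(0, nvec[, 3], -nvec[, 2])       # n x u: in-surface, along y
  lean <- sign(fp)
  lean[lean == 0] <- 1
  d <- -cos(theta) * nvec +
    sin(theta) * (lean * vvec)                  # unit axis, pointing down
  base <- cbind(x, y, zb)
  tip <- base + spec$axis_length * d

  # head-group sites
  don <- base + matrix(c(0, 0, 0.30), n, 3, byrow = TRUE)
  hyd <- don + matrix(c(0, 0, 0.10), n, 3, byrow = TRUE)
  acc <- base + matrix(c(0.15, 0, 0.30), n, 3, byrow = TRUE)

  # bonded pairs: disjoint x-adjacent lattice pairs, sampled reproducibly;
  # the same permutation is drawn for every frame so a drifting fraction
  # yields nested bond sets
  ix <- i0 %% ns; iy <- i0 %/% ns
  cand_a <- which(ix %% 2L == 0L & ix + 1L < ns &
                    (i0 + 1L) < n) # 0-based partner exists
  set.seed(spec$seed + 404L)
  cand_a <- cand_a[sample.int(length(cand_a))]
  m <- min(round(fb * n / 2), length(cand_a))
  truth_hb <- NULL
  if (m > 0) {
    a_i <- cand_a[seq_len(m)]
    b_i <- a_i + 1L
    u <- (base[a_i, , drop = FALSE] +
            matrix(c(0, 0, 0.30), m, 3, byrow = TRUE)) -
      acc[b_i, , drop = FALSE]
    u <- u / sqrt(rowSums(u^2))
    don[a_i, ] <- acc[b_i, , drop = FALSE] + 0.28 * u
    hyd[a_i, ] <- don[a_i, , drop = FALSE] - 0.10 * u
    truth_hb <- data.frame(donor_mol = a_i, acceptor_mol = b_i)
  }

  # per-molecule atom table (10 atoms each)
  bead_t <- seq_len(5) / 6
  names_per <- c("BAS", "TIP", "DON", "HD1", "ACC", paste0("M", 1:5))
  rm <- default_rolemap()$entries
  rmi <- match(paste("ESC", names_per, sep = "|"),
               paste(rm$residue, rm$atom, sep = "|"))
  coords <- vector("list", 10L)
  coords[[1]] <- base; coords[[2]] <- tip; coords[[3]] <- don
  coords[[4]] <- hyd; coords[[5]] <- acc
  for (j in seq_len(5))
    coords[[5L + j]] <- base + bead_t[j] * spec$axis_length * d
  surf <- do.call(rbind, lapply(seq_len(10L), function(k)
    data.frame(mol = seq_len(n), resname = "ESC", name = names_per[k],
               role = rm$role[rmi[k]], mass = rm$mass[rmi[k]],
               x = coords[[k]][, 1], y = coords[[k]][, 2],
               z = coords[[k]][, 3])))
  surf <- surf[order(surf$mol), ]

  # water stream: uniform density between a flat lower free surface at
  # y0 - thickness and the undulated upper surface z = f(y) (rejection
  # sampling keeps the density uniform under the wave)
  wat <- NULL
  if (spec$water_thickness > 0) {
    set.seed(spec$seed + 505L)
    vol <- L * L * spec$water_thickness  # mean column height = thickness
    nw <- round(spec$water_density * vol / (18.0154 * .amu_nm3_to_kg_m3))
    z_bot <- unname(w["y0"]) - spec$water_thickness
    z_top <- unname(w["y0"] + w["A"])
    wx <- wy <- wz <- numeric(0)
    while (length(wx) < nw) {
      todo <- nw - length(wx)
      draw <- ceiling(todo * (z_top - z_bot) /
                        max(spec$water_thickness, 1e-9)) + 16L
      cx <- runif(draw, 0, L); cy <- runif(draw, 0, L)
      cz <- runif(draw, z_bot, z_top)
      ok <- cz <= .wave_z(cy, w)
      wx <- c(wx, cx[ok]); wy <- c(wy, cy[ok]); wz <- c(wz, cz[ok])
    }
    wx <- wx[seq_len(nw)]; wy <- wy[seq_len(nw)]; wz <- wz[seq_len(nw)]
    if (spec$water_model == "bead") {
      wat <- data.frame(mol = n + seq_len(nw), resname = "W", name = "W",
                        role = "water_O", mass = 18.0154,
                        x = wx, y = wy, z = wz)
    } else {
      # rigid 3-site water at random orientation (O-H 0.0957 nm, 104.5 deg)
      az <- runif(nw, 0, 2 * pi); pol <- acos(runif(nw, -1, 1))
      e1 <- cbind(sin(pol) * cos(az), sin(pol) * sin(az), cos(pol))
      az2 <- runif(nw, 0, 2 * pi)
      # arbitrary unit vector orthogonal to e1
      ref <- cbind(-e1[, 2], e1[, 1], 0)
      bad <- abs(e1[, 3]) > 0.99
      ref[bad, ] <- cbind(1, 0, 0)[rep(1, sum(bad)), , drop = FALSE]
      ref <- ref - e1 * rowSums(ref * e1)
      ref <- ref / sqrt(rowSums(ref^2))
      e2 <- cbind(e1[, 2] * ref[, 3] - e1[, 3] * ref[, 2],
                  e1[, 3] * ref[, 1] - e1[, 1] * ref[, 3],
                  e1[, 1] * ref[, 2] - e1[, 2] * ref[, 1])
      hw <- 104.5 / 2 * pi / 180
      d1 <- cos(hw) * e1 + sin(hw) * (cos(az2) * ref + sin(az2) * e2)
      d2 <- cos(hw) * e1 - sin(hw) * (cos(az2) * ref + sin(az2) * e2)
      ow <- cbind(wx, wy, wz)
      wat <- do.call(rbind, list(
        data.frame(mol = n + seq_len(nw), resname = "SOL", name = "OW",
                   role = "water_O", mass = 15.999,
                   x = ow[, 1], y = ow[, 2], z = ow[, 3]),
        data.frame(mol = n + seq_len(nw), resname = "SOL", name = "HW1",
                   role = "water_H", mass = 1.008,
                   x = ow[, 1] + 0.0957 * d1[, 1],
                   y = ow[, 2] + 0.0957 * d1[, 2],
                   z = ow[, 3] + 0.0957 * d1[, 3]),
        data.frame(mol = n + seq_len(nw), resname = "SOL", name = "HW2",
                   role = "water_H", mass = 1.008,
                   x = ow[, 1] + 0.0957 * d2[, 1],
                   y = ow[, 2] + 0.0957 * d2[, 2],
                   z = ow[, 3] + 0.0957 * d2[, 3])))
      wat <- wat[order(wat$mol), ]
    }
  }

  atoms <- rbind(surf, wat)
  atoms <- cbind(id = seq_len(nrow(atoms)), atoms)
  frame <- monolayer_frame(atoms,
                           box = c(L, L, max(atoms$z) - min(atoms$z) + 10),
                           time = time)

  # ids of the true bonded triples (atom ids in the assembled table)
  truth_bonds <- NULL
  if (!is.null(truth_hb)) {
    id_lookup <- function(mols, nm) {
      sel <- atoms$name == nm & atoms$mol %in% mols
      atoms$id[sel][match(mols, atoms$mol[sel])]
    }
    truth_bonds <- data.frame(
      donor = id_lookup(truth_hb$donor_mol, "DON"),
      hydrogen = id_lookup(truth_hb$donor_mol, "HD1"),
      acceptor = id_lookup(truth_hb$acceptor_mol, "ACC"),
      donor_mol = truth_hb$donor_mol,
      acceptor_mol = truth_hb$acceptor_mol,
      category = "ss")
    truth_bonds <- truth_bonds[order(truth_bonds$donor), ]
    rownames(truth_bonds) <- NULL
  }

  structure(list(
    frame = frame,
    truth = list(wave = w, L = L,
                 tilt_deg = theta * 180 / pi,
                 base = base, axis = d,
                 hbonds = truth_bonds,
                 n_bonds = m)),
    class = "synthetic_layer")
}

#' Generate a synthetic trajectory
#'
#' Frames share the ground-truth wave and placement; each frame adds
#' independent Gaussian coordinate jitter of SD `frame_jitter`.  An optional
#' drift model moves the bonded-pair fraction along a saturating
#' exponential `f(t) = plateau + (start - plateau) * exp(-t / tau)` so that
#' relaxation-plateau detection has a known settling time.
#'
#' @param spec a [layer_spec()].
#' @param drift `NULL`, or `list(start=, plateau=, tau=)` for the H-bond
#'   fraction (tau in ns).
#' @return List with `frames` (list of [monolayer_frame()]) and `truth`
#'   (from the first frame, plus per-frame bond counts `n_bonds_t`).
#' @export
generate_trajectory <- function(spec, drift = NULL) {
  stopifnot(inherits(spec, "layer_spec"))
  if (!is.null(drift)) {
    stopifnot(all(c("start", "plateau", "tau") %in% names(drift)))
    if (drift$tau <= 0) .stopf("parameter error: drift tau must be > 0")
  }
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_dt
  frames <- vector("list", spec$n_frames)
  nb <- integer(spec$n_frames)
  truth <- NULL
  for (j in seq_len(spec$n_frames)) {
    f <- if (is.null(drift)) spec$hbond_fraction
         else drift$plateau + (drift$start - drift$plateau) *
           exp(-times[j] / drift$tau)
    lay <- generate_layer(spec, time = times[j],
                          hbond_fraction = min(max(f, 0), 1))
    fr <- lay$frame
    if (spec$frame_jitter > 0) {
      # per-frame jitter stream (generate_layer reseeds internally)
      set.seed(spec$seed + 606L + j)
      na <- nrow(fr$atoms)
      fr$atoms$x <- fr$atoms$x + rnorm(na, 0, spec$frame_jitter)
      fr$atoms$y <- fr$atoms$y + rnorm(na, 0, spec$frame_jitter)
      fr$atoms$z <- fr$atoms$z + rnorm(na, 0, spec$frame_jitter)
    }
    frames[[j]] <- fr
    nb[j] <- lay$truth$n_bonds
    if (j == 1L) truth <- lay$truth
  }
  truth$n_bonds_t <- data.frame(time = times, n_bonds = nb)
  list(frames = frames, truth = truth)
}
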