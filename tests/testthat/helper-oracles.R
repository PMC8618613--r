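# independent oracles and small frame builders used across tests

# brute-force all-pairs hydrogen-bond detector, written independently of
# the package's cell-list implementation: O(N^2) over donors x acceptors,
# lateral minimum image, best-hydrogen angle at the donor
brute_force_hbonds <- function(frame, dist_cut = 0.35, ang_cut = 30,
                               include_intra = FALSE) {
  a <- frame$atoms
  box <- frame$box
  mim <- function(d, L) d - L * round(d / L)
  don <- which(a$role == "donor" |
                 (a$role == "water_O" &
                    a$mol %in% a$mol[a$role == "water_H"]))
  acc <- which(a$role %in% c("acceptor", "water_O"))
  hyd <- which(a$role %in% c("hydrogen", "water_H"))
  surf_mols <- unique(a$mol[a$role == "aglycone_base"])
  water_mols <- unique(a$mol[a$role == "water_O"])
  out <- list()
  for (d in don) {
    hs <- hyd[a$mol[hyd] == a$mol[d]]
    if (!length(hs)) next
    # hydrogens belonging to this donor: nearest donor-capable atom wins
    dcap <- don[a$mol[don] == a$mol[d]]
    mine <- hs[vapply(hs, function(h) {
      d2 <- mim(a$x[dcap] - a$x[h], box[1])^2 +
        mim(a$y[dcap] - a$y[h], box[2])^2 + (a$z[dcap] - a$z[h])^2
      dcap[which.min(d2)] == d
    }, TRUE)]
    if (!length(mine)) next
    for (ac in acc) {
      if (ac == d) next
      intra <- a$mol[ac] == a$mol[d]
      if (intra && !include_intra) next
      dx <- mim(a$x[ac] - a$x[d], box[1])
      dy <- mim(a$y[ac] - a$y[d], box[2])
      dz <- a$z[ac] - a$z[d]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      if (r > dist_cut) next
      best <- Inf; bh <- NA_integer_
      for (h in mine) {
        vh <- c(mim(a$x[h] - a$x[d], box[1]), mim(a$y[h] - a$y[d], box[2]),
                a$z[h] - a$z[d])
        va <- c(dx, dy, dz)
        ang <- acos(min(1, max(-1, sum(vh * va) /
                                 sqrt(sum(vh^2) * sum(va^2))))) * 180 / pi
        if (ang < best) { best <- ang; bh <- h }
      }
      if (best <= ang_cut) {
        td <- if (a$mol[d] %in% surf_mols) "surfactant"
              else if (a$mol[d] %in% water_mols) "water" else "other"
        ta <- if (a$mol[ac] %in% surf_mols) "surfactant"
              else if (a$mol[ac] %in% water_mols) "water" else "other"
        cat_ <- if (intra) "intra"
                else if (td == "surfactant" && ta == "surfactant") "ss"
                else if (td == "water" && ta == "water") "ww" else "sw"
        out[[length(out) + 1L]] <- data.frame(
          donor = a$id[d], hydrogen = a$id[bh], acceptor = a$id[ac],
          category = cat_)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), category = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$donor, res$acceptor), ]
  rownames(res) <- NULL
  res
}

# a frame holding bare point atoms of one role (for RDF / density tests)
point_frame <- function(xyz, box, role = "aglycone_base", mass = 12,
                        resname = "X", name = "P") {
  n <- nrow(xyz)
  atoms <- data.frame(id = seq_len(n), mol = seq_len(n), resname = resname,
                      name = name, role = role, mass = mass,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (role == "aglycone_base") {
    tip <- atoms
    tip$role <- "aglycone_tip"
    tip$id <- tip$id + n
    tip$z <- tip$z - 1
    atoms <- rbind(atoms, tip)
  }
  monolayer_frame(atoms, box)
}

# a frame of surfactant axes with explicit base->tip vectors
axis_frame <- function(base, vec, box = c(10, 10, 20)) {
  n <- nrow(base)
  tip <- base + vec
  atoms <- rbind(
    data.frame(id = seq_len(n), mol = seq_len(n), resname = "ESC",
               name = "BAS", role = "aglycone_base", mass = 12,
               x = base[, 1], y = base[, 2], z = base[, 3]),
    data.frame(id = n + seq_len(n), mol = seq_len(n), resname = "ESC",
               name = "TIP", role = "aglycone_tip", mass = 12,
               x = tip[, 1], y = tip[, 2], z = tip[, 3]))
  monolayer_frame(atoms, box)
}

# analytic density profile from a function of z, on regular bins
analytic_profile <- function(f, zmax = 20, dz = 0.05, component = "water") {
  edges <- seq(0, zmax, by = dz)
  z <- (head(edges, -1) + tail(edges, -1)) / 2
  m <- matrix(f(z), ncol = 1, dimnames = list(NULL, component))
  density_profile(edges, m)
}
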