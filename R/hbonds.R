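# geometric hydrogen-bond detection, time series, relaxation plateau

#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triple is a hydrogen bond when the
#' donor-acceptor distance (lateral minimum image) is at most `dist` and the
#' hydrogen-donor-acceptor angle at the donor is at most `angle`.  The
#' defaults (0.35 nm, 30 degrees) are the convention of common MD analysis
#' tools.
#'
#' @param dist maximum donor-acceptor distance, nm.
#' @param angle maximum hydrogen-donor-acceptor angle, degrees.
#' @return Object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(dist = 0.35, angle = 30) {
  if (!.is_number(dist) || dist <= 0)
    .stopf("parameter error: distance cutoff must be > 0")
  if (!.is_number(angle) || angle <= 0 || angle > 90)
    .stopf("parameter error: angle cutoff must be in (0, 90]")
  structure(list(dist = dist, angle = angle), class = "hbond_criterion")
}

# donor/hydrogen/acceptor index sets of a frame; hydrogens are attached to
# the nearest donor-capable atom of the same molecule (lateral minimum image)
.hbond_sites <- function(frame) {
  a <- frame$atoms
  box <- frame$box
  don_i <- which(a$role == "donor" | a$role == "water_O")
  acc_i <- which(a$role == "acceptor" | a$role == "water_O")
  hyd_i <- which(a$role == "hydrogen" | a$role == "water_H")
  if (!length(don_i) || !length(acc_i))
    .stopf("frame contains no donor or no acceptor sites")
  # attach each hydrogen to the nearest donor-capable atom of its own
  # molecule (connectivity comes from the role map's molecule grouping,
  # not from a bond-length threshold)
  h_owner <- rep(NA_integer_, length(hyd_i))
  for (k in seq_along(hyd_i)) {
    h <- hyd_i[k]
    cand <- don_i[a$mol[don_i] == a$mol[h]]
    if (!length(cand)) next
    d2 <- .min_image(a$x[cand] - a$x[h], box[1])^2 +
      .min_image(a$y[cand] - a$y[h], box[2])^2 +
      (a$z[cand] - a$z[h])^2
    h_owner[k] <- cand[which.min(d2)]
  }
  # a pure-donor atom (role "donor") with no attached hydrogen is a role error
  strict_don <- don_i[a$role[don_i] == "donor"]
  no_h <- setdiff(strict_don, h_owner)
  if (length(no_h))
    .stopf("role error: donor atom(s) without an assigned hydrogen: id %s",
           paste(head(a$id[no_h], 5L), collapse = ", "))
  # water oxygens without hydrogens (bead water) cannot donate
  has_h <- don_i %in% h_owner
  list(don = don_i[has_h | a$role[don_i] == "donor"],
       acc = acc_i, hyd = hyd_i, h_owner = h_owner)
}

#' Detect hydrogen bonds in a frame
#'
#' Candidate donor-acceptor pairs are found with a lateral cell list
#' (minimum image in x and y; z is non-periodic, matching a slab with a
#' vacuum gap).  For each pair within the distance cutoff, the attached
#' hydrogen minimising the hydrogen-donor-acceptor angle is taken; the
#' triple is reported if that angle passes the cutoff.  Donor and acceptor
#' in the same molecule are excluded unless `include_intra = TRUE`, in which
#' case they are reported with category `"intra"`.
#'
#' Categories: `"ss"` surfactant-surfactant, `"sw"` surfactant-water (either
#' direction), `"ww"` water-water.
#'
#' @param frame a [monolayer_frame()].
#' @param criterion an [hbond_criterion()].
#' @param include_intra also report intramolecular bonds.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   ids), `donor_mol`, `acceptor_mol`, `category`, `distance`, `angle`.
#' @export
detect_hbonds <- function(frame, criterion = hbond_criterion(),
                          include_intra = FALSE) {
  stopifnot(inherits(frame, "monolayer_frame"),
            inherits(criterion, "hbond_criterion"))
  a <- frame$atoms
  box <- frame$box
  s <- .hbond_sites(frame)
  mtype <- molecule_types(frame)
  cut <- criterion$dist

  # lateral cell list over wrapped positions
  ncx <- max(1L, floor(box[1] / cut))
  ncy <- max(1L, floor(box[2] / cut))
  cellx <- function(x) floor(.wrap(x, box[1]) / box[1] * ncx) %% ncx
  celly <- function(y) floor(.wrap(y, box[2]) / box[2] * ncy) %% ncy
  acx <- cellx(a$x[s$acc]); acy <- celly(a$y[s$acc])
  acc_key <- acx * ncy + acy
  acc_split <- split(seq_along(s$acc), acc_key)

  dcx <- cellx(a$x[s$don]); dcy <- celly(a$y[s$don])
  hits_d <- integer(0); hits_a <- integer(0); hits_r <- numeric(0)
  offs <- expand.grid(ox = -1:1, oy = -1:1)
  don_key <- dcx * ncy + dcy
  for (key in unique(don_key)) {
    di <- which(don_key == key)
    kx <- key %/% ncy; ky <- key %% ncy
    nb_keys <- unique(((kx + offs$ox) %% ncx) * ncy + ((ky + offs$oy) %% ncy))
    cand <- unlist(acc_split[as.character(nb_keys)], use.names = FALSE)
    if (!length(cand)) next
    dI <- s$don[di]; aI <- s$acc[cand]
    dx <- .min_image(outer(a$x[dI], a$x[aI], "-"), box[1])
    dy <- .min_image(outer(a$y[dI], a$y[aI], "-"), box[2])
    dz <- outer(a$z[dI], a$z[aI], "-")
    r <- sqrt(dx^2 + dy^2 + dz^2)
    ok <- which(r <= cut, arr.ind = TRUE)
    if (nrow(ok)) {
      hits_d <- c(hits_d, di[ok[, 1]])
      hits_a <- c(hits_a, cand[ok[, 2]])
      hits_r <- c(hits_r, r[ok])
    }
  }
  if (!length(hits_d)) return(.empty_hbonds())

  dI <- s$don[hits_d]; aI <- s$acc[hits_a]
  same_atom <- dI == aI
  intra <- a$mol[dI] == a$mol[aI]
  keep <- !same_atom & (include_intra | !intra)
  dI <- dI[keep]; aI <- aI[keep]; rr <- hits_r[keep]
  if (!length(dI)) return(.empty_hbonds())

  # best hydrogen per (donor, acceptor)
  best_h <- integer(length(dI)); best_ang <- numeric(length(dI))
  for (k in seq_along(dI)) {
    hs <- s$hyd[which(s$h_owner == dI[k])]
    if (!length(hs)) { best_ang[k] <- Inf; next }
    vh <- cbind(.min_image(a$x[hs] - a$x[dI[k]], box[1]),
                .min_image(a$y[hs] - a$y[dI[k]], box[2]),
                a$z[hs] - a$z[dI[k]])
    va <- c(.min_image(a$x[aI[k]] - a$x[dI[k]], box[1]),
            .min_image(a$y[aI[k]] - a$y[dI[k]], box[2]),
            a$z[aI[k]] - a$z[dI[k]])
    cosang <- (vh %*% va) / (sqrt(rowSums(vh^2)) * sqrt(sum(va^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    j <- which.min(ang)
    best_h[k] <- hs[j]; best_ang[k] <- ang[j]
  }
  keep <- best_ang <= criterion$angle
  if (!any(keep)) return(.empty_hbonds())
  dI <- dI[keep]; aI <- aI[keep]
  out <- data.frame(
    donor = a$id[dI], hydrogen = a$id[best_h[keep]], acceptor = a$id[aI],
    donor_mol = a$mol[dI], acceptor_mol = a$mol[aI],
    category = NA_character_,
    distance = rr[keep], angle = best_ang[keep])
  td <- mtype[as.character(out$donor_mol)]
  ta <- mtype[as.character(out$acceptor_mol)]
  out$category <- ifelse(out$donor_mol == out$acceptor_mol, "intra",
    ifelse(td == "surfactant" & ta == "surfactant", "ss",
      ifelse(td == "water" & ta == "water", "ww", "sw")))
  out <- out[order(out$donor, out$acceptor), ]
  rownames(out) <- NULL
  out
}

.empty_hbonds <- function()
  data.frame(donor = integer(0), hydrogen = integer(0),
             acceptor = integer(0), donor_mol = integer(0),
             acceptor_mol = integer(0), category = character(0),
             distance = numeric(0), angle = numeric(0))

#' Per-frame hydrogen-bond counts by category
#'
#' @param frames list of [monolayer_frame()].
#' @param criterion an [hbond_criterion()].
#' @param block optional block duration (ns); if given, block averages of
#'   the per-molecule counts are attached.
#' @param include_intra include intramolecular bonds in the `ss` count.
#' @return Object of class `hbond_series`: data.frame with `time`, `n_ss`,
#'   `n_sw`, `n_ww`, `per_molecule_ss`, `per_molecule_sw`; attribute
#'   `blocks` (list of [block_average()] results) when `block` is given.
#' @export
hbond_timeseries <- function(frames, criterion = hbond_criterion(),
                             block = NULL, include_intra = FALSE) {
  if (inherits(frames, "monolayer_frame")) frames <- list(frames)
  if (!length(frames)) .stopf("need at least one frame")
  rows <- lapply(frames, function(f) {
    hb <- detect_hbonds(f, criterion, include_intra = include_intra)
    nsurf <- sum(molecule_types(f) == "surfactant")
    n_ss <- sum(hb$category == "ss") +
      if (include_intra) sum(hb$category == "intra") else 0L
    n_sw <- sum(hb$category == "sw")
    data.frame(time = f$time, n_ss = n_ss, n_sw = n_sw,
               n_ww = sum(hb$category == "ww"),
               per_molecule_ss = n_ss / nsurf,
               per_molecule_sw = n_sw / nsurf)
  })
  out <- do.call(rbind, rows)
  blocks <- NULL
  if (!is.null(block) && nrow(out) > 1L)
    blocks <- list(
      ss = block_average(out$time, out$per_molecule_ss, block),
      sw = block_average(out$time, out$per_molecule_sw, block))
  structure(out, blocks = blocks, class = c("hbond_series", "data.frame"))
}

#' Detect the relaxation plateau of a block-averaged series
#'
#' Returns the start time of the earliest suffix of at least three blocks
#' whose means all lie within `rel_tol` (relative to the suffix mean) of the
#' suffix mean, or `NA` if no such suffix exists.
#'
#' @param blocks a [block_average()] result (or data.frame with `t_start`
#'   and `mean`).
#' @param rel_tol relative tolerance.
#' @return Onset time (ns), or `NA_real_`.
#' @export
detect_plateau <- function(blocks, rel_tol = 0.02) {
  if (!.is_number(rel_tol) || rel_tol <= 0)
    .stopf("parameter error: rel_tol must be > 0")
  if (!is.data.frame(blocks) || !all(c("t_start", "mean") %in% names(blocks)))
    .stopf("blocks must have columns t_start, mean")
  n <- nrow(blocks)
  if (n < 3L) .stopf("need at least 3 blocks")
  m <- blocks$mean
  for (k in seq_len(n - 2L)) {
    suf <- m[k:n]
    mu <- mean(suf)
    if (all(abs(suf - mu) <= rel_tol * abs(mu) + 1e-15))
      return(blocks$t_start[k])
  }
  NA_real_
}
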