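# mass-density profiles along z, equimolecular dividing surface, half-widths

#' Construct a density profile object
#'
#' Normally produced by [compute_density_profile()]; the constructor is
#' exported so analytic profiles can be fed to [locate_eds()] and
#' [peak_half_width()].
#'
#' @param edges bin edges along z, nm (length `nbin + 1`).
#' @param density matrix `nbin x k` of densities, kg/m3, with named columns
#'   (conventionally `system`, `water`, `surfactant`).
#' @param sd optional matrix of per-block standard deviations.
#' @param box lateral box `(Lx, Ly)`, nm (optional, for mass integrals).
#' @return Object of class `density_profile`.
#' @export
density_profile <- function(edges, density, sd = NULL, box = NULL) {
  density <- as.matrix(density)
  if (length(edges) != nrow(density) + 1L)
    .stopf("edges must have nrow(density) + 1 values")
  if (any(density < 0, na.rm = TRUE)) .stopf("densities must be >= 0")
  structure(list(edges = edges, z = (head(edges, -1L) + tail(edges, -1L)) / 2,
                 bin_width = diff(edges)[1L], density = density, sd = sd,
                 box = box),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d bins of %.4g nm, z in [%.3g, %.3g] nm\n",
              length(x$z), x$bin_width, min(x$edges), max(x$edges)))
  cat("  components:", paste(colnames(x$density), collapse = ", "), "\n")
  invisible(x)
}

#' Mass-density profile along z per component
#'
#' Per-bin density is (mass in bin) / (Lx * Ly * bin_width), converted to
#' kg/m3 and averaged over frames.  Components are `system` (all atoms),
#' `water` and `surfactant` (by molecule type).  Atoms are binned at their
#' actual (unwrapped) z, so material in the vacuum gap is counted where it
#' sits.  With `block` set, the profile SD across block means is attached.
#'
#' @param frames list of [monolayer_frame()].
#' @param bin_width bin width, nm.
#' @param block optional block duration, ns.
#' @param z_range optional `(zmin, zmax)`; default spans the data.
#' @return A [density_profile()].
#' @export
compute_density_profile <- function(frames, bin_width = 0.05, block = NULL,
                                    z_range = NULL) {
  if (inherits(frames, "monolayer_frame")) frames <- list(frames)
  if (!length(frames)) .stopf("need at least one frame")
  if (!.is_number(bin_width) || bin_width <= 0)
    .stopf("parameter error: bin_width must be > 0")
  box <- frames[[1L]]$box
  if (bin_width > box[3L])
    .stopf("parameter error: bin_width exceeds the box height")
  if (is.null(z_range)) {
    zr <- range(unlist(lapply(frames, function(f) range(f$atoms$z))))
    z_range <- c(floor(zr[1L] / bin_width) * bin_width,
                 ceiling((zr[2L] + 1e-9) / bin_width) * bin_width)
  }
  edges <- seq(z_range[1L], z_range[2L], by = bin_width)
  nbin <- length(edges) - 1L
  comp_names <- c("system", "water", "surfactant")

  one_frame <- function(f) {
    a <- f$atoms
    mt <- molecule_types(f)
    comp <- mt[as.character(a$mol)]
    idx <- findInterval(a$z, edges, rightmost.closed = TRUE)
    ok <- idx >= 1L & idx <= nbin
    m <- matrix(0, nbin, 3L, dimnames = list(NULL, comp_names))
    add <- function(col, sel) {
      if (any(sel)) {
        s <- rowsum(a$mass[sel], idx[sel])
        m[as.integer(rownames(s)), col] <<- s[, 1L]
      }
    }
    add("system", ok)
    add("water", ok & comp == "water")
    add("surfactant", ok & comp == "surfactant")
    m
  }
  per_frame <- lapply(frames, one_frame)
  vol <- box[1L] * box[2L] * bin_width           # nm^3
  to_kg <- .amu_nm3_to_kg_m3 / vol
  mean_rho <- Reduce(`+`, per_frame) / length(per_frame) * to_kg

  sdm <- NULL
  if (!is.null(block) && length(frames) > 1L) {
    times <- vapply(frames, function(f) f$time, 0)
    bk <- floor(times / block)
    means <- lapply(split(seq_along(frames), bk), function(ii)
      Reduce(`+`, per_frame[ii]) / length(ii) * to_kg)
    if (length(means) > 1L) {
      mu <- Reduce(`+`, means) / length(means)
      sdm <- sqrt(Reduce(`+`, lapply(means, function(m) (m - mu)^2)) /
                    (length(means) - 1L))
    }
  }
  density_profile(edges, mean_rho, sd = sdm, box = box[1:2])
}

#' Integrated mass per component of a density profile
#'
#' @param profile a [density_profile()] with a lateral box attached.
#' @return Named vector of total masses, amu.
#' @export
profile_mass <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  if (is.null(profile$box)) .stopf("profile carries no lateral box")
  area <- profile$box[1L] * profile$box[2L]
  colSums(profile$density) * profile$bin_width * area / .amu_nm3_to_kg_m3
}

#' Locate the equimolecular dividing surface
#'
#' Gibbs construction on the water profile for a slab whose upper interface
#' is analysed: the bulk density is estimated as the mean over the window
#' of width `bulk_window` with the smallest mean |density gradient| (among
#' windows at least half as dense as the water maximum); the EDS is the
#' height `z_e` above that window at which the integrated water deficit
#' below `z_e` (relative to bulk) equals the integrated excess above, i.e.
#' `z_e = z_b + M_above / rho_bulk` with `M_above` the water mass per area
#' above the bulk window's upper edge `z_b`.
#'
#' @param profile a [density_profile()] with a `water` column (or a single
#'   unnamed column).
#' @param bulk_window width of the bulk-estimation window, nm.
#' @param max_sd_frac error if the SD of the chosen window exceeds this
#'   fraction of its mean (no identifiable bulk plateau).
#' @return List with `z` (EDS position, nm) and `bulk_density` (kg/m3).
#' @export
locate_eds <- function(profile, bulk_window = 1, max_sd_frac = 0.05) {
  stopifnot(inherits(profile, "density_profile"))
  rho <- if ("water" %in% colnames(profile$density))
    profile$density[, "water"] else profile$density[, 1L]
  z <- profile$z
  dz <- profile$bin_width
  wbin <- max(2L, round(bulk_window / dz))
  nb <- length(rho)
  if (nb < wbin + 2L) .stopf("profile too short for the bulk window")
  starts <- seq_len(nb - wbin + 1L)
  wmean <- vapply(starts, function(i) mean(rho[i:(i + wbin - 1L)]), 0)
  grad <- abs(diff(rho)) / dz
  wgrad <- vapply(starts, function(i) mean(grad[i:(i + wbin - 2L)]), 0)
  cand <- which(wmean >= 0.5 * max(rho))
  if (!length(cand)) .stopf("analysis error: no bulk water region")
  best <- cand[which.min(wgrad[cand])]
  win <- rho[best:(best + wbin - 1L)]
  if (sd(win) > max_sd_frac * mean(win))
    .stopf("analysis error: no bulk plateau detected (window SD %.3g > %g%% of mean)",
           sd(win), 100 * max_sd_frac)
  rho_b <- mean(win)
  ib <- best + wbin - 1L            # last bin inside the bulk window
  m_above <- sum(rho[(ib + 1L):nb]) * dz
  z_b <- profile$edges[ib + 1L]     # upper edge of the bulk window
  ze <- z_b + m_above / rho_b
  wet <- range(z[rho > 0])
  if (ze < wet[1L] - dz || ze > wet[2L] + dz)
    .stopf("analysis error: EDS outside the wetted z-range")
  list(z = ze, bulk_density = rho_b)
}

#' Half-width (FWHM/2) of a component density peak
#'
#' Finds the dominant maximum of the component profile and returns half of
#' its full width at half maximum, with the half-maximum crossings located
#' by linear interpolation between bin centres.  Two equal non-adjacent
#' maxima are refused as ambiguous; a peak whose half-maximum level is not
#' crossed on both sides (peak touching the z-boundary) is an error.
#'
#' @param profile a [density_profile()].
#' @param component column name, default `"surfactant"`.
#' @return Half-width, nm.
#' @export
peak_half_width <- function(profile, component = "surfactant") {
  stopifnot(inherits(profile, "density_profile"))
  v <- if (component %in% colnames(profile$density))
    profile$density[, component]
  else .stopf("no component '%s' in profile", component)
  z <- profile$z
  vmax <- max(v)
  if (vmax <= 0) .stopf("analysis error: empty component profile")
  peaks <- which(v >= vmax * (1 - 1e-9))
  if (any(diff(peaks) > 1L))
    .stopf("analysis error: ambiguous peak (two equal maxima)")
  ip <- peaks[ceiling(length(peaks) / 2)]
  half <- vmax / 2
  cross <- function(side) {
    idx <- if (side < 0) rev(seq_len(ip - 1L)) else (ip + 1L):length(v)
    if (ip + side < 1L || ip + side > length(v))
      .stopf("analysis error: peak touches the z-boundary")
    prev <- ip
    for (i in idx) {
      if (v[i] <= half) {
        # linear interpolation between bin centres prev and i
        frac <- (v[prev] - half) / (v[prev] - v[i])
        return(z[prev] + frac * (z[i] - z[prev]))
      }
      prev <- i
    }
    .stopf("analysis error: peak touches the z-boundary")
  }
  (cross(+1L) - cross(-1L)) / 2
}
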