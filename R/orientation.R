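# aglycone tilt, tilt histograms, rotational order parameter,
# surface slope and slope-corrected tilt

#' Per-molecule aglycone tilt angles
#'
#' The tilt alpha of a molecule is the angle between its aglycone vector
#' (tip minus base) and the +z axis, in degrees.  With the axis convention
#' of the synthetic layer — tip below base, pointing into the water — an
#' upright molecule reads alpha near 180 degrees and a flat-lying one near
#' 90 degrees.
#'
#' @param frames a [monolayer_frame()] or list of them.
#' @return Object of class `tilt_record`: data.frame with `time`, `mol`,
#'   `alpha` (degrees in `[0, 180]`).
#' @export
tilt_angles <- function(frames) {
  if (inherits(frames, "monolayer_frame")) frames <- list(frames)
  rows <- lapply(frames, function(f) {
    ax <- .axis_atoms(f)
    v <- ax$tip - ax$base
    len <- sqrt(rowSums(v^2))
    if (any(len < 1e-12))
      .stopf("geometry error: zero-length aglycone vector (molecule %s)",
             ax$mol[which(len < 1e-12)[1L]])
    alpha <- acos(pmin(1, pmax(-1, v[, 3L] / len))) * 180 / pi
    data.frame(time = f$time, mol = ax$mol, alpha = alpha)
  })
  structure(do.call(rbind, rows), class = c("tilt_record", "data.frame"))
}

#' Tilt histogram over angle bins
#'
#' Fractions over half-open bins `[lo, hi)`; values outside the covered
#' range are ignored and the returned fractions sum to 1 over the range.
#'
#' @param record a [tilt_angles()] result.
#' @param breaks increasing bin edges, degrees.
#' @return Named numeric vector of fractions, one per bin.
#' @export
tilt_histogram <- function(record, breaks = c(90, 120, 150, 180)) {
  if (!nrow(record)) .stopf("parameter error: empty tilt record")
  if (is.unsorted(breaks, strictly = TRUE))
    .stopf("parameter error: bin edges must be strictly increasing")
  a <- record$alpha
  idx <- findInterval(a, breaks)                  # [lo, hi)
  idx[a >= breaks[length(breaks)]] <- 0L          # beyond last edge: drop
  idx[abs(a - breaks[length(breaks)]) < 1e-9] <- length(breaks) - 1L
  inb <- idx >= 1L & idx <= length(breaks) - 1L
  if (!any(inb)) .stopf("no tilt values inside the histogram range")
  cnt <- tabulate(idx[inb], nbins = length(breaks) - 1L)
  setNames(cnt / sum(cnt),
           paste0("[", head(breaks, -1L), ",", tail(breaks, -1L), ")"))
}

#' Rotational order parameter
#'
#' `OP = mean(cos(180 - alpha))` over molecules and time: 1 for all
#' molecules upright (alpha = 180), 0 for flat-lying or isotropic
#' (alpha = 90).  `mode = "per_block"` averages over all molecules and
#' frames within consecutive blocks; `mode = "per_molecule"` averages over
#' time for each molecule inside the requested window.
#'
#' @param record a [tilt_angles()] result.
#' @param mode `"per_block"` or `"per_molecule"`.
#' @param block block duration, ns (per_block mode).
#' @param window optional `(t0, t1)` time window, ns.
#' @return For `per_block`: a [block_average()]-style data.frame of OP per
#'   block.  For `per_molecule`: data.frame with `mol`, `op`.
#' @export
order_parameter <- function(record, mode = c("per_block", "per_molecule"),
                            block = 50, window = NULL) {
  mode <- match.arg(mode)
  if (!nrow(record)) .stopf("parameter error: empty tilt record")
  r <- record
  if (!is.null(window)) {
    r <- r[r$time >= window[1L] & r$time <= window[2L], ]
    if (!nrow(r)) .stopf("parameter error: window outside record times")
  }
  opv <- cos((180 - r$alpha) * pi / 180)
  if (mode == "per_molecule") {
    out <- data.frame(op = as.numeric(tapply(opv, r$mol, mean)))
    out <- cbind(mol = as.integer(names(tapply(opv, r$mol, mean))), out)
    rownames(out) <- NULL
    return(out)
  }
  # per-frame mean first is unnecessary: the block mean over all
  # (molecule, frame) samples equals the mean of per-frame means when
  # every frame carries the same molecules
  times <- sort(unique(r$time))
  per_t <- tapply(opv, r$time, mean)
  if (length(times) == 1L) {
    return(data.frame(block = 0L, t_start = times, t_mid = times, n = 1L,
                      mean = as.numeric(per_t), sd = 0))
  }
  block_average(times, as.numeric(per_t[as.character(times)]), block)
}

#' Surface slope from a linear fit of base-atom z vs y
#'
#' Fits `z = a*y + b` over the base-atom coordinates inside each fit window
#' and reports the slope angle `arctan(|a|)` relative to the x-y plane
#' (equivalently, the tilt of the surface relative to the z-axis is
#' 90 degrees minus this; the angle reported here is the one entering the
#' tilt correction).  Windows default to the central half of each monotonic
#' segment of the fitted wave between consecutive extrema inside the box; a
#' user window containing an extremum of the fitted wave is refused.
#'
#' @param points a `surface_points` set (see [extract_surface_points()]) or
#'   a [monolayer_frame()] (base atoms are used).
#' @param fit a [fit_sine()] result used to locate wave segments (required
#'   unless `window` is given).
#' @param window optional `(y_lo, y_hi)` nm for a single fit window.
#' @param min_points minimum base-atom points per window.
#' @return data.frame with one row per window: `y_lo`, `y_hi`, `n`,
#'   `slope` (dz/dy), `angle` (degrees), `se_angle`.
#' @export
surface_slope <- function(points, fit = NULL, window = NULL,
                          min_points = 10) {
  pts <- .as_surface_points(points)
  windows <- if (!is.null(window)) {
    if (!is.null(fit)) {
      ex <- .wave_extrema(fit, attr(pts, "Ly"))
      if (any(ex > window[1L] & ex < window[2L]))
        .stopf("analysis error: fit window contains an extremum of the wave")
    }
    matrix(window, 1L)
  } else {
    if (is.null(fit)) .stopf("either a wave fit or an explicit window is required")
    .segment_windows(fit, attr(pts, "Ly"))
  }
  rows <- apply(windows, 1L, function(wn) {
    sel <- pts$y >= wn[1L] & pts$y < wn[2L]
    if (sum(sel) < min_points)
      .stopf("analysis error: fewer than %d base atoms in window [%.2f, %.2f]",
             min_points, wn[1L], wn[2L])
    m <- lm(z ~ y, data = pts[sel, ])
    a <- coef(m)[["y"]]
    # vcov warns on an exactly collinear (zero-residual) fit; the zero SE
    # it returns is the right answer there
    se_a <- sqrt(suppressWarnings(vcov(m))["y", "y"])
    data.frame(y_lo = wn[1L], y_hi = wn[2L], n = sum(sel), slope = a,
               angle = atan(abs(a)) * 180 / pi,
               se_angle = se_a / (1 + a^2) * 180 / pi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# extrema positions of the fitted wave inside [0, Ly)
.wave_extrema <- function(fit, Ly) {
  k <- 2 * pi / fit$B
  m <- seq(floor((-fit$C - pi / 2) * fit$B / (2 * pi)) - 1L,
           ceiling((k * Ly + pi) / pi) + 1L)
  y <- (pi / 2 + m * pi - fit$C) / k
  sort(y[y > 0 & y < Ly])
}

# central-half windows of full monotonic segments between extrema
.segment_windows <- function(fit, Ly) {
  ex <- .wave_extrema(fit, Ly)
  if (length(ex) < 2L)
    .stopf("analysis error: fewer than two wave extrema inside the box")
  lo <- head(ex, -1L); hi <- tail(ex, -1L)
  len <- hi - lo
  cbind(lo + len / 4, hi - len / 4)
}

#' Slope-corrected mean tilt
#'
#' Scalar correction of the mean tilt by the surface slope angle.  Because
#' measured tilts are folded into `[0, 180]`, the rotational sense of the
#' molecular lean relative to the surface slope is lost; both senses are
#' provided.  With `sense = "opposing"` (lean opposing the slope, so the
#' two contributions add in the raw angle) the corrected tilt is
#' `mean(alpha) - slope`; with `sense = "aligned"` (lean following the
#' slope, as in the synthetic generator) it is `mean(alpha) + slope`,
#' folded back into `[0, 180]`.  The SD combines the tilt SD and the slope
#' standard error in quadrature.
#'
#' @param record a [tilt_angles()] result, or a numeric vector of tilt
#'   angles (degrees).
#' @param slope a [surface_slope()] row (data.frame) or a slope angle in
#'   degrees.
#' @param sense `"opposing"` or `"aligned"`.
#' @return data.frame with `raw_mean`, `raw_sd`, `slope`, `corrected`,
#'   `corrected_sd`.
#' @export
corrected_tilt <- function(record, slope, sense = c("opposing", "aligned")) {
  sense <- match.arg(sense)
  alpha <- if (is.data.frame(record)) record$alpha else as.numeric(record)
  if (!length(alpha)) .stopf("parameter error: no tilt angles")
  if (is.data.frame(slope)) {
    s <- slope$angle; se <- slope$se_angle %||% 0
  } else {
    s <- as.numeric(slope); se <- 0
  }
  if (length(s) != 1L)
    .stopf("corrected_tilt expects a single slope; map over rows for segments")
  mu <- mean(alpha)
  corr <- if (sense == "opposing") mu - s else mu + s
  if (corr > 180) corr <- 360 - corr
  if (corr < 0) corr <- -corr
  sdv <- if (length(alpha) > 1L) sd(alpha) else 0
  data.frame(raw_mean = mu, raw_sd = sdv, slope = s, corrected = corr,
             corrected_sd = sqrt(sdv^2 + se^2))
}

#' Per-molecule tilt relative to the local normal of a fitted wave
#'
#' Extension of the scalar slope correction: for each surfactant the angle
#' between its aglycone vector and the inward local normal of the fitted
#' (or analytic) wave at the molecule's y, reported on the same 0-180 scale
#' as [tilt_angles()] (180 = along the inward normal, i.e. locally upright).
#'
#' @param frame a [monolayer_frame()].
#' @param wave a [fit_sine()] result or named vector `(A, B, C, y0)`.
#' @return data.frame with `mol`, `alpha_local` (degrees).
#' @export
local_tilt_angles <- function(frame, wave) {
  ax <- .axis_atoms(frame)
  w <- if (inherits(wave, "surface_wave_fit"))
    c(A = wave$A, B = wave$B, C = wave$C, y0 = wave$y0) else wave
  fp <- .wave_dz(ax$base[, 2L], w)
  nn <- sqrt(1 + fp^2)
  nvec <- cbind(0, -fp / nn, 1 / nn)
  v <- ax$tip - ax$base
  v <- v / sqrt(rowSums(v^2))
  cosang <- rowSums(v * nvec)
  data.frame(mol = ax$mol,
             alpha_local = acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
}
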