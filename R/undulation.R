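# surface extraction, smoothing to a middle line, and sine fitting of the
# layer undulation z(y) = y0 + A sin(2 pi y / B + C)

#' Per-block time-averaged base-atom positions
#'
#' For each block of `block` ns (or for all frames when `block = NULL`),
#' returns the per-molecule mean (x, y, z) of the aglycone base atom —
#' the point set that traces the layer surface.
#'
#' @param frames a [monolayer_frame()] or list of them.
#' @param block optional block duration, ns.
#' @return A `surface_points` data.frame (`mol`, `x`, `y`, `z`) for a single
#'   block, or a named list of them (one per block).  Attributes `Ly`
#'   (lateral box) and `block`.
#' @export
extract_surface_points <- function(frames, block = NULL) {
  if (inherits(frames, "monolayer_frame")) frames <- list(frames)
  if (!length(frames)) .stopf("need at least one frame")
  times <- vapply(frames, function(f) f$time, 0)
  Ly <- frames[[1L]]$box[2L]
  one <- function(idx) {
    per <- lapply(frames[idx], function(f) {
      ax <- .axis_atoms(f)
      data.frame(mol = ax$mol, x = ax$base[, 1L], y = ax$base[, 2L],
                 z = ax$base[, 3L])
    })
    all <- do.call(rbind, per)
    out <- data.frame(
      mol = sort(unique(all$mol)),
      x = as.numeric(tapply(all$x, all$mol, mean)),
      y = as.numeric(tapply(all$y, all$mol, mean)),
      z = as.numeric(tapply(all$z, all$mol, mean)))
    structure(out, Ly = Ly, class = c("surface_points", "data.frame"))
  }
  if (is.null(block)) return(one(seq_along(frames)))
  if (!.is_number(block) || block <= 0)
    .stopf("parameter error: block must be > 0")
  if (block > max(times) - min(times) + 1e-9 && length(frames) > 1L)
    .stopf("parameter error: block longer than the trajectory")
  k <- floor(times / block)
  lapply(split(seq_along(frames), k), one)
}

.as_surface_points <- function(x) {
  if (inherits(x, "surface_points")) return(x)
  if (inherits(x, "monolayer_frame")) return(extract_surface_points(x))
  if (is.data.frame(x) && all(c("y", "z") %in% names(x))) {
    if (is.null(attr(x, "Ly"))) attr(x, "Ly") <- max(x$y)
    return(x)
  }
  .stopf("expected surface points, a frame, or a data.frame with y and z")
}

#' Smooth surface points to a middle line
#'
#' Partitions the chosen lateral axis into `n_bins` equal bins over
#' `[0, L)` and takes the mean z per occupied bin, at the bin-centre
#' coordinate.  Empty bins are dropped.  `axis = "auto"` picks the lateral
#' axis along which the binned line has the larger variance (the wave
#' direction).
#'
#' @param points a `surface_points` set (or frame).
#' @param n_bins number of bins (>= 2).
#' @param axis `"y"`, `"x"`, or `"auto"`.
#' @return data.frame with `y` (bin centres along the chosen axis), `z`,
#'   `n` (points per bin); attributes `Ly`, `axis`.
#' @export
smooth_profile <- function(points, n_bins = 50, axis = c("y", "x", "auto")) {
  axis <- match.arg(axis)
  pts <- .as_surface_points(points)
  if (n_bins < 2L) .stopf("analysis error: need at least 2 bins")
  Ly <- attr(pts, "Ly")
  line_along <- function(u) {
    uu <- .wrap(u, Ly)
    idx <- pmin(floor(uu / Ly * n_bins) + 1L, n_bins)
    occ <- sort(unique(idx))
    data.frame(y = (occ - 0.5) * Ly / n_bins,
               z = as.numeric(tapply(pts$z, idx, mean)[as.character(occ)]),
               n = as.integer(table(idx)[as.character(occ)]))
  }
  if (axis == "auto") {
    ly <- line_along(pts$y); lx <- line_along(pts$x)
    axis <- if (var(lx$z) > var(ly$z)) "x" else "y"
  }
  out <- line_along(if (axis == "x") pts$x else pts$y)
  if (nrow(out) < 2L)
    .stopf("analysis error: all points fall in one bin")
  structure(out, Ly = Ly, axis = axis)
}

#' Fit a sine wave to the middle line
#'
#' Nonlinear least squares for `z(y) = y0 + A*sin(2*pi*y/B + C)`.
#' Initialisation: `A0 = (max - min)/2`, `y0_0 = mean(z)`, period
#' candidates from the dominant discrete-Fourier mode of the line (with the
#' box length as fallback), and a coarse grid of 8 starting phases; the
#' best-converged start wins and the result is canonicalised to `A >= 0`,
#' `C` in `(-pi, pi]`.  The period is not constrained by the box: B may
#' exceed `box_Ly` (the wave can span more than the periodic box).
#'
#' A flat line (zero variance) is reported with `A = 0`, `y0 = mean`, and
#' `degenerate = TRUE` (period unidentifiable) rather than as an error.
#'
#' @param line a [smooth_profile()] result, or data.frame with `y`, `z`.
#' @param box_Ly lateral box length along the fit axis, nm (default from
#'   the line's attribute).
#' @param n optional weights (points per bin) — used only to weight the
#'   least squares; defaults to the line's `n` if present.
#' @return Object of class `surface_wave_fit`: list with `A`, `B`, `C`,
#'   `y0`, `se` (named vector), `rms`, `box_Ly`, `degenerate`, `n_points`.
#' @export
fit_sine <- function(line, box_Ly = NULL, n = NULL) {
  y <- line$y; z <- line$z
  box_Ly <- box_Ly %||% attr(line, "Ly")
  if (is.null(box_Ly)) .stopf("box_Ly is required")
  if (length(y) < 8L) .stopf("need at least 8 points for the sine fit")
  if (diff(range(y)) < box_Ly / 2)
    .stopf("line must span at least half the box")
  w <- n %||% line$n %||% rep(1, length(y))

  if (sd(z) < 1e-12) {
    return(structure(list(A = 0, B = box_Ly, C = 0, y0 = mean(z),
                          se = c(A = NA_real_, B = NA_real_, C = NA_real_,
                                 y0 = NA_real_),
                          rms = 0, box_Ly = box_Ly, degenerate = TRUE,
                          n_points = length(y)),
                     class = "surface_wave_fit"))
  }

  # period candidates: dominant DFT mode on an evenly resampled line + box
  B_cands <- box_Ly
  if (length(y) >= 8L) {
    ys <- seq(min(y), max(y), length.out = 64L)
    zs <- approx(y, z, xout = ys, rule = 2L)$y
    sp <- Mod(fft(zs - mean(zs)))[2:32]
    kdom <- which.max(sp)
    span <- max(y) - min(y)
    B_cands <- unique(c(span / kdom, box_Ly))
  }
  A0 <- (max(z) - min(z)) / 2
  y00 <- mean(z)
  starts <- expand.grid(B = B_cands, C = seq(-pi, pi, length.out = 9L)[-9L])

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ y0 + A * sin(2 * pi * y / B + C),
                        data = data.frame(y = y, z = z),
                        start = list(A = A0, B = starts$B[i],
                                     C = starts$C[i], y0 = y00),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(w * residuals(fit)^2)
    if (is.null(best) || dev < best$dev - 1e-12)
      best <- list(fit = fit, dev = dev)
  }
  if (is.null(best))
    .stopf("fit error: sine fit failed to converge from any start")

  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    setNames(rep(NA_real_, 4L), names(cf)))
  A <- cf[["A"]]; B <- cf[["B"]]; C <- cf[["C"]]; y0 <- cf[["y0"]]
  if (B < 0) { B <- -B; C <- -C }                    # sin odd in y/B with C
  if (A < 0) { A <- -A; C <- C + pi }
  C <- ((C + pi) %% (2 * pi)) - pi
  if (C <= -pi + 1e-12) C <- pi
  structure(list(A = A, B = B, C = C, y0 = y0,
                 se = c(A = unname(se["A"]), B = unname(se["B"]),
                        C = unname(se["C"]), y0 = unname(se["y0"])),
                 rms = sqrt(mean(residuals(best$fit)^2)),
                 box_Ly = box_Ly, degenerate = FALSE,
                 n_points = length(y)),
            class = "surface_wave_fit")
}

#' @export
print.surface_wave_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("surface_wave_fit (degenerate/flat): A = 0, y0 = %.3f nm, period unidentifiable\n",
                x$y0))
  } else {
    cat(sprintf(
      "surface_wave_fit: A = %.3f nm, B = %.3f nm, C = %.3f rad, y0 = %.3f nm\n",
      x$A, x$B, x$C, x$y0))
    cat(sprintf("  rms residual %.4f nm over %d points; B/Ly = %.3f\n",
                x$rms, x$n_points, x$B / x$box_Ly))
  }
  invisible(x)
}

#' Predict the fitted wave
#' @param object a [fit_sine()] result.
#' @param y positions, nm.
#' @param ... unused.
#' @return Predicted z, nm.
#' @export
predict.surface_wave_fit <- function(object, y, ...) {
  object$y0 + object$A * sin(2 * pi * y / object$B + object$C)
}

#' Ratio of the fitted wave period to the box length
#'
#' @param fit a [fit_sine()] result.
#' @param box_Ly box length along the fit axis (default from the fit).
#' @return `B / box_Ly`, dimensionless.
#' @export
wave_box_ratio <- function(fit, box_Ly = NULL) {
  stopifnot(inherits(fit, "surface_wave_fit"))
  if (fit$degenerate) .stopf("period unidentifiable for a flat layer")
  fit$B / (box_Ly %||% fit$box_Ly)
}
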