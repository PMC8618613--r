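# 2D (in-plane) and 3D radial distribution functions of reference atoms

.rdf_common <- function(frames, r_max, dr, role) {
  if (inherits(frames, "monolayer_frame")) frames <- list(frames)
  if (!length(frames)) .stopf("need at least one frame")
  box <- frames[[1L]]$box
  if (!.is_number(r_max) || !.is_number(dr) || r_max <= 0 || dr <= 0)
    .stopf("parameter error: r_max and dr must be > 0")
  if (r_max > min(box[1L], box[2L]) / 2)
    .stopf("parameter error: r_max exceeds half the lateral box (minimum image)")
  list(frames = frames, box = box,
       edges = seq(0, r_max, by = dr))
}

.rdf_engine <- function(frames, edges, box, role, lateral) {
  nb <- length(edges) - 1L
  gsum <- numeric(nb)
  npair_tot <- 0
  for (f in frames) {
    a <- f$atoms
    ref <- a[a$role == role, c("x", "y", "z")]
    if (nrow(ref) < 2L) .stopf("need at least 2 reference atoms")
    d <- .pair_dists(as.matrix(ref), box, lateral_only = lateral)
    h <- tabulate(findInterval(d[d < edges[nb + 1L]], edges,
                               rightmost.closed = FALSE), nbins = nb)
    npair <- nrow(ref) * (nrow(ref) - 1L) / 2
    npair_tot <- npair_tot + npair
    r_lo <- head(edges, -1L); r_hi <- tail(edges, -1L)
    shell <- if (lateral) pi * (r_hi^2 - r_lo^2) / (box[1L] * box[2L])
             else 4 / 3 * pi * (r_hi^3 - r_lo^3) /
               (box[1L] * box[2L] * box[3L])
    gsum <- gsum + h / (npair * shell)
  }
  list(g = gsum / length(frames), npairs = npair_tot)
}

#' In-plane (2D) radial distribution function
#'
#' Pair distances use (x, y) only, under lateral minimum image; all
#' reference atoms are projected to one plane.  Normalisation uses the
#' ideal-gas annulus count at the mean areal density, so uniformly random
#' in-plane placement gives g(r) = 1.
#'
#' @param frames a [monolayer_frame()] or list of them.
#' @param r_max,dr histogram extent and bin width, nm.  `r_max` must not
#'   exceed half the lateral box.
#' @param role reference-atom role (default the aglycone base, the
#'   analysis's reference carbon).
#' @return Object of class `rdf_result`: data.frame with `r` (bin centres)
#'   and `g`; attributes `mode`, `npairs`.
#' @export
rdf_2d <- function(frames, r_max = 4, dr = 0.02, role = "aglycone_base") {
  cm <- .rdf_common(frames, r_max, dr, role)
  eng <- .rdf_engine(cm$frames, cm$edges, cm$box, role, lateral = TRUE)
  structure(data.frame(r = (head(cm$edges, -1L) + tail(cm$edges, -1L)) / 2,
                       g = eng$g),
            mode = "2D", npairs = eng$npairs,
            class = c("rdf_result", "data.frame"))
}

#' 3D radial distribution function
#'
#' Full 3D distances with lateral minimum image (z is non-periodic, as for
#' a slab with a vacuum gap).  Normalisation uses the ideal-gas shell count
#' at the whole-box volumetric density — the convention of common MD tools —
#' so slab geometry makes g(r) fall below 1 at large r.
#'
#' @inheritParams rdf_2d
#' @return An `rdf_result` with `mode = "3D"`.
#' @export
rdf_3d <- function(frames, r_max = 4, dr = 0.02, role = "aglycone_base") {
  cm <- .rdf_common(frames, r_max, dr, role)
  eng <- .rdf_engine(cm$frames, cm$edges, cm$box, role, lateral = FALSE)
  structure(data.frame(r = (head(cm$edges, -1L) + tail(cm$edges, -1L)) / 2,
                       g = eng$g),
            mode = "3D", npairs = eng$npairs,
            class = c("rdf_result", "data.frame"))
}
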