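# shared internal helpers and physical constants

# Boltzmann constant, J/K (CODATA)
.kB <- 1.380649e-23

# 1 amu / nm^3 expressed in kg / m^3
.amu_nm3_to_kg_m3 <- 1.66053906660

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum-image displacement along one periodic axis
#' @noRd
.min_image <- function(d, L) d - L * round(d / L)

#' Wrap coordinates into [0, L)
#' @noRd
.wrap <- function(x, L) x - L * floor(x / L)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' All unique pair displacements between rows of two coordinate matrices,
#' lateral minimum image in x and y; z (if present) is non-periodic.
#' Returns distances only, chunked to bound memory.
#' @noRd
.pair_dists <- function(coords, box, lateral_only = FALSE, chunk = 1024L) {
  n <- nrow(coords)
  if (n < 2L) return(numeric(0))
  out <- vector("list", ceiling(n / chunk))
  k <- 0L
  for (lo in seq(1L, n - 1L, by = chunk)) {
    hi <- min(lo + chunk - 1L, n - 1L)
    idx <- lo:hi
    # pairs (i, j) with j > i, computed block-wise
    dx <- .min_image(outer(coords[idx, 1L], coords[, 1L], "-"), box[1L])
    dy <- .min_image(outer(coords[idx, 2L], coords[, 2L], "-"), box[2L])
    d2 <- dx^2 + dy^2
    if (!lateral_only) {
      dz <- outer(coords[idx, 3L], coords[, 3L], "-")
      d2 <- d2 + dz^2
    }
    keep <- outer(idx, seq_len(n), "<")
    k <- k + 1L
    out[[k]] <- sqrt(d2[keep])
  }
  unlist(out[seq_len(k)], use.names = FALSE)
}
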