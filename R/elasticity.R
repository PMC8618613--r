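# thin-elastic-sheet wrinkle mechanics: from interfacial shear and
# dilatational moduli plus layer thickness to Poisson's ratio, Young's
# moduli, flexural rigidity and the wrinkle wavelength

#' Poisson's ratio from interfacial moduli
#'
#' `nu = G_D / (2 * G_S) - 1`.  Values outside (0, 0.5) are physically
#' unusual for this model and trigger a warning.
#'
#' @param G_D interfacial dilatational modulus, N/m.
#' @param G_S interfacial shear modulus, N/m.
#' @return Poisson's ratio, dimensionless.
#' @export
poisson_ratio <- function(G_D, G_S) {
  if (!.is_number(G_S) || G_S <= 0)
    .stopf("parameter error: G_S must be > 0")
  if (!.is_number(G_D) || G_D <= 0)
    .stopf("parameter error: G_D must be > 0")
  nu <- G_D / (2 * G_S) - 1
  if (nu <= -1 || nu >= 1)
    .stopf("parameter error: |nu| >= 1 (G_D/G_S = %.3g)", G_D / G_S)
  if (nu <= 0 || nu >= 0.5)
    warning(sprintf("nu = %.3f outside (0, 0.5): physically unusual", nu),
            call. = FALSE)
  nu
}

#' 2D Young's modulus of the layer
#'
#' `Ys = 2 * G_S * (1 + nu)`.  Substituting the Poisson's-ratio relation
#' gives the identity `Ys = G_D`.
#'
#' @param G_S interfacial shear modulus, N/m.
#' @param nu Poisson's ratio.
#' @return 2D Young's modulus, N/m.
#' @export
young_modulus_2d <- function(G_S, nu) 2 * G_S * (1 + nu)

#' Pseudo-bulk Young's modulus
#'
#' `Y = Ys / h` for a sheet of thickness `h`.
#'
#' @param Ys 2D Young's modulus, N/m.
#' @param h layer thickness, m.
#' @return Young's modulus, Pa.
#' @export
young_modulus_bulk <- function(Ys, h) {
  if (!.is_number(h) || h <= 0) .stopf("parameter error: h must be > 0")
  Ys / h
}

#' Flexural rigidity of the sheet
#'
#' `D = Y * h^3 / (1 - nu^2)`.  With `classical = TRUE` the classical
#' plate-theory factor 1/12 is applied as well
#' (`D = Y * h^3 / (12 * (1 - nu^2))`).
#'
#' @param Y pseudo-bulk Young's modulus, Pa.
#' @param h layer thickness, m.
#' @param nu Poisson's ratio (|nu| < 1).
#' @param classical apply the 1/12 plate factor.
#' @return Flexural rigidity, J.
#' @export
flexural_rigidity <- function(Y, h, nu, classical = FALSE) {
  if (!.is_number(nu) || abs(nu) >= 1)
    .stopf("parameter error: |nu| must be < 1")
  if (!.is_number(h) || h <= 0) .stopf("parameter error: h must be > 0")
  D <- Y * h^3 / (1 - nu^2)
  if (classical) D <- D / 12
  D
}

#' Flexural rigidity in thermal-energy units
#'
#' @param D flexural rigidity, J.
#' @param T_K temperature, K.
#' @return `D / (k_B * T)`, dimensionless.
#' @export
rigidity_in_kBT <- function(D, T_K = 293) {
  if (!.is_number(T_K) || T_K <= 0) .stopf("parameter error: T must be > 0")
  D / (.kB * T_K)
}

#' Wrinkle wavelength of a compressed elastic sheet
#'
#' `lambda = 2 * sqrt(pi) * (D / sigma)^(1/4) * L^(1/2)`: flexural rigidity
#' D (J), surface tension sigma (N/m) and sheet length L (m) give the
#' wavelength in m (`D/sigma` has units of m^2).
#'
#' @param D flexural rigidity, J.
#' @param sigma surface tension, N/m.
#' @param L sheet length, m.
#' @return Wrinkle wavelength, m.
#' @export
wrinkle_wavelength <- function(D, sigma, L) {
  if (!.is_number(sigma) || sigma <= 0)
    .stopf("parameter error: sigma must be > 0")
  if (!.is_number(L) || L <= 0) .stopf("parameter error: L must be > 0")
  2 * sqrt(pi) * (D / sigma)^(1 / 4) * sqrt(L)
}

#' Full elasticity chain from interfacial moduli
#'
#' Composes [poisson_ratio()], [young_modulus_2d()], [young_modulus_bulk()],
#' [flexural_rigidity()] and [rigidity_in_kBT()] — plus
#' [wrinkle_wavelength()] when `sigma` and `L` are supplied — without any
#' intermediate rounding.
#'
#' @param G_S interfacial shear modulus, N/m.
#' @param G_D interfacial dilatational modulus, N/m.
#' @param h layer thickness, in the unit named by `h_unit`.
#' @param T_K temperature, K.
#' @param sigma optional surface tension, N/m.
#' @param L optional sheet length, m.
#' @param h_unit `"nm"` (default) or `"m"`.
#' @param classical apply the classical 1/12 plate factor in the rigidity.
#' @return Object of class `elastic_results`: list with `nu`, `Ys` (N/m),
#'   `Y` (Pa), `D` (J), `D_kBT`, `lambda` (m or `NA`), and the inputs.
#' @export
elastic_chain <- function(G_S, G_D, h, T_K = 293, sigma = NULL, L = NULL,
                          h_unit = c("nm", "m"), classical = FALSE) {
  h_unit <- match.arg(h_unit)
  h_m <- if (h_unit == "nm") h * 1e-9 else h
  nu <- poisson_ratio(G_D, G_S)
  Ys <- young_modulus_2d(G_S, nu)
  Y <- young_modulus_bulk(Ys, h_m)
  D <- flexural_rigidity(Y, h_m, nu, classical = classical)
  lam <- if (!is.null(sigma) && !is.null(L))
    wrinkle_wavelength(D, sigma, L) else NA_real_
  structure(list(nu = nu, Ys = Ys, Y = Y, D = D,
                 D_kBT = rigidity_in_kBT(D, T_K), lambda = lam,
                 inputs = list(G_S = G_S, G_D = G_D, h_m = h_m, T_K = T_K,
                               sigma = sigma, L = L, classical = classical)),
            class = "elastic_results")
}

#' @export
print.elastic_results <- function(x, ...) {
  cat("elastic sheet results:\n")
  cat(sprintf("  Poisson ratio        nu    = %.3f\n", x$nu))
  cat(sprintf("  2D Young modulus     Ys    = %.3f N/m\n", x$Ys))
  cat(sprintf("  pseudo-bulk modulus  Y     = %.3g Pa\n", x$Y))
  cat(sprintf("  flexural rigidity    D     = %.3g J  (%.0f kBT at %g K)\n",
              x$D, x$D_kBT, x$inputs$T_K))
  if (!is.na(x$lambda))
    cat(sprintf("  wrinkle wavelength   lambda = %.3g m\n", x$lambda))
  invisible(x)
}
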