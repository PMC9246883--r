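#' Dimensionless numbers of a droplet microflow
#'
#' Computes the standard groups delineating droplet-flow regimes. All
#' inputs are SI: density rho (kg/m^3), viscosities (Pa s), interfacial
#' tension gamma (N/m), droplet velocity V_d (m/s), hydraulic diameter D_h
#' (m), channel width w (m), mean arc radius R (m).
#'
#' \itemize{
#'   \item Reynolds `Re = rho * V_d * D_h / mu` (inertia vs. viscosity;
#'     `mu` defaults to the continuous-phase viscosity `mu_c`)
#'   \item Capillary `Ca = mu_c * V_d / gamma` (viscous vs. interfacial)
#'   \item Weber `We = rho * V_d^2 * D_h / gamma` (inertia vs. interfacial)
#'   \item Bond `Bo = delta_rho * g * D_h^2 / gamma` (buoyancy vs. interfacial)
#'   \item Dean `kappa = sqrt(w / (2 R)) * Re` (secondary curved-channel flow)
#'   \item viscosity ratio `lambda = mu_d / mu_c`
#' }
#'
#' @param rho Fluid density, kg/m^3.
#' @param mu_c,mu_d Continuous / dispersed phase dynamic viscosity, Pa s.
#' @param gamma Interfacial tension, N/m.
#' @param V_d Droplet velocity, m/s.
#' @param D_h Hydraulic diameter, m.
#' @param delta_rho Density difference across the interface, kg/m^3.
#' @param g Gravitational acceleration, m/s^2.
#' @param w Channel width, m (Dean number only).
#' @param R Mean arc radius, m (Dean number only).
#' @param Re Optional externally determined Reynolds number for the Dean
#'   number (otherwise computed from rho, V_d, D_h, mu_c).
#' @return Named list with the requested numbers; groups whose inputs are
#'   missing are omitted.
#' @export
dimensionless_numbers <- function(rho = NULL, mu_c = NULL, mu_d = NULL,
                                  gamma = NULL, V_d = NULL, D_h = NULL,
                                  delta_rho = NULL, g = 9.81,
                                  w = NULL, R = NULL, Re = NULL) {
  have <- function(...) all(!vapply(list(...), is.null, logical(1)))
  out <- list()
  if (is.null(Re) && have(rho, V_d, D_h, mu_c)) Re <- rho * V_d * D_h / mu_c
  if (!is.null(Re)) out$Re <- Re
  if (have(mu_c, V_d, gamma)) out$Ca <- mu_c * V_d / gamma
  if (have(rho, V_d, D_h, gamma)) out$We <- rho * V_d^2 * D_h / gamma
  if (have(delta_rho, gamma, D_h)) out$Bo <- delta_rho * g * D_h^2 / gamma
  if (have(mu_c, mu_d)) out$lambda <- mu_d / mu_c
  if (have(w, R)) {
    if (is.null(Re)) stopf("Dean number needs Re (directly or via rho, V_d, D_h, mu_c)")
    out$Dean <- sqrt(w / (2 * R)) * Re
  }
  if (length(out) == 0) stopf("no dimensionless group computable from the supplied parameters")
  out
}

#' Gutter resistance ratio of a droplet in a curved channel
#'
#' In a curved rectangular channel the continuous phase bypasses a
#' confined droplet through corner gutters that subtend the same arc angle
#' but different radii, hence different lengths. With negligible
#' interfacial deformation the hydrodynamic resistance of each gutter is
#' proportional to its length, so the ratio of outer to inner gutter
#' resistance reduces to the radius ratio (the arc angle cancels).
#'
#' @param r_inner,r_outer Inner and outer gutter radii (same units).
#' @return `r_outer / r_inner`.
#' @export
gutter_resistance_ratio <- function(r_inner, r_outer) {
  if (!is_scalar_num(r_inner) || !is_scalar_num(r_outer) ||
      r_inner <= 0 || r_outer <= r_inner)
    stopf("need 0 < r_inner < r_outer")
  r_outer / r_inner
}
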