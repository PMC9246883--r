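#' Rectangular duct geometry
#'
#' @param width Channel width (y extent), micrometers.
#' @param height Channel height / depth (z extent), micrometers.
#' @param length Streamwise extent rendered in synthetic scenes, micrometers.
#' @return An object of class `duct_geometry` with the derived hydraulic
#'   diameter `D_h = 2*width*height/(width + height)`.
#' @export
duct_geometry <- function(width = 90, height = 35, length = 400) {
  if (width <= 0 || height <= 0 || length <= 0)
    stopf("duct dimensions must be positive")
  g <- list(width = width, height = height, length = length,
            D_h = 2 * width * height / (width + height))
  class(g) <- "duct_geometry"
  g
}

# Unit-scale shape of fully developed laminar flow in a rectangular duct
# (Fourier series over odd modes; y, z centered on the cross-section).
duct_shape <- function(y, z, width, height, n_terms = 51) {
  a <- width / 2
  b <- height / 2
  u <- 0
  for (i in seq(1, 2 * n_terms - 1, by = 2)) {
    k <- i * pi / (2 * a)
    u <- u + (-1)^((i - 1) / 2) / i^3 *
      (1 - cosh(k * z) / cosh(k * b)) * cos(k * y)
  }
  u
}

# Cross-section integral of duct_shape by midpoint quadrature (cached per
# geometry within a session).
duct_shape_integral <- local({
  cache <- new.env(parent = emptyenv())
  function(width, height, n_terms = 51, n_grid = 201) {
    key <- paste(width, height, n_terms, n_grid)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ys <- (seq_len(n_grid) - 0.5) / n_grid * width - width / 2
    zs <- (seq_len(n_grid) - 0.5) / n_grid * height - height / 2
    dy <- width / n_grid
    dz <- height / n_grid
    val <- sum(outer(ys, zs, function(yy, zz)
      duct_shape(yy, zz, width, height, n_terms))) * dy * dz
    cache[[key]] <- val
    val
  }
})

#' Analytic Poiseuille velocity in a rectangular duct
#'
#' Axial speed of fully developed pressure-driven laminar flow, from the
#' classical Fourier-series solution, scaled so that the integral of the
#' profile over the cross-section equals the volumetric flow rate.
#'
#' @param y,z Cross-section coordinates, micrometers, centered on the duct
#'   axis (`|y| <= width/2`, `|z| <= height/2`). Vectorized.
#' @param geom A [duct_geometry()].
#' @param flow_rate Volumetric flow rate in microliters per hour.
#' @param n_terms Number of odd series terms (default 51).
#' @return Axial speed in micrometers per second (same length as `y`).
#' @export
poiseuille_velocity <- function(y, z, geom, flow_rate = 5, n_terms = 51) {
  if (any(abs(y) > geom$width / 2 + 1e-9) || any(abs(z) > geom$height / 2 + 1e-9))
    stopf("(y, z) outside the duct cross-section")
  q_um3_s <- flow_rate * 1e9 / 3600          # uL/hr -> um^3/s
  scale <- q_um3_s / duct_shape_integral(geom$width, geom$height, n_terms)
  pmax(scale * duct_shape(y, z, geom$width, geom$height, n_terms), 0)
}

#' Solenoidal recirculation test field
#'
#' An analytically divergence-free cellular velocity field inside a box
#' `[0,Lx] x [0,Ly] x [0,Lz]`, built from two stream-function rolls. The
#' normal velocity vanishes on every face and the field is mirror-symmetric
#' about the horizontal (XY) and vertical (XZ) mid-planes in the sense of a
#' recirculating droplet interior: reflecting `y -> Ly - y` negates `v` and
#' preserves `u` and `w`. With `secondary = 0` the field reduces to a stack
#' of closed planar rolls (closed pathlines at fixed y).
#'
#' @param pos Numeric matrix (n x 3) or length-3 vector of positions, um.
#' @param box Length-3 numeric `(Lx, Ly, Lz)`, micrometers.
#' @param amplitude Peak speed scale, micrometers per second.
#' @param secondary Relative amplitude of the in-plane (XY) roll that makes
#'   the field fully 3D; 0 gives closed 2D rolls.
#' @return An n x 3 matrix of velocity components (u, v, w), um/s.
#' @export
recirculation_velocity <- function(pos, box, amplitude = 100, secondary = 0.5) {
  p <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
  if (any(p[, 1] < -1e-9 | p[, 1] > box[1] + 1e-9 |
          p[, 2] < -1e-9 | p[, 2] > box[2] + 1e-9 |
          p[, 3] < -1e-9 | p[, 3] > box[3] + 1e-9))
    stopf("position outside the recirculation box")
  Lx <- box[1]; Ly <- box[2]; Lz <- box[3]
  sx <- sin(pi * p[, 1] / Lx); cx <- cos(pi * p[, 1] / Lx)
  sy <- sin(pi * p[, 2] / Ly)
  s2y <- sin(2 * pi * p[, 2] / Ly); c2y <- cos(2 * pi * p[, 2] / Ly)
  sz <- sin(pi * p[, 3] / Lz); cz <- cos(pi * p[, 3] / Lz)
  u <- amplitude * (sx * cz * sy + secondary * sx * c2y * sz)
  v <- -amplitude * secondary * (Ly / (2 * Lx)) * cx * s2y * sz
  w <- -amplitude * (Lz / Lx) * cx * sz * sy
  cbind(u = u, v = v, w = w)
}

#' Advect particles through a velocity field (classical RK4)
#'
#' Fixed-step fourth-order Runge-Kutta integration; the fields used here are
#' smooth, so a fixed step is reproducible and accurate.
#'
#' @param field A function `pos (n x 3 matrix, um) -> n x 3 velocity (um/s)`.
#' @param pos n x 3 matrix of initial positions, micrometers.
#' @param dt Time step, seconds.
#' @param n_steps Number of steps.
#' @param keep_path If `TRUE`, return the full trajectory array
#'   `(n_steps + 1) x n x 3`; otherwise only the final positions.
#' @export
advect_rk4 <- function(field, pos, dt, n_steps, keep_path = FALSE) {
  p <- if (is.matrix(pos)) pos else matrix(pos, ncol = 3)
  if (keep_path) {
    path <- array(NA_real_, c(n_steps + 1L, nrow(p), 3L))
    path[1, , ] <- p
  }
  for (s in seq_len(n_steps)) {
    k1 <- field(p)
    k2 <- field(p + dt / 2 * k1)
    k3 <- field(p + dt / 2 * k2)
    k4 <- field(p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (keep_path) path[s + 1L, , ] <- p
  }
  if (keep_path) path else p
}
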