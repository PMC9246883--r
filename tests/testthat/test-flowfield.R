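test_that("lattice averaging honors overlap geometry and conserves counts", {
  b <- rbind(c(0, 20), c(0, 20), c(0, 20))
  one <- data.frame(x_um = 5.3, y_um = 5.2, z_um = 5.1, u = 1, v = 0, w = 0)
  f1 <- lattice_average(one, lattice_spec(c(4, 2, 1), 0.5, bounds = b))
  expect_equal(sum(f1$count), 8)                # interior point, 2 per axis
  expect_true(all(f1$u[f1$count > 0] == 1))

  set.seed(2)
  vv <- data.frame(x_um = runif(400, 0, 20), y_um = runif(400, 0, 20),
                   z_um = runif(400, 0, 20), u = 3.3, v = -1, w = 0.5)
  f0 <- lattice_average(vv, lattice_spec(c(2, 2, 2), 0, bounds = b))
  expect_equal(sum(f0$count), 400)              # overlap 0: counts conserved
  fo <- lattice_average(vv, lattice_spec(c(2, 2, 2), 0.5, bounds = b))
  expect_true(all(abs(fo$u[fo$count > 0] - 3.3) < 1e-12))  # uniform field
  expect_true(all(abs(fo$v[fo$count > 0] + 1) < 1e-12))
  # 50% overlap: element centers spaced at half the element size
  expect_equal(diff(fo$centers[[1]])[1], 1)
  expect_error(lattice_spec(c(1, 1, 1), 1.2), "overlap")
})

test_that("continuity error separates solenoidal from uncorrelated fields", {
  box <- c(60, 30, 24)
  grid <- expand.grid(x = seq(0.5, 59.5, 1), y = seq(0.5, 29.5, 1),
                      z = seq(0.5, 23.5, 1))
  P <- as.matrix(grid)
  V <- recirculation_velocity(P, box, amplitude = 100)
  vec <- data.frame(x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
                    u = V[, 1], v = V[, 2], w = V[, 3])
  spec2 <- lattice_spec(c(2, 2, 2), 0.5)
  ce <- continuity_eta(lattice_average(vec, spec2))
  expect_lte(ce$eta_median, 0.1)                # analytic mass conservation

  set.seed(6)
  bad <- vec
  bad$u <- rnorm(nrow(bad)); bad$v <- rnorm(nrow(bad)); bad$w <- rnorm(nrow(bad))
  ce_bad <- continuity_eta(lattice_average(bad, spec2))
  expect_gte(ce_bad$eta_median, 0.8)            # uncorrelated components
  expect_lte(ce_bad$eta_median, 1)

  # eta is invariant under uniform velocity rescaling
  sc <- vec
  sc$u <- 7.3 * sc$u; sc$v <- 7.3 * sc$v; sc$w <- 7.3 * sc$w
  ce_sc <- continuity_eta(lattice_average(sc, spec2))
  expect_equal(ce_sc$eta, ce$eta)

  # subvolume restriction really restricts
  ce_sub <- continuity_eta(lattice_average(vec, spec2),
                           subvolume = list(x = c(20, 40)))
  expect_lt(ce_sub$n_defined, ce$n_defined)
  expect_error(continuity_eta(lattice_average(vec[1:3, ], spec2)), "undefined")
})

test_that("eta~ follows the element-size trend of pathline-sampled noisy data", {
  # pathline-sampled vectors at experiment scale (~80k between-frame vectors,
  # mm/s speeds at 300 fps) with the reported localization noise (0.12 um X,
  # 0.21 um Y, 0.15 um Z): eta~ is worst for 1 um elements, declines to a
  # minimum near 4 um, rises slightly at 6 um, and stays < 0.5 above 1 um
  box <- c(60, 30, 24)
  f <- function(p) recirculation_velocity(p, box, amplitude = 2000)
  set.seed(9)
  n <- 800
  P0 <- cbind(runif(n, 2, 58), runif(n, 2, 28), runif(n, 2, 22))
  path <- advect_rk4(f, P0, dt = 1 / 3000, n_steps = 990, keep_path = TRUE)
  samp <- path[seq(1, 991, 10), , ]             # 100 frames at 300 fps
  frames <- dim(samp)[1]
  xs <- samp[, , 1] + rnorm(length(samp[, , 1]), 0, 0.12)
  ys <- samp[, , 2] + rnorm(length(samp[, , 2]), 0, 0.21)
  zs <- samp[, , 3] + rnorm(length(samp[, , 3]), 0, 0.15)
  dt <- 1 / 300
  i <- 1:(frames - 1)
  vec <- data.frame(
    x_um = as.vector((xs[i, ] + xs[i + 1, ]) / 2),
    y_um = as.vector((ys[i, ] + ys[i + 1, ]) / 2),
    z_um = as.vector((zs[i, ] + zs[i + 1, ]) / 2),
    u = as.vector(diff(xs)) / dt, v = as.vector(diff(ys)) / dt,
    w = as.vector(diff(zs)) / dt)
  etas <- vapply(c(1, 2, 4, 6), function(s)
    continuity_eta(lattice_average(vec, lattice_spec(rep(s, 3), 0.5)))$eta_median,
    numeric(1))
  expect_equal(which.max(etas), 1L)             # smallest elements noisiest
  expect_equal(which.min(etas), 3L)             # minimum at 4 um cubes
  expect_gt(etas[4], etas[3])                   # discretization rise at 6 um
  expect_true(all(etas[2:4] < 0.5))
})

test_that("profiles through a duct field are parabolic with no-slip", {
  # profile across the short axis of a tall duct is very nearly parabolic
  g <- duct_geometry(20, 60)
  grid <- expand.grid(x = seq(0.5, 39.5, 2), y = seq(-9.75, 9.75, 0.25),
                      z = seq(-29.5, 29.5, 1))
  vec <- data.frame(x_um = grid$x, y_um = grid$y, z_um = grid$z,
                    u = poiseuille_velocity(grid$y, grid$z, g, 2), v = 0, w = 0)
  field <- lattice_average(vec, lattice_spec(c(4, 1, 2), 0.5))
  prof <- profile_line(field, axis = "y", at = c(x = 20, z = 0), component = "u")
  fit <- profile_parabola(prof)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(max(prof$value[c(1, nrow(prof))]), max(prof$value))  # no-slip edges

  uni <- vec; uni$u <- 5
  fu <- lattice_average(uni, lattice_spec(c(4, 1, 2), 0.5))
  pu <- profile_parabola(profile_line(fu, axis = "y", at = c(x = 20, z = 0)))
  expect_lt(abs(pu$coefficients[["I(s^2)"]]), 1e-9)  # zero curvature
  expect_error(profile_line(field, axis = "y", at = c(x = 30)), "supply")
})

test_that("dimensionless groups follow their defining formulas", {
  # printed curved-channel case: w = 120 um, R = 250 um, Re = 0.022
  d <- dimensionless_numbers(w = 120e-6, R = 250e-6, Re = 0.022)
  expect_equal(d$Dean, sqrt(0.24) * 0.022)
  expect_equal(round(d$Dean, 3), 0.011)

  z <- dimensionless_numbers(rho = 1150, mu_c = 0.013, mu_d = 0.0087,
                             gamma = 5e-3, V_d = 0, D_h = 58e-6,
                             delta_rho = 100)
  expect_equal(z$Re, 0); expect_equal(z$Ca, 0); expect_equal(z$We, 0)
  expect_equal(z$lambda, 0.0087 / 0.013)

  base <- dimensionless_numbers(rho = 1150, mu_c = 0.013, gamma = 5e-3,
                                V_d = 0.003, D_h = 58e-6, delta_rho = 100)
  dbl <- dimensionless_numbers(rho = 1150, mu_c = 0.013, gamma = 1e-2,
                               V_d = 0.003, D_h = 58e-6, delta_rho = 100)
  expect_equal(dbl$Ca, base$Ca / 2)             # doubling gamma halves these
  expect_equal(dbl$We, base$We / 2)
  expect_equal(dbl$Bo, base$Bo / 2)
  expect_error(dimensionless_numbers(w = 1), "no dimensionless group")
  expect_error(dimensionless_numbers(w = 1e-4, R = 2e-4), "Re")
})

test_that("gutter resistance ratio is the radius ratio", {
  expect_equal(round(gutter_resistance_ratio(190, 310), 1), 1.6)
  expect_equal(gutter_resistance_ratio(100, 300), 3)
  expect_equal(gutter_resistance_ratio(150, 150 + 1e-9), 1, tolerance = 1e-6)
  expect_error(gutter_resistance_ratio(310, 190), "r_inner < r_outer")
})

test_that("lattice CSV export lists non-empty elements with diagnostics", {
  g12 <- expand.grid(x = seq(0.5, 11.5, 1), y = seq(0.5, 11.5, 1),
                     z = seq(0.5, 11.5, 1))
  V <- recirculation_velocity(as.matrix(g12), c(12, 12, 12), amplitude = 10)
  vv <- data.frame(x_um = g12$x, y_um = g12$y, z_um = g12$z,
                   u = V[, 1], v = V[, 2], w = V[, 3])
  f <- lattice_average(vv, lattice_spec(c(2, 2, 2), 0.5))
  ce <- continuity_eta(f)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lattice_csv(f, path, continuity = ce, header_comment = "cfg abc123")
  expect_match(readLines(path, n = 1), "^# cfg abc123")
  d <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(d), sum(f$count > 0))
  expect_true(all(c("cx", "cy", "cz", "u", "v", "w", "count", "eta") %in% names(d)))
  expect_equal(sum(d$count), sum(f$count))
})
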