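test_that("defocus rendering is deterministic and range-checked", {
  m <- fix_model(noise_sd = 0.02)
  a <- render_particle_image(3, m)
  b <- render_particle_image(3, m)
  expect_identical(a, b)
  expect_false(identical(a, render_particle_image(3, m, seed = 99L)))
  expect_error(render_particle_image(100, fix_model()), "outside the model range")
  expect_error(optical_model(aberration_asymmetry = 0), "injective")
})

test_that("the focal plane renders the sharpest image (Brenner gradient)", {
  m <- fix_model()
  zs <- seq(m$z_min, m$z_max, by = m$z_step)
  b <- vapply(zs, function(z) brenner_gradient(render_particle_image(z, m)),
              numeric(1))
  expect_equal(zs[which.max(b)], 0)
})

test_that("the z -> pattern map is injective with sign asymmetry", {
  m <- fix_model()
  zs <- seq(m$z_min, m$z_max, by = m$z_step)
  imgs <- lapply(zs, function(z) render_particle_image(z, m))
  V <- vapply(imgs, function(x) {
    v <- as.vector(x) - mean(x); v / sqrt(sum(v^2))
  }, numeric(1024))
  S <- crossprod(V)
  diag(S) <- NA
  expect_lt(max(S, na.rm = TRUE), 1)            # all levels distinguishable
  i5 <- which(zs == 5); im5 <- which(zs == -5)
  expect_lt(S[i5, im5], 0.99)                   # sign ambiguity removed
})

test_that("reference stacks carry exact ground truth, with and without tilt", {
  m <- fix_model()
  st <- render_reference_stack(m, tilt = c(0, 0), particles_per_level = 2)
  expect_equal(st$info$z_true, st$info$z_label)
  expect_equal(length(st$crops), m$n_levels * 2)

  full <- optical_model()                       # published geometry
  labels <- (seq_len(full$n_levels) - 1 - full$focal_index) * full$z_step
  expect_equal(diff(range(labels)), 54.5)       # (110 - 1) * 0.5
  expect_lt(min(labels), -25)                   # range extends past -25 um

  # slope giving a 4 um (-2..+2 about mid-field) spread across a 614.4 um field
  a <- 4 / 614.4
  st2 <- render_reference_stack(m, tilt = c(a, 0), particles_per_level = 3,
                                field_size = c(614.4, 345.6))
  lev0 <- st2$info[st2$info$z_label == 0, ]
  dev <- lev0$z_true - lev0$z_label          # -2..+2 um about the field center
  expect_lte(max(abs(dev)), 2 + 1e-9)
  expect_gt(diff(range(dev)), 2)             # positions span the field
})

test_that("rectangular-duct Poiseuille profile obeys no-slip, symmetry and flux", {
  g <- duct_geometry(90, 35)
  expect_equal(g$D_h, 2 * 90 * 35 / 125)
  expect_equal(poiseuille_velocity(45, 0, g, 5), 0)       # side wall
  expect_equal(poiseuille_velocity(0, 17.5, g, 5), 0, tolerance = 1e-6)
  ys <- seq(-44, 44, length.out = 23); zs <- seq(-17, 17, length.out = 23)
  grid <- expand.grid(y = ys, z = zs)
  u <- poiseuille_velocity(grid$y, grid$z, g, 5)
  expect_equal(unname(which.max(u)), which(grid$y == 0 & grid$z == 0))
  expect_error(poiseuille_velocity(46, 0, g, 5), "outside")

  # independent quadrature oracle: Simpson product rule on a 161^2 grid
  n <- 161
  ys <- seq(-45, 45, length.out = n); zs <- seq(-17.5, 17.5, length.out = n)
  wgt <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  U <- outer(ys, zs, function(a, b) poiseuille_velocity(a, b, g, 5))
  Q <- (diff(ys)[1] / 3) * (diff(zs)[1] / 3) * as.numeric(t(wgt) %*% U %*% wgt)
  expect_equal(Q, 5e9 / 3600, tolerance = 0.005)
})

test_that("recirculation field is solenoidal, bounded and mirror-symmetric", {
  box <- c(100, 50, 40)
  set.seed(7)
  P <- cbind(runif(100, 1, 99), runif(100, 1, 49), runif(100, 1, 39))
  h <- 1e-5
  for (k in sample(100, 10)) {                  # analytic divergence ~ 0
    p <- P[k, , drop = FALSE]
    div <- (recirculation_velocity(p + c(h, 0, 0), box)[1] -
            recirculation_velocity(p - c(h, 0, 0), box)[1] +
            recirculation_velocity(p + c(0, h, 0), box)[2] -
            recirculation_velocity(p - c(0, h, 0), box)[2] +
            recirculation_velocity(p + c(0, 0, h), box)[3] -
            recirculation_velocity(p - c(0, 0, h), box)[3]) / (2 * h)
    expect_lt(abs(div), 1e-6)
  }
  V <- recirculation_velocity(P, box)
  M <- recirculation_velocity(cbind(P[, 1], box[2] - P[, 2], P[, 3]), box)
  expect_equal(M[, 1], V[, 1])                  # u preserved
  expect_equal(M[, 2], -V[, 2])                 # v negated
  expect_equal(M[, 3], V[, 3])                  # w preserved
  # zero normal component on faces
  expect_equal(recirculation_velocity(c(0, 25, 20), box)[1], 0)
  expect_equal(recirculation_velocity(c(50, 0, 20), box)[2], 0)
  expect_equal(recirculation_velocity(c(50, 25, 0), box)[3], 0)
  expect_error(recirculation_velocity(c(200, 0, 0), box), "outside")
})

test_that("RK4 pathlines close on planar rolls and converge at 4th order", {
  box <- c(100, 50, 40)
  f <- function(p) recirculation_velocity(p, box, amplitude = 100, secondary = 0)
  start <- matrix(c(30, 25, 10), 1)
  # dense integration to locate the orbital period (first return to start)
  path <- advect_rk4(f, start, dt = 0.002, n_steps = 4000, keep_path = TRUE)
  d <- sqrt((path[, 1, 1] - 30)^2 + (path[, 1, 3] - 10)^2)
  away <- which(d > 5)[1]
  ret <- away + which.min(d[away:length(d)]) - 1L
  expect_lt(d[ret], 0.05)                       # closed loop
  # step-halving: error vs a fine reference shrinks ~ 2^4
  Tend <- 0.8
  ref <- advect_rk4(f, start, dt = Tend / 3200, n_steps = 3200)
  e1 <- sqrt(sum((advect_rk4(f, start, dt = Tend / 100, n_steps = 100) - ref)^2))
  e2 <- sqrt(sum((advect_rk4(f, start, dt = Tend / 200, n_steps = 200) - ref)^2))
  expect_gt(e1 / e2, 8)                         # >= ~2^3, consistent with O(dt^4)
})

test_that("simulated video renders truth-consistent frames", {
  m <- fix_model()
  still <- simulate_video(function(p) matrix(0, nrow(p), 3), m,
                          frame_size_px = c(64L, 64L), n_frames = 4,
                          init = matrix(c(10, 10, 2), 1), fps = 300)
  expect_identical(still$frames[[1]], still$frames[[4]])
  uni <- simulate_video(function(p) cbind(rep(300, nrow(p)), 0, 0), m,
                        frame_size_px = c(96L, 48L), n_frames = 10,
                        init = matrix(c(3, 7, 1, 5, 12, -3), 2, byrow = TRUE),
                        fps = 300)
  tr <- uni$truth[uni$truth$particle_id == 1, ]
  expect_equal(diff(tr$x_um), rep(1, 9))        # 300 um/s at 300 fps
  expect_equal(diff(tr$y_um), rep(0, 9))
  expect_equal(diff(tr$z_um), rep(0, 9))
})

test_that("scene bundles round-trip through TIFF + CSV + JSON", {
  m <- fix_model()
  sc <- simulate_video(function(p) cbind(rep(100, nrow(p)), 0, 0), m,
                       frame_size_px = c(64L, 48L), n_frames = 3,
                       init = matrix(c(8, 8, 0), 1), fps = 300)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  bk <- read_scene(dir)
  expect_equal(length(bk$frames), 3)
  expect_equal(bk$frames[[1]], sc$frames[[1]], tolerance = 1e-4)  # 16-bit quantization
  expect_equal(bk$fps, 300)
  expect_equal(bk$model$n_levels, m$n_levels)
  visible <- sc$truth[sc$truth$visible, ]
  expect_equal(nrow(bk$truth), nrow(visible))
  expect_equal(bk$truth$x_um, visible$x_um)
})

test_that("TIFF stacks round-trip and reject non-TIFF input", {
  set.seed(3)
  fr <- list(matrix(runif(35), 5, 7), matrix(runif(35), 5, 7))
  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(fr, p, bits = 16)
  bk <- read_tiff_stack(p)
  expect_equal(length(bk), 2)
  expect_equal(bk[[1]], fr[[1]], tolerance = 1e-4)
  # writing the quantized data again is lossless
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(bk, p2, bits = 16)
  expect_identical(read_tiff_stack(p2), bk)
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff at all, just text padding out bytes", bad)
  expect_error(read_tiff_stack(bad), "not a TIFF")
})
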