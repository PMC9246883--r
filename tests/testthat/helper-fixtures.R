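# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# Compact optical model: 41 levels x 0.5 um -> z in [-10, 10] um.
fix_model <- function(noise_sd = 0, seed = 42L)
  optical_model(n_levels = 41, z_range_h = 20, noise_sd = noise_sd, rng_seed = seed)

# Reference library for the compact model (one bead per level).
fix_library <- function() cached("lib41", {
  m <- fix_model()
  st <- render_reference_stack(m, particles_per_level = 1)
  build_library(split(st$crops, st$info$level), m$z_step, m$focal_index)
})

fix_score_matrix <- function() cached("sm41", library_score_matrix(fix_library()))

# Small noise-free Poiseuille duct scene: flow along x, duct width = frame
# height, depth 20 um matching the compact model's range.
fix_duct_scene <- function() cached("duct_scene", {
  m <- fix_model()
  fw <- c(192L, 128L)
  wy <- fw[2] * m$pixel_size                  # 40.96 um
  g <- duct_geometry(wy, 18, 200)
  field <- function(p) cbind(poiseuille_velocity(p[, 2] - wy / 2, p[, 3], g, 1.2), 0, 0)
  sim <- simulate_video(field, m, frame_size_px = fw, n_frames = 30, fps = 300,
                        init = 5L, wrap_x = fw[1] * m$pixel_size,
                        spawn_box = rbind(c(0, fw[1] * m$pixel_size),
                                          c(6, wy - 6), c(-8, 8)))
  sim$geom <- g
  sim$frame_wy <- wy
  sim
})

# Tilted calibration: +-2 um of label error across a 614.4 um field plus a
# y-slope. The stack carries 40 beads per level for tilt assessment; the
# library itself is built from the first 13 beads of each level (a
# realistic per-frame bead count), which leaves visible median bias.
fix_tilt_truth <- list(a = 4 / 614.4, b = 0.004)
fix_tilt_stack <- function() cached("tilt_stack", {
  m <- fix_model()
  render_reference_stack(m, tilt = c(fix_tilt_truth$a, fix_tilt_truth$b),
                         particles_per_level = 40,
                         field_size = c(614.4, 614.4), seed = 1L)
})
fix_tilt_subset <- function() cached("tilt_subset", {
  st <- fix_tilt_stack()
  unlist(lapply(split(seq_along(st$crops), st$info$level), function(ix) ix[1:13]))
})
fix_tilt_library <- function() cached("tilt_lib", {
  st <- fix_tilt_stack()
  sub <- fix_tilt_subset()
  m <- fix_model()
  build_library(split(st$crops[sub], st$info$level[sub]), m$z_step, m$focal_index)
})
# tilt plane fitted from near-focus crops (|label| <= 3 um, where the median
# templates are cleanest) classified against the biased library itself
fix_tilt_fit <- function() cached("tilt_fit", {
  st <- fix_tilt_stack()
  lib <- fix_tilt_library()
  sm <- library_score_matrix(lib)
  keep <- abs(st$info$z_label) <= 3
  zp <- vapply(st$crops[keep], function(cr) classify_z(cr, lib, sm)$z, numeric(1))
  estimate_tilt(data.frame(x_um = st$info$x_um[keep], y_um = st$info$y_um[keep],
                           z_predicted = zp, z_label = st$info$z_label[keep]))
})

# Straight synthetic pathlines with optional Gaussian z-noise.
fix_linear_pathlines <- function(n = 40, L = 30, z_sd = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(k) {
    x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 20); z0 <- runif(1, -10, 10)
    vx <- runif(1, 50, 300)
    t <- (0:(L - 1)) / 300
    data.frame(pathline_id = k, track_id = k, frame = 0:(L - 1), t_s = t,
               x_um = x0 + vx * t, y_um = y0, z_um = z0 + rnorm(L, 0, z_sd))
  }))
}
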