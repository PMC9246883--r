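#' Optical model for synthetic defocus imaging
#'
#' Parametric stand-in for the brightfield point-spread function of a seed
#' bead imaged through a low-NA objective with deliberate spherical
#' aberration. A defocused bead is rendered as a bright core plus a system of
#' concentric rings whose radius grows with distance from the focal plane;
#' the ring spacing is modulated by the *sign* of the defocus so that
#' patterns above and below focus are distinguishable (the role played by
#' the objective's correction collar in the real optics). The model is not a
#' wave-optics computation: it is an injective, smooth pattern family that
#' lets the classification pipeline be tested with exact ground truth.
#'
#' @param pixel_size Pixel pitch in micrometers per pixel.
#' @param bead_diameter Seed bead diameter, micrometers.
#' @param z_range_h Usable Z-range (depth of the working volume), micrometers.
#' @param z_step Calibration step between reference levels, micrometers.
#' @param n_levels Number of reference levels spanning the range.
#' @param ring_gain Growth of the defocus ring radius per micrometer of
#'   defocus (dimensionless, micrometer radius per micrometer |z|).
#' @param aberration_asymmetry Signed modulation of the ring spacing per
#'   micrometer of z; must be non-zero so the z -> pattern map is injective
#'   (removes the above/below-focus ambiguity).
#' @param background_level,particle_contrast Background intensity and peak
#'   particle amplitude, on a 0-1 scale.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param rng_seed Integer seed controlling every stochastic choice made by
#'   renderers that use this model.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(pixel_size = 0.32, bead_diameter = 3.0,
                          z_range_h = 54, z_step = 0.5, n_levels = 110,
                          ring_gain = 0.12, aberration_asymmetry = 0.012,
                          background_level = 0.35, particle_contrast = 0.45,
                          noise_sd = 0, rng_seed = 1L) {
  if (z_step <= 0) stopf("z_step must be > 0")
  if (n_levels < 2) stopf("n_levels must be >= 2")
  if (aberration_asymmetry == 0)
    stopf("aberration_asymmetry must be non-zero: the defocus pattern must be injective in z")
  focal_index <- n_levels %/% 2                 # 0-based level whose label is 0
  z_labels <- (seq_len(n_levels) - 1L - focal_index) * z_step
  m <- list(pixel_size = pixel_size, bead_diameter = bead_diameter,
            z_range_h = z_range_h, z_step = z_step, n_levels = as.integer(n_levels),
            ring_gain = ring_gain, aberration_asymmetry = aberration_asymmetry,
            background_level = background_level, particle_contrast = particle_contrast,
            noise_sd = noise_sd, rng_seed = as.integer(rng_seed),
            focal_index = as.integer(focal_index),
            z_min = min(z_labels), z_max = max(z_labels),
            crop_px = 32L)
  class(m) <- "optical_model"
  m
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model: ", x$n_levels, " levels x ", x$z_step, " um (z in [",
      x$z_min, ", ", x$z_max, "] um), ", x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

# Radially evaluated defocus pattern (no background, no noise), at radial
# distances r (um) from the particle center for defocus z (um).
defocus_radial <- function(r, z, model) {
  az <- abs(z)
  core_sd <- 0.45 + 0.02 * az                   # central lobe blurs slowly, um
  # the sign of z is encoded three ways, mimicking a correction-collar
  # aberration: rings grow slightly faster above focus, ring spacing is
  # modulated by signed z, and rings are brighter above focus than below;
  # together these make the pattern family injective over the whole range
  ring_r <- 0.9 + model$ring_gain * (az + 0.15 * z)
  ring_w <- 0.8 + 0.05 * az                     # annulus envelope width
  spacing <- 1.0 * (1 + model$aberration_asymmetry * z)
  core_amp <- 1 / (1 + 0.55 * az)               # peak fades as energy spreads into rings
  ring_amp <- 0.5 / (1 + 0.28 * az)^1.5 * (1 + 0.5 * tanh(z / 2))
  core <- core_amp * exp(-r^2 / (2 * core_sd^2))
  rings <- ring_amp * exp(-(r - ring_r)^2 / (2 * ring_w^2)) *
    cos(2 * pi * (r - ring_r) / spacing)
  core + rings
}

#' Render a single defocused particle image
#'
#' Evaluates the parametric defocus pattern analytically at pixel centers of
#' a 32 x 32 crop (no FFT shifting, so sub-pixel placement introduces no
#' interpolation artifacts). The particle center sits at the geometric crop
#' center (pixel coordinates (15.5, 15.5), 0-based) plus `subpixel_offset`.
#'
#' @param z Defocus in micrometers (0 = focal plane).
#' @param model An [optical_model()].
#' @param subpixel_offset Length-2 numeric, (dx, dy) offset of the particle
#'   center from the crop center, micrometers.
#' @param seed Seed for the additive noise draw; defaults to the model seed
#'   so identical calls are bit-identical.
#' @return A 32 x 32 numeric matrix (rows = y, columns = x) of intensities
#'   in \[0, 1\].
#' @export
render_particle_image <- function(z, model, subpixel_offset = c(0, 0),
                                  seed = model$rng_seed) {
  half_step <- model$z_step / 2
  if (z < model$z_min - half_step || z > model$z_max + half_step)
    stopf("z = %.3f um outside the model range [%.3f, %.3f]",
          z, model$z_min, model$z_max)
  n <- model$crop_px
  px <- model$pixel_size
  cx <- (n - 1) / 2 + subpixel_offset[1] / px   # pixel coords of particle center
  cy <- (n - 1) / 2 + subpixel_offset[2] / px
  xs <- (0:(n - 1) - cx) * px
  ys <- (0:(n - 1) - cy) * px
  r <- sqrt(outer(ys^2, xs^2, `+`))
  img <- model$background_level +
    model$particle_contrast * defocus_radial(r, z, model)
  if (model$noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(n * n, 0, model$noise_sd), n, n))
  clamp01(img)
}

#' Render a calibration reference stack with known ground truth
#'
#' Emulates the acquisition of a reference library: at each of the model's
#' levels, `particles_per_level` beads are placed at random positions in a
#' virtual field of view and their crops rendered. When a `tilt` plane
#' (a, b) is supplied the *true* defocus of a bead at field position (x, y)
#' is `z_level + a*(x - W/2) + b*(y - H/2)` — the slide is tilted about the
#' field center, so the focal level still has zero mean depth — while its
#' recorded label remains `z_level`: exactly the situation tilt relabeling
#' must correct.
#'
#' @param model An [optical_model()].
#' @param tilt Optional length-2 numeric (a, b), micrometer of z per
#'   micrometer of field x and y.
#' @param particles_per_level Beads rendered per level.
#' @param field_size Length-2 numeric, field of view (width, height) in
#'   micrometers over which bead positions are drawn.
#' @param seed RNG seed (defaults to the model seed).
#' @return A list with `crops` (list of 32 x 32 matrices) and `info`, a
#'   data frame with columns `level` (0-based), `z_label`, `z_true`,
#'   `x_um`, `y_um`.
#' @export
render_reference_stack <- function(model, tilt = c(0, 0), particles_per_level = 1,
                                   field_size = c(614.4, 345.6),
                                   seed = model$rng_seed) {
  if (particles_per_level < 1) stopf("particles_per_level must be >= 1")
  n_lev <- model$n_levels
  z_labels <- (seq_len(n_lev) - 1L - model$focal_index) * model$z_step
  total <- n_lev * particles_per_level
  pos <- with_seed(mix_seed(seed, 7L), cbind(
    stats::runif(total, 0, field_size[1]),
    stats::runif(total, 0, field_size[2])))
  info <- data.frame(
    level = rep(0:(n_lev - 1L), each = particles_per_level),
    z_label = rep(z_labels, each = particles_per_level),
    x_um = pos[, 1], y_um = pos[, 2])
  z_true <- info$z_label + tilt[1] * (info$x_um - field_size[1] / 2) +
    tilt[2] * (info$y_um - field_size[2] / 2)
  # tilt can push extreme levels past the renderable range; truth is clipped
  info$z_true <- pmin(pmax(z_true, model$z_min), model$z_max)
  crops <- vector("list", total)
  for (i in seq_len(total))
    crops[[i]] <- render_particle_image(info$z_true[i], model, seed = mix_seed(seed, i))
  list(crops = crops, info = info)
}
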