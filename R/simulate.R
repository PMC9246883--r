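#' Simulate a seeded-flow video with exact ground truth
#'
#' Advects seed particles through a prescribed velocity field with
#' fixed-step RK4 (dt = 1/(10 fps)) and renders every frame by analytic
#' evaluation of the defocus pattern at pixel centers. Particles outside
#' the frame or the model's Z-range are not rendered but remain in the
#' scene. With `wrap_x` set, particles leaving the right edge re-enter on
#' the left (steady duct flow at constant seeding density).
#'
#' @param field Function `pos (n x 3 um) -> n x 3 velocity (um/s)`.
#' @param model An [optical_model()].
#' @param frame_size_px Length-2 integer, frame (width, height) in pixels.
#' @param n_frames Number of frames to render.
#' @param fps Frame rate, frames per second.
#' @param init Either an n x 3 matrix of initial positions (um) or an
#'   integer particle count drawn uniformly over `spawn_box`.
#' @param spawn_box 3 x 2 matrix of (min, max) per axis for random spawns;
#'   defaults to the frame extent and the model Z-range.
#' @param wrap_x Optional period (um): x positions wrap modulo this length.
#' @param seed RNG seed (defaults to the model seed).
#' @return List with `frames` (list of matrices), `truth` (data frame
#'   `frame`, `particle_id`, `x_um`, `y_um`, `z_um`, `visible`), `fps`,
#'   `model`.
#' @export
simulate_video <- function(field, model, frame_size_px = c(192L, 128L),
                           n_frames = 50L, fps = 300,
                           init = 10L, spawn_box = NULL, wrap_x = NULL,
                           seed = model$rng_seed) {
  px <- model$pixel_size
  wx <- frame_size_px[1] * px
  wy <- frame_size_px[2] * px
  if (is.matrix(init)) {
    pos <- init
  } else {
    if (is.null(spawn_box))
      spawn_box <- rbind(c(0, wx), c(0, wy),
                         c(model$z_min * 0.9, model$z_max * 0.9))
    pos <- with_seed(mix_seed(seed, 11L), cbind(
      stats::runif(init, spawn_box[1, 1], spawn_box[1, 2]),
      stats::runif(init, spawn_box[2, 1], spawn_box[2, 2]),
      stats::runif(init, spawn_box[3, 1], spawn_box[3, 2])))
  }
  n_p <- nrow(pos)
  sub_steps <- 10L
  dt <- 1 / (sub_steps * fps)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    vis <- pos[, 1] >= 0 & pos[, 1] < wx & pos[, 2] >= 0 & pos[, 2] < wy &
      pos[, 3] >= model$z_min & pos[, 3] <= model$z_max
    truth[[f]] <- data.frame(frame = f - 1L, particle_id = seq_len(n_p),
                             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                             visible = vis)
    frames[[f]] <- render_frame(pos[vis, , drop = FALSE], model, frame_size_px,
                                seed = mix_seed(seed, 1000L + f))
    if (f < n_frames) {
      pos <- advect_rk4(field, pos, dt, sub_steps)
      if (!is.null(wrap_x)) pos[, 1] <- pos[, 1] %% wrap_x
    }
  }
  list(frames = frames, truth = do.call(rbind, truth), fps = fps, model = model)
}

# Composite defocus patterns of the given particles (n x 3 positions, um)
# onto a flat background frame; intensities above background add linearly.
render_frame <- function(pos, model, frame_size_px, seed = model$rng_seed) {
  w <- frame_size_px[1]; h <- frame_size_px[2]
  img <- matrix(model$background_level, h, w)
  n_c <- model$crop_px
  halfc <- (n_c - 1) / 2
  px <- model$pixel_size
  if (nrow(pos) > 0) for (i in seq_len(nrow(pos))) {
    xp <- pos[i, 1] / px
    yp <- pos[i, 2] / px
    left <- round(xp - halfc)                    # 0-based col of crop's first px
    top <- round(yp - halfc)
    noiseless <- model
    noiseless$noise_sd <- 0
    crop <- render_particle_image(pos[i, 3], noiseless,
                                  subpixel_offset = c((xp - left - halfc) * px,
                                                      (yp - top - halfc) * px))
    cols <- (left + 1):(left + n_c)
    rows <- (top + 1):(top + n_c)
    ic <- cols >= 1 & cols <= w
    ir <- rows >= 1 & rows <= h
    img[rows[ir], cols[ic]] <- img[rows[ir], cols[ic]] +
      (crop[ir, ic, drop = FALSE] - model$background_level)
  }
  if (model$noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(h * w, 0, model$noise_sd), h, w))
  clamp01(img)
}

#' Write / read a simulated scene bundle
#'
#' A scene directory holds `video.tif` (multi-page grayscale), `truth.csv`
#' (`frame,particle_id,x_um,y_um,z_um`) and `scene.json` (fps and optics
#' parameters).
#'
#' @param scene Output of [simulate_video()].
#' @param path Directory to create.
#' @export
write_scene <- function(scene, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tiff_stack(scene$frames, file.path(path, "video.tif"))
  tr <- scene$truth[scene$truth$visible, c("frame", "particle_id", "x_um", "y_um", "z_um")]
  utils::write.csv(tr, file.path(path, "truth.csv"), row.names = FALSE)
  m <- scene$model
  jsonlite::write_json(
    list(fps = scene$fps,
         optics = m[c("pixel_size", "bead_diameter", "z_range_h", "z_step",
                      "n_levels", "ring_gain", "aberration_asymmetry",
                      "background_level", "particle_contrast", "noise_sd",
                      "rng_seed")]),
    file.path(path, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @return `read_scene()` returns a list with `frames`, `truth`, `fps`,
#'   `model`.
#' @export
read_scene <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "scene.json"), simplifyVector = TRUE)
  model <- do.call(optical_model, as.list(meta$optics))
  list(frames = read_tiff_stack(file.path(path, "video.tif")),
       truth = utils::read.csv(file.path(path, "truth.csv")),
       fps = meta$fps, model = model)
}
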