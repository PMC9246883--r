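#' Objective step size corrected for refractive-index mismatch
#'
#' When the objective moves through air but the imaged particles sit in a
#' working fluid of higher refractive index, the focal plane moves by less
#' than the objective. To obtain reference levels spaced by
#' `desired_z_step` inside the fluid, the objective must step by
#' `desired_z_step / (n_wf / n_air)`.
#'
#' @param desired_z_step Desired spacing of reference levels in the working
#'   fluid, micrometers.
#' @param n_wf Refractive index of the working fluid (default 1.41, a 45/55
#'   v/v water/glycerol mixture index-matched to PDMS).
#' @param n_air Refractive index of the immersion medium (air, 1.0).
#' @return Objective step size in micrometers.
#' @export
corrected_step_size <- function(desired_z_step, n_wf = 1.41, n_air = 1.0) {
  if (n_wf <= 0 || n_air <= 0) stopf("refractive indices must be positive")
  desired_z_step / (n_wf / n_air)
}

#' Brenner-gradient focus metric and focal-frame selection
#'
#' The Brenner gradient of a frame is `sum((I[x+s, y] - I[x, y])^2)` with a
#' fixed horizontal shift `s = 2` pixels; the best-focused frame of a
#' calibration stack maximizes it. Ties break toward the lower index.
#'
#' @param stack List of image matrices ordered by objective height.
#' @param shift Pixel shift of the difference (classic value 2).
#' @return `brenner_focus()`: the (1-based) index of the sharpest frame.
#'   `brenner_gradient()`: the scalar metric of one frame.
#' @export
brenner_focus <- function(stack, shift = 2L) {
  if (length(stack) < 2) stopf("need at least 2 frames to pick a focal plane")
  b <- vapply(stack, brenner_gradient, numeric(1), shift = shift)
  if (all(b == b[1])) stopf("degenerate stack: Brenner gradient is constant")
  which.max(b)                                   # which.max takes the first max
}

#' @rdname brenner_focus
#' @param frame An image matrix.
#' @export
brenner_gradient <- function(frame, shift = 2L) {
  nc <- ncol(frame)
  if (nc <= shift) stopf("frame narrower than the Brenner shift")
  d <- frame[, (1 + shift):nc, drop = FALSE] - frame[, 1:(nc - shift), drop = FALSE]
  sum(d^2)
}

#' Build a reference library of per-level median defocus images
#'
#' Each level image is the per-pixel median across all crops recorded at
#' that level; the median suppresses outlier crops (foreign objects, bad
#' detections) that would contaminate a mean template. Levels are labeled
#' `(level - focal_index) * z_step` micrometers. For even crop counts the
#' lower median is used (reproducible, integer-friendly).
#'
#' @param crops_by_level List (one element per level, ascending z) of lists
#'   of 32 x 32 crop matrices.
#' @param z_step Level spacing, micrometers.
#' @param focal_index 0-based index of the level whose label is 0.
#' @param pixel_size Micrometers per pixel, stored as metadata.
#' @param tilt Optional tilt plane (see [estimate_tilt()]) recorded as
#'   provenance when the library was built from relabeled crops.
#' @return An object of class `reference_library`.
#' @export
build_library <- function(crops_by_level, z_step, focal_index,
                          pixel_size = 0.32, tilt = NULL, allow_empty = FALSE) {
  n_levels <- length(crops_by_level)
  if (n_levels < 1) stopf("no levels supplied")
  dims <- NULL
  level_images <- vector("list", n_levels)
  for (k in seq_len(n_levels)) {
    crops <- crops_by_level[[k]]
    crops <- crops[!vapply(crops, is.null, logical(1))]
    if (length(crops) == 0) {
      if (allow_empty) next
      stopf("level %d has no crops", k - 1L)
    }
    d <- dim(crops[[1]])
    if (is.null(dims)) dims <- d
    if (!all(vapply(crops, function(c) identical(dim(c), dims), logical(1))))
      stopf("level %d: crop shapes differ", k - 1L)
    if (length(crops) == 1L) {
      level_images[[k]] <- crops[[1]]
    } else {
      arr <- array(unlist(crops), c(dims, length(crops)))
      level_images[[k]] <- apply(arr, c(1, 2), lower_median)
    }
  }
  z_labels <- (seq_len(n_levels) - 1L - focal_index) * z_step
  lib <- list(level_images = level_images, z_labels = z_labels, z_step = z_step,
              z_range_h = (n_levels - 1L) * z_step, n_levels = as.integer(n_levels),
              pixel_size = pixel_size, focal_index = as.integer(focal_index),
              tilt = tilt)
  class(lib) <- "reference_library"
  lib
}

# Lower median: the floor(n/2 + 1)-th order statistic for odd n, the
# n/2-th for even n (so the result is always an observed value).
lower_median <- function(x) {
  n <- length(x)
  sort(x, partial = (n + 1L) %/% 2L)[(n + 1L) %/% 2L]
}

#' @export
print.reference_library <- function(x, ...) {
  cat("Reference library: ", x$n_levels, " levels, z in [",
      min(x$z_labels), ", ", max(x$z_labels), "] um, step ", x$z_step, " um",
      if (!is.null(x$tilt)) " (tilt-relabeled)", "\n", sep = "")
  invisible(x)
}

#' Estimate slide tilt from classification residuals
#'
#' Fits, by least squares, a plane `z_pred - z_label = a*x + b*y + z0` to
#' the per-particle residual between classified and nominal depth across
#' the field of view. A non-zero plane means the calibration slide was
#' tilted: particles recorded at one objective height do not share a true
#' depth, and the level labels are biased by position.
#'
#' @param per_particle Data frame with columns `x_um`, `y_um`,
#'   `z_predicted`, `z_label`.
#' @param per_level_intercepts When several levels are present (default),
#'   each level gets its own intercept so that level-wise prediction bias —
#'   a median library built from tilted calibration data is itself biased
#'   level by level — does not contaminate the slopes; the slopes are then
#'   estimated purely from the within-level variation across the field, and
#'   `z0` is the count-weighted mean of the level offsets.
#' @return A `tilt_plane` list with slopes `a`, `b` (um per um), offset
#'   `z0` (um) and `fit_residual_rmse` (um).
#' @export
estimate_tilt <- function(per_particle, per_level_intercepts = TRUE) {
  req <- c("x_um", "y_um", "z_predicted", "z_label")
  if (!all(req %in% names(per_particle)))
    stopf("per_particle needs columns %s", paste(req, collapse = ", "))
  if (nrow(per_particle) < 3) stopf("need at least 3 particles to fit a plane")
  resid <- per_particle$z_predicted - per_particle$z_label
  lev <- factor(per_particle$z_label)
  use_levels <- per_level_intercepts && nlevels(lev) > 1 &&
    nrow(per_particle) >= nlevels(lev) + 2
  X <- if (use_levels)
    cbind(stats::model.matrix(~ lev - 1), per_particle$x_um, per_particle$y_um)
  else cbind(1, per_particle$x_um, per_particle$y_um)
  if (qr(X)$rank < ncol(X)) stopf("degenerate design: particle positions are collinear")
  fit <- stats::lm.fit(X, resid)
  k <- ncol(X)
  offsets <- fit$coefficients[seq_len(k - 2)]
  z0 <- if (use_levels) sum(offsets * tabulate(lev)) / length(lev) else offsets[[1]]
  plane <- list(a = unname(fit$coefficients[k - 1]),
                b = unname(fit$coefficients[k]),
                z0 = unname(z0),
                fit_residual_rmse = sqrt(mean(fit$residuals^2)))
  class(plane) <- "tilt_plane"
  plane
}

#' Relabel reference crops for slide tilt
#'
#' Applies a fitted [estimate_tilt()] plane to crop metadata: each crop's
#' depth label becomes `z_label + a*x + b*y + z0`. Use
#' [rebuild_library()] afterwards to regroup the relabeled crops onto the
#' level grid and recompute median images.
#'
#' @param info Data frame with columns `x_um`, `y_um`, `z_label`.
#' @param plane A `tilt_plane`.
#' @return `info` with a corrected `z_label` column.
#' @export
relabel <- function(info, plane) {
  if (!all(is.finite(c(plane$a, plane$b, plane$z0))))
    stopf("tilt plane coefficients must be finite")
  info$z_label <- info$z_label + plane$a * info$x_um + plane$b * info$y_um + plane$z0
  info
}

#' Rebuild a reference library from crops with continuous labels
#'
#' Groups crops by the nearest level on a `z_step` grid (relabeled crops no
#' longer sit exactly on levels) and rebuilds per-level median images.
#' Levels left without any crop are dropped from the ends; an interior
#' empty level is filled by linear interpolation between its nearest
#' populated neighbors (or raises an error with `fill = "error"`), keeping
#' the constant level spacing intact.
#'
#' @param crops List of crop matrices.
#' @param info Data frame with a (possibly continuous) `z_label` column,
#'   parallel to `crops`.
#' @param z_step Level spacing, micrometers.
#' @param pixel_size Metadata, micrometers per pixel.
#' @param tilt Optional `tilt_plane` recorded as provenance.
#' @param fill `"interpolate"` (default) or `"error"` for interior levels
#'   that receive no crop.
#' @return A `reference_library`.
#' @export
rebuild_library <- function(crops, info, z_step, pixel_size = 0.32, tilt = NULL,
                            fill = c("interpolate", "error")) {
  fill <- match.arg(fill)
  lev <- round(info$z_label / z_step)
  rng <- range(lev)
  idx_by_level <- split(seq_along(crops), factor(lev, levels = rng[1]:rng[2]))
  empty <- vapply(idx_by_level, length, integer(1)) == 0L
  keep <- which(!empty)
  if (length(keep) == 0) stopf("no crops to build a library from")
  first <- min(keep); last <- max(keep)
  holes <- which(empty[first:last]) + first - 1L
  if (length(holes) && fill == "error")
    stopf("interior level(s) without crops: %s",
          paste(names(idx_by_level)[holes], collapse = ", "))
  levels_kept <- (rng[1]:rng[2])[first:last]
  crops_by_level <- lapply(idx_by_level[first:last], function(ix) crops[ix])
  lib <- build_library(
    lapply(crops_by_level, function(cl) if (length(cl)) cl else list(NULL)),
    z_step, focal_index = -levels_kept[1], pixel_size = pixel_size, tilt = tilt,
    allow_empty = TRUE)
  # interpolate interior holes between the nearest populated neighbors
  pop <- which(!vapply(lib$level_images, is.null, logical(1)))
  for (k in which(vapply(lib$level_images, is.null, logical(1)))) {
    lo <- max(pop[pop < k]); hi <- min(pop[pop > k])
    wgt <- (k - lo) / (hi - lo)
    lib$level_images[[k]] <- (1 - wgt) * lib$level_images[[lo]] +
      wgt * lib$level_images[[hi]]
  }
  lib
}

#' Save / load a reference library bundle
#'
#' The bundle is a directory holding `levels.tif` (one page per level,
#' ascending z) and `library.json` (z labels, step, pixel size, focal
#' index, tilt). The round trip is lossless to 16-bit quantization of the
#' images; [load_library()] validates that page count and metadata agree.
#'
#' @param lib A `reference_library`.
#' @param path Directory to create/fill.
#' @export
save_library <- function(lib, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tiff_stack(lib$level_images, file.path(path, "levels.tif"), bits = 16L)
  meta <- list(z_labels = lib$z_labels, z_step = lib$z_step,
               z_range_h = lib$z_range_h, n_levels = lib$n_levels,
               pixel_size = lib$pixel_size, focal_index = lib$focal_index,
               tilt = if (is.null(lib$tilt)) NULL else unclass(lib$tilt))
  jsonlite::write_json(meta, file.path(path, "library.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_library
#' @return `load_library()` returns the `reference_library`.
#' @export
load_library <- function(path) {
  json_path <- file.path(path, "library.json")
  tif_path <- file.path(path, "levels.tif")
  if (!file.exists(json_path) || !file.exists(tif_path))
    stopf("not a library bundle (missing levels.tif or library.json): %s", path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  images <- read_tiff_stack(tif_path)
  if (length(images) != meta$n_levels)
    stopf("library bundle corrupt: %d pages but metadata says %d levels",
          length(images), meta$n_levels)
  lib <- list(level_images = images, z_labels = meta$z_labels,
              z_step = meta$z_step, z_range_h = meta$z_range_h,
              n_levels = as.integer(meta$n_levels), pixel_size = meta$pixel_size,
              focal_index = as.integer(meta$focal_index),
              tilt = if (is.null(meta$tilt)) NULL else
                structure(meta$tilt, class = "tilt_plane"))
  class(lib) <- "reference_library"
  lib
}
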