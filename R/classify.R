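#' Extract per-spot crops from video frames
#'
#' For each spot of each track, a 32 x 32 pixel crop is cut from the raw
#' frame, centered on the nearest pixel to the subpixel spot position (the
#' residual offset is recorded; no resampling is ever applied to pixel
#' data). Crops that would extend past the frame border are padded with the
#' frame's median intensity and flagged.
#'
#' @param frames List of image matrices.
#' @param tracks Track data frame (`track_id`, `frame`, `x_px`, `y_px`).
#' @param crop_px Crop side length (default 32).
#' @return A list of crop stacks, one per track (named by track id); each
#'   stack is a list with `crops` (list of matrices), `offsets_px`
#'   (n x 2 residual subpixel offsets), `padded` (logical), and the track's
#'   rows of `tracks`.
#' @export
extract_crops <- function(frames, tracks, crop_px = 32L) {
  half <- crop_px / 2
  by_track <- split(seq_len(nrow(tracks)), tracks$track_id)
  lapply(by_track, function(rows) {
    sel <- tracks[rows, , drop = FALSE]
    sel <- sel[order(sel$frame), , drop = FALSE]
    crops <- vector("list", nrow(sel))
    offsets <- matrix(0, nrow(sel), 2)
    padded <- logical(nrow(sel))
    for (i in seq_len(nrow(sel))) {
      fr <- frames[[sel$frame[i] + 1L]]
      # left/top pixel index so the spot sits nearest the geometric center
      left <- round(sel$x_px[i] - (half - 0.5))
      top <- round(sel$y_px[i] - (half - 0.5))
      offsets[i, ] <- c(sel$x_px[i] - (left + half - 0.5),
                        sel$y_px[i] - (top + half - 0.5))
      cols <- (left + 1):(left + crop_px)
      rws <- (top + 1):(top + crop_px)
      in_c <- cols >= 1 & cols <= ncol(fr)
      in_r <- rws >= 1 & rws <= nrow(fr)
      if (all(in_c) && all(in_r)) {
        crops[[i]] <- fr[rws, cols]
      } else {
        padded[i] <- TRUE
        cr <- matrix(stats::median(fr), crop_px, crop_px)
        cr[which(in_r), which(in_c)] <- fr[rws[in_r], cols[in_c]]
        crops[[i]] <- cr
      }
    }
    list(track_id = sel$track_id[1], crops = crops, offsets_px = offsets,
         padded = padded, spots = sel)
  })
}

#' Normalized cross-correlation of two equally shaped images
#'
#' Zero-lag, zero-mean, unit-variance correlation: the score is 1 exactly
#' when one image is a positive-gain affine intensity transform of the
#' other, and -1 for a negated copy.
#'
#' @param a,b Numeric matrices of identical shape.
#' @return Scalar in \[-1, 1\].
#' @export
ncc_score <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("ncc_score: shapes differ")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stopf("ncc_score undefined: zero-variance image")
  sum(a * b) / (na * nb)
}

# Precompute the library's level images as centered, unit-norm vectors so a
# whole library is scored with one matrix product per crop.
library_score_matrix <- function(lib) {
  V <- vapply(lib$level_images, function(img) {
    v <- as.vector(img) - mean(img)
    n <- sqrt(sum(v^2))
    if (n == 0) stopf("library level image has zero variance")
    v / n
  }, numeric(length(lib$level_images[[1]])))
  t(V)                                           # n_levels x n_pixels
}

#' Classify the depth of one particle crop against a reference library
#'
#' Scores the crop against every level's median image by normalized
#' cross-correlation, takes the best level (ties resolved toward the focal
#' plane, then the lower index), and refines to a continuous Z by a
#' three-point parabola through the scores of the best level and its two
#' neighbors. At the ends of the range the level label is returned
#' unrefined.
#'
#' @param crop 32 x 32 numeric matrix.
#' @param lib A `reference_library` (at least 3 levels).
#' @param score_matrix Optional precomputed [library_score_matrix()]
#'   (computed on the fly otherwise; pass it when classifying many crops).
#' @return A list of class `z_prediction`: `z` (um, continuous),
#'   `best_level` (0-based), `score` (NCC at the best level),
#'   `score_margin` (best minus second best).
#' @export
classify_z <- function(crop, lib, score_matrix = NULL) {
  if (lib$n_levels < 3) stopf("library must have at least 3 levels")
  if (is.null(score_matrix)) score_matrix <- library_score_matrix(lib)
  v <- as.vector(crop) - mean(crop)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stopf("cannot classify a zero-variance crop")
  scores <- as.vector(score_matrix %*% (v / nv))
  best <- max(scores)
  cand <- which(scores == best)
  if (length(cand) > 1) {                        # ties: nearest focal, then lower
    d <- abs(cand - 1L - lib$focal_index)
    cand <- cand[order(d, cand)]
  }
  k <- cand[1]
  z <- lib$z_labels[k]
  # an exact template match pins the peak at the node; otherwise refine by a
  # parabola through the best level and its neighbors (skipped at range ends)
  if (scores[k] < 1 - 1e-12 && k > 1 && k < lib$n_levels) {
    den <- scores[k - 1] - 2 * scores[k] + scores[k + 1]
    if (den < 0)
      z <- z + 0.5 * (scores[k - 1] - scores[k + 1]) / den * lib$z_step
  }
  second <- if (lib$n_levels >= 2) max(scores[-k]) else NA_real_
  structure(list(z = z, best_level = k - 1L, score = scores[k],
                 score_margin = scores[k] - second),
            class = "z_prediction")
}

#' Classify every crop of a track's time-stack
#'
#' Crops are classified independently (no temporal coupling); temporal
#' cleanup is left to the downstream order-5 median filter on pathlines. A
#' crop whose score is undefined (zero variance) yields `NA` with a flag
#' rather than aborting the track.
#'
#' @param cropstack One element of [extract_crops()] output (or a bare list
#'   of crop matrices).
#' @param lib A `reference_library`.
#' @param score_matrix Optional precomputed [library_score_matrix()].
#' @return Data frame with columns `z_um`, `best_level`, `score`, `margin`,
#'   `failed`, one row per crop in order.
#' @export
classify_track <- function(cropstack, lib, score_matrix = NULL) {
  crops <- if (is.list(cropstack) && !is.null(cropstack$crops)) cropstack$crops
           else cropstack
  if (is.null(score_matrix)) score_matrix <- library_score_matrix(lib)
  out <- data.frame(z_um = rep(NA_real_, length(crops)), best_level = NA_integer_,
                    score = NA_real_, margin = NA_real_, failed = FALSE)
  for (i in seq_along(crops)) {
    p <- tryCatch(classify_z(crops[[i]], lib, score_matrix), error = function(e) NULL)
    if (is.null(p)) { out$failed[i] <- TRUE; next }
    out$z_um[i] <- p$z
    out$best_level[i] <- p$best_level
    out$score[i] <- p$score
    out$margin[i] <- p$score_margin
  }
  out
}

#' Classification accuracy (RMSE)
#'
#' Root mean square error between predicted and ground-truth values; the
#' accuracy metric reported per axis by the method. Divide by the Z-range
#' `h` for the normalized accuracy.
#'
#' @param predicted,truth Equal-length numeric vectors.
#' @return RMSE, same units as the inputs.
#' @export
accuracy_sigma <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stopf("length mismatch")
  if (length(predicted) == 0) stopf("empty input")
  sqrt(mean((predicted - truth)^2))
}

#' Apply an external per-crop Z regressor (pluggable classifier)
#'
#' The pipeline is agnostic to how crops are mapped to depths: any
#' `function(list_of_crops) -> numeric z (um)` — for example a wrapper
#' around an external deep-learning regressor, or predictions read from a
#' file — can stand in for [classify_track()]. This helper validates the
#' contract (length, units within the library range, finiteness).
#'
#' @param cropstack As in [classify_track()].
#' @param classifier Function taking a list of crops and returning one z
#'   (micrometers) per crop.
#' @param lib Reference library defining the legal z range.
#' @return Data frame shaped like [classify_track()] output (scores `NA`).
#' @export
classify_track_with <- function(cropstack, classifier, lib) {
  crops <- if (is.list(cropstack) && !is.null(cropstack$crops)) cropstack$crops
           else cropstack
  z <- classifier(crops)
  if (length(z) != length(crops))
    stopf("classifier returned %d predictions for %d crops", length(z), length(crops))
  lo <- min(lib$z_labels) - lib$z_step / 2
  hi <- max(lib$z_labels) + lib$z_step / 2
  bad <- is.finite(z) & (z < lo | z > hi)
  if (any(bad))
    stopf("classifier predictions outside the library range [%g, %g] um", lo, hi)
  data.frame(z_um = as.numeric(z), best_level = NA_integer_, score = NA_real_,
             margin = NA_real_, failed = !is.finite(z))
}
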