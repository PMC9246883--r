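# Spot detection: Laplacian-of-Gaussian blob detector with subpixel
# refinement, the same scheme TrackMate applies to brightfield bead video.

# Separable Gaussian smoothing with edge renormalization (truncated kernel
# weights are rescaled near borders so flat regions stay flat).
gaussian_smooth <- function(img, sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-hw:hw)^2 / (2 * sigma^2))
  band <- function(n) {
    K <- matrix(0, n, n)
    for (o in -hw:hw) {
      idx <- seq_len(n - abs(o))
      if (o >= 0) K[cbind(idx, idx + o)] <- g[o + hw + 1]
      else K[cbind(idx - o, idx)] <- g[o + hw + 1]
    }
    K / rowSums(K)
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

# Scale-normalized negative Laplacian of the Gaussian-smoothed image:
# positive peaks at bright blobs of radius ~ sigma*sqrt(2).
log_response <- function(img, sigma) {
  s <- gaussian_smooth(img, sigma)
  n <- nrow(s); m <- ncol(s)
  lap <- matrix(0, n, m)
  lap[2:(n - 1), 2:(m - 1)] <-
    s[1:(n - 2), 2:(m - 1)] + s[3:n, 2:(m - 1)] +
    s[2:(n - 1), 1:(m - 2)] + s[2:(n - 1), 3:m] - 4 * s[2:(n - 1), 2:(m - 1)]
  -sigma^2 * lap
}

#' Detect particle spots in one frame (LoG detector)
#'
#' Applies a Laplacian-of-Gaussian filter at the scale matched to the
#' expected spot radius, finds local maxima of the response above a quality
#' threshold, and refines each maximum to subpixel position by a quadratic
#' fit to its 3 x 3 response neighborhood. Maxima on the image border are
#' discarded. Coordinates are 0-based pixels with the origin at the center
#' of the top-left pixel.
#'
#' @param frame Image matrix (rows = y, columns = x), intensities in \[0,1\].
#' @param radius_px Expected bright-core radius in pixels; the LoG scale is
#'   `radius_px / sqrt(2)`.
#' @param quality_threshold Minimum LoG response; when `NULL` an automatic
#'   Otsu threshold on the positive response values is used.
#' @param frame_index 0-based frame number stored with each spot.
#' @return Data frame with columns `frame`, `x_px`, `y_px`, `quality`,
#'   `source` (`"detected"`). May have zero rows.
#' @export
log_detect <- function(frame, radius_px = 3, quality_threshold = NULL,
                       frame_index = 0L) {
  if (radius_px <= 0) stopf("radius_px must be positive")
  R <- log_response(frame, radius_px / sqrt(2))
  n <- nrow(R); m <- ncol(R)
  if (is.null(quality_threshold)) {
    pos <- R[R > 0]
    # the floor keeps numerical ripple on featureless frames from firing
    quality_threshold <- if (length(pos) < 2) Inf else
      max(otsu_threshold(pos), 1e-6)
  }
  empty <- data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      quality = numeric(0), source = character(0))
  if (n < 3 || m < 3) return(empty)
  C <- R[2:(n - 1), 2:(m - 1)]
  is_max <- C > quality_threshold &
    C >= R[1:(n - 2), 2:(m - 1)] & C >= R[3:n, 2:(m - 1)] &
    C >= R[2:(n - 1), 1:(m - 2)] & C >= R[2:(n - 1), 3:m] &
    C >= R[1:(n - 2), 1:(m - 2)] & C >= R[1:(n - 2), 3:m] &
    C >= R[3:n, 1:(m - 2)] & C >= R[3:n, 3:m]
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  i <- hits[, 1] + 1L                            # row in R
  j <- hits[, 2] + 1L                            # col in R
  # 3-point parabola per axis on the response
  denx <- R[cbind(i, j - 1)] - 2 * R[cbind(i, j)] + R[cbind(i, j + 1)]
  deny <- R[cbind(i - 1, j)] - 2 * R[cbind(i, j)] + R[cbind(i + 1, j)]
  dx <- ifelse(denx < 0, 0.5 * (R[cbind(i, j - 1)] - R[cbind(i, j + 1)]) / denx, 0)
  dy <- ifelse(deny < 0, 0.5 * (R[cbind(i - 1, j)] - R[cbind(i + 1, j)]) / deny, 0)
  dx <- pmin(pmax(dx, -0.5), 0.5)
  dy <- pmin(pmax(dy, -0.5), 0.5)
  out <- data.frame(frame = as.integer(frame_index),
                    x_px = (j - 1) + dx, y_px = (i - 1) + dy,
                    quality = R[cbind(i, j)], source = "detected")
  out[order(out$quality, decreasing = TRUE), , drop = FALSE]
}

#' Detect spots across a frame stack
#'
#' @param frames List of image matrices.
#' @inheritParams log_detect
#' @return Data frame of spots from all frames (0-based `frame` column).
#' @export
detect_stack <- function(frames, radius_px = 3, quality_threshold = NULL) {
  out <- lapply(seq_along(frames), function(f)
    log_detect(frames[[f]], radius_px, quality_threshold, frame_index = f - 1L))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance on a 256-bin histogram; used to
#' auto-calibrate the LoG quality threshold when none is given.
#'
#' @param x Numeric values.
#' @param n_bins Histogram bins.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins), n_bins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  centers[which.max(sb)]
}

#' Particle image density of a video
#'
#' Fraction of pixels covered by particle images (disks of the defocus
#' pattern radius around each spot), averaged over frames. The published
#' operating guideline is to keep this below 0.01 pixel/pixel so that
#' particle collisions stay rare.
#'
#' @param frames List of image matrices.
#' @param radius_px Footprint radius of one particle image, pixels.
#' @param spots Optional pre-detected spot data frame (else spots are
#'   detected with [detect_stack()] at this radius).
#' @param quality_threshold Passed to the detector when `spots` is `NULL`.
#' @return Mean covered fraction (pixel/pixel).
#' @export
particle_image_density <- function(frames, radius_px, spots = NULL,
                                   quality_threshold = NULL) {
  if (is.null(spots)) spots <- detect_stack(frames, radius_px, quality_threshold)
  n <- nrow(frames[[1]]); m <- ncol(frames[[1]])
  covered <- numeric(length(frames))
  for (f in seq_along(frames)) {
    sp <- spots[spots$frame == f - 1L, , drop = FALSE]
    if (nrow(sp) == 0) next
    mask <- matrix(FALSE, n, m)
    ys <- matrix(0:(n - 1), n, m)
    xs <- matrix(0:(m - 1), n, m, byrow = TRUE)
    for (s in seq_len(nrow(sp)))
      mask <- mask | ((xs - sp$x_px[s])^2 + (ys - sp$y_px[s])^2 <= radius_px^2)
    covered[f] <- mean(mask)
  }
  mean(covered)
}
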