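#' Assemble 3D pathlines from 2D tracks and per-spot depths
#'
#' Converts pixel coordinates to micrometers (`x = x_px * pixel_size`),
#' frames to seconds (`t = frame / fps`), and attaches the classified depth
#' sequence. A missing depth (`NA`) or a frame gap splits the track into
#' separate pathlines: interpolating across a gap would mix time bases.
#'
#' @param tracks Track data frame (`track_id`, `frame`, `x_px`, `y_px`).
#' @param z_um Numeric vector of depths, parallel to the rows of `tracks`
#'   (classified per spot), micrometers.
#' @param pixel_size Micrometers per pixel.
#' @param fps Frames per second.
#' @return Data frame with columns `pathline_id`, `track_id`, `frame`,
#'   `t_s`, `x_um`, `y_um`, `z_um`, ordered by pathline then time.
#' @export
assemble_pathlines <- function(tracks, z_um, pixel_size, fps) {
  if (length(z_um) != nrow(tracks))
    stopf("z_um has %d entries for %d spots", length(z_um), nrow(tracks))
  d <- data.frame(track_id = tracks$track_id, frame = as.integer(tracks$frame),
                  t_s = tracks$frame / fps,
                  x_um = tracks$x_px * pixel_size, y_um = tracks$y_px * pixel_size,
                  z_um = z_um)
  d <- d[order(d$track_id, d$frame), , drop = FALSE]
  new_track <- c(TRUE, d$track_id[-1] != d$track_id[-nrow(d)])
  gap <- c(TRUE, diff(d$frame) != 1L) | new_track
  miss <- is.na(d$z_um)
  seg_break <- gap | miss | c(TRUE, miss[-nrow(d)])
  d$pathline_id <- cumsum(seg_break)
  d <- d[!miss, , drop = FALSE]
  d$pathline_id <- match(d$pathline_id, unique(d$pathline_id))
  rownames(d) <- NULL
  d[, c("pathline_id", "track_id", "frame", "t_s", "x_um", "y_um", "z_um")]
}

# Sliding median of odd window `order`; ends use a symmetrically shrunk
# window (no data invented beyond the sequence).
medfilt <- function(x, order = 5L) {
  if (order %% 2 != 1 || order < 3) stopf("median filter order must be odd >= 3")
  n <- length(x)
  hw <- (order - 1L) %/% 2L
  out <- x
  for (i in seq_len(n)) {
    k <- min(hw, i - 1L, n - i)
    out[i] <- stats::median(x[(i - k):(i + k)])
  }
  out
}

#' Median-filter pathline depths
#'
#' Applies a sliding median of odd window `order` (default 5) to the Z
#' sequence of each pathline — the standard cleanup for single-frame
#' classification spikes and short "error plateaus". X, Y and t are never
#' touched.
#'
#' @param pathlines Pathline data frame ([assemble_pathlines()]).
#' @param order Odd window length >= 3.
#' @return The pathlines with filtered `z_um`.
#' @export
median_filter_z <- function(pathlines, order = 5L) {
  for (pid in unique(pathlines$pathline_id)) {
    sel <- pathlines$pathline_id == pid
    pathlines$z_um[sel] <- medfilt(pathlines$z_um[sel], order)
  }
  pathlines
}

#' Instantaneous velocity vectors from between-frame displacements
#'
#' For each consecutive spot pair of each pathline: components are
#' `delta(position)/delta(t)` and the vector sits at the pair midpoint. A
#' gap-free pathline of L spots yields L - 1 vectors.
#'
#' @param pathlines Pathline data frame.
#' @return Data frame with columns `x_um`, `y_um`, `z_um` (midpoint),
#'   `u`, `v`, `w` (um/s), `dt_s`, `pathline_id`, `track_id`.
#' @export
instantaneous_velocities <- function(pathlines) {
  out <- lapply(split(pathlines, pathlines$pathline_id), function(p) {
    L <- nrow(p)
    if (L < 2) return(NULL)
    i <- seq_len(L - 1)
    dt <- p$t_s[i + 1] - p$t_s[i]
    data.frame(x_um = (p$x_um[i] + p$x_um[i + 1]) / 2,
               y_um = (p$y_um[i] + p$y_um[i + 1]) / 2,
               z_um = (p$z_um[i] + p$z_um[i + 1]) / 2,
               u = (p$x_um[i + 1] - p$x_um[i]) / dt,
               v = (p$y_um[i + 1] - p$y_um[i]) / dt,
               w = (p$z_um[i + 1] - p$z_um[i]) / dt,
               dt_s = dt, pathline_id = p$pathline_id[1], track_id = p$track_id[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter unphysical velocity vectors
#'
#' Gross Z-classification errors produce sharp jumps in depth and thus
#' unphysically large out-of-plane velocities. The default gate removes
#' vectors whose out-of-plane component exceeds `w_max` in magnitude;
#' `mode = "magnitude"` gates on the full speed instead.
#'
#' @param vectors Velocity data frame ([instantaneous_velocities()]).
#' @param w_max Limit, micrometers per second.
#' @param mode `"w"` (default, |w| gate) or `"magnitude"` (|(u,v,w)| gate).
#' @return List with `kept` (data frame) and `removed_count`.
#' @export
filter_wmax <- function(vectors, w_max, mode = c("w", "magnitude")) {
  if (w_max <= 0) stopf("w_max must be positive")
  mode <- match.arg(mode)
  crit <- if (mode == "w") abs(vectors$w) else
    sqrt(vectors$u^2 + vectors$v^2 + vectors$w^2)
  keep <- crit <= w_max
  list(kept = vectors[keep, , drop = FALSE], removed_count = sum(!keep))
}

#' Pathline precision (median per-pathline residual RMSE)
#'
#' In a steady duct flow, pathlines are straight up to a slight tilt of the
#' system, so the residual scatter of Z about a 1-D linear model measures
#' the precision of the depth prediction. Per pathline, Z is regressed on
#' the in-plane arc length s (one predictor, z = c0 + c1 s; optionally a
#' two-predictor plane z ~ x + y) and the residual RMSE computed; the
#' report gives the median and non-parametric IQR across pathlines. An
#' analogous in-plane fit (y ~ x) gives the lateral precision.
#'
#' @param pathlines Pathline data frame; pathlines shorter than 3 spots or
#'   stationary in-plane are excluded with a flag.
#' @param predictor `"arclength"` (default) or `"xy"` (plane fit).
#' @return List of class `precision_report`: `E_prec`, `iqr`,
#'   `E_prec_inplane`, `per_pathline` (data frame with `rmse_z`, `slope`,
#'   `rmse_y`, `excluded`).
#' @export
precision_eprec <- function(pathlines, predictor = c("arclength", "xy")) {
  predictor <- match.arg(predictor)
  rows <- lapply(split(pathlines, pathlines$pathline_id), function(p) {
    L <- nrow(p)
    out <- data.frame(pathline_id = p$pathline_id[1], L = L, rmse_z = NA_real_,
                      slope = NA_real_, rmse_y = NA_real_, excluded = TRUE)
    if (L < 3) return(out)
    s <- c(0, cumsum(sqrt(diff(p$x_um)^2 + diff(p$y_um)^2)))
    if (max(s) < 1e-9) return(out)               # stationary: slope undefined
    X <- if (predictor == "arclength") cbind(1, s) else cbind(1, p$x_um, p$y_um)
    fit <- stats::lm.fit(X, p$z_um)
    fy <- stats::lm.fit(cbind(1, p$x_um), p$y_um)
    out$rmse_z <- sqrt(mean(fit$residuals^2))
    out$slope <- unname(fit$coefficients[2])
    out$rmse_y <- sqrt(mean(fy$residuals^2))
    out$excluded <- FALSE
    out
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  ok <- per[!per$excluded, , drop = FALSE]
  if (nrow(ok) == 0) stopf("no pathline long enough for a precision fit")
  structure(list(E_prec = stats::median(ok$rmse_z),
                 iqr = stats::IQR(ok$rmse_z),
                 E_prec_inplane = stats::median(ok$rmse_y),
                 median_slope = stats::median(ok$slope),
                 per_pathline = per),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("E_prec = %.3f um (IQR %.3f), in-plane %.3f um, median slope %.4g um/um, n = %d pathlines\n",
              x$E_prec, x$iqr, x$E_prec_inplane, x$median_slope,
              sum(!x$per_pathline$excluded)))
  invisible(x)
}

#' Write / read pathline CSV
#'
#' The on-disk schema is `track_id,frame,t_s,x_um,y_um,z_um` (plus
#' `pathline_id` when present). `read_pathlines()` accepts a `column_map`
#' naming which input columns hold each field, so externally produced
#' pathline tables (e.g. deposited datasets with other headers) can be
#' ingested without editing files.
#'
#' @param pathlines Pathline data frame.
#' @param path CSV path.
#' @param header_comment Optional provenance line written as a leading
#'   `# ...` comment.
#' @export
write_pathlines <- function(pathlines, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(pathlines, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathlines
#' @param column_map Named character vector mapping the canonical names
#'   (`track_id`, `frame`, `t_s`, `x_um`, `y_um`, `z_um`) to columns of the
#'   file; canonical names missing from the map must exist verbatim.
#' @param fps Frame rate used to reconstruct `t_s` when the file has
#'   frames but no time column.
#' @export
read_pathlines <- function(path, column_map = NULL, fps = NULL) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!is.null(column_map))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(d)) stopf("column '%s' not found in %s", src, path)
      d[[canon]] <- d[[src]]
    }
  need <- c("track_id", "frame", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("pathline file lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"t_s" %in% names(d)) {
    if (is.null(fps)) stopf("file has no t_s column: supply fps")
    d$t_s <- d$frame / fps
  }
  if (!"pathline_id" %in% names(d)) d$pathline_id <- d$track_id
  d[, c("pathline_id", "track_id", "frame", "t_s", "x_um", "y_um", "z_um")]
}
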