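#' Arc geometry of a curved channel
#'
#' @param center Length-2 numeric, arc center (cx, cy), micrometers.
#' @param r_inner,r_outer Inner and outer wall radii, micrometers.
#' @param depth Channel depth, micrometers.
#' @return Object of class `arc_geometry` with derived `width` and mid
#'   radius `r_mid = (r_inner + r_outer) / 2`.
#' @export
arc_geometry <- function(center = c(0, 0), r_inner = 190, r_outer = 310,
                         depth = 38) {
  if (r_inner <= 0 || r_outer <= r_inner) stopf("need 0 < r_inner < r_outer")
  structure(list(center = center, r_inner = r_inner, r_outer = r_outer,
                 width = r_outer - r_inner, depth = depth,
                 r_mid = (r_inner + r_outer) / 2),
            class = "arc_geometry")
}

check_motion <- function(pathlines, motion, value_cols) {
  need <- c("frame", value_cols)
  if (!all(need %in% names(motion)))
    stopf("motion table needs columns %s", paste(need, collapse = ", "))
  missing_frames <- setdiff(unique(pathlines$frame), motion$frame)
  if (length(missing_frames))
    stopf("no droplet reference for frame(s): %s",
          paste(sort(missing_frames), collapse = ", "))
}

#' Transform pathlines into a straight-moving droplet's frame
#'
#' Subtracts the droplet's per-frame in-plane reference position (its
#' centroid) from every spot, so a particle co-moving with the droplet
#' becomes a stationary point and the internal recirculation appears as
#' closed loops. Depth is unchanged. The per-frame shift is rigid:
#' inter-particle distances within a frame are preserved.
#'
#' @param pathlines Pathline data frame (um coordinates).
#' @param motion Data frame `frame`, `cx_um`, `cy_um` (droplet reference
#'   position per frame).
#' @param invert If `TRUE`, apply the inverse transform (droplet frame back
#'   to lab frame).
#' @return Pathlines with transformed `x_um`, `y_um`.
#' @export
straight_frame_transform <- function(pathlines, motion, invert = FALSE) {
  check_motion(pathlines, motion, c("cx_um", "cy_um"))
  i <- match(pathlines$frame, motion$frame)
  s <- if (invert) 1 else -1
  pathlines$x_um <- pathlines$x_um + s * motion$cx_um[i]
  pathlines$y_um <- pathlines$y_um + s * motion$cy_um[i]
  pathlines
}

#' Transform pathlines into the frame of a droplet moving along an arc
#'
#' In a curved channel the droplet's bulk motion is a rotation about the
#' arc center, so subtracting it requires compensating each bead's *arc*
#' displacement at its own radius: positions are converted to polar
#' coordinates (r, phi) about the center, the droplet's angular position
#' theta(frame) is subtracted, and the result unrolled to a local Cartesian
#' frame with streamwise coordinate `s = r * (phi - theta)` and radial
#' coordinate `r - r_mid`. A bead rotating rigidly with the droplet maps to
#' a stationary point; a bead at radius r advancing an extra angle
#' `dphi` maps to a streamwise displacement `r * dphi`.
#'
#' @param pathlines Pathline data frame (lab-frame um coordinates).
#' @param motion Data frame `frame`, `theta_rad` (droplet angular position).
#' @param geom An [arc_geometry()].
#' @param clip_tol_um Beads outside the annulus by more than this margin
#'   are flagged (`clipped` column) with a warning.
#' @return Pathlines with `x_um` = streamwise s, `y_um` = r - r_mid,
#'   `z_um` unchanged, plus columns `r_um`, `phi_rad`, `clipped`.
#' @export
curved_frame_transform <- function(pathlines, motion, geom, clip_tol_um = 1.5) {
  check_motion(pathlines, motion, "theta_rad")
  i <- match(pathlines$frame, motion$frame)
  dx <- pathlines$x_um - geom$center[1]
  dy <- pathlines$y_um - geom$center[2]
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  out_of_annulus <- r < geom$r_inner - clip_tol_um | r > geom$r_outer + clip_tol_um
  if (any(out_of_annulus))
    warning(sprintf("%d spot(s) outside the channel annulus by > %g um (flagged)",
                    sum(out_of_annulus), clip_tol_um))
  phi_rel <- phi - motion$theta_rad[i]
  phi_rel <- atan2(sin(phi_rel), cos(phi_rel))   # wrap to (-pi, pi]
  pathlines$x_um <- r * phi_rel
  pathlines$y_um <- r - geom$r_mid
  pathlines$r_um <- r
  pathlines$phi_rad <- phi
  pathlines$clipped <- out_of_annulus
  pathlines
}

#' Invert a curved-frame transform
#'
#' Maps droplet-frame coordinates (`x_um` = streamwise s, `y_um` = radial)
#' back to lab-frame positions; the round trip reproduces the input to
#' machine precision.
#'
#' @inheritParams curved_frame_transform
#' @export
curved_frame_inverse <- function(pathlines, motion, geom) {
  check_motion(pathlines, motion, "theta_rad")
  i <- match(pathlines$frame, motion$frame)
  r <- pathlines$y_um + geom$r_mid
  phi <- pathlines$x_um / r + motion$theta_rad[i]
  pathlines$x_um <- geom$center[1] + r * cos(phi)
  pathlines$y_um <- geom$center[2] + r * sin(phi)
  pathlines$r_um <- NULL
  pathlines$phi_rad <- NULL
  pathlines$clipped <- NULL
  pathlines
}

#' Derive droplet angular motion from the beads themselves
#'
#' When no independent droplet reference is available, theta(frame) can be
#' estimated from the beads: the angular displacement between consecutive
#' frames is summarized (median by default, robust to recirculation) over
#' all beads present in both frames and accumulated.
#'
#' @param pathlines Lab-frame pathline data frame.
#' @param geom An [arc_geometry()].
#' @param method `"median"` (robust, default) or `"mean"`.
#' @return Data frame `frame`, `theta_rad` with theta(first frame) = 0.
#' @export
derive_arc_motion <- function(pathlines, geom, method = c("median", "mean")) {
  method <- match.arg(method)
  agg <- if (method == "median") stats::median else mean
  phi <- atan2(pathlines$y_um - geom$center[2], pathlines$x_um - geom$center[1])
  frames <- sort(unique(pathlines$frame))
  dtheta <- numeric(length(frames) - 1L)
  for (k in seq_along(dtheta)) {
    a <- pathlines$frame == frames[k]
    b <- pathlines$frame == frames[k + 1L]
    common <- intersect(pathlines$pathline_id[a], pathlines$pathline_id[b])
    if (length(common) == 0) stopf("no bead spans frames %d-%d", frames[k], frames[k + 1L])
    pa <- phi[a][match(common, pathlines$pathline_id[a])]
    pb <- phi[b][match(common, pathlines$pathline_id[b])]
    d <- atan2(sin(pb - pa), cos(pb - pa))
    dtheta[k] <- agg(d)
  }
  data.frame(frame = frames, theta_rad = c(0, cumsum(dtheta)))
}
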