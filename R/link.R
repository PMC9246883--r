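#' Link detected spots into 2D tracks
#'
#' Greedy mutual-nearest-neighbor frame-to-frame linking under a
#' displacement gate: between consecutive frames, candidate pairs are
#' accepted in order of increasing distance (ties broken by lowest spot
#' index), each spot used at most once, and only when the displacement is
#' at most `max_displacement_px`. Unmatched spots terminate or start
#' tracks; there is no gap closing. The result is deterministic and
#' invariant to the ordering of spots within a frame.
#'
#' @param spots Data frame with columns `frame` (0-based), `x_px`, `y_px`,
#'   and optionally `quality`, `source`.
#' @param max_displacement_px Largest allowed frame-to-frame displacement.
#' @return Data frame of the same spots with a `track_id` column (1-based,
#'   numbered by track start frame then start position), ordered by
#'   `track_id` then `frame`.
#' @export
link_spots <- function(spots, max_displacement_px) {
  if (max_displacement_px <= 0) stopf("max_displacement_px must be positive")
  if (nrow(spots) == 0)
    return(cbind(spots, track_id = integer(0)))
  # canonical order: frame, then x, then y -> permutation invariance
  ord <- order(spots$frame, spots$x_px, spots$y_px)
  spots <- spots[ord, , drop = FALSE]
  rownames(spots) <- NULL
  n <- nrow(spots)
  track_of <- integer(n)
  next_track <- 1L
  frames <- sort(unique(spots$frame))
  idx_by_frame <- split(seq_len(n), spots$frame)
  prev_idx <- idx_by_frame[[as.character(frames[1])]]
  track_of[prev_idx] <- seq_len(length(prev_idx))
  next_track <- length(prev_idx) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur_idx <- idx_by_frame[[as.character(frames[fi])]]
    linked <- rep(FALSE, length(cur_idx))
    if (frames[fi] == frames[fi - 1] + 1 && length(prev_idx) > 0) {
      D <- outer(spots$x_px[prev_idx], spots$x_px[cur_idx], `-`)^2 +
        outer(spots$y_px[prev_idx], spots$y_px[cur_idx], `-`)^2
      D[D > max_displacement_px^2] <- Inf
      used_p <- rep(FALSE, length(prev_idx))
      repeat {
        dmin <- min(D)
        if (!is.finite(dmin)) break
        hit <- which(D == dmin, arr.ind = TRUE)
        # deterministic tie-break: lowest previous index, then lowest current
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
        track_of[cur_idx[hit[2]]] <- track_of[prev_idx[hit[1]]]
        linked[hit[2]] <- TRUE
        used_p[hit[1]] <- TRUE
        D[hit[1], ] <- Inf
        D[, hit[2]] <- Inf
      }
    }
    for (k in which(!linked)) {
      track_of[cur_idx[k]] <- next_track
      next_track <- next_track + 1L
    }
    prev_idx <- cur_idx
  }
  spots$track_id <- track_of
  # renumber tracks by (start frame, start x, start y)
  starts <- spots[!duplicated(spots$track_id), , drop = FALSE]
  starts <- starts[order(starts$frame, starts$x_px, starts$y_px), , drop = FALSE]
  remap <- seq_len(nrow(starts))
  names(remap) <- as.character(starts$track_id)
  spots$track_id <- unname(remap[as.character(spots$track_id)])
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

#' Merge manual spot corrections into tracks
#'
#' Inserts manually placed spots (recovered false negatives) into existing
#' tracks, the file-based equivalent of interactive track correction. The
#' raw video is never modified; a manual spot only extends a pathline.
#'
#' @param tracks Track data frame (as from [link_spots()]).
#' @param corrections Data frame with columns `track_id`, `frame`, `x_px`,
#'   `y_px`.
#' @return Tracks with manual spots inserted in frame order, their
#'   `source` set to `"manual"` and `quality` 0.
#' @export
merge_corrections <- function(tracks, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0) return(tracks)
  req <- c("track_id", "frame", "x_px", "y_px")
  if (!all(req %in% names(corrections)))
    stopf("corrections need columns %s", paste(req, collapse = ", "))
  for (i in seq_len(nrow(corrections))) {
    ci <- corrections[i, ]
    if (!ci$track_id %in% tracks$track_id)
      stopf("correction %d targets unknown track %s", i, ci$track_id)
    clash <- tracks$track_id == ci$track_id & tracks$frame == ci$frame
    if (any(clash))
      stopf("correction %d: track %s already has a spot at frame %d",
            i, ci$track_id, ci$frame)
  }
  add <- data.frame(frame = as.integer(corrections$frame),
                    x_px = corrections$x_px, y_px = corrections$y_px,
                    quality = 0, source = "manual",
                    track_id = corrections$track_id)
  out <- rbind(tracks[, names(add)], add)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track summary
#'
#' @param tracks Track data frame.
#' @return Data frame with one row per track: `track_id`, `n_spots`,
#'   `first_frame`, `last_frame`, `n_gaps` (missing interior frames).
#' @export
track_summary <- function(tracks) {
  by_track <- split(tracks$frame, tracks$track_id)
  data.frame(
    track_id = as.integer(names(by_track)),
    n_spots = vapply(by_track, length, integer(1)),
    first_frame = vapply(by_track, min, numeric(1)),
    last_frame = vapply(by_track, max, numeric(1)),
    n_gaps = vapply(by_track, function(f) diff(range(f)) + 1 - length(f), numeric(1)),
    row.names = NULL)
}
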