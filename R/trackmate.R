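#' Import tracks from a TrackMate XML file
#'
#' Reads the `Model` section of a TrackMate session file: spots from
#' `AllSpots/SpotsInFrame/Spot` (attributes `ID`, `POSITION_X`,
#' `POSITION_Y`, `FRAME`) and links from `AllTracks/Track/Edge`
#' (`SPOT_SOURCE_ID`, `SPOT_TARGET_ID`). When a `FilteredTracks` element is
#' present only the listed tracks are kept, mirroring the file's own track
#' filter. Spots that belong to no track are excluded from the output but
#' counted in the `n_unlinked` attribute.
#'
#' @param path Path to a TrackMate XML file.
#' @return Track data frame (`track_id`, `frame`, `x_px`, `y_px`,
#'   `quality`, `source`) with attributes `n_unlinked` (spot count outside
#'   any track) and `spot_ids` (original TrackMate spot IDs).
#' @export
import_trackmate_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("malformed TrackMate XML: %s", conditionMessage(e)))
  spot_nodes <- xml2::xml_find_all(doc, ".//Model/AllSpots/SpotsInFrame/Spot")
  if (length(spot_nodes) == 0) stopf("no Spot elements under Model/AllSpots")
  need_attr <- function(nodes, attr) {
    v <- xml2::xml_attr(nodes, attr)
    if (anyNA(v)) stopf("Spot element missing required attribute %s", attr)
    v
  }
  spots <- data.frame(
    id = as.numeric(need_attr(spot_nodes, "ID")),
    x_px = as.numeric(need_attr(spot_nodes, "POSITION_X")),
    y_px = as.numeric(need_attr(spot_nodes, "POSITION_Y")),
    frame = as.integer(need_attr(spot_nodes, "FRAME")),
    quality = suppressWarnings(as.numeric(xml2::xml_attr(spot_nodes, "QUALITY"))))
  spots$quality[is.na(spots$quality)] <- 0
  track_nodes <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
  filtered <- xml2::xml_find_all(doc, ".//Model/FilteredTracks/TrackID")
  keep_ids <- if (length(filtered) > 0)
    as.numeric(xml2::xml_attr(filtered, "TRACK_ID")) else NULL
  rows <- list()
  for (tn in track_nodes) {
    tid <- as.numeric(xml2::xml_attr(tn, "TRACK_ID"))
    if (is.na(tid)) stopf("Track element missing TRACK_ID")
    if (!is.null(keep_ids) && !tid %in% keep_ids) next
    edges <- xml2::xml_find_all(tn, "./Edge")
    src <- as.numeric(xml2::xml_attr(edges, "SPOT_SOURCE_ID"))
    tgt <- as.numeric(xml2::xml_attr(edges, "SPOT_TARGET_ID"))
    if (anyNA(src) || anyNA(tgt))
      stopf("Edge in track %s missing SPOT_SOURCE_ID/SPOT_TARGET_ID", tid)
    ids <- unique(c(src, tgt))
    sel <- spots[match(ids, spots$id), , drop = FALSE]
    if (anyNA(sel$id)) stopf("track %s references unknown spot IDs", tid)
    sel$track_id <- tid
    rows[[length(rows) + 1L]] <- sel
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = numeric(0), x_px = numeric(0), y_px = numeric(0),
               frame = integer(0), quality = numeric(0), track_id = numeric(0))
  n_unlinked <- nrow(spots) - length(unique(out$id))
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  res <- data.frame(track_id = out$track_id, frame = out$frame,
                    x_px = out$x_px, y_px = out$y_px,
                    quality = out$quality, source = "detected")
  rownames(res) <- NULL
  attr(res, "n_unlinked") <- n_unlinked
  attr(res, "spot_ids") <- out$id
  res
}

#' Export tracks to a minimal TrackMate XML file
#'
#' Writes `Model/AllSpots`, `Model/AllTracks` (consecutive-frame edges) and
#' `Model/FilteredTracks` so the file round-trips through
#' [import_trackmate_xml()] and loads in TrackMate-compatible tools.
#'
#' @param tracks Track data frame.
#' @param path Output path.
#' @export
export_trackmate_xml <- function(tracks, path) {
  doc <- xml2::xml_new_root("TrackMate", version = "7.0.0")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "pixel", timeunits = "frame")
  allspots <- xml2::xml_add_child(model, "AllSpots",
                                  nspots = as.character(nrow(tracks)))
  tracks$spot_id <- seq_len(nrow(tracks)) - 1L
  for (f in sort(unique(tracks$frame))) {
    sif <- xml2::xml_add_child(allspots, "SpotsInFrame", frame = as.character(f))
    sel <- tracks[tracks$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(sel)))
      xml2::xml_add_child(sif, "Spot",
        ID = as.character(sel$spot_id[i]),
        name = paste0("ID", sel$spot_id[i]),
        POSITION_X = format(sel$x_px[i], digits = 17),
        POSITION_Y = format(sel$y_px[i], digits = 17),
        POSITION_Z = "0",
        FRAME = as.character(sel$frame[i]),
        QUALITY = format(sel$quality[i] %||% 0, digits = 17))
  }
  alltracks <- xml2::xml_add_child(model, "AllTracks")
  ftracks <- xml2::xml_add_child(model, "FilteredTracks")
  for (tid in unique(tracks$track_id)) {
    sel <- tracks[tracks$track_id == tid, , drop = FALSE]
    sel <- sel[order(sel$frame), , drop = FALSE]
    tn <- xml2::xml_add_child(alltracks, "Track", TRACK_ID = as.character(tid),
                              NUMBER_SPOTS = as.character(nrow(sel)))
    if (nrow(sel) > 1)
      for (i in seq_len(nrow(sel) - 1))
        xml2::xml_add_child(tn, "Edge",
          SPOT_SOURCE_ID = as.character(sel$spot_id[i]),
          SPOT_TARGET_ID = as.character(sel$spot_id[i + 1]))
    xml2::xml_add_child(ftracks, "TrackID", TRACK_ID = as.character(tid))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
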