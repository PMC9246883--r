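# End-to-end workflow: simulate/ingest -> library -> track -> classify ->
# pathlines -> velocity lattice -> continuity report.

# Rolling hash of the canonical JSON of a config, for output provenance.
# Output locations are excluded: the hash identifies the analysis, not
# where its artifacts land.
config_hash <- function(config) {
  config$out_dir <- NULL
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()],
#' with defaults mirroring the published operating point: 0.32 um/px,
#' 300 fps, 0.5 um reference step over a 54 um range, order-5 median
#' filter, LoG radius 3 px, and a 4 x 2 x 1 um lattice with 50% overlap.
#' Override any entry (possibly loaded from a JSON file via
#' [jsonlite::read_json()]) before passing it on.
#'
#' @param ... Named overrides merged over the defaults (one level deep).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    video_path = NULL,                    # multi-page TIFF to analyze, or
    simulate = list(                      # ... a synthetic scene to generate
      flow = "poiseuille", flow_rate = 5, duct_width = 90, duct_height = 35,
      frame_size_px = c(192L, 128L), n_frames = 60L, n_particles = 8L),
    optics = list(pixel_size = 0.32, fps = 300, z_step = 0.5, n_levels = 110,
                  noise_sd = 0, n_wf = 1.41, n_air = 1.0),
    library_path = NULL,                  # load a saved bundle, else synthetic
    trackmate_xml = NULL,                 # import tracks instead of detecting
    corrections_path = NULL,              # manual-spot CSV
    tracking = list(radius_px = 3, quality_threshold = NULL, max_disp_px = 12),
    filters = list(median_order = 5L, w_max = NULL, w_max_mode = "w"),
    lattice = list(element = c(4, 2, 1), overlap = 0.5, subvolume = NULL)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Run the full defocusing-velocimetry pipeline
#'
#' Executes every stage on either a synthetic scene (generated with the
#' configured seed, hence fully reproducible) or a user-supplied video and
#' library, and writes the standard artifacts to `config$out_dir`:
#' `pathlines.csv`, `vectors.csv`, `field.csv` and `report.json`. Every
#' CSV carries a `# dptv <version> config <hash>` provenance header.
#'
#' @param config Configuration list, see [default_config()].
#' @return Invisibly, a list with the in-memory results: `tracks`,
#'   `pathlines`, `vectors`, `field`, `continuity`, `report`.
#' @export
run_pipeline <- function(config = default_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  hash <- config_hash(config)
  version <- as.character(utils::packageVersion("dptv"))
  tag <- sprintf("dptv %s config %s", version, hash)
  opt <- config$optics
  model <- optical_model(pixel_size = opt$pixel_size, z_step = opt$z_step,
                         n_levels = opt$n_levels, noise_sd = opt$noise_sd %||% 0,
                         rng_seed = config$seed)
  fps <- opt$fps
  truth <- NULL
  if (!is.null(config$video_path)) {
    frames <- stage("ingest", read_tiff_stack(config$video_path))
  } else {
    sim <- config$simulate
    field <- if (identical(sim$flow, "poiseuille")) {
      geom <- duct_geometry(sim$duct_width, sim$duct_height,
                            sim$frame_size_px[1] * opt$pixel_size)
      frame_wy <- sim$frame_size_px[2] * opt$pixel_size
      function(p) cbind(poiseuille_velocity(p[, 2] - frame_wy / 2, p[, 3],
                                            geom, sim$flow_rate), 0, 0)
    } else {
      box <- c(sim$frame_size_px * opt$pixel_size, model$z_max - model$z_min)
      function(p) recirculation_velocity(
        cbind(p[, 1], p[, 2], p[, 3] - model$z_min), box,
        amplitude = sim$amplitude %||% 200)
    }
    frame_w_um <- sim$frame_size_px * opt$pixel_size
    spawn <- if (identical(sim$flow, "poiseuille")) {
      # keep seeds inside both the duct cross-section and the usable Z-range
      half_y <- min(frame_w_um[2], sim$duct_width) / 2 - 2
      half_z <- 0.95 * min(sim$duct_height / 2, model$z_max)
      rbind(c(0, frame_w_um[1]),
            frame_w_um[2] / 2 + c(-half_y, half_y),
            c(-half_z, half_z))
    } else NULL
    scene <- stage("simulate", simulate_video(
      field, model, frame_size_px = sim$frame_size_px, n_frames = sim$n_frames,
      fps = fps, init = sim$n_particles, spawn_box = spawn,
      wrap_x = if (identical(sim$flow, "poiseuille")) frame_w_um[1] else NULL,
      seed = config$seed))
    frames <- scene$frames
    truth <- scene$truth
  }
  lib <- stage("library", {
    if (!is.null(config$library_path)) load_library(config$library_path)
    else {
      stack <- render_reference_stack(model, particles_per_level = 1,
                                      seed = mix_seed(config$seed, 3L))
      build_library(split(stack$crops, stack$info$level), model$z_step,
                    focal_index = model$focal_index, pixel_size = model$pixel_size)
    }
  })
  trk <- config$tracking
  tracks <- stage("track", {
    if (!is.null(config$trackmate_xml)) import_trackmate_xml(config$trackmate_xml)
    else {
      spots <- detect_stack(frames, trk$radius_px, trk$quality_threshold)
      link_spots(spots, trk$max_disp_px)
    }
  })
  if (!is.null(config$corrections_path))
    tracks <- stage("corrections", merge_corrections(
      tracks, utils::read.csv(config$corrections_path, comment.char = "#")))
  stacks <- stage("crops", extract_crops(frames, tracks))
  score_m <- library_score_matrix(lib)
  zs <- stage("classify", {
    z <- rep(NA_real_, nrow(tracks))
    for (st in stacks) {
      pred <- classify_track(st, lib, score_m)
      pred$z_um[st$padded] <- NA       # truncated border patterns: unreliable
      rows <- match(paste(st$spots$track_id, st$spots$frame),
                    paste(tracks$track_id, tracks$frame))
      z[rows] <- pred$z_um
    }
    z
  })
  pl <- stage("pathlines", {
    p <- assemble_pathlines(tracks, zs, model$pixel_size, fps)
    median_filter_z(p, config$filters$median_order %||% 5L)
  })
  vec <- stage("velocities", instantaneous_velocities(pl))
  removed <- 0L
  if (!is.null(config$filters[["w_max"]])) {
    fl <- filter_wmax(vec, config$filters[["w_max"]],
                      config$filters$w_max_mode %||% "w")
    vec <- fl$kept
    removed <- fl$removed_count
  }
  lat <- config$lattice
  field <- stage("grid", lattice_average(vec, lattice_spec(lat$element, lat$overlap)))
  cont <- stage("continuity",
                tryCatch(continuity_eta(field, lat$subvolume), error = function(e) NULL))
  prec <- tryCatch(precision_eprec(pl), error = function(e) NULL)
  sigma_z <- if (!is.null(truth)) z_accuracy_vs_truth(pl, truth) else NULL
  report <- list(
    package_version = version, config_hash = hash, seed = config$seed,
    counts = list(frames = length(frames), spots = nrow(tracks),
                  tracks = length(unique(tracks$track_id)),
                  pathlines = length(unique(pl$pathline_id)),
                  vectors = nrow(vec), removed_by_wmax = removed,
                  wmax_filter_applied = !is.null(config$filters[["w_max"]])),
    precision = if (!is.null(prec))
      list(E_prec_um = prec$E_prec, iqr_um = prec$iqr,
           inplane_um = prec$E_prec_inplane) else NULL,
    accuracy = sigma_z,
    continuity = if (!is.null(cont))
      list(element_um = lat$element, eta_median = cont$eta_median,
           n_elements = cont$n_defined) else NULL,
    lattice = list(element_um = lat$element, overlap = lat$overlap,
                   median_count = stats::median(field$count[field$count > 0])))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pathlines(pl, file.path(config$out_dir, "pathlines.csv"), tag)
    con <- file(file.path(config$out_dir, "vectors.csv"), "w")
    writeLines(paste0("# ", tag), con)
    utils::write.csv(vec, con, row.names = FALSE)
    close(con)
    write_lattice_csv(field, file.path(config$out_dir, "field.csv"), cont, tag)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(tracks = tracks, pathlines = pl, vectors = vec, field = field,
                 continuity = cont, report = report, library = lib, truth = truth))
}

# RMSE of classified depths against simulator ground truth, matching each
# pathline spot to the nearest true particle position in its frame.
z_accuracy_vs_truth <- function(pathlines, truth, match_tol_um = 2) {
  err <- numeric(0)
  for (f in unique(pathlines$frame)) {
    p <- pathlines[pathlines$frame == f, , drop = FALSE]
    tr <- truth[truth$frame == f & truth$visible, , drop = FALSE]
    if (nrow(tr) == 0) next
    for (i in seq_len(nrow(p))) {
      d2 <- (tr$x_um - p$x_um[i])^2 + (tr$y_um - p$y_um[i])^2
      j <- which.min(d2)
      if (d2[j] <= match_tol_um^2) err <- c(err, p$z_um[i] - tr$z_um[j])
    }
  }
  if (length(err) == 0) return(NULL)
  list(sigma_z_um = sqrt(mean(err^2)), n_matched = length(err))
}
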