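test_that("pathline assembly converts units and splits on gaps", {
  tracks <- data.frame(track_id = 1L, frame = c(0L, 1L, 2L, 300L),
                       x_px = c(100, 110, 120, 130), y_px = 50)
  pl <- assemble_pathlines(tracks, c(0, 1, 2, 3), pixel_size = 0.32, fps = 300)
  expect_equal(pl$x_um[1], 32.0)                # 100 px * 0.32 um/px
  expect_equal(pl$t_s[pl$frame == 300], 1.0)    # frame 300 at 300 fps
  expect_equal(length(unique(pl$pathline_id)), 2)  # frame gap splits

  # a missing depth splits too, and the NA row is dropped
  pl2 <- assemble_pathlines(data.frame(track_id = 1L, frame = 0:4,
                                       x_px = 0:4, y_px = 0),
                            c(1, 1, NA, 1, 1), 0.32, 300)
  expect_equal(nrow(pl2), 4)
  expect_equal(length(unique(pl2$pathline_id)), 2)
  expect_error(assemble_pathlines(tracks, 1:3, 0.32, 300), "entries")
})

test_that("order-5 median filter removes spikes and short plateaus", {
  pl <- data.frame(pathline_id = 1, track_id = 1, frame = 0:4, t_s = 0:4,
                   x_um = 0:4, y_um = 0, z_um = c(1, 1, 9, 1, 1))
  expect_equal(median_filter_z(pl)$z_um, rep(1, 5))
  pl$z_um <- rep(3, 5)
  expect_equal(median_filter_z(pl)$z_um, rep(3, 5))       # constant unchanged
  # 2-frame error plateau inside a constant track: removed by window 5
  z <- c(2, 2, 7, 7, 2, 2, 2)
  expect_equal(dptv:::medfilt(z, 5), rep(2, 7))
  # idempotence on spike-free output
  set.seed(2)
  z2 <- dptv:::medfilt(cumsum(rnorm(30)), 5)
  expect_equal(dptv:::medfilt(z2, 5), dptv:::medfilt(dptv:::medfilt(z2, 5), 5))
  expect_error(dptv:::medfilt(z, 4), "odd")
})

test_that("instantaneous velocities are midpoint displacement rates", {
  pl <- data.frame(pathline_id = 1, track_id = 1, frame = 0:120, t_s = (0:120) / 300,
                   x_um = (0:120) / 3, y_um = 5, z_um = 2)
  v <- instantaneous_velocities(pl)
  expect_equal(nrow(v), 120)                    # L - 1 vectors
  expect_equal(v$u, rep(100, 120))              # (1/3 um per frame) * 300 fps
  expect_equal(v$v, rep(0, 120))
  expect_equal(v$w, rep(0, 120))
  expect_equal(v$x_um[1], mean(pl$x_um[1:2]))

  # RK4-advected tracer through the recirculation field: velocities match
  # the analytic field at the midpoints to within 2%
  box <- c(100, 50, 40)
  f <- function(p) recirculation_velocity(p, box, amplitude = 200)
  path <- advect_rk4(f, matrix(c(30, 20, 10), 1), dt = 1 / 3000, n_steps = 300,
                     keep_path = TRUE)
  samp <- path[seq(1, 301, 10), 1, ]            # every 10th step = one frame
  pl2 <- data.frame(pathline_id = 1, track_id = 1, frame = 0:30,
                    t_s = (0:30) / 300, x_um = samp[, 1], y_um = samp[, 2],
                    z_um = samp[, 3])
  v2 <- instantaneous_velocities(pl2)
  truth <- f(cbind(v2$x_um, v2$y_um, v2$z_um))
  speed_err <- sqrt(rowSums((cbind(v2$u, v2$v, v2$w) - truth)^2)) /
    sqrt(rowSums(truth^2))
  expect_lt(stats::median(speed_err), 0.02)
})

test_that("the w_max gate removes exactly the unphysical vectors", {
  v <- data.frame(x_um = 1:10, y_um = 0, z_um = 0, u = 100, v = 0,
                  w = c(rep(10, 8), 5000, -2000), dt_s = 1 / 300,
                  pathline_id = 1, track_id = 1)
  ok <- filter_wmax(v[1:8, ], 1300)
  expect_equal(ok$removed_count, 0)
  fl <- filter_wmax(v, 1300)
  expect_equal(fl$removed_count, 2)
  expect_true(all(abs(fl$kept$w) <= 1300))
  # unit-change commutation: scaling velocities and the gate together
  v2 <- v; v2$u <- v$u * 1e-3; v2$v <- v$v * 1e-3; v2$w <- v$w * 1e-3
  expect_equal(filter_wmax(v2, 1.3)$removed_count, fl$removed_count)
  # full-magnitude mode gates on speed
  vm <- data.frame(x_um = 1, y_um = 0, z_um = 0, u = 1200, v = 600, w = 0,
                   dt_s = 1, pathline_id = 1, track_id = 1)
  expect_equal(filter_wmax(vm, 1300, mode = "w")$removed_count, 0)
  expect_equal(filter_wmax(vm, 1300, mode = "magnitude")$removed_count, 1)
  expect_error(filter_wmax(v, -5), "positive")
})

test_that("pathline precision matches the closed-form residual expectation", {
  perfect <- fix_linear_pathlines(n = 10, L = 20, z_sd = 0)
  rep0 <- precision_eprec(perfect)
  expect_equal(rep0$E_prec, 0, tolerance = 1e-12)

  # Gaussian depth noise of SD 0.15 um on straight tracks: the residual RMSE
  # of an L-point, 2-parameter fit has expectation 0.15 * sqrt((L - 2) / L)
  L <- 30
  noisy <- fix_linear_pathlines(n = 60, L = L, z_sd = 0.15, seed = 5)
  rep1 <- precision_eprec(noisy)
  expect_lt(abs(rep1$E_prec - 0.15 * sqrt((L - 2) / L)) /
              (0.15 * sqrt((L - 2) / L)), 0.15)
  expect_gt(rep1$iqr, 0)

  # stationary pathline is excluded with a flag
  stat <- data.frame(pathline_id = 99, track_id = 99, frame = 0:9,
                     t_s = (0:9) / 300, x_um = 1, y_um = 1, z_um = rnorm(10))
  rep2 <- precision_eprec(rbind(perfect, stat))
  expect_true(rep2$per_pathline$excluded[rep2$per_pathline$pathline_id == 99])
  expect_error(precision_eprec(stat), "no pathline")
})

test_that("pathline CSV round-trips and accepts external column maps", {
  pl <- fix_linear_pathlines(n = 3, L = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pathlines(pl, path, header_comment = "test provenance")
  expect_match(readLines(path, n = 1), "^# test provenance")
  bk <- read_pathlines(path)
  expect_equal(bk$x_um, pl$x_um)
  expect_equal(bk$z_um, pl$z_um)

  # foreign schema via a column map
  foreign <- data.frame(TrackID = 1, T = 0:4, PosX = 1:5, PosY = 0, Depth = 2)
  fpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(foreign, fpath, row.names = FALSE)
  got <- read_pathlines(fpath, column_map = c(track_id = "TrackID", frame = "T",
                                              x_um = "PosX", y_um = "PosY",
                                              z_um = "Depth"), fps = 300)
  expect_equal(got$z_um, rep(2, 5))
  expect_equal(got$t_s, (0:4) / 300)
  expect_error(read_pathlines(fpath, column_map = c(x_um = "Nope")), "not found")
})
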