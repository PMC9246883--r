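#' Lattice specification for velocity averaging
#'
#' Overlapping rectangular volume elements: with overlap fraction f, element
#' origins are spaced `element * (1 - f)` per axis (50% overlap spaces
#' centers at half the element size). The lattice origin is anchored at the
#' lower data bound.
#'
#' @param element Length-3 numeric, element size (dx, dy, dz), micrometers.
#' @param overlap Overlap fraction in \[0, 1).
#' @param bounds Optional 3 x 2 matrix of (min, max) per axis; defaults to
#'   the extent of the data being averaged.
#' @return Object of class `lattice_spec`.
#' @export
lattice_spec <- function(element = c(4, 2, 1), overlap = 0.5, bounds = NULL) {
  if (any(element <= 0)) stopf("element sizes must be positive")
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  structure(list(element = element, overlap = overlap, bounds = bounds),
            class = "lattice_spec")
}

#' Lattice-average instantaneous velocity vectors
#'
#' Each vector contributes to every element whose box contains its midpoint
#' (up to 8 elements at 50% overlap for an interior point); the element
#' value is the arithmetic mean of the contributing components.
#'
#' @param vectors Velocity data frame with columns `x_um`, `y_um`, `z_um`,
#'   `u`, `v`, `w`.
#' @param spec A [lattice_spec()].
#' @return Object of class `lattice_field`: arrays `u`, `v`, `w` (`NA`
#'   where empty), integer array `count`, `centers` (list of per-axis
#'   center coordinates), `spacing`, `element`.
#' @export
lattice_average <- function(vectors, spec) {
  P <- cbind(vectors$x_um, vectors$y_um, vectors$z_um)
  comp <- cbind(vectors$u, vectors$v, vectors$w)
  bounds <- spec$bounds
  if (is.null(bounds))
    bounds <- t(apply(P, 2, range))
  el <- spec$element
  sp <- el * (1 - spec$overlap)
  n_el <- pmax(1L, floor((bounds[, 2] - bounds[, 1] - el) / sp) + 1L)
  dims <- as.integer(n_el)
  # per axis, the elements containing coordinate p span indices
  # ceil((p - origin - el)/sp) .. floor((p - origin)/sp), clipped to the grid
  lo <- hi <- matrix(0L, nrow(P), 3)
  for (a in 1:3) {
    rel <- P[, a] - bounds[a, 1]
    lo[, a] <- pmax(0L, as.integer(ceiling((rel - el[a]) / sp[a] - 1e-9)))
    hi[, a] <- pmin(dims[a] - 1L, as.integer(floor(rel / sp[a] + 1e-9)))
  }
  span <- as.integer(floor(el / sp)) + 1L
  lin_parts <- list()
  row_parts <- list()
  for (i in 0:(span[1] - 1L)) for (j in 0:(span[2] - 1L)) for (l in 0:(span[3] - 1L)) {
    ok <- lo[, 1] + i <= hi[, 1] & lo[, 2] + j <= hi[, 2] & lo[, 3] + l <= hi[, 3]
    if (!any(ok)) next
    lin_parts[[length(lin_parts) + 1L]] <-
      (lo[ok, 1] + i) + dims[1] * ((lo[ok, 2] + j) + dims[2] * (lo[ok, 3] + l))
    row_parts[[length(row_parts) + 1L]] <- which(ok)
  }
  all_lin <- unlist(lin_parts)
  all_row <- unlist(row_parts)
  n_cells <- prod(dims)
  count <- array(tabulate(all_lin + 1L, n_cells), dims)
  sums <- rowsum(comp[all_row, , drop = FALSE], all_lin)
  groups <- as.integer(rownames(sums)) + 1L
  mean_arr <- function(a) {
    m <- rep(NA_real_, n_cells)
    m[groups] <- sums[, a] / count[groups]
    array(m, dims)
  }
  centers <- lapply(1:3, function(a)
    bounds[a, 1] + (0:(dims[a] - 1L)) * sp[a] + el[a] / 2)
  structure(list(u = mean_arr(1), v = mean_arr(2), w = mean_arr(3),
                 count = count, centers = centers, spacing = sp,
                 element = el, bounds = bounds),
            class = "lattice_field")
}

#' @export
print.lattice_field <- function(x, ...) {
  ne <- sum(x$count > 0)
  cat(sprintf("Lattice field %d x %d x %d (%s um elements), %d non-empty elements, median count %g\n",
              dim(x$count)[1], dim(x$count)[2], dim(x$count)[3],
              paste(x$element, collapse = " x "), ne,
              stats::median(x$count[x$count > 0])))
  invisible(x)
}

#' Continuity-error field of a lattice-averaged velocity field
#'
#' For each interior element whose six axis neighbors are all non-empty,
#' central finite differences of the element-mean components give the
#' discrete divergence terms du/dx, dv/dy, dw/dz. Incompressibility demands
#' the streamwise term X = du/dx balance the transverse sum
#' Y = -(dv/dy + dw/dz), so the per-element continuity error is their
#' normalized mismatch `eta = |X - Y| / (|X| + |Y|)`: 0 for perfect mass
#' conservation, and median 1 for uncorrelated velocity components (X and Y
#' then agree in sign only half the time). The summary statistic is the
#' median over defined elements. Elements with an empty neighbor, a zero
#' denominator, or on the lattice boundary are excluded rather than
#' imputed.
#'
#' @param field A `lattice_field`.
#' @param subvolume Optional named list of axis ranges (`x`, `y`, `z`, each
#'   `c(lo, hi)` in micrometers) restricting which element centers are
#'   evaluated.
#' @return Object of class `continuity_field`: `eta` (array, `NA` where
#'   undefined), `eta_median`, `n_defined`, `subvolume`.
#' @export
continuity_eta <- function(field, subvolume = NULL) {
  dims <- dim(field$count)
  eta <- array(NA_real_, dims)
  ok <- field$count > 0
  if (all(dims >= 3)) {
    ii <- 2:(dims[1] - 1); jj <- 2:(dims[2] - 1); ll <- 2:(dims[3] - 1)
    defined <- ok[ii, jj, ll] &
      ok[ii - 1, jj, ll] & ok[ii + 1, jj, ll] &
      ok[ii, jj - 1, ll] & ok[ii, jj + 1, ll] &
      ok[ii, jj, ll - 1] & ok[ii, jj, ll + 1]
    dudx <- (field$u[ii + 1, jj, ll] - field$u[ii - 1, jj, ll]) / (2 * field$spacing[1])
    dvdy <- (field$v[ii, jj + 1, ll] - field$v[ii, jj - 1, ll]) / (2 * field$spacing[2])
    dwdz <- (field$w[ii, jj, ll + 1] - field$w[ii, jj, ll - 1]) / (2 * field$spacing[3])
    den <- abs(dudx) + abs(dvdy + dwdz)
    e <- ifelse(defined & den > 0, abs(dudx + dvdy + dwdz) / den, NA_real_)
    eta[ii, jj, ll] <- e
  }
  if (!is.null(subvolume)) {
    keep_axis <- function(a, name) {
      r <- subvolume[[name]]
      if (is.null(r)) rep(TRUE, dims[a]) else
        field$centers[[a]] >= r[1] & field$centers[[a]] <= r[2]
    }
    kx <- keep_axis(1, "x"); ky <- keep_axis(2, "y"); kz <- keep_axis(3, "z")
    mask <- outer(outer(kx, ky, `&`), kz, `&`)
    eta[!mask] <- NA_real_
  }
  n_def <- sum(!is.na(eta))
  if (n_def == 0) stopf("continuity error undefined everywhere (too sparse a field)")
  structure(list(eta = eta, eta_median = stats::median(eta, na.rm = TRUE),
                 n_defined = n_def, subvolume = subvolume),
            class = "continuity_field")
}

#' @export
print.continuity_field <- function(x, ...) {
  cat(sprintf("Continuity error: median eta = %.3f over %d elements\n",
              x$eta_median, x$n_defined))
  invisible(x)
}

#' Sample a 1-D profile through a lattice field
#'
#' Extracts element means along one axis at the elements nearest a given
#' line, e.g. the spanwise velocity profile at the duct centerline.
#'
#' @param field A `lattice_field`.
#' @param axis `"x"`, `"y"` or `"z"`: the axis the profile runs along.
#' @param at Named numeric fixing the other two coordinates, micrometers
#'   (nearest element centers are used).
#' @param component `"u"`, `"v"`, `"w"` or `"speed"`.
#' @return Data frame with the axis coordinate `s`, `value`, and `count`.
#' @export
profile_line <- function(field, axis = "y", at = c(x = 0, z = 0),
                         component = "u") {
  axes <- c(x = 1L, y = 2L, z = 3L)
  a <- axes[[axis]]
  others <- setdiff(1:3, a)
  idx_fix <- vapply(others, function(o) {
    nm <- names(axes)[o]
    if (!nm %in% names(at)) stopf("profile_line: supply '%s' in `at`", nm)
    which.min(abs(field$centers[[o]] - at[[nm]]))
  }, integer(1))
  sel <- vector("list", 3)
  sel[[a]] <- seq_along(field$centers[[a]])
  sel[[others[1]]] <- idx_fix[1]
  sel[[others[2]]] <- idx_fix[2]
  take <- function(arr) arr[sel[[1]], sel[[2]], sel[[3]]]
  val <- switch(component,
                u = take(field$u), v = take(field$v), w = take(field$w),
                speed = sqrt(take(field$u)^2 + take(field$v)^2 + take(field$w)^2),
                stopf("unknown component '%s'", component))
  out <- data.frame(s = field$centers[[a]], value = val, count = take(field$count))
  out <- out[out$count > 0, , drop = FALSE]
  if (nrow(out) == 0) stopf("profile line crosses no non-empty element")
  rownames(out) <- NULL
  out
}

#' Goodness of a parabolic fit to a profile
#'
#' @param profile Output of [profile_line()].
#' @return List with the quadratic fit coefficients and `r_squared`.
#' @export
profile_parabola <- function(profile) {
  fit <- stats::lm(value ~ s + I(s^2), data = profile)
  # a perfect fit (uniform field) trips lm's summary warning; R^2 = 1 is fine
  list(coefficients = stats::coef(fit),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Export a lattice field as CSV
#'
#' Schema: `cx,cy,cz,u,v,w,count,eta` (eta `NA` where undefined or when no
#' continuity field is given); empty elements are omitted.
#'
#' @param field A `lattice_field`.
#' @param path CSV path.
#' @param continuity Optional matching `continuity_field`.
#' @param header_comment Optional leading `# ...` provenance line.
#' @export
write_lattice_csv <- function(field, path, continuity = NULL, header_comment = NULL) {
  dims <- dim(field$count)
  grid <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]), l = seq_len(dims[3]))
  idx <- as.matrix(grid)
  d <- data.frame(cx = field$centers[[1]][grid$i], cy = field$centers[[2]][grid$j],
                  cz = field$centers[[3]][grid$l],
                  u = field$u[idx], v = field$v[idx], w = field$w[idx],
                  count = field$count[idx],
                  eta = if (is.null(continuity)) NA_real_ else continuity$eta[idx])
  d <- d[d$count > 0, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}
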