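# Parametric spherical basket catheter: geometry, placement, electrode-
# tissue distance maps, and linear interpolation onto a periodic 2-D
# projection (longitude x arc-latitude chart of the basket sphere).

#' Build a basket-catheter geometry
#'
#' Electrodes are placed along `n_splines` meridians of a sphere at equal
#' arc spacing, centred on the equator. The default 8x8 geometry with a
#' 31 mm diameter and 4.8 mm inter-electrode spacing corresponds to the
#' smallest commercial 64-pole basket; alternative densities (4x6, 16x16)
#' keep the same meridional span unless an explicit spacing is given.
#'
#' @param n_splines Number of splines (labelled A, B, ...; >= 3).
#' @param n_electrodes Electrodes per spline (>= 2).
#' @param diameter_mm Basket diameter in mm (default 31).
#' @param spacing_mm Arc spacing along each spline in mm. Default: 4.8 for
#'   8 electrodes per spline, otherwise the 8x8 span (33.6 mm) divided by
#'   `n_electrodes - 1`.
#' @return A `basket`: electrode coordinates (canonical frame: centre at
#'   the origin, pole axis +z), ids, spline/ring structure.
#' @export
build_basket <- function(n_splines = 8, n_electrodes = 8, diameter_mm = 31,
                         spacing_mm = NULL) {
  stopifnot(n_splines >= 3, n_electrodes >= 2)
  r <- diameter_mm / 2
  if (is.null(spacing_mm)) {
    spacing_mm <- if (n_electrodes == 8) 4.8 else 33.6 / (n_electrodes - 1)
  }
  if (spacing_mm * (n_electrodes - 1) >= pi * r)
    stop("electrode spacing overruns the poles")
  # arc positions along the meridian, symmetric about the equator
  arc <- (seq_len(n_electrodes) - (n_electrodes + 1) / 2) * spacing_mm
  lat <- arc / r                       # arc-latitude in radians
  lon <- 2 * pi * (seq_len(n_splines) - 1) / n_splines
  grid <- expand.grid(k = seq_len(n_electrodes), s = seq_len(n_splines))
  phi <- lat[grid$k]
  lam <- lon[grid$s]
  coords <- cbind(r * cos(phi) * cos(lam),
                  r * cos(phi) * sin(lam),
                  r * sin(phi))
  spl_lab <- make_spline_labels(n_splines)
  structure(
    list(n_splines = n_splines, n_electrodes = n_electrodes,
         radius_mm = r, spacing_mm = spacing_mm,
         lat = lat, lon = lon,
         spline = grid$s, ring = grid$k,
         ids = paste0(spl_lab[grid$s], grid$k),
         coords = coords,
         center = c(0, 0, 0), axis = c(0, 0, 1)),
    class = "basket")
}

make_spline_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else apply(expand.grid(LETTERS, LETTERS)[seq_len(n), 2:1], 1,
             paste0, collapse = "")
}

#' @export
print.basket <- function(x, ...) {
  cat(sprintf("basket: %dx%d electrodes, diameter %g mm, spacing %.2f mm\n",
              x$n_splines, x$n_electrodes, 2 * x$radius_mm, x$spacing_mm))
  cat(sprintf("  centre (%.1f, %.1f, %.1f), axis (%.2f, %.2f, %.2f)\n",
              x$center[1], x$center[2], x$center[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

# rotation matrix taking +z to unit vector `axis`
rot_to_axis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  c2 <- sum(z * a)
  if (abs(c2 + 1) < 1e-12) return(diag(c(1, -1, -1)))  # antiparallel
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c2)
}

#' Place a basket rigidly in space
#'
#' Applies a rigid transform: the canonical pole axis +z is rotated onto
#' `axis` and the centre translated to `center`. If a `domain` is given,
#' electrodes penetrating the tissue surface are pulled radially inside
#' with a warning.
#'
#' @param basket A `basket`.
#' @param center Target centre (mm).
#' @param axis Target pole axis (default unchanged).
#' @param domain Optional `tissue_domain` for penetration checks
#'   (cylinder geometry only).
#' @return The transformed `basket`.
#' @export
place_basket <- function(basket, center = c(0, 0, 0), axis = c(0, 0, 1),
                         domain = NULL) {
  stopifnot(inherits(basket, "basket"))
  Rm <- rot_to_axis(axis)
  base <- build_basket(basket$n_splines, basket$n_electrodes,
                       2 * basket$radius_mm, basket$spacing_mm)
  coords <- t(Rm %*% t(base$coords)) +
    matrix(center, nrow(base$coords), 3, byrow = TRUE)
  out <- basket
  out$coords <- coords
  out$center <- center
  out$axis <- axis / sqrt(sum(axis^2))
  if (!is.null(domain) && domain$geometry == "cylinder") {
    Rc <- domain$cylinder_radius
    rad <- sqrt(coords[, 1]^2 + coords[, 2]^2)
    bad <- rad >= Rc
    if (any(bad)) {
      warning(sum(bad), " electrode(s) penetrated the tissue surface; ",
              "repositioned radially")
      f <- (Rc - domain$dx / 2) / rad[bad]
      out$coords[bad, 1:2] <- coords[bad, 1:2] * f
    }
  }
  out
}

#' Electrode-tissue distance map
#'
#' Exact nearest-neighbour distances between electrodes and conducting
#' tissue nodes, plus the bucket counts used for coverage reporting
#' (d <= 0.5 cm, 0.5 < d <= 1 cm, d > 1 cm).
#'
#' @param basket A `basket`.
#' @param dom A `tissue_domain`.
#' @return A `distance_map`: `electrode_d` (mm per electrode), `node_d`
#'   (mm per tissue node, NA for obstacles), `buckets` (electrode counts).
#' @export
distance_map <- function(basket, dom) {
  stopifnot(inherits(basket, "basket"), inherits(dom, "tissue_domain"))
  tn <- which(!dom$obstacle)
  if (length(tn) == 0) stop("domain has no conducting nodes")
  P <- dom$coords[tn, , drop = FALSE]
  E <- basket$coords
  d2 <- outer(rowSums(E^2), rowSums(P^2), "+") - 2 * E %*% t(P)
  d2[d2 < 0] <- 0
  De <- sqrt(d2)
  electrode_d <- apply(De, 1, min)
  node_d <- rep(NA_real_, dom$n_nodes)
  node_d[tn] <- apply(De, 2, min)
  buckets <- c(near = sum(electrode_d <= 5),
               mid = sum(electrode_d > 5 & electrode_d <= 10),
               far = sum(electrode_d > 10))
  structure(list(electrode_d = electrode_d, node_d = node_d,
                 buckets = buckets, basket = basket),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf(
    "distance_map: %d electrodes (d<=5mm: %d, 5-10mm: %d, >10mm: %d)\n",
    length(x$electrode_d), x$buckets["near"], x$buckets["mid"],
    x$buckets["far"]))
  invisible(x)
}

#' Projection grid for basket interpolation
#'
#' A periodic longitude x arc-latitude chart of the basket sphere. Grid
#' points lie strictly between the first and last electrode rings (the
#' pole caps are not interpolated).
#'
#' @param basket A `basket`.
#' @param n_points Total number of interpolation points (default 57600,
#'   split as a square grid).
#' @return A `projection_grid` with longitudes, latitudes, interpolation
#'   weights (3 electrodes per point) and 3-D point coordinates.
#' @export
projection_grid <- function(basket, n_points = 57600) {
  nlon <- max(8L, as.integer(round(sqrt(n_points))))
  nlat <- max(4L, as.integer(round(n_points / nlon)))
  lons <- 2 * pi * (seq_len(nlon) - 1) / nlon
  a0 <- min(basket$lat); a1 <- max(basket$lat)
  lats <- a0 + (seq_len(nlat)) * (a1 - a0) / (nlat + 1)

  ns <- basket$n_splines; np <- basket$n_electrodes
  eid <- function(s, k) (s - 1L) * np + k  # electrode index for spline s, ring k

  grid <- expand.grid(ilon = seq_len(nlon), ilat = seq_len(nlat))
  lon <- lons[grid$ilon]; lat <- lats[grid$ilat]
  # spline cell and fraction (periodic)
  uf <- lon / (2 * pi) * ns
  s0 <- pmin(floor(uf), ns - 1)
  u <- uf - s0
  s0 <- as.integer(s0) + 1L
  s1 <- ifelse(s0 == ns, 1L, s0 + 1L)
  # ring cell and fraction
  k0 <- findInterval(lat, basket$lat, rightmost.closed = TRUE)
  k0 <- pmin(pmax(k0, 1L), np - 1L)
  v <- (lat - basket$lat[k0]) / (basket$lat[k0 + 1] - basket$lat[k0])
  v <- pmin(pmax(v, 0), 1)

  lower <- u >= v  # triangle split with fixed diagonal (seam-consistent)
  widx <- matrix(0L, nrow(grid), 3)
  wval <- matrix(0, nrow(grid), 3)
  # lower triangle: (s0,k0), (s1,k0), (s1,k0+1); weights (1-u, u-v, v)
  widx[lower, ] <- cbind(eid(s0[lower], k0[lower]),
                         eid(s1[lower], k0[lower]),
                         eid(s1[lower], k0[lower] + 1L))
  wval[lower, ] <- cbind(1 - u[lower], u[lower] - v[lower], v[lower])
  up <- !lower   # upper triangle: (s0,k0), (s1,k0+1), (s0,k0+1)
  widx[up, ] <- cbind(eid(s0[up], k0[up]),
                      eid(s1[up], k0[up] + 1L),
                      eid(s0[up], k0[up] + 1L))
  wval[up, ] <- cbind(1 - v[up], u[up], v[up] - u[up])

  # 3-D point coordinates on the (placed) sphere
  r <- basket$radius_mm
  canon <- cbind(r * cos(lat) * cos(lon), r * cos(lat) * sin(lon),
                 r * sin(lat))
  Rm <- rot_to_axis(basket$axis)
  pts <- t(Rm %*% t(canon)) +
    matrix(basket$center, nrow(canon), 3, byrow = TRUE)

  structure(list(nlon = nlon, nlat = nlat, lons = lons, lats = lats,
                 widx = widx - 1L, wval = wval, points = pts,
                 basket = basket),
            class = "projection_grid")
}

#' Interpolate electrode values onto the 2-D projection
#'
#' Piecewise-linear (barycentric on the triangulated electrode lattice,
#' periodic in longitude) interpolation of per-electrode time series.
#'
#' @param values Matrix n_electrodes x n_frames (e.g. `egm_set$traces`), or
#'   a numeric vector for a single frame.
#' @param grid A `projection_grid`.
#' @return Matrix n_grid_points x n_frames (vector input returns a vector).
#' @export
interpolate_to_projection <- function(values, grid) {
  stopifnot(inherits(grid, "projection_grid"))
  vec <- is.null(dim(values))
  if (vec) values <- matrix(values, ncol = 1)
  ne <- grid$basket$n_splines * grid$basket$n_electrodes
  if (nrow(values) != ne)
    stop("values must have one row per electrode (", ne, ")")
  ng <- nrow(grid$widx)
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(ng), 3), j = as.integer(grid$widx) + 1L,
    x = as.numeric(grid$wval), dims = c(ng, ne))
  out <- as.matrix(W %*% values)
  if (vec) as.numeric(out) else out
}

#' Phase singularities on the interpolated basket projection
#'
#' Full basket mapping chain: band-pass filter the electrode electrograms,
#' form their analytic signals, linearly interpolate onto the periodic
#' projection, take the instantaneous phase per grid point, and evaluate
#' the per-plaquette topological charge on every frame. (Interpolation
#' commutes with the linear filter and Hilbert transform, so interpolating
#' the analytic signal is exactly equivalent to interpolating the raw
#' electrograms first and filtering per grid point.)
#'
#' @param egm An `egm_set` sampled at the basket electrodes.
#' @param grid A `projection_grid`.
#' @param lo_hz,hi_hz Filter band (default 7-10 Hz).
#' @param trim_ms Edge trim per end in ms (default 500).
#' @return A list with `detections` (a `ps_detections` data.frame whose
#'   `x`/`z` columns are longitude/arc-latitude and `X`,`Y`,`Z` lie on the
#'   basket sphere), `times`, `electrode_phase` (a `phase_movie` of the
#'   electrode-level phases, for rotation counting), and `grid`.
#' @export
basket_phase_ps <- function(egm, grid, lo_hz = 7, hi_hz = 10,
                            trim_ms = 500) {
  stopifnot(inherits(egm, "egm_set"), inherits(grid, "projection_grid"))
  fs <- 1000 / median(diff(egm$times))
  filt <- bandpass(egm$traces, fs, lo_hz, hi_hz)
  Z <- analytic_signal(filt)
  tt <- egm$times
  keep <- tt >= min(tt) + trim_ms & tt <= max(tt) - trim_ms
  if (!any(keep)) stop("movie too short to trim ", trim_ms, " ms per end")
  Zk <- Z[, keep, drop = FALSE]
  M <- projection_ps_cpp(Zk, grid$widx, grid$wval, grid$nlon, grid$nlat,
                         TRUE)
  times <- tt[keep]
  det <- if (nrow(M) == 0) empty_detections() else
    projection_detections(M, grid, times)
  eph <- structure(list(phase = atan2(Im(Zk), Re(Zk)), times = times,
                        provenance = "from_egm", band = c(lo_hz, hi_hz),
                        trim_ms = trim_ms, coords = egm$coords,
                        ids = egm$ids),
                   class = "phase_movie")
  list(detections = det, times = times, electrode_phase = eph, grid = grid)
}

projection_detections <- function(M, grid, times) {
  i <- M[, 2]; j <- M[, 3]  # 0-based plaquette lower-left
  dlon <- 2 * pi / grid$nlon
  lon <- (grid$lons[i + 1] + dlon / 2) %% (2 * pi)
  dlat <- if (grid$nlat > 1) grid$lats[2] - grid$lats[1] else 0
  lat <- grid$lats[j + 1] + dlat / 2
  r <- grid$basket$radius_mm
  canon <- cbind(r * cos(lat) * cos(lon), r * cos(lat) * sin(lon),
                 r * sin(lat))
  Rm <- rot_to_axis(grid$basket$axis)
  pts <- t(Rm %*% t(canon)) +
    matrix(grid$basket$center, nrow(canon), 3, byrow = TRUE)
  out <- data.frame(frame = M[, 1] + 1L, t_ms = times[M[, 1] + 1L],
                    x = lon, z = lat, X = pts[, 1], Y = pts[, 2],
                    Z = pts[, 3], charge = as.integer(M[, 4]))
  class(out) <- c("ps_detections", "data.frame")
  out
}

#' Basket geometry as a CSV table
#'
#' Columns `spline_label`, `electrode_index`, `x`, `y`, `z` (mm).
#'
#' @param basket A `basket`.
#' @param path Output path (`NULL` returns the data.frame).
#' @export
write_basket_csv <- function(basket, path = NULL) {
  df <- data.frame(
    spline_label = make_spline_labels(basket$n_splines)[basket$spline],
    electrode_index = basket$ring,
    x = basket$coords[, 1], y = basket$coords[, 2], z = basket$coords[, 3])
  if (is.null(path)) return(df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
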