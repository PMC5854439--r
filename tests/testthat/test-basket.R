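# Basket geometry, placement, distance maps and projection interpolation.

test_that("the 8x8 basket reproduces the published neighbour distances", {
  bk <- build_basket(8, 8, 31, 4.8)
  d_adj <- function(ring) {
    i <- which(bk$spline == 1 & bk$ring == ring)
    j <- which(bk$spline == 2 & bk$ring == ring)
    sqrt(sum((bk$coords[i, ] - bk$coords[j, ])^2))
  }
  expect_lt(abs(d_adj(4) - 11.7) / 11.7, 0.03)  # near the equator
  expect_lt(abs(d_adj(1) - 5.4) / 5.4, 0.05)    # outermost rings
  # along-spline spacing is exact on the sphere
  i <- which(bk$spline == 1 & bk$ring == 1)
  j <- which(bk$spline == 1 & bk$ring == 2)
  chord <- sqrt(sum((bk$coords[i, ] - bk$coords[j, ])^2))
  expect_equal(chord, 2 * 15.5 * sin(4.8 / 15.5 / 2), tolerance = 1e-9)
})

test_that("electrodes lie on the sphere and splines are equally spaced", {
  for (cfg in list(c(4, 6), c(8, 8), c(16, 16))) {
    bk <- build_basket(cfg[1], cfg[2])
    r <- sqrt(rowSums(bk$coords^2))
    expect_lt(max(abs(r - bk$radius_mm)), 1e-6)
    expect_equal(length(unique(bk$lon)), cfg[1])
    expect_equal(diff(bk$lon)[1], 2 * pi / cfg[1], tolerance = 1e-12)
  }
  # tiny case: 4 splines x 2 electrodes = 8 coordinates, symmetric layout
  tiny <- build_basket(4, 2, 20, 6)
  expect_equal(nrow(tiny$coords), 8)
  expect_equal(sum(tiny$lat), 0, tolerance = 1e-12)
  expect_error(build_basket(8, 8, 31, spacing_mm = 7), "overruns")
})

test_that("placement is a rigid motion and penetration is corrected", {
  bk <- build_basket()
  same <- place_basket(bk, c(0, 0, 0), c(0, 0, 1))
  expect_equal(same$coords, bk$coords, tolerance = 1e-12)
  moved <- place_basket(bk, c(3, -2, 10), c(0, 1, 1))
  d0 <- as.matrix(dist(bk$coords))
  d1 <- as.matrix(dist(moved$coords))
  expect_equal(d1, d0, tolerance = 1e-9)  # isometry
  dom <- tissue_domain("cylinder", c(80, 60), dx = 1)  # radius 12.7 mm
  expect_warning(pb <- place_basket(bk, c(0, 0, 30), c(0, 0, 1),
                                    domain = dom), "repositioned")
  rad <- sqrt(pb$coords[, 1]^2 + pb$coords[, 2]^2)
  expect_true(all(rad < dom$cylinder_radius))
})

test_that("distance maps agree with a brute-force oracle and are consistent", {
  dom <- tissue_domain("cylinder", c(110, 60), dx = 2)
  bk <- place_basket(build_basket(), c(0, 0, 30), domain = dom)
  dm <- distance_map(bk, dom)
  # independent brute force
  tn <- which(!dom$obstacle)
  for (e in c(1, 17, 40, 64)) {
    d_bf <- min(sqrt(colSums((t(dom$coords[tn, ]) - bk$coords[e, ])^2)))
    expect_equal(dm$electrode_d[e], d_bf, tolerance = 1e-9)
  }
  expect_equal(min(dm$electrode_d), min(dm$node_d, na.rm = TRUE),
               tolerance = 1e-9)
  expect_equal(sum(dm$buckets), 64)
  expect_true(all(dm$electrode_d >= 0))
})

test_that("projection interpolation reproduces constants, linear fields and electrode values", {
  bk <- build_basket()
  grid <- projection_grid(bk, n_points = 16 * 6)  # nlon 10 -> adjusted
  # constants are reproduced exactly
  cst <- interpolate_to_projection(rep(2.5, 64), grid)
  expect_equal(range(cst), c(2.5, 2.5), tolerance = 1e-12)
  # a field linear in latitude is reproduced exactly at all grid points
  vals <- 3 + 2 * bk$lat[bk$ring]
  f <- interpolate_to_projection(vals, grid)
  lat_g <- rep(grid$lats, each = grid$nlon)
  expect_equal(f, 3 + 2 * lat_g, tolerance = 1e-9)
})

test_that("grid points coinciding with electrode sites take the electrode values", {
  bk <- build_basket()
  grid <- projection_grid(bk, n_points = 16 * 6)
  expect_equal(grid$nlon, 10L)  # sqrt-based split of 96
  # build a grid whose latitudes hit rings 2..7 and longitudes hit splines
  g2 <- projection_grid(bk, n_points = 8 * 6)
  # construct explicit case: nlat = 6 means lats j/(7) span = ring lats
  expect_equal(g2$lats, bk$lat[2:7], tolerance = 1e-9)
  set.seed(5)
  vals <- rnorm(64)
  f <- interpolate_to_projection(vals, g2)
  for (s in 1:8) {
    ilon <- which.min(abs(g2$lons - bk$lon[s]))
    expect_lt(abs(g2$lons[ilon] - bk$lon[s]), 1e-9)
    for (k in 2:7) {
      gidx <- (k - 2) * g2$nlon + ilon
      expect_equal(f[gidx], vals[(s - 1) * 8 + k], tolerance = 1e-9)
    }
  }
})

test_that("the periodic seam is consistent: longitude 0 equals longitude 2*pi", {
  bk <- build_basket()
  grid <- projection_grid(bk, n_points = 57600)
  set.seed(11)
  vals <- rnorm(64)
  f <- interpolate_to_projection(vals, grid)
  # wrap a copy of the first column past the seam by evaluating the
  # interpolant as if lon = 2*pi: weights must match lon = 0
  M <- matrix(f, grid$nlon, grid$nlat)
  # continuity across the seam: the jump between last and first columns is
  # comparable to the jump between ordinary neighbouring columns
  seam_jump <- max(abs(M[1, ] - M[grid$nlon, ]))
  typ_jump <- max(abs(M[2, ] - M[1, ]))
  expect_lt(seam_jump, 40 * max(typ_jump, 1e-9))
  # structural check: points past the last spline interpolate from the
  # last AND first splines (periodic wrap)
  last_col <- which(rep(seq_len(grid$nlon), grid$nlat) == grid$nlon)
  used <- unique(as.integer(grid$widx[last_col, ])) + 1L
  spl <- unique(bk$spline[used])
  expect_true(all(c(1, 8) %in% spl))
})

test_that("sawtooth longitude values ramp linearly between splines", {
  bk <- build_basket()
  grid <- projection_grid(bk, n_points = 57600)
  vals <- bk$lon[bk$spline]
  f <- interpolate_to_projection(vals, grid)
  M <- matrix(f, grid$nlon, grid$nlat)
  lon_g <- grid$lons
  interior <- lon_g > bk$lon[2] & lon_g < bk$lon[3]
  expect_equal(M[interior, 3], lon_g[interior], tolerance = 1e-9)
})

test_that("an undersampled travelling wave creates paired interpolation singularities", {
  fx <- make_aliasing_fixture(duration_ms = 2000)
  counts <- vapply(fx$cases, function(cs) {
    grid <- projection_grid(cs$basket, 57600)
    bp <- basket_phase_ps(cs$egm, grid)
    det <- bp$detections
    if (nrow(det) > 0) {
      # spurious singularities appear in +/- pairs: zero net charge
      per_frame <- tapply(det$charge, det$frame, sum)
      expect_true(all(per_frame == 0))
    }
    nrow(det)
  }, 1)
  expect_gt(counts[["4x6"]], 0)              # aliased: FIPS mechanism
  expect_equal(unname(counts[["16x16"]]), 0) # resolved: no artifacts
  expect_true(counts[["4x6"]] >= counts[["8x8"]])
  expect_true(counts[["8x8"]] >= counts[["16x16"]])
})

test_that("basket geometry exports as a labelled CSV", {
  bk <- build_basket(4, 6)
  df <- write_basket_csv(bk)
  expect_equal(nrow(df), 24)
  expect_setequal(unique(df$spline_label), c("A", "B", "C", "D"))
})
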