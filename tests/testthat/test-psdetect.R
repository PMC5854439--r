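# Topological-charge detection, index-sum conservation, tracking and
# rotation counting — validated against analytic vortex oracles.

test_that("an ideal vortex yields exactly one +1 charge at its centre", {
  pm <- analytic_vortex_movie(c(10.5, 10.5), omega = 0.05,
                              duration_ms = 30, size_mm = c(20, 20), dx = 1)
  det <- detect_ps(pm)
  expect_equal(nrow(det), length(pm$times))      # one detection per frame
  expect_true(all(det$charge == 1L))
  expect_true(all(abs(det$x - 10.5) < 1 & abs(det$z - 10.5) < 1))
})

test_that("mirroring the field flips the chirality", {
  pm <- analytic_vortex_movie(c(10.5, 10.5), charges = -1L, omega = 0.05,
                              duration_ms = 10, size_mm = c(20, 20), dx = 1)
  det <- detect_ps(pm)
  expect_true(all(det$charge == -1L))
})

test_that("two opposite vortices give two detections and zero net charge", {
  pm <- analytic_vortex_movie(rbind(c(6.5, 10.5), c(14.5, 10.5)),
                              charges = c(1L, -1L), omega = 0.04,
                              duration_ms = 10, size_mm = c(20, 20), dx = 1)
  det <- detect_ps(pm)
  for (f in unique(det$frame)) {
    d <- det[det$frame == f, ]
    expect_equal(nrow(d), 2)
    expect_equal(sum(d$charge), 0)
  }
})

test_that("interior charge sum equals the boundary winding number (100 random fields)", {
  set.seed(42)
  nx <- 12; ny <- 12
  dom <- tissue_domain("sheet", c(nx - 1, ny - 1), dx = 1)
  # ordered outer boundary path, counter-clockwise
  bottom <- basketmap:::node_id(dom, 1:nx, 1)
  right <- basketmap:::node_id(dom, nx, 2:ny)
  top <- basketmap:::node_id(dom, (nx - 1):1, ny)
  left <- basketmap:::node_id(dom, 1, (ny - 1):2)
  path <- c(bottom, right, top, left)
  for (k in 1:100) {
    ph <- runif(dom$n_nodes, -pi, pi)
    pm <- structure(list(phase = matrix(ph, ncol = 1), times = 0,
                         provenance = "analytic", trim_ms = 0,
                         coords = dom$coords, domain = dom),
                    class = "phase_movie")
    det <- detect_ps(pm)
    expect_identical(sum(det$charge), boundary_winding(ph, path))
  }
})

test_that("detection is invariant to a global phase offset", {
  set.seed(7)
  dom <- tissue_domain("sheet", c(10, 10), dx = 1)
  ph <- runif(dom$n_nodes, -pi, pi)
  mk <- function(p) structure(list(phase = matrix(p, ncol = 1), times = 0,
                                   provenance = "analytic", trim_ms = 0,
                                   coords = dom$coords, domain = dom),
                              class = "phase_movie")
  d1 <- detect_ps(mk(ph))
  d2 <- detect_ps(mk(basketmap:::wrap_angle(ph + 1.234)))
  expect_equal(d1$x, d2$x)
  expect_equal(d1$charge, d2$charge)
})

test_that("generic polygonal elements carry the correct integer charge", {
  # ideal vortex sampled on a triangle around/away from the core
  pts <- rbind(c(1, 0), c(-0.5, 0.9), c(-0.5, -0.9), c(3, 0.1), c(4, 0.1),
               c(3.5, 1))
  ph <- atan2(pts[, 2], pts[, 1])
  expect_identical(topological_charge(ph, list(1:3, 4:6)), c(1L, 0L))
  expect_identical(topological_charge(-ph, list(1:3)), -1L)
  expect_error(topological_charge(ph, list(1:2)), "at least 3")
  expect_identical(topological_charge(c(NA, ph[-1]), list(1:3)),
                   NA_integer_)
})

test_that("a stationary singularity links into a single full-length track", {
  pm <- analytic_vortex_movie(c(10.5, 10.5), omega = 0.05,
                              duration_ms = 40, size_mm = c(20, 20), dx = 1)
  det <- detect_ps(pm)
  tracks <- track_ps(det, link_radius = 3)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$n_frames, length(pm$times))
})

test_that("distant singularities are never merged and gaps are bridged", {
  pm <- analytic_vortex_movie(rbind(c(5.5, 5.5), c(25.5, 25.5)),
                              charges = c(1L, 1L), omega = 0.05,
                              duration_ms = 20, size_mm = c(30, 30), dx = 1)
  det <- detect_ps(pm)
  tracks <- track_ps(det, link_radius = 4)
  expect_length(tracks, 2)
  # remove one intermediate frame of one singularity: still one track
  det2 <- det[!(det$frame == 10 & det$x < 10), ]
  tracks2 <- track_ps(det2, link_radius = 4, max_gap_frames = 2)
  expect_length(tracks2, 2)
})

test_that("rotation counts match the vortex angular frequency", {
  omega <- 2 * pi / 100                    # one turn per 100 ms
  pm <- analytic_vortex_movie(c(10.5, 10.5), omega = omega,
                              duration_ms = 500, size_mm = c(20, 20), dx = 1)
  det <- detect_ps(pm)
  tracks <- track_rotations(track_ps(det, 3), pm)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$rotations, 5, tolerance = 0.1)
  expect_equal(tracks[[1]]$mean_cycle_ms, 100, tolerance = 0.05)
})

test_that("the rotor filter keeps only tracks with at least one full cycle", {
  omega <- 2 * pi / 100
  pm <- analytic_vortex_movie(c(10.5, 10.5), omega = omega,
                              duration_ms = 500, size_mm = c(20, 20), dx = 1)
  det <- detect_ps(pm)
  tracks <- track_rotations(track_ps(det, 3), pm)
  expect_length(filter_rotors(tracks, 1), 1)
  # a 40 ms slice has only 0.4 rotations
  short <- track_rotations(track_ps(det[det$t_ms <= 40, ], 3), pm)
  expect_length(filter_rotors(short, 1), 0)
  expect_identical(filter_rotors(list(), 1), list())
})

test_that("a meandering core's track bbox matches the prescribed orbit", {
  times <- 0:400
  r_orbit <- 3
  cx <- 15.5 + r_orbit * cos(2 * pi * times / 200)
  cz <- 15.5 + r_orbit * sin(2 * pi * times / 200)
  dom <- tissue_domain("sheet", c(30, 30), dx = 1)
  base <- function(t) basketmap:::wrap_angle(
    atan2(dom$surf[, "z"] - cz[t + 1], dom$surf[, "x"] - cx[t + 1]) -
      0.06 * t)
  ph <- vapply(times, base, numeric(dom$n_nodes))
  pm <- structure(list(phase = ph, times = times, provenance = "analytic",
                       trim_ms = 0, coords = dom$coords, domain = dom),
                  class = "phase_movie")
  det <- detect_ps(pm)
  tracks <- track_ps(det, link_radius = 3)
  expect_length(tracks, 1)
  bb <- tracks[[1]]$meander_bbox
  area <- (bb["xmax"] - bb["xmin"]) * (bb["zmax"] - bb["zmin"])
  expect_lt(abs(area - 36) / 36, 0.35)  # (2r)^2 up to one element width
})

test_that("tracks export to a tidy CSV table", {
  pm <- analytic_vortex_movie(c(10.5, 10.5), omega = 0.05, duration_ms = 5,
                              size_mm = c(20, 20), dx = 1)
  tracks <- track_ps(detect_ps(pm), 3)
  df <- write_tracks_csv(tracks)
  expect_named(df, c("track_id", "frame_ms", "x", "y", "z", "charge"))
  expect_equal(nrow(df), 6)
})
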