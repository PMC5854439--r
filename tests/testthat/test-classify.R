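# Activation sequences, track classification and summary metrics.

# electrode EGMs rotating around a projection position (lon0, lat0):
# activation phase equals the angular position of each electrode
rotating_egm <- function(bk, lon0, lat0, f_hz = 8.5, duration_ms = 3000,
                         scramble = FALSE, seed = 1) {
  times <- seq(0, duration_ms, by = 1)
  elon <- bk$lon[bk$spline]
  elat <- bk$lat[bk$ring]
  ang <- atan2(elat - lat0, basketmap:::wrap_angle(elon - lon0))
  if (scramble) {
    set.seed(seed)
    ang <- sample(ang)
  }
  traces <- t(vapply(seq_along(ang), function(e)
    cos(2 * pi * f_hz * times / 1000 - ang[e]), numeric(length(times))))
  structure(list(traces = traces, times = times, coords = bk$coords,
                 ids = bk$ids, sigma_b = NA),
            class = "egm_set")
}

track_at <- function(lon0, lat0, bk, t_ms = seq(500, 2500, by = 1),
                     cycle_ms = 1000 / 8.5) {
  r <- bk$radius_mm
  xyz <- cbind(r * cos(lat0) * cos(lon0), r * cos(lat0) * sin(lon0),
               r * sin(lat0))
  make_test_track(t_ms, rep(lon0, length(t_ms)), rep(lat0, length(t_ms)),
                  xyz[rep(1, length(t_ms)), , drop = FALSE],
                  mean_cycle_ms = cycle_ms)
}

test_that("electrogram activation times mark the steepest negative deflection", {
  times <- seq(0, 2000, by = 1)
  f <- 8
  x <- cos(2 * pi * f * times / 1000)
  at <- egm_activation_times(x, times)
  # one activation per cycle
  expect_equal(length(at), f * 2, tolerance = 0.13)
  expect_equal(median(diff(at)), 1000 / f, tolerance = 0.01)
  # steepest negative slope of cos occurs where sin is maximal
  expect_lt(abs((at[3] * f / 1000 * 2 * pi) %% (2 * pi) - pi / 2), 0.1)
  expect_length(egm_activation_times(rep(0, 100), seq_len(100)), 0)
})

test_that("a rotating activation pattern scores as fully sequential", {
  bk <- build_basket()
  lon0 <- bk$lon[2] + pi / 8; lat0 <- 0.05
  egm <- rotating_egm(bk, lon0, lat0)
  tr <- track_at(lon0, lat0, bk)
  sq <- activation_sequence_score(tr, egm, bk)
  expect_equal(sq$score, 1.0)
  expect_gte(sq$n_cycles, 10)
})

test_that("scrambled activation ordering scores as non-sequential", {
  bk <- build_basket()
  lon0 <- bk$lon[2] + pi / 8; lat0 <- 0.05
  egm <- rotating_egm(bk, lon0, lat0, scramble = TRUE, seed = 4)
  tr <- track_at(lon0, lat0, bk)
  sq <- activation_sequence_score(tr, egm, bk)
  expect_lt(sq$score, 0.5)
})

test_that("one third of random orderings of four electrodes are circularly monotone", {
  # brute-force oracle: a cyclic sequence of 4 distinct activation phases
  # is consistent iff the wrapped increments share one sign
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  phases <- c(0.1, 0.3, 0.6, 0.8) * 2 * pi
  consistent <- apply(perms, 1, function(p) {
    al <- phases[p]
    d <- basketmap:::wrap_angle(diff(c(al, al[1])))
    all(d > 0) || all(d < 0)
  })
  expect_equal(mean(consistent), 1 / 3)
})

test_that("classification separates matched, sequential and artifactual tracks", {
  bk <- build_basket()
  dom <- tissue_domain("cylinder", c(110, 60), dx = 2)
  bk <- place_basket(bk, c(0, 0, 30), domain = dom)
  lon0 <- bk$lon[2] + pi / 8; lat0 <- 0.05
  egm <- rotating_egm(bk, lon0, lat0)
  # the basket track, and a ground-truth rotor exactly radially outside it
  tr <- track_at(lon0, lat0, bk)
  tr$detections$X <- tr$detections$X + bk$center[1]
  tr$detections$Y <- tr$detections$Y + bk$center[2]
  tr$detections$Z <- tr$detections$Z + bk$center[3]
  proj <- basketmap:::project_to_tissue(
    as.matrix(tr$detections[, c("X", "Y", "Z")]), bk, dom)
  gt <- make_test_track(tr$detections$t_ms, lon0, lat0, proj)
  cl <- classify_tracks(list(tr), list(gt), egm, bk, dom)
  expect_equal(cl[[1]]$label, "TRUE_ROTOR")
  expect_lt(cl[[1]]$match_distance_mm, 1)
  # no ground truth, sequential activation -> IMPS
  cl2 <- classify_tracks(list(tr), list(), egm, bk, dom)
  expect_equal(cl2[[1]]$label, "IMPS")
  # no ground truth, scrambled activation -> FIPS
  egm_s <- rotating_egm(bk, lon0, lat0, scramble = TRUE, seed = 4)
  cl3 <- classify_tracks(list(tr), list(), egm_s, bk, dom)
  expect_equal(cl3[[1]]$label, "FIPS")
  # labels are exhaustive and exclusive
  labs <- vapply(c(cl, cl2, cl3), `[[`, "", "label")
  expect_true(all(labs %in% c("TRUE_ROTOR", "IMPS", "FIPS")))
})

test_that("TRUE_ROTOR share never grows when the match threshold shrinks", {
  bk <- build_basket()
  dom <- tissue_domain("cylinder", c(110, 60), dx = 2)
  bk <- place_basket(bk, c(0, 0, 30), domain = dom)
  lon0 <- bk$lon[2] + pi / 8
  egm <- rotating_egm(bk, lon0, 0.05)
  set.seed(8)
  tracks <- lapply(seq(-0.4, 0.4, length.out = 5), function(la)
    track_at(lon0, la, bk))
  tracks <- lapply(tracks, function(tr) {
    tr$detections$Z <- tr$detections$Z + 30; tr
  })
  gt <- track_at(lon0, 0.05, bk)
  gt$detections$Z <- gt$detections$Z + 30
  counts <- vapply(c(20, 10, 5, 2), function(th) {
    cl <- classify_tracks(tracks, list(gt), egm, bk, dom,
                          match_threshold_mm = th)
    sum(vapply(cl, `[[`, "", "label") == "TRUE_ROTOR")
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection percentages count frames with at least one track per label", {
  window <- seq(500, 1500, by = 1)
  bk <- build_basket()
  t1 <- track_at(0.5, 0, bk, t_ms = window)            # full window
  t2 <- track_at(2.5, 0.2, bk, t_ms = seq(500, 999))   # half window
  cl <- list(structure(list(track = t1, label = "TRUE_ROTOR",
                            match_distance_mm = 0, sequential_score = 1,
                            surrounding_electrodes = character(0),
                            flagged = FALSE), class = "classified_track"),
             structure(list(track = t2, label = "FIPS",
                            match_distance_mm = NA, sequential_score = 0.1,
                            surrounding_electrodes = character(0),
                            flagged = FALSE), class = "classified_track"))
  pct <- detection_percentages(cl, window)
  expect_equal(unname(pct["TRUE_ROTOR"]), 100)
  expect_equal(unname(pct["FIPS"]), 100 * 500 / 1001, tolerance = 0.01)
  expect_equal(unname(pct["IMPS"]), 0)
  expect_equal(unname(detection_percentages(list(), window)),
               c(0, 0, 0))
  expect_error(detection_percentages(cl, numeric(0)), "window")
})

test_that("coverage metrics agree with a brute-force bucket count", {
  dom <- tissue_domain("cylinder", c(110, 60), dx = 2)
  bk <- place_basket(build_basket(), c(0, 0, 30), domain = dom)
  dm <- distance_map(bk, dom)
  cov <- coverage_metrics(dm)
  tn <- which(!dom$obstacle)
  d_bf <- vapply(tn, function(n)
    min(sqrt(rowSums((bk$coords - matrix(dom$coords[n, ], 64, 3,
                                         byrow = TRUE))^2))), 1)
  expect_equal(cov$tissue_d05, 100 * mean(d_bf <= 5), tolerance = 1e-9)
  expect_equal(cov$tissue_d10, 100 * mean(d_bf > 5 & d_bf <= 10),
               tolerance = 1e-9)
  # meander subset restricted correctly; far basket covers nothing
  far <- place_basket(build_basket(), c(0, 0, 300))
  dm_far <- distance_map(far, dom)
  cov_far <- coverage_metrics(dm_far)
  expect_equal(cov_far$tissue_d05, 0)
  expect_equal(cov_far$tissue_d10, 0)
})

test_that("trajectory distances report rigid offsets exactly", {
  bk <- build_basket()
  a <- track_at(1, 0, bk)
  expect_equal(trajectory_distance(a, a)$median_mm, 0)
  b <- a
  b$detections$X <- b$detections$X + 3
  b$detections$Y <- b$detections$Y + 4
  td <- trajectory_distance(a, b)
  expect_equal(td$min_mm, 5)
  expect_equal(td$median_mm, 5)
  expect_equal(td$max_mm, 5)
  c2 <- a
  c2$detections$t_ms <- c2$detections$t_ms + 1e6
  expect_error(trajectory_distance(a, c2), "overlap")
})
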