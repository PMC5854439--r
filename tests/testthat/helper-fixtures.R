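# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# the shipped standard scenario (expensive: built once, used by the
# acceptance tests)
get_standard_scenario <- function() {
  cached("standard_scenario", function() standard_scenario())
}

get_scenario_sources <- function() {
  cached("scenario_sources", function()
    compute_sources(get_standard_scenario()$movie))
}

# placement reports on the standard scenario (8x8 basket)
get_report <- function(placement) {
  cached(paste0("report_", placement), function()
    run_pipeline(get_standard_scenario(), build_basket(), placement,
                 sources = get_scenario_sources()))
}

# far-field masking runs (near placement; sources restricted to the rotor +
# edge-reentry region so most of the domain, including the pacing site, is
# silent)
get_masked_report <- function(n_splines, n_electrodes) {
  cached(sprintf("masked_%dx%d", n_splines, n_electrodes), function() {
    sc <- get_standard_scenario()
    masks <- make_farfield_masks(sc)
    run_pipeline(sc, build_basket(n_splines, n_electrodes), "near",
                 sources = get_scenario_sources(),
                 source_mask = masks$rotor_reentry)
  })
}

# aliasing-fixture mapping results per density
get_aliasing_results <- function() {
  cached("aliasing", function() {
    fx <- make_aliasing_fixture(duration_ms = 2000)
    lapply(fx$cases, function(cs) {
      grid <- projection_grid(cs$basket, 57600)
      bp <- basket_phase_ps(cs$egm, grid)
      tracks <- track_rotations(track_ps(bp$detections, 4, 2),
                                bp$electrode_phase)
      rot <- filter_rotors(tracks, 1)
      cl <- classify_tracks(rot, list(), cs$egm, cs$basket)
      list(detections = bp$detections, tracks = rot, classified = cl,
           times = bp$times,
           fips_pct = detection_percentages(cl, bp$times)[["FIPS"]])
    })
  })
}

# per-region APD table at the three study protocols (shared by the
# cellular acceptance tests)
get_apd_table <- function() {
  cached("apd_table", function() {
    regions <- crn_region_table()$region
    do.call(rbind, lapply(regions, function(rg) {
      t1000 <- pace_cell(membrane_model(rg, "control"),
                         pacing_protocol(1000, 60))
      c500 <- pace_cell(membrane_model(rg, "control"),
                        pacing_protocol(500, 120))
      f500 <- pace_cell(membrane_model(rg, "cAF"),
                        pacing_protocol(500, 120))
      data.frame(region = rg,
                 apd95_1000 = apd(t1000, 0.95),
                 apd90_1000 = apd(t1000, 0.90),
                 apd90_500_ctrl = apd(c500, 0.90),
                 apd90_500_caf = apd(f500, 0.90))
    }))
  })
}

# a small synthetic ps_track for classification tests
make_test_track <- function(t_ms, lon, lat, xyz, charge = 1L,
                            mean_cycle_ms = 115) {
  d <- data.frame(frame = seq_along(t_ms), t_ms = t_ms, x = lon, z = lat,
                  X = xyz[, 1], Y = xyz[, 2], Z = xyz[, 3],
                  charge = charge)
  class(d) <- c("ps_detections", "data.frame")
  structure(list(detections = d, birth_ms = min(t_ms),
                 death_ms = max(t_ms), chirality = charge,
                 n_frames = nrow(d),
                 meander_bbox = c(xmin = min(d$x), xmax = max(d$x),
                                  zmin = min(d$z), zmax = max(d$z)),
                 rotations = length(t_ms), mean_cycle_ms = mean_cycle_ms),
            class = "ps_track")
}

# keep long honest failure lists from terminating the reporter early
options(testthat.progress.max_fails = 1000L)
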