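# Synthetic scenarios and analytic fixtures: every stage of the mapping
# chain is testable without external data.

#' Analytic rotating-vortex phase movie
#'
#' `theta(x, y, t) = sum_k q_k * atan2(y - y_k, x - x_k) - omega * t`,
#' wrapped to (-pi, pi]; an exact oracle for topological-charge detection.
#'
#' @param centers Matrix (k x 2) of vortex centres in mm (or a length-2
#'   vector for one vortex).
#' @param charges Integer charges, one per centre (default +1).
#' @param omega Angular frequency in rad/ms.
#' @param duration_ms Movie length (frames at 1 ms).
#' @param size_mm Sheet size `c(Lx, Ly)`.
#' @param dx Grid spacing in mm.
#' @return A `phase_movie` on a sheet `tissue_domain`.
#' @export
analytic_vortex_movie <- function(centers, charges = NULL, omega = 0.05,
                                  duration_ms = 100, size_mm = c(20, 20),
                                  dx = 1) {
  if (omega == 0) stop("omega must be nonzero")
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  if (is.null(charges)) charges <- rep(1L, nrow(centers))
  stopifnot(length(charges) == nrow(centers))
  dom <- tissue_domain("sheet", size_mm, dx = dx)
  times <- seq(0, duration_ms, by = 1)
  base <- rep(0, dom$n_nodes)
  for (k in seq_len(nrow(centers))) {
    base <- base + charges[k] * atan2(dom$surf[, "z"] - centers[k, 2],
                                      dom$surf[, "x"] - centers[k, 1])
  }
  ph <- vapply(times, function(t) wrap_angle(base - omega * t),
               numeric(dom$n_nodes))
  structure(list(phase = ph, times = times, provenance = "analytic",
                 band = c(NA, NA), trim_ms = 0, coords = dom$coords,
                 domain = dom),
            class = "phase_movie")
}

# states sampled along one paced cycle, used for phase-distribution
# initialisation of a spiral wave
cycle_state_library <- function(model, bcl = 180, n_beats = 20) {
  crn_cycle_states_cpp(crn_initial_state_cpp(), model$scalars, bcl,
                       n_beats, 28, 2, 0.01, 1)
}

# Archimedean-spiral phase-distribution initial condition
spiral_states <- function(dom, model, center, lambda_mm = 30, bcl = 180) {
  lib <- cycle_state_library(model, bcl = bcl)
  ns <- ncol(lib)
  L <- if (dom$periodic_x) dom$size_mm[1] else Inf
  dxv <- wrap_dx(dom$surf[, "x"] - center[1], L)
  dzv <- dom$surf[, "z"] - center[2]
  r <- sqrt(dxv^2 + dzv^2)
  psi <- (atan2(dzv, dxv) / (2 * pi) + r / lambda_mm) %% 1
  idx <- pmin(ns, floor(psi * ns) + 1L)
  lib[, idx, drop = FALSE]
}

#' Build the standard rotor + far-field pacing scenario
#'
#' A cylindrical atrial-surface analog (periodic circumference) hosting one
#' sustained spiral wave (initiated by a phase-distribution initial
#' condition) plus a distant high-frequency point-pacing source near the
#' bottom edge, emulating a stable rotor coexisting with an ectopic focus
#' train. The rotor's distal arm wraps the cylinder and circulates around
#' the top edge, the anatomical-reentry analog.
#'
#' @param condition Membrane condition (default `"cAF"`, whose short APD
#'   sustains a stable spiral at this domain size).
#' @param duration_ms Simulated time (default 2500).
#' @param circumference_mm,height_mm Cylinder size (default 110 x 60).
#' @param dx Node spacing in mm (default 0.5).
#' @param D Base diffusivity in mm^2/ms.
#' @param conductivity_scale Conductivity multiplier (default 0.85, the
#'   gap-junctional remodeling accompanying cAF).
#' @param rotor_center Spiral-core seed position `c(x, z)` in surface mm.
#' @param pacing_cl_ms Ectopic-train cycle length (default 110).
#' @param pacing_stop_ms Stop pacing at this time (default: never).
#' @param dt Time step in ms.
#' @param seed RNG seed echoed into the scenario (the generator itself is
#'   deterministic).
#' @param region Region tag for the (homogeneous) membrane (default RA_PM).
#' @return A `scenario`: list with `movie` (`vm_movie`), `domain`,
#'   `ground_truth` (list: `tracks`, `times`, `rotor_track`), `params`.
#' @export
standard_scenario <- function(condition = "cAF", duration_ms = 2500,
                              circumference_mm = 110, height_mm = 60,
                              dx = 0.5, D = 0.1, conductivity_scale = 0.85,
                              rotor_center = c(55, 40), pacing_cl_ms = 110,
                              pacing_stop_ms = Inf, dt = 0.02, seed = 1,
                              region = "RA_PM") {
  set.seed(seed)
  dom <- tissue_domain("cylinder", c(circumference_mm, height_mm), dx = dx,
                       region = region, D = D)
  model <- membrane_model(region, condition)
  states <- spiral_states(dom, model, rotor_center)
  pace_nodes <- nodes_in_disk(dom, c((rotor_center[1] + circumference_mm / 2)
                                     %% circumference_mm, 4), 2)
  n_pulses <- if (is.finite(pacing_stop_ms))
    max(0L, floor(pacing_stop_ms / pacing_cl_ms)) else
      ceiling(duration_ms / pacing_cl_ms)
  stimuli <- if (n_pulses > 0)
    list(stimulus(pace_nodes, onset = 20, amplitude = 56, duration = 2,
                  period = pacing_cl_ms, count = n_pulses))
  else list()
  movie <- run_tissue(dom, condition, stimuli, duration = duration_ms,
                      dt = dt, record_dt = 1, init = states,
                      conductivity_scale = conductivity_scale)
  gt <- scenario_ground_truth(movie)
  if (is.null(gt$rotor_track))
    stop("spiral failed to form or was not sustained; ",
         "adjust the scenario parameters")
  structure(list(movie = movie, domain = dom, ground_truth = gt,
                 params = list(condition = condition,
                               duration_ms = duration_ms,
                               circumference_mm = circumference_mm,
                               height_mm = height_mm, dx = dx, D = D,
                               conductivity_scale = conductivity_scale,
                               rotor_center = rotor_center,
                               pacing_cl_ms = pacing_cl_ms,
                               pacing_stop_ms = pacing_stop_ms, dt = dt,
                               seed = seed, region = region)),
            class = "scenario")
}

#' Ground-truth phase singularities of a membrane-potential movie
#'
#' Applies the phase pipeline to V_m (the endocardium-analog reference),
#' detects and tracks singularities, and identifies the dominant rotor
#' track (most frames, >= 1 rotation).
#'
#' @param movie A `vm_movie`.
#' @param lo_hz,hi_hz Filter band.
#' @param trim_ms Edge trim.
#' @param link_radius_mm Tracking link radius (default 5).
#' @return List with `tracks` (rotor-grade tracks), `all_tracks`,
#'   `rotor_track` (the dominant one or NULL), `times` (analysis window),
#'   `phase` (the trimmed tissue `phase_movie`).
#' @export
scenario_ground_truth <- function(movie, lo_hz = 7, hi_hz = 10,
                                  trim_ms = 500, link_radius_mm = 5) {
  pm <- phase_movie(movie, lo_hz, hi_hz, trim_ms)
  det <- detect_ps(pm)
  tracks <- track_ps(det, link_radius = link_radius_mm, max_gap_frames = 5)
  tracks <- track_rotations(tracks, pm)
  rot <- filter_rotors(tracks, 1)
  rotor <- NULL
  if (length(rot)) rotor <- rot[[which.max(vapply(rot, function(t)
    t$n_frames, 1))]]
  list(tracks = rot, all_tracks = tracks, rotor_track = rotor,
       times = pm$times, phase = pm)
}

#' Named basket placements for a scenario
#'
#' Three presets along the cylinder axis: `near` centres the basket at the
#' rotor's mean axial position, `mid` and `far` displace it by 12 and
#' 24 mm toward the pacing end.
#'
#' @param scenario A `scenario`.
#' @param basket A `basket` (placed copies are returned).
#' @param which Subset of `c("near", "mid", "far")`.
#' @return Named list of placed baskets.
#' @export
basket_placements <- function(scenario, basket,
                              which = c("near", "mid", "far")) {
  dom <- scenario$domain
  rt <- scenario$ground_truth$rotor_track
  z_rot <- mean(rt$detections$z)
  r <- basket$radius_mm
  zmin <- r + 1; zmax <- dom$size_mm[2] - r - 1
  clamp <- function(z) min(max(z, zmin), zmax)
  offs <- c(near = 0, mid = -12, far = -24)
  out <- lapply(which, function(w)
    place_basket(basket, center = c(0, 0, clamp(z_rot + offs[[w]])),
                 axis = c(0, 0, 1), domain = dom))
  names(out) <- which
  out
}

#' Aliasing fixture: a spatially undersampled travelling wave
#'
#' Synthesizes electrode electrograms of an oblique travelling wave with
#' five cycles around the circumference -- beyond the spline Nyquist limit
#' of the 4- and 8-spline baskets but resolved by 16 splines -- and a steep
#' axial phase gradient. On the sparsest basket the interpolated analytic
#' signal passes through zero inside electrode cells, so its phase maps
#' contain spurious singularity pairs (the FIPS mechanism) while the
#' tissue ground truth has none and the dense basket resolves the wave.
#'
#' @param freq_hz Temporal frequency (default 8.5, inside the 7-10 Hz
#'   band).
#' @param m_lon Spatial cycles around the circumference (default 5).
#' @param lat_span_rad Extra phase accumulated across the electrode
#'   latitude span (default 2.8*pi; makes the wave oblique and steep).
#' @param duration_ms Trace length (default 3000).
#' @param densities Basket configurations, list of `c(n_splines,
#'   n_electrodes)`.
#' @return List per density: `egm` (`egm_set`), `basket`, plus shared
#'   `ground_truth` (empty track list) and parameters.
#' @export
make_aliasing_fixture <- function(freq_hz = 8.5, m_lon = 5,
                                  lat_span_rad = 2.8 * pi,
                                  duration_ms = 3000,
                                  densities = list(c(4, 6), c(8, 8),
                                                   c(16, 16))) {
  times <- seq(0, duration_ms, by = 1)
  out <- lapply(densities, function(dd) {
    bk <- build_basket(dd[1], dd[2])
    lat01 <- (bk$lat[bk$ring] - min(bk$lat)) / diff(range(bk$lat))
    alpha <- m_lon * bk$lon[bk$spline] + lat_span_rad * lat01
    traces <- t(vapply(seq_along(alpha), function(e)
      cos(2 * pi * freq_hz * times / 1000 - alpha[e]), numeric(length(times))))
    egm <- structure(list(traces = traces, times = times,
                          coords = bk$coords, ids = bk$ids, sigma_b = NA),
                     class = "egm_set")
    list(egm = egm, basket = bk, density = paste0(dd[1], "x", dd[2]))
  })
  names(out) <- vapply(out, function(x) x$density, "")
  list(cases = out, ground_truth = list(),
       params = list(freq_hz = freq_hz, m_lon = m_lon,
                     lat_span_rad = lat_span_rad,
                     duration_ms = duration_ms))
}

#' Nested source masks for the far-field experiment
#'
#' Three nested node sets: the whole tissue; the rotor region plus the
#' top-edge reentry band; and the rotor core only. Masking the sources to
#' the middle set silences the pacing half of the domain, so any basket
#' singularity detected over it is driven purely by far field.
#'
#' @param scenario A `scenario`.
#' @param core_margin_mm Margin around the rotor trajectory for the core
#'   mask (default 5).
#' @param region_margin_mm Margin for the rotor+reentry mask (default 12).
#' @param edge_band_mm Width of the top-edge band included in the middle
#'   mask (default 10).
#' @return List `all`, `rotor_reentry`, `rotor_core` of node indices
#'   (nested).
#' @export
make_farfield_masks <- function(scenario, core_margin_mm = 5,
                                region_margin_mm = 12, edge_band_mm = 10) {
  dom <- scenario$domain
  rt <- scenario$ground_truth$rotor_track
  all_nodes <- which(!dom$obstacle)
  core <- meander_nodes(rt, dom, core_margin_mm)
  region <- union(meander_nodes(rt, dom, region_margin_mm),
                  nodes_in_rect(dom, c(-Inf, Inf),
                                c(dom$size_mm[2] - edge_band_mm, Inf)))
  region <- union(region, core)
  if (!all(core %in% region) || !all(region %in% all_nodes))
    stop("masks are not nested")
  list(all = all_nodes, rotor_reentry = sort(region),
       rotor_core = sort(core))
}

#' Pacing-only control scenario
#'
#' Same cylinder as the standard scenario but without the spiral: only the
#' ectopic pacing train runs, so the tissue carries plane/target waves and
#' no interior phase singularity.
#'
#' @inheritParams standard_scenario
#' @return A `scenario` whose ground truth contains no rotor track.
#' @export
pacing_only_scenario <- function(condition = "cAF", duration_ms = 2000,
                                 circumference_mm = 110, height_mm = 60,
                                 dx = 0.5, D = 0.1,
                                 conductivity_scale = 0.85,
                                 pacing_cl_ms = 110, dt = 0.02, seed = 1,
                                 region = "RA_PM") {
  set.seed(seed)
  dom <- tissue_domain("cylinder", c(circumference_mm, height_mm), dx = dx,
                       region = region, D = D)
  model <- membrane_model(region, condition)
  tr <- pace_cell(model, pacing_protocol(pacing_cl_ms * 2, 10), dt = 0.01)
  states <- matrix(tr$final_state, nrow = 21, ncol = dom$n_nodes)
  pace_nodes <- nodes_in_disk(dom, c(circumference_mm / 4, 4), 2)
  stim <- stimulus(pace_nodes, onset = 20, amplitude = 56, duration = 2,
                   period = pacing_cl_ms,
                   count = ceiling(duration_ms / pacing_cl_ms))
  movie <- run_tissue(dom, condition, list(stim), duration = duration_ms,
                      dt = dt, record_dt = 1, init = states,
                      conductivity_scale = conductivity_scale)
  pm <- phase_movie(movie)
  det <- detect_ps(pm)
  tracks <- track_rotations(track_ps(det, 5, 5), pm)
  structure(list(movie = movie, domain = dom,
                 ground_truth = list(tracks = filter_rotors(tracks, 1),
                                     all_tracks = tracks,
                                     rotor_track = NULL, times = pm$times,
                                     phase = pm),
                 params = list(condition = condition,
                               duration_ms = duration_ms, seed = seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario: %s, %d nodes, %.0f ms, %d rotor-grade track(s)\n",
              x$params$condition, x$domain$n_nodes,
              x$params$duration_ms, length(x$ground_truth$tracks)))
  invisible(x)
}
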