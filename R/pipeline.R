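# End-to-end orchestration: scenario -> electrograms -> basket -> phase ->
# singularity tracking -> classification -> report.

#' Run the full basket-mapping pipeline on a scenario
#'
#' @param scenario A `scenario` from [standard_scenario()] (or
#'   [pacing_only_scenario()]).
#' @param basket A `basket`, either already placed or canonical (then
#'   `placement` selects a preset).
#' @param placement `"near"`, `"mid"` or `"far"` (ignored when `basket`
#'   is already placed, i.e. its centre is nonzero).
#' @param n_projection_points Interpolation grid size (default 57600).
#' @param lo_hz,hi_hz Filter band (default 7-10 Hz).
#' @param trim_ms Edge trim per end (default 500).
#' @param match_threshold_mm,seq_threshold Classification thresholds.
#' @param link_radius_mm Basket-track linking radius (default 4).
#' @param source_mask Optional node indices: restrict the equivalent
#'   sources to this set (far-field experiments).
#' @param sources Optional precomputed `source_field` (skips
#'   recomputation when sweeping placements/densities).
#' @return A `detection_report`.
#' @export
run_pipeline <- function(scenario, basket = build_basket(),
                         placement = "near", n_projection_points = 57600,
                         lo_hz = 7, hi_hz = 10, trim_ms = 500,
                         match_threshold_mm = 10, seq_threshold = 0.8,
                         link_radius_mm = 4, source_mask = NULL,
                         sources = NULL) {
  stopifnot(inherits(scenario, "scenario"), inherits(basket, "basket"))
  if (all(basket$center == 0)) {
    if (is.null(scenario$ground_truth$rotor_track))
      stop("scenario has no rotor track; place the basket explicitly")
    basket <- basket_placements(scenario, basket, placement)[[placement]]
  } else placement <- "custom"

  if (is.null(sources)) sources <- compute_sources(scenario$movie)
  if (!is.null(source_mask)) sources <- mask_sources(sources, source_mask)

  egm <- egm_at_points(sources, basket)
  grid <- projection_grid(basket, n_projection_points)
  bp <- basket_phase_ps(egm, grid, lo_hz, hi_hz, trim_ms)
  tracks <- track_ps(bp$detections, link_radius = link_radius_mm,
                     max_gap_frames = 2)
  tracks <- track_rotations(tracks, bp$electrode_phase)
  rotors <- filter_rotors(tracks, 1)
  classified <- classify_tracks(rotors, scenario$ground_truth$tracks, egm,
                                basket, scenario$domain,
                                match_threshold_mm, seq_threshold)
  pct <- detection_percentages(classified, bp$times)

  dmap <- distance_map(basket, scenario$domain)
  rt <- scenario$ground_truth$rotor_track
  cov <- coverage_metrics(dmap, if (!is.null(rt))
    meander_nodes(rt, scenario$domain) else NULL)

  # trajectory accuracy: the basket track closest (median projected
  # distance) to the ground-truth singularity set stands in for "the
  # detected rotor", whether or not it clears the match threshold --
  # distant placements then report honestly large distances
  traj <- NULL
  gt_tracks <- scenario$ground_truth$tracks
  if (length(gt_tracks) && length(classified)) {
    gt_all <- do.call(rbind, lapply(gt_tracks, function(tr)
      tr$detections))
    gt_union <- structure(list(detections = gt_all), class = "ps_track")
    cand <- lapply(classified, function(ct)
      tryCatch(trajectory_distance(gt_union, ct$track, basket,
                                   scenario$domain),
               error = function(e) NULL))
    usable <- which(vapply(cand, function(td)
      !is.null(td) && td$n_frames >= 10, TRUE))
    if (length(usable)) {
      best <- usable[which.min(vapply(cand[usable], `[[`, 1, "median_mm"))]
      traj <- cand[[best]]
    }
  }

  structure(list(
    percentages = pct, coverage = cov, trajectory = traj,
    classified = classified, n_tracks = length(rotors),
    basket = basket, window_ms = range(bp$times),
    config = list(placement = placement,
                  density = paste0(basket$n_splines, "x",
                                   basket$n_electrodes),
                  n_projection_points = n_projection_points,
                  band_hz = c(lo_hz, hi_hz), trim_ms = trim_ms,
                  match_threshold_mm = match_threshold_mm,
                  seq_threshold = seq_threshold,
                  link_radius_mm = link_radius_mm,
                  masked = !is.null(source_mask),
                  basket_center = basket$center,
                  scenario = scenario$params)),
    class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: %s basket, %s placement%s\n",
              x$config$density, x$config$placement,
              if (x$config$masked) " (masked sources)" else ""))
  cat(sprintf("  TRUE_ROTOR %.1f%%  IMPS %.1f%%  FIPS %.1f%%  (%d tracks)\n",
              x$percentages["TRUE_ROTOR"], x$percentages["IMPS"],
              x$percentages["FIPS"], x$n_tracks))
  if (!is.null(x$trajectory))
    cat(sprintf("  trajectory distance: %.1f / %.1f / %.1f mm (min/med/max)\n",
                x$trajectory$min_mm, x$trajectory$median_mm,
                x$trajectory$max_mm))
  cat(sprintf("  coverage d<=5mm: %.0f%%, 5-10mm: %.0f%%\n",
              x$coverage$tissue_d05, x$coverage$tissue_d10))
  invisible(x)
}

#' Compare detection reports side by side
#'
#' @param reports Named list of `detection_report` (>= 2, same scenario).
#' @return A data.frame: one row per report with placement, density and the
#'   per-label percentages.
#' @export
compare_runs <- function(reports) {
  stopifnot(length(reports) >= 2)
  seeds <- vapply(reports, function(r) r$config$scenario$seed, 1)
  if (length(unique(seeds)) > 1)
    stop("reports come from different scenarios; refusing to compare")
  df <- do.call(rbind, lapply(seq_along(reports), function(k) {
    r <- reports[[k]]
    data.frame(run = if (!is.null(names(reports))) names(reports)[k]
               else as.character(k),
               placement = r$config$placement, density = r$config$density,
               true_rotor_pct = unname(r$percentages["TRUE_ROTOR"]),
               imps_pct = unname(r$percentages["IMPS"]),
               fips_pct = unname(r$percentages["FIPS"]),
               traj_median_mm = if (!is.null(r$trajectory))
                 r$trajectory$median_mm else NA_real_)
  }))
  rownames(df) <- NULL
  df
}

#' Write a detection report as JSON
#'
#' All thresholds and configuration are echoed alongside the metrics.
#'
#' @param report A `detection_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  obj <- list(percentages = as.list(report$percentages),
              coverage = report$coverage,
              trajectory = report$trajectory,
              n_tracks = report$n_tracks,
              window_ms = report$window_ms,
              config = report$config,
              tracks = lapply(report$classified, function(ct)
                list(label = ct$label,
                     match_distance_mm = ct$match_distance_mm,
                     sequential_score = ct$sequential_score,
                     n_frames = ct$track$n_frames,
                     birth_ms = ct$track$birth_ms,
                     death_ms = ct$track$death_ms)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
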