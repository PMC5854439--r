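# Classification of basket-map phase singularities against tissue ground
# truth, and the study's summary metrics.
#
# A detected basket singularity is a TRUE_ROTOR when its (radially
# projected) trajectory stays close to a ground-truth tissue singularity;
# otherwise it is an IMPS (imaginary PS: far-field driven, surrounding
# electrodes still activate sequentially) or a FIPS (false interpolation
# PS: surrounding electrodes do not activate sequentially).

#' Activation times of a unipolar electrogram
#'
#' Activation is marked at the steepest negative deflection (most negative
#' dV/dt), with a refractory separation between detected activations.
#'
#' @param trace Numeric electrogram.
#' @param times Sample times in ms.
#' @param min_separation_ms Minimum spacing between activations (default
#'   60).
#' @param depth_frac Only deflections steeper than `depth_frac` times the
#'   steepest deflection count (default 0.2).
#' @return Activation times in ms (possibly empty).
#' @export
egm_activation_times <- function(trace, times, min_separation_ms = 60,
                                 depth_frac = 0.2) {
  dv <- diff(trace) / diff(times)
  tmid <- (times[-1] + times[-length(times)]) / 2
  thr <- depth_frac * min(dv)
  if (!is.finite(thr) || thr >= 0) return(numeric(0))
  cand <- which(dv < thr)
  if (length(cand) == 0) return(numeric(0))
  ord <- cand[order(dv[cand])]  # steepest first
  taken <- numeric(0)
  for (i in ord) {
    ti <- tmid[i]
    if (all(abs(taken - ti) >= min_separation_ms)) taken <- c(taken, ti)
  }
  sort(taken)
}

# surrounding lattice electrodes of a projection position (lon, lat):
# the 4 corners of the containing cell
surrounding_electrodes <- function(basket, lon, lat) {
  ns <- basket$n_splines; np <- basket$n_electrodes
  uf <- (lon %% (2 * pi)) / (2 * pi) * ns
  s0 <- as.integer(pmin(floor(uf), ns - 1)) + 1L
  s1 <- if (s0 == ns) 1L else s0 + 1L
  k0 <- findInterval(lat, basket$lat, rightmost.closed = TRUE)
  k0 <- pmin(pmax(k0, 1L), np - 1L)
  eid <- function(s, k) (s - 1L) * np + k
  c(eid(s0, k0), eid(s1, k0), eid(s1, k0 + 1L), eid(s0, k0 + 1L))
}

#' Sequential-activation score around a detected singularity
#'
#' For each rotation cycle, the activation times of the electrodes
#' surrounding the singularity are tested for consistency with a single
#' propagating wavefront: either a circular rotation (activation phases
#' strictly monotone around the ring, winding exactly once in either
#' direction, the local-rotor signature) or one sweeping/near-simultaneous
#' front (all delays within 35\% of the cycle, the far-field signature).
#' Interpolation artifacts fail both: their surrounding activations are
#' scattered across the cycle without a consistent order. The score is the
#' fraction of evaluated cycles that are consistent.
#'
#' @param track A `ps_track` from the basket projection (detections carry
#'   longitude/arc-latitude in `x`/`z`).
#' @param egm The raw (unfiltered) `egm_set` at the basket electrodes.
#' @param basket The `basket` geometry.
#' @param cycle_ms Rotation period; default: the track's `mean_cycle_ms`,
#'   falling back to the median inter-activation interval.
#' @return List with `score` (NA when fewer than 3 surrounding electrodes
#'   show activations), `n_cycles`, `electrodes` (ids used).
#' @export
activation_sequence_score <- function(track, egm, basket, cycle_ms = NULL) {
  d <- track$detections
  lon <- atan2(mean(sin(d$x)), mean(cos(d$x))) %% (2 * pi)
  lat <- mean(d$z)
  el <- surrounding_electrodes(basket, lon, lat)
  acts <- lapply(el, function(e)
    egm_activation_times(egm$traces[e, ], egm$times))
  have <- vapply(acts, function(a) length(a) >= 2, TRUE)
  if (sum(have) < 3)
    return(list(score = NA_real_, n_cycles = 0L, electrodes = egm$ids[el]))
  el <- el[have]; acts <- acts[have]

  if (is.null(cycle_ms)) cycle_ms <- track$mean_cycle_ms
  if (is.null(cycle_ms) || !is.finite(cycle_ms)) {
    iai <- unlist(lapply(acts, function(a) diff(a)))
    cycle_ms <- median(iai)
  }
  if (!is.finite(cycle_ms) || cycle_ms <= 0)
    return(list(score = NA_real_, n_cycles = 0L, electrodes = egm$ids[el]))

  # angular order of electrodes around the singularity (projection plane)
  elon <- basket$lon[basket$spline[el]]
  elat <- basket$lat[basket$ring[el]]
  ang <- atan2(elat - lat, wrap_angle(elon - lon))
  ord <- order(ang)
  el <- el[ord]; acts <- acts[ord]

  # cycles anchored on the reference electrode's activations (the
  # surrounding electrode with the most detected activations): for each
  # anchor inside the track's lifetime, every other electrode contributes
  # its activation nearest in time (within half a cycle)
  ref <- which.max(vapply(acts, length, 1L))
  anchors <- acts[[ref]]
  anchors <- anchors[anchors >= track$birth_ms & anchors <= track$death_ms]
  if (length(anchors) == 0)
    return(list(score = NA_real_, n_cycles = 0L, electrodes = egm$ids[el]))
  ok <- 0L; tot <- 0L
  for (tk in anchors) {
    ta <- vapply(seq_along(acts), function(e) {
      if (e == ref) return(0)
      a <- acts[[e]]
      if (length(a) == 0) return(NA_real_)
      d <- a - tk
      d <- d[abs(d) <= cycle_ms / 2]
      if (length(d) == 0) NA_real_ else d[which.min(abs(d))]
    }, 1)
    use <- is.finite(ta)
    if (sum(use) < 3) next
    tot <- tot + 1L
    # (i) circular rotation: activation phases strictly monotone around
    # the ring, winding exactly +-2*pi
    alpha <- 2 * pi * (ta[use] %% cycle_ms) / cycle_ms
    dal <- wrap_angle(diff(c(alpha, alpha[1])))
    tol <- 2 * pi * 0.02
    rotation <- (all(dal > tol) || all(dal < -tol)) &&
      abs(abs(sum(dal)) - 2 * pi) < 1e-6
    # (ii) single sweeping front: all delays within 35% of the cycle
    sweep <- diff(range(ta[use])) <= 0.35 * cycle_ms
    if (rotation || sweep) ok <- ok + 1L
  }
  list(score = if (tot > 0) ok / tot else NA_real_, n_cycles = tot,
       electrodes = egm$ids[el])
}

# project basket-sphere points radially (from the basket centre) onto the
# tissue surface of a cylinder domain
project_to_tissue <- function(pts, basket, dom) {
  if (is.null(dom) || dom$geometry != "cylinder") return(pts)
  Rc <- dom$cylinder_radius
  ctr <- basket$center
  out <- pts
  for (r in seq_len(nrow(pts))) {
    dvec <- pts[r, ] - ctr
    a <- dvec[1]^2 + dvec[2]^2
    if (a < 1e-12) next
    b <- 2 * (ctr[1] * dvec[1] + ctr[2] * dvec[2])
    cc <- ctr[1]^2 + ctr[2]^2 - Rc^2
    s <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
    out[r, ] <- ctr + s * dvec
  }
  out
}

#' Classify basket tracks against tissue ground truth
#'
#' @param tracks Basket `ps_track` list (from [track_ps()] on
#'   [basket_phase_ps()] detections, with rotations filled in).
#' @param gt_tracks Ground-truth `ps_track` list from the tissue phase
#'   movie (the endocardium-analog reference).
#' @param egm Raw `egm_set` at the electrodes (for the sequential-
#'   activation criterion).
#' @param basket The `basket`.
#' @param dom The `tissue_domain` (for radial projection of basket
#'   singularities onto the tissue; optional).
#' @param match_threshold_mm TRUE_ROTOR distance threshold (default 10).
#' @param seq_threshold Sequential-activation score threshold separating
#'   IMPS from FIPS (default 0.8).
#' @return List of `classified_track` objects: `track`, `label`
#'   (TRUE_ROTOR / IMPS / FIPS), `match_distance_mm`, `sequential_score`,
#'   `surrounding_electrodes`, `flagged`.
#' @export
classify_tracks <- function(tracks, gt_tracks, egm, basket, dom = NULL,
                            match_threshold_mm = 10, seq_threshold = 0.8) {
  gt <- if (length(gt_tracks))
    do.call(rbind, lapply(gt_tracks, function(tr)
      tr$detections[, c("t_ms", "X", "Y", "Z")]))
  else NULL
  lapply(tracks, function(tr) {
    d <- tr$detections
    proj <- project_to_tissue(as.matrix(d[, c("X", "Y", "Z")]), basket, dom)
    mdist <- NA_real_
    if (!is.null(gt)) {
      dd <- vapply(seq_len(nrow(d)), function(r) {
        sel <- abs(gt$t_ms - d$t_ms[r]) <= 2.5
        if (!any(sel)) return(NA_real_)
        min(sqrt((gt$X[sel] - proj[r, 1])^2 + (gt$Y[sel] - proj[r, 2])^2 +
                   (gt$Z[sel] - proj[r, 3])^2))
      }, 1)
      if (any(is.finite(dd))) mdist <- median(dd, na.rm = TRUE)
    }
    sq <- activation_sequence_score(tr, egm, basket)
    flagged <- is.na(sq$score)
    label <- if (is.finite(mdist) && mdist <= match_threshold_mm)
      "TRUE_ROTOR"
    else if (!is.na(sq$score) && sq$score >= seq_threshold) "IMPS"
    else "FIPS"
    structure(list(track = tr, label = label, match_distance_mm = mdist,
                   sequential_score = sq$score,
                   surrounding_electrodes = sq$electrodes,
                   flagged = flagged),
              class = "classified_track")
  })
}

#' @export
print.classified_track <- function(x, ...) {
  cat(sprintf("%s: dist %.1f mm, seq score %s, %d frames\n", x$label,
              x$match_distance_mm,
              ifelse(is.na(x$sequential_score), "NA",
                     sprintf("%.2f", x$sequential_score)),
              x$track$n_frames))
  invisible(x)
}

#' Per-label detection percentages over the analysis window
#'
#' For each label, the percentage of window frames in which at least one
#' track of that label is present.
#'
#' @param classified List of `classified_track`.
#' @param window_times Frame times of the trimmed analysis window (ms).
#' @return Named numeric vector (percent) for TRUE_ROTOR, IMPS, FIPS.
#' @export
detection_percentages <- function(classified, window_times) {
  if (length(window_times) == 0) stop("zero-length analysis window")
  labs <- c("TRUE_ROTOR", "IMPS", "FIPS")
  out <- setNames(numeric(3), labs)
  for (lb in labs) {
    tms <- unlist(lapply(classified, function(ct)
      if (ct$label == lb) ct$track$detections$t_ms else NULL))
    out[lb] <- 100 * mean(window_times %in% tms)
  }
  out
}

#' Tissue nodes in the rotor meandering area
#'
#' @param gt_track Ground-truth `ps_track`.
#' @param dom The `tissue_domain`.
#' @param margin_mm Margin added around the trajectory bounding box
#'   (default 2).
#' @return Integer node indices.
#' @export
meander_nodes <- function(gt_track, dom, margin_mm = 2) {
  bb <- gt_track$meander_bbox
  nodes_in_rect(dom, c(bb["xmin"] - margin_mm, bb["xmax"] + margin_mm),
                c(bb["zmin"] - margin_mm, bb["zmax"] + margin_mm))
}

#' Basket coverage metrics
#'
#' Percentage of conducting tissue nodes within 0.5 cm (and 0.5-1 cm) of
#' at least one electrode, overall and restricted to the rotor meandering
#' area.
#'
#' @param dmap A `distance_map`.
#' @param meander Integer node indices of the meandering area (optional).
#' @return Named list of percentages (`tissue_d05`, `tissue_d10`,
#'   `meander_d05`, `meander_d10`; meander entries NA when no meander set
#'   is given or it is empty).
#' @export
coverage_metrics <- function(dmap, meander = NULL) {
  nd <- dmap$node_d
  tis <- which(is.finite(nd))
  res <- list(
    tissue_d05 = 100 * mean(nd[tis] <= 5),
    tissue_d10 = 100 * mean(nd[tis] > 5 & nd[tis] <= 10),
    meander_d05 = NA_real_, meander_d10 = NA_real_)
  if (!is.null(meander) && length(meander) > 0) {
    m <- intersect(meander, tis)
    res$meander_d05 <- 100 * mean(nd[m] <= 5)
    res$meander_d10 <- 100 * mean(nd[m] > 5 & nd[m] <= 10)
  }
  res
}

#' Distance between a true and a detected trajectory
#'
#' Per-frame 3-D distance between the ground-truth tissue singularity and
#' the basket-detected singularity (radially projected onto the tissue
#' surface when `basket` and `dom` are given).
#'
#' @param true_track Ground-truth `ps_track`.
#' @param detected_track Basket `ps_track`.
#' @param basket,dom Optional geometry for radial projection.
#' @return List with `min_mm`, `median_mm`, `max_mm`, `n_frames`.
#' @export
trajectory_distance <- function(true_track, detected_track, basket = NULL,
                                dom = NULL) {
  a <- true_track$detections; b <- detected_track$detections
  bp <- as.matrix(b[, c("X", "Y", "Z")])
  if (!is.null(basket)) bp <- project_to_tissue(bp, basket, dom)
  common <- intersect(round(a$t_ms), round(b$t_ms))
  if (length(common) == 0) stop("tracks have no temporal overlap")
  dd <- vapply(common, function(tm) {
    ia <- which(round(a$t_ms) == tm)
    ib <- which(round(b$t_ms) == tm)
    min(sqrt(outer(a$X[ia], bp[ib, 1], "-")^2 +
               outer(a$Y[ia], bp[ib, 2], "-")^2 +
               outer(a$Z[ia], bp[ib, 3], "-")^2))
  }, 1)
  list(min_mm = min(dd), median_mm = median(dd), max_mm = max(dd),
       n_frames = length(dd))
}
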