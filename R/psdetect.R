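# Phase-singularity detection (per-element topological charge) and
# trajectory tracking.
#
# For each grid plaquette (or polygonal element) the phase differences
# along the oriented boundary are wrapped to (-pi, pi] and summed; the sum
# is an exact multiple of 2*pi, and elements with sum +-2*pi contain a
# phase singularity of that chirality.

wrap_angle <- function(a) a - 2 * pi * floor(a / (2 * pi) + 0.5)

#' Topological charge of polygonal elements
#'
#' @param phase Numeric vector of node phases (radians).
#' @param elements List of integer vectors, each an ordered closed path of
#'   node indices (the first node is implicitly appended at the end).
#' @return Integer vector in {-1, 0, +1} (elements with non-finite phase
#'   are returned as NA).
#' @export
topological_charge <- function(phase, elements) {
  vapply(elements, function(el) {
    if (length(el) < 3) stop("element must have at least 3 nodes")
    p <- phase[el]
    if (any(!is.finite(p))) return(NA_integer_)
    d <- wrap_angle(diff(c(p, p[1])))
    s <- sum(d)
    if (abs(s) > 2 * pi - 1e-6) as.integer(sign(s)) else 0L
  }, integer(1))
}

#' Winding number of phase along an ordered closed path
#'
#' @param phase Node phases.
#' @param path Ordered node indices of the closed path.
#' @return Integer winding number.
#' @export
boundary_winding <- function(phase, path) {
  p <- phase[path]
  d <- wrap_angle(diff(c(p, p[1])))
  as.integer(round(sum(d) / (2 * pi)))
}

#' Detect phase singularities per frame
#'
#' Runs the per-plaquette topological charge on every frame of a phase
#' movie defined on a structured grid (a `tissue_domain` movie or a basket
#' projection). Plaquettes touching non-conducting (obstacle) nodes are
#' skipped.
#'
#' @param pm A `phase_movie` carrying a `domain` (tissue ground truth), or
#'   a projection phase movie from [interpolate_to_projection()].
#' @return A `ps_detections` data.frame with columns `frame` (index),
#'   `t_ms`, `x`, `z` (surface mm or projection coords), `X`, `Y`, `Z`
#'   (3-D mm), `charge`.
#' @export
detect_ps <- function(pm) {
  stopifnot(inherits(pm, "phase_movie"))
  if (!is.null(pm$domain)) {
    dom <- pm$domain
    ph <- pm$phase
    if (any(dom$obstacle)) ph[dom$obstacle, ] <- NA_real_
    M <- grid_ps_cpp(ph, dom$nx, dom$ny, dom$periodic_x)
    if (nrow(M) == 0) return(empty_detections())
    i <- M[, 2]; j <- M[, 3]
    # plaquette centre in surface coordinates (wrap-aware in x)
    xs <- (i + 0.5) * dom$dx
    if (dom$periodic_x) xs <- xs %% dom$size_mm[1]
    zs <- (j + 0.5) * dom$dz
    XYZ <- surf_to_3d(dom, xs, zs)
    out <- data.frame(frame = M[, 1] + 1L, t_ms = pm$times[M[, 1] + 1L],
                      x = xs, z = zs, X = XYZ[, 1], Y = XYZ[, 2],
                      Z = XYZ[, 3], charge = as.integer(M[, 4]))
  } else if (!is.null(pm$projection)) {
    pr <- pm$projection
    M <- grid_ps_cpp(pm$phase, pr$nlon, pr$nlat, TRUE)
    if (nrow(M) == 0) return(empty_detections())
    out <- projection_detections(M, pr, pm$times)
  } else stop("phase movie carries no grid geometry")
  class(out) <- c("ps_detections", "data.frame")
  out
}

empty_detections <- function() {
  out <- data.frame(frame = integer(0), t_ms = numeric(0), x = numeric(0),
                    z = numeric(0), X = numeric(0), Y = numeric(0),
                    Z = numeric(0), charge = integer(0))
  class(out) <- c("ps_detections", "data.frame")
  out
}

surf_to_3d <- function(dom, x, z) {
  if (dom$periodic_x) {
    R <- dom$cylinder_radius
    th <- 2 * pi * x / dom$size_mm[1]
    cbind(R * cos(th), R * sin(th), z)
  } else {
    cbind(x, z, 0)
  }
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour linking with a same-chirality constraint.
#'
#' @param det A `ps_detections` data.frame.
#' @param link_radius Maximum 3-D jump between consecutive detections in mm.
#' @param max_gap_frames Frames a track may skip and still be continued.
#' @return A list of `ps_track` objects (see [track_rotations()] for
#'   rotation counting).
#' @export
track_ps <- function(det, link_radius, max_gap_frames = 2) {
  if (nrow(det) == 0) return(list())
  det <- det[order(det$frame), , drop = FALSE]
  tracks <- list()       # finished + active; each has rows, last_frame
  active <- integer(0)   # indices into tracks
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    # drop stale tracks
    if (length(active)) {
      last <- vapply(active, function(k) tracks[[k]]$last_frame, 1)
      active <- active[f - last <= max_gap_frames + 1]
    }
    used <- logical(length(active))
    for (r in rows) {
      if (length(active)) {
        px <- det$X[r]; py <- det$Y[r]; pz <- det$Z[r]
        dist <- vapply(seq_along(active), function(a) {
          k <- active[a]
          if (used[a] || tracks[[k]]$charge != det$charge[r]) return(Inf)
          q <- tracks[[k]]$last_pos
          sqrt((px - q[1])^2 + (py - q[2])^2 + (pz - q[3])^2)
        }, 1)
        a_best <- which.min(dist)
        if (length(a_best) && is.finite(dist[a_best]) &&
            dist[a_best] <= link_radius) {
          k <- active[a_best]
          tracks[[k]]$rows <- c(tracks[[k]]$rows, r)
          tracks[[k]]$last_frame <- f
          tracks[[k]]$last_pos <- c(px, py, pz)
          used[a_best] <- TRUE
          next
        }
      }
      k <- length(tracks) + 1L
      tracks[[k]] <- list(rows = r, last_frame = f, charge = det$charge[r],
                          last_pos = c(det$X[r], det$Y[r], det$Z[r]))
      active <- c(active, k)
      used <- c(used, TRUE)
    }
  }
  lapply(tracks, function(tr) {
    d <- det[tr$rows, , drop = FALSE]
    structure(list(detections = d, birth_ms = min(d$t_ms),
                   death_ms = max(d$t_ms), chirality = tr$charge,
                   n_frames = nrow(d),
                   meander_bbox = c(xmin = min(d$x), xmax = max(d$x),
                                    zmin = min(d$z), zmax = max(d$z)),
                   rotations = NA_real_),
              class = "ps_track")
  })
}

#' @export
print.ps_track <- function(x, ...) {
  cat(sprintf(
    "ps_track: chirality %+d, %d frames (%.0f..%.0f ms), rotations %s\n",
    x$chirality, x$n_frames, x$birth_ms, x$death_ms,
    ifelse(is.na(x$rotations), "?", sprintf("%.1f", x$rotations))))
  invisible(x)
}

unwrap_phase <- function(p) {
  dp <- wrap_angle(diff(p))
  c(p[1], p[1] + cumsum(dp))
}

#' Count rotations of tracked singularities
#'
#' The rotation count of a track is the total unwrapped phase excursion,
#' divided by 2*pi, of a probe channel a fixed distance from the track's
#' mean position, evaluated over the track's lifetime.
#'
#' @param tracks List of `ps_track`.
#' @param pm The `phase_movie` the detections came from.
#' @param probe_dist_mm Probe offset from the track centre (default 3 grid
#'   elements).
#' @return The tracks with `rotations` and `mean_cycle_ms` filled in.
#' @export
track_rotations <- function(tracks, pm, probe_dist_mm = NULL) {
  coords <- pm$coords
  if (is.null(probe_dist_mm)) {
    probe_dist_mm <- if (!is.null(pm$domain)) 3 * pm$domain$dx else 3
  }
  lapply(tracks, function(tr) {
    ctr <- colMeans(tr$detections[, c("X", "Y", "Z"), drop = FALSE])
    d <- sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2 +
                (coords[, 3] - ctr[3])^2)
    cand <- which(d >= probe_dist_mm)
    probe <- if (length(cand)) cand[which.min(d[cand])] else which.max(d)
    sel <- pm$times >= tr$birth_ms & pm$times <= tr$death_ms
    p <- pm$phase[probe, sel]
    p <- p[is.finite(p)]
    if (length(p) < 2) {
      tr$rotations <- 0
      return(tr)
    }
    u <- unwrap_phase(p)
    tr$rotations <- abs(u[length(u)] - u[1]) / (2 * pi)
    tr$mean_cycle_ms <- if (tr$rotations > 0.5)
      (tr$death_ms - tr$birth_ms) / tr$rotations else NA_real_
    tr
  })
}

#' Keep tracks with at least a minimum number of rotations
#'
#' An excitatory wave pivoting around a singularity for at least one full
#' cycle is the operational definition of a rotor.
#'
#' @param tracks List of `ps_track` (after [track_rotations()]).
#' @param min_rotations Minimum rotation count (default 1).
#' @return Filtered list.
#' @export
filter_rotors <- function(tracks, min_rotations = 1) {
  Filter(function(tr) isTRUE(tr$rotations >= min_rotations), tracks)
}

#' Export tracks as a CSV table
#'
#' Columns `track_id`, `frame_ms`, `x`, `y`, `z`, `charge`.
#'
#' @param tracks List of `ps_track`.
#' @param path Output path (`NULL` returns the data.frame).
#' @export
write_tracks_csv <- function(tracks, path = NULL) {
  rows <- lapply(seq_along(tracks), function(k) {
    d <- tracks[[k]]$detections
    data.frame(track_id = k, frame_ms = d$t_ms, x = d$X, y = d$Y, z = d$Z,
               charge = d$charge)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), frame_ms = numeric(0), x = numeric(0),
               y = numeric(0), z = numeric(0), charge = integer(0))
  if (is.null(path)) return(df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
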