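# Tissue domains and the monodomain reaction-diffusion solver.
#
# Domains are structured quadrilateral grids over a 2-D sheet, an annulus
# (sheet with a central non-conducting hole) or a cylindrical surface
# (periodic in the circumferential direction). Surface coordinates are
# (x, z) in mm with x the arc length around the cylinder; 3-D node
# coordinates are stored for distance computations against the basket.

#' Build a tissue domain
#'
#' @param geometry `"sheet"`, `"annulus"` or `"cylinder"`.
#' @param size_mm For a sheet/annulus: `c(Lx, Ly)` in mm. For a cylinder:
#'   `c(circumference, height)` in mm.
#' @param dx Node spacing in mm (square grid).
#' @param region Either a single region tag applied everywhere, or a
#'   character vector of length `n_nodes`, or a function `f(x, z)` returning
#'   the tag per node (vectorized).
#' @param holes List of non-conducting circular holes, each
#'   `list(center = c(x, z), radius = r)` in surface coordinates (the
#'   annulus geometry adds a central hole automatically via
#'   `hole_radius`).
#' @param hole_radius Radius of the central hole for `geometry = "annulus"`.
#' @param D Isotropic diffusivity in mm^2/ms, or `c(Dx, Dz)` for
#'   axis-aligned anisotropy. This is the equivalent monodomain tensor
#'   lambda/(1+lambda) * D_i expressed as a diffusivity (conductivity over
#'   membrane capacitance per unit area).
#' @param cylinder_radius Optional explicit cylinder radius (default
#'   `circumference / (2*pi)`).
#' @return A `tissue_domain` object.
#' @export
tissue_domain <- function(geometry = c("sheet", "annulus", "cylinder"),
                          size_mm, dx = 0.3, region = "RA_PM",
                          holes = list(), hole_radius = 5,
                          D = 0.1, cylinder_radius = NULL) {
  geometry <- match.arg(geometry)
  if (dx <= 0) stop("dx must be positive")
  stopifnot(length(size_mm) == 2, size_mm[1] > 0, size_mm[2] >= 0)
  periodic_x <- geometry == "cylinder"

  if (periodic_x) {
    nx <- max(3L, as.integer(round(size_mm[1] / dx)))
    xs <- (seq_len(nx) - 1) * (size_mm[1] / nx)  # exact periodic spacing
    dx_x <- size_mm[1] / nx
  } else {
    nx <- as.integer(round(size_mm[1] / dx)) + 1L
    xs <- (seq_len(nx) - 1) * dx
    dx_x <- dx
  }
  ny <- as.integer(round(size_mm[2] / dx)) + 1L
  zs <- (seq_len(ny) - 1) * dx

  grid <- expand.grid(x = xs, z = zs, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)

  if (geometry == "annulus") {
    holes <- c(holes, list(list(center = size_mm / 2, radius = hole_radius)))
  }
  obstacle <- rep(FALSE, n)
  for (h in holes) {
    dxh <- wrap_dx(grid$x - h$center[1], if (periodic_x) size_mm[1] else Inf)
    obstacle <- obstacle | (dxh^2 + (grid$z - h$center[2])^2 <= h$radius^2)
  }

  if (is.function(region)) {
    region <- region(grid$x, grid$z)
  } else if (length(region) == 1L) {
    region <- rep(region, n)
  }
  if (length(region) != n) stop("region must resolve to one tag per node")
  valid <- crn_region_table()$region
  if (!all(region %in% valid))
    stop("unknown region tag(s): ",
         paste(unique(setdiff(region, valid)), collapse = ", "))

  if (length(D) == 1) D <- c(D, D)
  stopifnot(all(D > 0))

  if (periodic_x) {
    R <- if (is.null(cylinder_radius)) size_mm[1] / (2 * pi) else cylinder_radius
    th <- 2 * pi * grid$x / size_mm[1]
    coords <- cbind(R * cos(th), R * sin(th), grid$z)
  } else {
    coords <- cbind(grid$x, grid$z, 0)
  }

  dom <- structure(
    list(geometry = geometry, size_mm = size_mm, dx = dx_x, dz = dx,
         nx = nx, ny = ny, n_nodes = n, periodic_x = periodic_x,
         surf = cbind(x = grid$x, z = grid$z), coords = coords,
         region = region, obstacle = obstacle,
         Dx = rep(D[1], n), Dz = rep(D[2], n),
         cylinder_radius = if (periodic_x) {
           if (is.null(cylinder_radius)) size_mm[1] / (2 * pi)
           else cylinder_radius
         } else NA_real_),
    class = "tissue_domain")
  dom
}

# signed x-difference with periodic wrapping (L = Inf disables wrapping)
wrap_dx <- function(d, L) {
  if (!is.finite(L)) return(d)
  d - L * round(d / L)
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("tissue_domain: %s %gx%g mm, dx %.3g mm, %d nodes (%d blocked)\n",
              x$geometry, x$size_mm[1], x$size_mm[2], x$dx, x$n_nodes,
              sum(x$obstacle)))
  cat("  regions:", paste(unique(x$region), collapse = ", "), "\n")
  invisible(x)
}

# node index (1-based) from grid position i (x), j (z)
node_id <- function(dom, i, j) (j - 1L) * dom$nx + i

#' Select nodes inside a disk (surface coordinates)
#'
#' @param dom A `tissue_domain`.
#' @param center `c(x, z)` in mm.
#' @param radius Radius in mm.
#' @return Integer node indices.
#' @export
nodes_in_disk <- function(dom, center, radius) {
  L <- if (dom$periodic_x) dom$size_mm[1] else Inf
  d2 <- wrap_dx(dom$surf[, "x"] - center[1], L)^2 +
    (dom$surf[, "z"] - center[2])^2
  which(d2 <= radius^2 & !dom$obstacle)
}

#' Select nodes inside an axis-aligned rectangle (surface coordinates)
#'
#' @param dom A `tissue_domain`.
#' @param xlim,zlim Ranges in mm.
#' @return Integer node indices.
#' @export
nodes_in_rect <- function(dom, xlim, zlim) {
  which(dom$surf[, "x"] >= xlim[1] & dom$surf[, "x"] <= xlim[2] &
          dom$surf[, "z"] >= zlim[1] & dom$surf[, "z"] <= zlim[2] &
          !dom$obstacle)
}

# Build the no-flux finite-difference diffusion operator as CSR arrays.
# Face diffusivities are harmonic means of the node values; faces into
# obstacle nodes (or across the boundary) carry zero flux. Units: applied to
# V in mV it returns mV/ms.
build_laplacian <- function(dom, conductivity_scale = 1) {
  nx <- dom$nx; ny <- dom$ny; n <- dom$n_nodes
  Dx <- dom$Dx * conductivity_scale
  Dz <- dom$Dz * conductivity_scale
  obst <- dom$obstacle
  idx2 <- function(i, j) (j - 1L) * nx + i

  ptr <- integer(n + 1L)
  idx <- vector("list", n)
  val <- vector("list", n)
  hm <- function(a, b) 2 * a * b / (a + b)

  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      nd <- idx2(i, j)
      if (obst[nd]) { idx[[nd]] <- integer(0); val[[nd]] <- numeric(0); next }
      nbr <- integer(0); w <- numeric(0)
      # x neighbours (periodic if cylinder)
      for (s in c(-1L, 1L)) {
        ii <- i + s
        if (dom$periodic_x) ii <- ((ii - 1L) %% nx) + 1L
        if (ii >= 1L && ii <= nx) {
          nb <- idx2(ii, j)
          if (!obst[nb]) {
            wf <- hm(Dx[nd], Dx[nb]) / dom$dx^2
            nbr <- c(nbr, nb); w <- c(w, wf)
          }
        }
      }
      # z neighbours
      for (s in c(-1L, 1L)) {
        jj <- j + s
        if (jj >= 1L && jj <= ny) {
          nb <- idx2(i, jj)
          if (!obst[nb]) {
            wf <- hm(Dz[nd], Dz[nb]) / dom$dz^2
            nbr <- c(nbr, nb); w <- c(w, wf)
          }
        }
      }
      idx[[nd]] <- c(nbr, nd)
      val[[nd]] <- c(w, -sum(w))
    }
  }
  lens <- vapply(idx, length, 1L)
  ptr <- c(0L, cumsum(lens))
  list(ptr = as.integer(ptr),
       idx = as.integer(unlist(idx) - 1L),
       val = as.numeric(unlist(val)))
}

#' Define a stimulus event
#'
#' @param nodes Integer node indices receiving the stimulus.
#' @param onset Onset time in ms.
#' @param amplitude Depolarizing amplitude in pA/pF (default 28).
#' @param duration Pulse duration in ms (default 2).
#' @param period Repetition period in ms (0 = one-shot).
#' @param count Number of pulses when periodic (default 1).
#' @return A `stimulus_event`.
#' @export
stimulus <- function(nodes, onset = 0, amplitude = 28, duration = 2,
                     period = 0, count = 1) {
  stopifnot(length(nodes) >= 1, duration > 0, amplitude > 0)
  if (period > 0 && duration >= period)
    stop("stimulus duration must be shorter than its period")
  structure(list(nodes = sort(unique(as.integer(nodes))), onset = onset,
                 amplitude = amplitude, duration = duration,
                 period = period, count = as.integer(count)),
            class = "stimulus_event")
}

# convert stimuli to the (n0, n1, onset, period, duration, count, amplitude)
# row format of the C++ stepper, splitting node sets into contiguous runs
stim_matrix <- function(stimuli) {
  rows <- list()
  for (s in stimuli) {
    nd <- s$nodes - 1L  # 0-based
    breaks <- c(0L, which(diff(nd) != 1L), length(nd))
    for (k in seq_len(length(breaks) - 1L)) {
      run <- nd[(breaks[k] + 1L):breaks[k + 1L]]
      rows[[length(rows) + 1L]] <-
        c(run[1], run[length(run)], s$onset,
          if (s$period > 0) s$period else -1,
          s$duration, if (s$period > 0) s$count else 1L, s$amplitude)
    }
  }
  if (length(rows) == 0) return(matrix(numeric(0), ncol = 7))
  do.call(rbind, rows)
}

# per-node scalar table for the C++ stepper
region_scalars <- function(dom, condition) {
  regs <- unique(dom$region)
  mat <- sapply(regs, function(r) membrane_model(r, condition)$scalars)
  mat <- matrix(mat, nrow = 6, dimnames = list(scalar_names, regs))
  list(idx = as.integer(match(dom$region, regs) - 1L), mat = mat)
}

#' Run a monodomain simulation
#'
#' Operator-split explicit scheme: one Rush-Larsen reaction step followed by
#' one explicit diffusion step per dt. The stability bound
#' `dt <= dx^2 / (2 (Dx + Dz))` is checked.
#'
#' @param dom A `tissue_domain`.
#' @param condition `"control"` or `"cAF"` (per-node membrane models are
#'   chosen by the domain's region map).
#' @param stimuli List of [stimulus()] events.
#' @param duration Simulated time in ms.
#' @param dt Time step in ms (default 0.02).
#' @param record_dt Output cadence in ms (default 1, matching the
#'   electrogram temporal resolution).
#' @param init Initial state: `"rest"` (resting CRN state everywhere),
#'   `"paced"` (single-cell steady state after `init_beats` beats at
#'   `init_bcl`), or a 21 x n_nodes matrix of states.
#' @param conductivity_scale Multiplier on the diffusion tensor (e.g. 0.85
#'   for the chronic-AF gap-junctional remodeling).
#' @param init_bcl,init_beats Pre-pacing protocol for `init = "paced"`.
#' @param t0 Time offset assigned to the first recorded frame.
#' @return A `vm_movie`: list with `frames` (n_nodes x n_frames mV),
#'   `times` (ms), `domain`, `states` (final 21 x n_nodes), `dt`,
#'   `condition`, `conductivity_scale`.
#' @export
run_tissue <- function(dom, condition = "control", stimuli = list(),
                       duration = 1000, dt = 0.02, record_dt = 1,
                       init = "rest", conductivity_scale = 1,
                       init_bcl = 500, init_beats = 20, t0 = 0) {
  stopifnot(inherits(dom, "tissue_domain"))
  dmax <- if (dom$ny == 1L) max(dom$Dx) * conductivity_scale else
    max(dom$Dx + dom$Dz) * conductivity_scale
  dt_max <- dom$dx^2 / (2 * dmax)
  if (dt > dt_max)
    stop(sprintf("dt = %g exceeds the diffusion stability bound %.4g ms",
                 dt, dt_max))
  L <- build_laplacian(dom, conductivity_scale)
  sc <- region_scalars(dom, condition)

  if (is.matrix(init)) {
    stopifnot(nrow(init) == 21, ncol(init) == dom$n_nodes)
    states <- init[, , drop = FALSE]  # copy: the C++ stepper works in place
  } else if (identical(init, "rest")) {
    states <- matrix(crn_initial_state_cpp(), nrow = 21, ncol = dom$n_nodes)
  } else if (identical(init, "paced")) {
    states <- matrix(0, nrow = 21, ncol = dom$n_nodes)
    for (r in unique(dom$region)) {
      m <- membrane_model(r, condition)
      tr <- pace_cell(m, pacing_protocol(init_bcl, init_beats), dt = 0.01)
      states[, dom$region == r] <- tr$final_state
    }
  } else stop("init must be 'rest', 'paced' or a state matrix")

  res <- monodomain_run_cpp(states, L$ptr, L$idx, L$val, sc$idx, sc$mat,
                            stim_matrix(stimuli), duration, dt, record_dt, t0)
  structure(list(frames = res$frames, times = res$times, domain = dom,
                 states = res$states, dt = dt, condition = condition,
                 conductivity_scale = conductivity_scale),
            class = "vm_movie")
}

#' @export
print.vm_movie <- function(x, ...) {
  cat(sprintf("vm_movie: %d nodes x %d frames (%.0f..%.0f ms, %s)\n",
              nrow(x$frames), ncol(x$frames), min(x$times), max(x$times),
              x$condition))
  invisible(x)
}

#' Cross-field S1-S2 stimuli for spiral-wave initiation
#'
#' S1 is a plane wave launched from the low-z edge; S2 is a half-domain
#' rectangle applied when the S1 repolarization tail crosses the domain
#' centre, creating a free phase end that curls into a spiral (a
#' counter-rotating pair on periodic domains).
#'
#' @param dom A `tissue_domain`.
#' @param t_s2 S2 onset time in ms.
#' @param amplitude Stimulus amplitude in pA/pF.
#' @return List of two [stimulus()] events.
#' @export
cross_field_stimuli <- function(dom, t_s2, amplitude = 40) {
  s1 <- stimulus(nodes_in_rect(dom, c(-Inf, Inf), c(-Inf, 2 * dom$dz)),
                 onset = 0, amplitude = amplitude, duration = 2)
  s2 <- stimulus(nodes_in_rect(dom, c(-Inf, dom$size_mm[1] / 2),
                               c(dom$size_mm[2] / 2, Inf)),
                 onset = t_s2, amplitude = amplitude, duration = 2)
  list(s1, s2)
}

#' Measure conduction velocity on a 1-D strand
#'
#' Builds a homogeneous strand, initializes every node from the single-cell
#' steady state at the pacing rate, paces one end, and fits a line to the
#' activation times (upstroke crossing of -40 mV, linearly interpolated)
#' over the central half of the strand on the last beat.
#'
#' @param condition `"control"` or `"cAF"`.
#' @param region Region tag (default RA_PM).
#' @param bcl Pacing cycle length in ms.
#' @param n_beats Beats delivered to the strand (the cell is pre-paced to
#'   steady state first; default 3).
#' @param length_mm Strand length in mm (>= 20).
#' @param dx Node spacing in mm.
#' @param D Diffusivity in mm^2/ms.
#' @param conductivity_scale Multiplier on D (0.85 for cAF gap-junction
#'   remodeling).
#' @param dt Time step in ms.
#' @param init_beats Pre-pacing beats for the single-cell steady state.
#' @return List with `cv_cm_s`, `activation_times`, `positions_mm`,
#'   `r_squared`.
#' @export
measure_cv <- function(condition = "control", region = "RA_PM", bcl = 500,
                       n_beats = 3, length_mm = 30, dx = 0.3, D = 0.1,
                       conductivity_scale = 1, dt = 0.01, init_beats = 120) {
  if (length_mm < 20) stop("strand must be at least 20 mm")
  dom <- tissue_domain("sheet", c(length_mm, 0), dx = dx, region = region,
                       D = D)
  stopifnot(dom$ny == 1L)
  m <- membrane_model(region, condition)
  tr <- pace_cell(m, pacing_protocol(bcl, init_beats), dt = 0.01)
  states <- matrix(tr$final_state, nrow = 21, ncol = dom$n_nodes)
  # stimulated segment scaled with the space constant (source-sink match)
  extent_mm <- max(1.5, 5 * sqrt(D * conductivity_scale))
  stim <- stimulus(which(dom$surf[, "x"] <= extent_mm), onset = 5,
                   amplitude = 28, duration = 2,
                   period = bcl, count = n_beats)
  mov <- run_tissue(dom, condition, list(stim), duration = bcl * n_beats,
                    dt = dt, record_dt = 0.25, init = states,
                    conductivity_scale = conductivity_scale)
  t_last <- 5 + bcl * (n_beats - 1)
  at <- activation_times_vm(mov, threshold = -40, after_ms = t_last - 1)
  x <- dom$surf[, "x"]
  sel <- x >= length_mm * 0.25 & x <= length_mm * 0.75
  if (any(!is.finite(at[sel])))
    stop("conduction block: some strand nodes never activated")
  fit <- lm(at[sel] ~ x[sel])
  slope <- coef(fit)[2]  # ms per mm
  if (!is.finite(slope) || slope <= 0)
    stop("conduction block or retrograde activation on the strand")
  list(cv_cm_s = as.numeric(100 / slope),  # (1/slope) mm/ms = 100/slope cm/s
       activation_times = at, positions_mm = x,
       r_squared = summary(fit)$r.squared)
}

# first upstroke crossing of `threshold` after `after_ms`, per node,
# linearly interpolated between frames; NA if never crossed
activation_times_vm <- function(movie, threshold = -40, after_ms = 0) {
  tt <- movie$times
  f <- movie$frames
  sel <- which(tt >= after_ms)
  at <- rep(NA_real_, nrow(f))
  for (n in seq_len(nrow(f))) {
    v <- f[n, sel]
    k <- which(v[-1] >= threshold & v[-length(v)] < threshold)[1]
    if (!is.na(k)) {
      t1 <- tt[sel[k]]; t2 <- tt[sel[k + 1]]
      v1 <- v[k]; v2 <- v[k + 1]
      at[n] <- t1 + (threshold - v1) / (v2 - v1) * (t2 - t1)
    }
  }
  at
}
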