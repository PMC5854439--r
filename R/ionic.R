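# Cellular electrophysiology: CRN human atrial model, regional variants,
# chronic-AF remodeling, single-cell pacing and APD measurement.

#' Regional conductance scaling table (control conditions)
#'
#' Dimensionless multipliers applied to the baseline CRN maximal conductances
#' of I_to, I_CaL and I_Kr to reproduce the action-potential heterogeneity of
#' nine atrial regions. The RA/PM row is the identity (baseline CRN).
#'
#' @return A data.frame with one row per region and columns `region`,
#'   `g_to`, `g_CaL`, `g_Kr`.
#' @export
crn_region_table <- function() {
  data.frame(
    region = c("RA_PM", "CT_BBRA", "TVR", "RAA", "LA", "BBLA", "MVR",
               "LAA", "PV"),
    g_to  = c(1.00, 1.00, 1.00, 0.68, 1.00, 1.00, 1.00, 0.68, 1.00),
    g_CaL = c(1.00, 1.67, 0.67, 1.00, 1.00, 1.67, 0.67, 1.00, 1.00),
    g_Kr  = c(1.00, 1.00, 1.53, 1.00, 1.60, 1.60, 2.44, 1.60, 2.20),
    stringsAsFactors = FALSE
  )
}

#' Chronic-AF remodeling multipliers
#'
#' Multiplicative changes of five maximal conductances under chronic atrial
#' fibrillation, applied on top of the regional control scalings. Remodeling
#' differs between the right-atrial family of regions (RA_PM, CT_BBRA, TVR,
#' RAA) and the left-atrial family (LA, BBLA, MVR, LAA, PV).
#'
#' @return A data.frame with columns `channel`, `RA`, `LA` holding the
#'   multipliers (e.g. a 45\% reduction is 0.55).
#' @export
caf_remodeling_table <- function() {
  data.frame(
    channel = c("g_to", "g_CaL", "g_K1", "g_Kur", "g_Ks"),
    RA = c(0.55, 0.35, 2.00, 0.40, 2.50),
    LA = c(0.25, 0.35, 2.00, 0.55, 2.00),
    stringsAsFactors = FALSE
  )
}

ra_family <- c("RA_PM", "CT_BBRA", "TVR", "RAA")

# scalar order used by the C++ kernels
scalar_names <- c("g_to", "g_CaL", "g_Kr", "g_K1", "g_Kur", "g_Ks")

#' Build a regional CRN membrane model
#'
#' Composes the regional control conductance scalars with, optionally, the
#' chronic-AF remodeling multipliers (RA-family regions use the RA column of
#' the remodeling table, LA-family regions the LA column).
#'
#' @param region One of `"RA_PM"`, `"CT_BBRA"`, `"TVR"`, `"RAA"`, `"LA"`,
#'   `"BBLA"`, `"MVR"`, `"LAA"`, `"PV"`.
#' @param condition `"control"` or `"cAF"`.
#' @return An object of class `membrane_model`: a list with `region`,
#'   `condition`, `scalars` (named multipliers for g_to, g_CaL, g_Kr, g_K1,
#'   g_Kur, g_Ks), `capacitance_pF` and `state_dim`.
#' @examples
#' m <- membrane_model("RAA", "control")
#' m$scalars[["g_to"]]   # 0.68
#' @export
membrane_model <- function(region = "RA_PM",
                           condition = c("control", "cAF")) {
  tab <- crn_region_table()
  if (length(region) != 1L || !region %in% tab$region) {
    stop("unknown region '", paste(region, collapse = ","),
         "'; valid regions: ", paste(tab$region, collapse = ", "))
  }
  condition <- match.arg(condition)
  row <- tab[tab$region == region, ]
  sc <- c(g_to = row$g_to, g_CaL = row$g_CaL, g_Kr = row$g_Kr,
          g_K1 = 1, g_Kur = 1, g_Ks = 1)
  if (condition == "cAF") {
    rem <- caf_remodeling_table()
    col <- if (region %in% ra_family) rem$RA else rem$LA
    names(col) <- rem$channel
    for (ch in rem$channel) sc[[ch]] <- sc[[ch]] * col[[ch]]
  }
  stopifnot(all(sc > 0))
  structure(
    list(region = region, condition = condition,
         scalars = sc[scalar_names],
         capacitance_pF = 100, state_dim = 21L),
    class = "membrane_model"
  )
}

#' @export
print.membrane_model <- function(x, ...) {
  cat("CRN membrane model -", x$region, "(", x$condition, ")\n")
  cat("  conductance scalars:\n")
  for (nm in names(x$scalars))
    cat(sprintf("    %-6s %.3f\n", nm, x$scalars[[nm]]))
  invisible(x)
}

#' CRN resting initial state
#'
#' The published resting state of the CRN model (V_m = -81.18 mV), used as
#' the starting point of all pacing protocols.
#'
#' @param model Optional `membrane_model` (the resting state is shared).
#' @return Named numeric vector of length 21.
#' @export
crn_initial_state <- function(model = NULL) {
  y <- crn_initial_state_cpp()
  names(y) <- crn_state_names()
  y
}

crn_state_names <- function() {
  c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "fca", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel")
}

#' Evaluate the CRN right-hand side
#'
#' Returns d(state)/dt for a given state, model and stimulus current. The
#' membrane equation is dV_m/dt = -(I_ion + I_stim) with all currents in
#' pA/pF; a depolarizing stimulus of amplitude A is passed as
#' `stim = -A` (inward current convention).
#'
#' @param state Numeric vector of length 21 (see [crn_initial_state()]).
#' @param model A `membrane_model`.
#' @param stim Stimulus current in pA/pF (negative = depolarizing).
#' @return Named numeric vector of derivatives (per ms).
#' @export
crn_derivatives <- function(state, model, stim = 0) {
  stopifnot(inherits(model, "membrane_model"))
  if (any(!is.finite(state))) stop("non-finite value in state")
  dy <- crn_rhs_cpp(as.numeric(state), model$scalars, stim)
  names(dy) <- crn_state_names()
  dy
}

#' Pacing protocol
#'
#' @param bcl Basic cycle length in ms.
#' @param n_beats Number of stimuli.
#' @param stim_amplitude Stimulus amplitude in pA/pF (magnitude of the
#'   depolarizing pulse; default 28).
#' @param stim_duration Pulse duration in ms (default 2).
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(bcl, n_beats, stim_amplitude = 28,
                            stim_duration = 2) {
  stopifnot(n_beats >= 1, stim_duration < bcl, bcl > 0)
  structure(list(bcl = bcl, n_beats = as.integer(n_beats),
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration),
            class = "pacing_protocol")
}

#' @export
print.pacing_protocol <- function(x, ...) {
  cat(sprintf("pacing: %d beats @ BCL %g ms (%g pA/pF, %g ms)\n",
              x$n_beats, x$bcl, x$stim_amplitude, x$stim_duration))
  invisible(x)
}

#' Pace a single cell
#'
#' Integrates the CRN model under a pacing protocol with Rush-Larsen updates
#' for the gating variables and forward Euler for V_m and the
#' concentrations. State is carried across beats; by default only the final
#' cycle (plus a short lead-in) is recorded for APD measurement.
#'
#' @param model A `membrane_model`.
#' @param protocol A `pacing_protocol`.
#' @param dt Time step in ms (default 0.01; must be <= 0.02).
#' @param record_ms Record the last `record_ms` milliseconds (default: last
#'   cycle plus 100 ms). Use `Inf` to record the full run.
#' @param record_dt Recording cadence in ms (default 0.1).
#' @return An `ap_trace`: list with `times` (ms), `vm` (mV), `protocol`,
#'   `model`, `final_state`.
#' @export
pace_cell <- function(model, protocol, dt = 0.01,
                      record_ms = NULL, record_dt = 0.1) {
  stopifnot(inherits(model, "membrane_model"),
            inherits(protocol, "pacing_protocol"))
  if (dt > 0.02) stop("dt must be <= 0.02 ms for the explicit scheme")
  if (is.null(record_ms)) record_ms <- protocol$bcl + 100
  if (!is.finite(record_ms)) record_ms <- -1
  r <- crn_pace_cpp(crn_initial_state_cpp(), model$scalars,
                    protocol$bcl, protocol$n_beats,
                    protocol$stim_amplitude, protocol$stim_duration,
                    dt, record_ms, record_dt)
  stopifnot(length(r$times) == length(r$vm),
            all(diff(r$times) > 0))
  structure(list(times = r$times, vm = r$vm, protocol = protocol,
                 model = model, final_state = r$state),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("ap_trace: %s (%s), %d samples over %.0f ms\n",
              x$model$region, x$model$condition, length(x$times),
              diff(range(x$times))))
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, ...) {
  plot(x$times, x$vm, type = "l", xlab = "time (ms)", ylab = "Vm (mV)", ...)
  invisible(x)
}

#' @export
as.data.frame.ap_trace <- function(x, ...) {
  data.frame(time_ms = x$times, vm_mV = x$vm)
}

#' Measure action-potential duration
#'
#' APD is measured on the last beat of the trace: from the time of maximal
#' upstroke velocity to the time V_m falls below
#' `V_rest + (1 - fraction) * amplitude`, where `amplitude = peak - V_rest`
#' and `V_rest` is V_m just before the final stimulus.
#'
#' @param trace An `ap_trace` (must contain the final stimulated beat).
#' @param fraction Repolarization fraction (0.9 for APD90, 0.95 for APD95).
#' @return Duration in ms.
#' @export
apd <- function(trace, fraction = 0.9) {
  stopifnot(inherits(trace, "ap_trace"), fraction > 0, fraction < 1)
  p <- trace$protocol
  t_stim <- p$bcl * (p$n_beats - 1)
  tt <- trace$times; vm <- trace$vm
  i0 <- which(tt >= t_stim)[1]
  if (is.na(i0))
    stop("trace does not contain the final stimulated beat")
  # rest reference just before the final stimulus (the first sample when
  # the trace starts at the stimulus onset)
  v_rest <- vm[max(i0 - 1, 1)]
  seg <- i0:length(vm)
  peak <- max(vm[seg])
  if (peak < -40)
    stop("no action potential detected (peak ", round(peak, 1),
         " mV < -40 mV)", call. = FALSE)
  amplitude <- peak - v_rest
  dvdt <- diff(vm) / diff(tt)
  iup <- (i0 - 1) + which.max(dvdt[i0:(length(dvdt))])
  t_up <- tt[iup]
  threshold <- v_rest + (1 - fraction) * amplitude
  after <- which(tt > t_up & vm < threshold)
  if (length(after) == 0)
    stop("repolarization to the ", fraction,
         " threshold not reached within the trace")
  i_cross <- after[1]
  # linear interpolation of the crossing time
  t1 <- tt[i_cross - 1]; t2 <- tt[i_cross]
  v1 <- vm[i_cross - 1]; v2 <- vm[i_cross]
  t_cross <- if (v1 == v2) t2 else t1 + (threshold - v1) / (v2 - v1) * (t2 - t1)
  as.numeric(t_cross - t_up)
}

#' Action-potential summary features
#'
#' @param trace An `ap_trace`.
#' @return List with `v_rest`, `peak`, `amplitude`, `max_dvdt` (mV/ms),
#'   `apd90`, `apd95`.
#' @export
ap_features <- function(trace) {
  p <- trace$protocol
  t_stim <- p$bcl * (p$n_beats - 1)
  tt <- trace$times; vm <- trace$vm
  i0 <- which(tt >= t_stim)[1]
  v_rest <- vm[max(i0 - 1, 1)]
  peak <- max(vm[i0:length(vm)])
  dvdt <- diff(vm) / diff(tt)
  list(v_rest = v_rest, peak = peak, amplitude = peak - v_rest,
       max_dvdt = max(dvdt[i0:length(dvdt)]),
       apd90 = apd(trace, 0.90), apd95 = apd(trace, 0.95))
}

#' Serialize a membrane model to YAML
#'
#' Flat key/value text format for provenance.
#'
#' @param model A `membrane_model`.
#' @param path Output file path (`NULL` returns the YAML string).
#' @export
write_model_yaml <- function(model, path = NULL) {
  obj <- list(region = model$region, condition = model$condition,
              capacitance_pF = model$capacitance_pF,
              state_dim = model$state_dim,
              scalars = as.list(model$scalars))
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a membrane model from YAML
#'
#' @param path File written by [write_model_yaml()].
#' @return A `membrane_model`.
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  m <- membrane_model(obj$region, obj$condition)
  stopifnot(all(abs(unlist(obj$scalars)[scalar_names] -
                    m$scalars[scalar_names]) < 1e-9))
  m
}

#' Write an AP trace as CSV
#'
#' Columns `time_ms`, `vm_mV`.
#'
#' @param trace An `ap_trace`.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
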