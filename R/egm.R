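# Unipolar electrogram forward model.
#
# Under equal anisotropy ratios the extracellular potential obeys a Poisson
# equation whose right-hand side is -1/(1+lambda) * div(D_i grad Vm). The
# torso volume conductor is replaced by an infinite homogeneous medium of
# conductivity sigma_b, so the potential at a point p is the free-space
# Green's function sum over equivalent current sources at the cell
# (node) centroids.

#' Equivalent current sources from a membrane-potential movie
#'
#' The per-node source density is computed with the same discrete diffusion
#' operator used by the tissue solver (discrete consistency):
#' `s = -1/lambda * (L Vm)` where `L` encodes the equivalent monodomain
#' tensor `lambda/(1+lambda) * D_i`, which equals the analytic source
#' `-1/(1+lambda) * div(D_i grad Vm)`.
#'
#' @param movie A `vm_movie`.
#' @param lambda Extracellular-to-intracellular anisotropy ratio (default 1).
#' @param thickness_mm Wall thickness assigned to each node's source
#'   element (default 0.75 mm).
#' @return A `source_field`: list with `s` (n_nodes x n_frames), `times`,
#'   `centroids` (3-D mm), `measure` (mm^3), `domain`, `mask` (node subset
#'   currently included).
#' @export
compute_sources <- function(movie, lambda = 1, thickness_mm = 0.75) {
  stopifnot(inherits(movie, "vm_movie"))
  dom <- movie$domain
  L <- build_laplacian(dom, movie$conductivity_scale)
  n <- dom$n_nodes
  # sparse CSR product L %*% Vm for all frames
  s <- csr_mult(L, movie$frames)
  s <- -s / lambda
  structure(list(s = s, times = movie$times, centroids = dom$coords,
                 measure = rep(dom$dx * dom$dz * thickness_mm, n),
                 domain = dom, mask = seq_len(n), lambda = lambda),
            class = "source_field")
}

csr_mult <- function(L, X) {
  n <- length(L$ptr) - 1L
  counts <- diff(L$ptr)
  M <- Matrix::sparseMatrix(i = rep.int(seq_len(n), counts),
                            j = L$idx + 1L, x = L$val, dims = c(n, n))
  as.matrix(M %*% X)
}

#' @export
print.source_field <- function(x, ...) {
  cat(sprintf("source_field: %d sources x %d frames (%d in mask)\n",
              nrow(x$s), ncol(x$s), length(x$mask)))
  invisible(x)
}

#' Restrict sources to a region (far-field masking experiments)
#'
#' Sources outside the mask are zeroed; electrograms computed downstream
#' then contain only the far field of the retained region.
#'
#' @param sources A `source_field`.
#' @param nodes Integer node indices to keep.
#' @return A masked `source_field`.
#' @export
mask_sources <- function(sources, nodes) {
  stopifnot(inherits(sources, "source_field"))
  nodes <- intersect(as.integer(nodes), seq_len(nrow(sources$s)))
  if (length(nodes) == 0) stop("mask resolves to an empty cell set")
  out <- sources
  drop <- setdiff(seq_len(nrow(sources$s)), nodes)
  out$s[drop, ] <- 0
  out$mask <- sort(nodes)
  out
}

#' Unipolar electrograms at arbitrary points
#'
#' `V_e(p, t) = 1/(4 pi sigma_b) * sum_c s_c(t) * measure_c / |p - c|`,
#' the unbounded-medium solution of the extracellular Poisson problem.
#' Distances below `dx/2` are clamped to avoid the kernel singularity.
#'
#' @param sources A `source_field` (see [compute_sources()]).
#' @param points Matrix (n x 3) of electrode coordinates in mm, or a
#'   `basket` object.
#' @param sigma_b Bath conductivity in S/m (default 1; rescales amplitudes
#'   only).
#' @param ids Optional electrode id strings.
#' @return An `egm_set`: list with `traces` (n_electrodes x n_frames, mV
#'   nominal), `times`, `coords`, `ids`, `clamped` (count of clamped
#'   electrode-source pairs).
#' @export
egm_at_points <- function(sources, points, sigma_b = 1, ids = NULL) {
  stopifnot(inherits(sources, "source_field"))
  if (inherits(points, "basket")) {
    ids <- points$ids
    points <- points$coords
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  rmin <- sources$domain$dx / 2
  k <- 1 / (4 * pi * sigma_b)
  G <- egm_gain_cpp(sources$centroids, sources$measure, points, k, rmin)
  traces <- G %*% sources$s
  if (is.null(ids)) ids <- sprintf("e%03d", seq_len(nrow(points)))
  structure(list(traces = traces, times = sources$times, coords = points,
                 ids = ids, sigma_b = sigma_b),
            class = "egm_set")
}

#' @export
print.egm_set <- function(x, ...) {
  cat(sprintf("egm_set: %d electrodes x %d frames (%.0f..%.0f ms)\n",
              nrow(x$traces), ncol(x$traces), min(x$times), max(x$times)))
  invisible(x)
}

#' Root-mean-square amplitude per electrode
#'
#' @param egm An `egm_set`.
#' @return Numeric vector of RMS values (after mean removal).
#' @export
egm_vrms <- function(egm) {
  apply(egm$traces, 1, function(v) sqrt(mean((v - mean(v))^2)))
}

#' Write electrograms as multi-channel CSV
#'
#' Columns `t_ms`, then one column per electrode id.
#'
#' @param egm An `egm_set`.
#' @param path Output path.
#' @export
write_egm_csv <- function(egm, path) {
  df <- data.frame(t_ms = egm$times, t(egm$traces))
  names(df) <- c("t_ms", egm$ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Electrode coordinate table as CSV
#'
#' @param egm An `egm_set` or `basket`.
#' @param path Output path.
#' @export
write_electrode_csv <- function(egm, path) {
  df <- data.frame(id = egm$ids, x_mm = egm$coords[, 1],
                   y_mm = egm$coords[, 2], z_mm = egm$coords[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
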