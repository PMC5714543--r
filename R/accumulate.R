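#' Warp a phase dose onto the reference grid
#'
#' Pull-back dose warping: for each reference voxel centre p, the output is
#' the trilinear sample of the phase-k dose at p + u_k(p), where u_k is the
#' reference-to-phase displacement field. Samples outside the dose-grid
#' extent are 0. This is plain trilinear voxel warping without
#' energy/mass-congruent transfer.
#'
#' @param dose a `scalar_volume` of the phase-k dose.
#' @param field a `displacement_field` (reference -> phase k).
#' @return a `scalar_volume` on the reference geometry.
#' @export
warp_dose <- function(dose, field) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(field, "displacement_field"))
  if (!geometry_equal(dose$geometry, field$geometry))
    stop("dose and field geometries do not match")
  g <- field$geometry
  pts <- voxel_centers(g)
  n <- nrow(pts)
  pts[, 1] <- pts[, 1] + field$u[seq_len(n)]
  pts[, 2] <- pts[, 2] + field$u[n + seq_len(n)]
  pts[, 3] <- pts[, 3] + field$u[2L * n + seq_len(n)]
  vals <- interp_trilinear(dose, pts)
  scalar_volume(g, array(pmax(vals, 0), dim = g$shape), kind = "dose")
}

#' Equal-weight 4D dose accumulation
#'
#' Warps every per-phase dose to the reference phase through its
#' displacement field and averages with the phase time weights (equal
#' weights 1/N by default): D_acc = sum_k w_k * warp(D_k, u_k). Phase 0 is
#' the reference (its field must be identity) and the result lives on the
#' reference geometry.
#'
#' @param doses list of N `scalar_volume` phase doses.
#' @param fields list of N `displacement_field`s (reference -> phase).
#' @param weights optional numeric weights summing to 1 (default rep(1/N)).
#' @param technique provenance tag stored on the result.
#' @return a `scalar_volume` of class `c("accumulated_dose",
#'   "scalar_volume")` with `weights` and `technique` attributes.
#' @export
accumulate_equal_weight <- function(doses, fields, weights = NULL,
                                    technique = "4D") {
  n <- length(doses)
  if (n < 1L) stop("need at least one phase")
  if (length(fields) != n) stop("need one displacement field per phase dose")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("need one weight per phase")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  g <- doses[[1]]$geometry
  acc <- array(0, dim = g$shape)
  for (k in seq_len(n)) {
    w <- warp_dose(doses[[k]], fields[[k]])
    acc <- acc + weights[k] * w$values
  }
  out <- scalar_volume(g, acc, kind = "dose")
  class(out) <- c("accumulated_dose", class(out))
  attr(out, "weights") <- weights
  attr(out, "technique") <- technique
  out
}

#' Select the mid-ventilation phase
#'
#' Returns the phase whose superior-inferior (craniocaudal) tumour centroid
#' best approximates the time-averaged SI position: argmin_k |z_k - mean(z)|.
#' Ties are broken toward the lower phase index.
#'
#' @param traj a [make_trajectory()] trajectory, or a numeric vector of SI
#'   centroid positions per phase.
#' @return 0-based phase index.
#' @export
select_midv_phase <- function(traj) {
  z <- if (inherits(traj, "breathing_trajectory")) traj$offsets[, 3] else as.numeric(traj)
  if (length(z) < 1L) stop("need at least one phase")
  d <- abs(z - mean(z))
  # tolerance so exactly symmetric phases tie toward the lower index
  which(d <= min(d) + 1e-9)[1] - 1L
}
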