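#' Displacement vector field
#'
#' Per-voxel 3-vector (mm) in the pull-back convention: for a reference-phase
#' point p, the corresponding breathing-phase point is p + u(p). External
#' fields supplied in the opposite (push-forward) convention must be
#' inverted before use.
#'
#' @param geometry a [grid_geometry()].
#' @param u numeric 4D array of dim c(shape, 3), mm.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(geometry, u) {
  stopifnot(inherits(geometry, "grid_geometry"))
  u <- as.array(u)
  if (!identical(dim(u), c(as.integer(geometry$shape), 3L)))
    stop("field dimensions must be c(shape, 3)")
  storage.mode(u) <- "double"
  if (!all(is.finite(u))) stop("field values must be finite")
  structure(list(geometry = geometry, u = u), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<displacement_field> |u| range [%g, %g] mm\n", min(mag), max(mag)))
  print(x$geometry)
  invisible(x)
}

#' An identity (zero) displacement field
#' @param geometry a `grid_geometry`.
#' @export
identity_field <- function(geometry) {
  displacement_field(geometry, array(0, dim = c(geometry$shape, 3L)))
}

#' Periodic breathing trajectory (cos^2n model)
#'
#' Tumor centroid offsets over one breathing cycle sampled at N equally
#' time-binned phases, using the classic cos^(2n) respiratory model:
#' offset_k = (A/2) * (2 * cos^(2n)(pi k / N) - 1) per axis, where A is the
#' peak-to-peak amplitude. Phase 0 is the designated end-exhale extreme
#' (offset +A/2) and serves as the accumulation reference; with the default
#' exponent n = 2 (cos^4) the time-averaged position lies off-centre, so the
#' mid-ventilation phase differs from the mid-cycle index.
#'
#' @param amplitude length-3 peak-to-peak amplitude (mm) along (LR, AP, SI).
#' @param n_phases number of phases N (default 10).
#' @param exponent the n of cos^(2n) (default 2).
#' @param period breathing period in seconds (metadata only).
#' @return An object of class `breathing_trajectory` with fields
#'   `offsets` (N-by-3 mm, absolute offsets about the excursion midpoint),
#'   `amplitude`, `n_phases`, `exponent`, `period` and `motion_3d` (the
#'   peak-to-peak Euclidean excursion of the centroid sequence).
#' @examples
#' tr <- make_trajectory(c(0, 0, 10))
#' diff(range(tr$offsets[, 3])) # == 10
#' @export
make_trajectory <- function(amplitude, n_phases = 10L, exponent = 2, period = 4) {
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) == 1L) amplitude <- c(0, 0, amplitude)
  stopifnot(length(amplitude) == 3L)
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  n_phases <- as.integer(n_phases)
  if (n_phases < 2L) stop("need at least 2 phases")
  k <- 0:(n_phases - 1L)
  c_k <- cos(pi * k / n_phases)^(2 * exponent)
  offsets <- outer(2 * c_k - 1, amplitude / 2)
  d <- sweep(offsets, 2, offsets[1, ]) # excursion relative to phase 0
  motion_3d <- {
    # all axes share the time profile, so the excursion is collinear
    mag <- sqrt(rowSums(d^2))
    diff(range(2 * c_k - 1)) / 2 * sqrt(sum(amplitude^2))
  }
  structure(list(offsets = offsets, amplitude = amplitude,
                 n_phases = n_phases, exponent = exponent, period = period,
                 motion_3d = motion_3d),
            class = "breathing_trajectory")
}

#' @export
print.breathing_trajectory <- function(x, ...) {
  cat(sprintf("<breathing_trajectory> N=%d, A=(%g, %g, %g) mm p-p, cos^%d, 3D motion %.1f mm\n",
              x$n_phases, x$amplitude[1], x$amplitude[2], x$amplitude[3],
              2 * x$exponent, x$motion_3d))
  invisible(x)
}

# phase-k displacement of the tumour centroid relative to phase 0
trajectory_deltas <- function(traj) {
  sweep(traj$offsets, 2, traj$offsets[1, ])
}

#' Synthetic thorax phantom specification
#'
#' Describes a simplified thorax: an ellipsoidal body, two ellipsoidal
#' lungs, a spherical tumour (GTV) inside one lung, and cylindrical
#' posterior-medial organs at risk (cord, esophagus, trachea) plus a
#' spherical heart. Defaults are sized so the largest cohort tumour
#' (78 cc) with full breathing motion and PTV margins stays inside the
#' lung and body at every phase.
#'
#' @param geometry grid to rasterize on; default 80 x 64 x 80 voxels at
#'   2.5 mm isotropic spacing (200 x 160 x 200 mm extent).
#' @param gtv_center tumour centre (mm) at the reference (end-exhale) phase.
#' @param gtv_radius tumour radius in mm.
#' @param body_semiaxes,lung_semiaxes,lung_offset_x body/lung ellipsoid
#'   parameters in mm.
#' @param densities named list of relative densities (body, lung, tumor).
#' @param posterior logical flag recording an anterior/posterior lesion
#'   (metadata used for cohort stratification; the dose model is isotropic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = grid_geometry(c(80L, 64L, 80L), spacing = c(2.5, 2.5, 2.5)),
                         gtv_center = c(50, -25, 0), gtv_radius = 10,
                         body_semiaxes = c(100, 80, 100),
                         lung_semiaxes = c(42, 60, 85), lung_offset_x = 50,
                         densities = list(body = 1.0, lung = 0.26, tumor = 1.0),
                         posterior = FALSE) {
  stopifnot(inherits(geometry, "grid_geometry"), gtv_radius > 0)
  spec <- structure(list(geometry = geometry, gtv_center = as.numeric(gtv_center),
                         gtv_radius = gtv_radius,
                         body_semiaxes = as.numeric(body_semiaxes),
                         lung_semiaxes = as.numeric(lung_semiaxes),
                         lung_offset_x = lung_offset_x,
                         densities = densities, posterior = isTRUE(posterior)),
                    class = "phantom_spec")
  lc <- lung_center(spec)
  rel <- abs(spec$gtv_center - lc) + gtv_radius
  if (any(rel > spec$lung_semiaxes))
    stop("GTV does not fit inside the lung ellipsoid")
  spec
}

lung_center <- function(spec) {
  c(sign(spec$gtv_center[1]) * spec$lung_offset_x, 0, 0)
}

# normalized ellipsoid radius of points w.r.t. the body surface
body_rho <- function(spec, pts) {
  sqrt((pts[, 1] / spec$body_semiaxes[1])^2 +
       (pts[, 2] / spec$body_semiaxes[2])^2 +
       (pts[, 3] / spec$body_semiaxes[3])^2)
}

# smoothstep on [0,1]
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# spatial envelope of the motion field: plateau of 1 around the tumour
# (rigid tumour motion), Gaussian decay with sigma = 3 * GTV radius, and a
# smoothstep taper that reaches exactly 0 within the outermost 2% shell of
# the body ellipsoid (static chest wall; boundary voxels never move).
motion_envelope <- function(spec, pts, taper_width = 0.08, edge_gap = 0.02) {
  d <- sqrt((pts[, 1] - spec$gtv_center[1])^2 +
            (pts[, 2] - spec$gtv_center[2])^2 +
            (pts[, 3] - spec$gtv_center[3])^2)
  # the plateau covers the tumour plus the uniform tracking PTV margin, so
  # target and PTV move rigidly and a tracking plan follows them exactly
  plateau <- 1.5 * spec$gtv_radius + 5
  sigma <- 3 * spec$gtv_radius
  g <- exp(-pmax(d - plateau, 0)^2 / (2 * sigma^2))
  g * smoothstep((1 - body_rho(spec, pts) - edge_gap) / taper_width)
}

#' Build a 4D phase set and reference structures from a phantom
#'
#' Generates the N breathing phases of a phantom: per-phase density volume,
#' per-phase displacement field (pull-back, reference phase 0 to phase k)
#' and tumour centroid, with equal time weights 1/N. The displacement field
#' is the phase centroid shift times a smooth spatial envelope (exactly 1
#' in a plateau around the tumour, Gaussian decay with scale 3x the GTV
#' radius, zero at the body surface), so the phase-0 field is identically
#' zero and far tissue is static. Structures are contoured at the reference
#' (end-exhale) phase.
#'
#' @param spec a [phantom_spec()].
#' @param traj a [make_trajectory()] trajectory.
#' @return list with `phases` (class `phase4d_set`: list of N phases, each
#'   with `density`, `field`, `centroid`, `weight`) and `structures`
#'   (a [structure_set()] with GTV, BODY, LUNGS, CORD, ESOPHAGUS, TRACHEA,
#'   HEART at phase 0).
#' @export
make_phase_set <- function(spec, traj) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(traj, "breathing_trajectory"))
  g <- spec$geometry
  deltas <- trajectory_deltas(traj)
  lc <- lung_center(spec)
  # reject tumours that leave the lung (and hence the body) under motion
  for (k in seq_len(traj$n_phases)) {
    ck <- spec$gtv_center + deltas[k, ]
    rel <- abs(ck - lc) + spec$gtv_radius
    if (any(rel > spec$lung_semiaxes))
      stop(sprintf("tumour leaves the lung at phase %d (centroid %.1f, %.1f, %.1f mm)",
                   k - 1L, ck[1], ck[2], ck[3]))
  }
  pts <- voxel_centers(g)
  env <- motion_envelope(spec, pts)
  body <- rasterize_ellipsoid(g, c(0, 0, 0), spec$body_semiaxes)
  lungs_r <- rasterize_ellipsoid(g, c(spec$lung_offset_x, 0, 0), spec$lung_semiaxes)
  lungs_l <- rasterize_ellipsoid(g, c(-spec$lung_offset_x, 0, 0), spec$lung_semiaxes)
  lungs <- binary_mask(g, lungs_r$values | lungs_l$values)
  gtv <- rasterize_sphere(g, spec$gtv_center, spec$gtv_radius)
  zr <- c(-0.8, 0.8) * spec$body_semiaxes[3]
  cord <- rasterize_cylinder(g, c(0, 0.55 * spec$body_semiaxes[2]), 5, zr)
  eso <- rasterize_cylinder(g, c(6, 0.38 * spec$body_semiaxes[2]), 4, zr)
  trach <- rasterize_cylinder(g, c(-6, 0.22 * spec$body_semiaxes[2]), 6,
                              c(0.1, 0.8) * spec$body_semiaxes[3])
  heart <- rasterize_sphere(g, c(-15, -0.15 * spec$body_semiaxes[2],
                                 -0.3 * spec$body_semiaxes[3]), 22)
  structures <- structure_set(list(
    GTV = gtv, BODY = body, LUNGS = lungs, CORD = cord,
    ESOPHAGUS = eso, TRACHEA = trach, HEART = heart))

  base_density <- rep(0, prod(g$shape))
  base_density[body$values] <- spec$densities$body
  base_density[lungs$values] <- spec$densities$lung
  phases <- vector("list", traj$n_phases)
  for (k in seq_len(traj$n_phases)) {
    dk <- deltas[k, ]
    u <- c(dk[1] * env, dk[2] * env, dk[3] * env)
    dim(u) <- c(g$shape, 3L)
    ck <- spec$gtv_center + dk
    d2 <- (pts[, 1] - ck[1])^2 + (pts[, 2] - ck[2])^2 + (pts[, 3] - ck[3])^2
    dens <- base_density
    dens[d2 <= spec$gtv_radius^2] <- spec$densities$tumor
    phases[[k]] <- list(
      density = scalar_volume(g, array(dens, dim = g$shape), kind = "density"),
      field = displacement_field(g, u),
      centroid = ck,
      weight = 1 / traj$n_phases)
  }
  phases <- structure(phases, class = "phase4d_set",
                      trajectory = traj, reference_phase = 0L)
  list(phases = phases, structures = structures)
}

#' @export
print.phase4d_set <- function(x, ...) {
  tr <- attr(x, "trajectory")
  cat(sprintf("<phase4d_set> %d phases, reference phase 0 (end-exhale), 3D motion %.1f mm\n",
              length(x), tr$motion_3d))
  invisible(x)
}
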