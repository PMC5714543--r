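#' Treatment plan specification for the toy dose models
#'
#' Captures the delivery contrast under study: a `"tracking"` technique whose
#' dose cloud follows the moving target (robotic tracking delivery), and a
#' `"fixed"` technique whose dose cloud is static in room coordinates while
#' the anatomy moves through it (gantry-based delivery planned at the
#' mid-ventilation phase). The dose model is an isodose-shaped cloud with a
#' Gaussian penumbra, not a transport calculation: the maximum dose is
#' prescription / (isodose fraction) and the prescription isodose surface
#' coincides with the PTV surface.
#'
#' @param technique `"tracking"` or `"fixed"`.
#' @param prescription_gy total prescription dose in Gy (default 60).
#' @param fractions number of fractions (default 3). The default schedules
#'   are 60 Gy / 3 fx (peripheral) and 48 Gy / 6 fx (central).
#' @param isodose_pct prescription isodose as % of maximum dose; tracking
#'   plans use 62-83%, fixed plans 78-85%.
#' @param penumbra_sigma Gaussian penumbra SD in mm (default 3 tracking,
#'   5 fixed).
#' @param target name of the PTV structure the cloud is shaped to.
#' @param mu_per_gy monitor units per Gy (delivery-efficiency model).
#' @param dose_rate_mu_min machine dose rate in MU/min (600 tracking,
#'   400 fixed).
#' @param scatter_frac fraction of the cloud carried by a broad scatter /
#'   peripheral-dose component (low-density lung widens penumbra and many
#'   crossing beams deposit a dose bath). Both components cross the
#'   prescription isodose at the PTV surface, so coverage normalization is
#'   unaffected. Defaults: 0.25 tracking (many-beam bath), 0.2 fixed.
#' @param scatter_scale width multiplier of the scatter component relative
#'   to `penumbra_sigma` (defaults: 6 tracking, 4 fixed).
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(technique = c("tracking", "fixed"),
                      prescription_gy = 60, fractions = 3L,
                      isodose_pct = NULL, penumbra_sigma = NULL,
                      target = NULL, mu_per_gy = NULL,
                      dose_rate_mu_min = NULL, scatter_frac = NULL,
                      scatter_scale = NULL) {
  technique <- match.arg(technique)
  if (is.null(isodose_pct)) isodose_pct <- if (technique == "tracking") 75 else 80
  if (is.null(penumbra_sigma)) penumbra_sigma <- if (technique == "tracking") 3 else 5
  if (is.null(target)) target <- if (technique == "tracking") "PTV_CK" else "PTV_VMAT"
  if (is.null(mu_per_gy)) mu_per_gy <- if (technique == "tracking") 223 else 60
  if (is.null(dose_rate_mu_min)) dose_rate_mu_min <- if (technique == "tracking") 600 else 400
  if (is.null(scatter_frac)) scatter_frac <- if (technique == "tracking") 0.25 else 0.2
  if (is.null(scatter_scale)) scatter_scale <- if (technique == "tracking") 6 else 4
  stopifnot(prescription_gy > 0, fractions >= 1,
            isodose_pct > 0, isodose_pct <= 100,
            penumbra_sigma > 0, mu_per_gy > 0, dose_rate_mu_min > 0,
            scatter_frac >= 0, scatter_frac < 1, scatter_scale >= 1)
  structure(list(technique = technique, prescription_gy = prescription_gy,
                 fractions = as.integer(fractions), isodose_pct = isodose_pct,
                 penumbra_sigma = penumbra_sigma, target = target,
                 mu_per_gy = mu_per_gy, dose_rate_mu_min = dose_rate_mu_min,
                 scatter_frac = scatter_frac, scatter_scale = scatter_scale),
            class = "plan_spec")
}

#' @export
print.plan_spec <- function(x, ...) {
  cat(sprintf("<plan_spec:%s> %g Gy / %d fx @ %g%% isodose, sigma %g mm, %g MU/Gy\n",
              x$technique, x$prescription_gy, x$fractions, x$isodose_pct,
              x$penumbra_sigma, x$mu_per_gy))
  invisible(x)
}

# shoulder profile: 1 well inside the target, Gaussian falloff outside,
# crossing the prescription isodose fraction exactly at surface distance 0
dose_profile <- function(dist_mm, isodose_frac, sigma) {
  d0 <- sigma * sqrt(2 * log(1 / isodose_frac))
  exp(-pmax(dist_mm + d0, 0)^2 / (2 * sigma^2))
}

# sharp penumbra plus broad scatter component; both cross the isodose
# fraction at distance 0, so the prescription surface stays on the PTV
plan_profile <- function(dist_mm, plan) {
  frac <- plan$isodose_pct / 100
  core <- dose_profile(dist_mm, frac, plan$penumbra_sigma)
  if (plan$scatter_frac <= 0) return(core)
  broad <- dose_profile(dist_mm, frac, plan$scatter_scale * plan$penumbra_sigma)
  (1 - plan$scatter_frac) * core + plan$scatter_frac * broad
}

# volume-equivalent sphere radius of a mask, mm
equivalent_radius_mm <- function(mask) {
  (3 * volume_cc(mask) * 1000 / (4 * pi))^(1 / 3)
}

# covering-sphere radius: max distance of member voxel centres from centroid
covering_radius_mm <- function(mask, center) {
  idx <- which(mask$values, arr.ind = TRUE)
  g <- mask$geometry
  w <- sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  sqrt(max((w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
           (w[, 3] - center[3])^2))
}

mask_centroid <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  g <- mask$geometry
  colMeans(sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+"))
}

# per-axis half-extents of a mask (range of member voxel centres + half voxel)
mask_half_extents <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  g <- mask$geometry
  w <- sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  (apply(w, 2, max) - apply(w, 2, min)) / 2 + g$spacing / 2
}

#' Per-phase dose for a target-tracking plan
#'
#' In each breathing phase the dose cloud is re-centred on the displaced
#' target: dose(p) = D_max * G(distance of p to the displaced PTV surface),
#' with D_max = prescription / isodose fraction and a Gaussian shoulder of
#' SD `penumbra_sigma`, so the prescription isodose surface follows the
#' displaced PTV boundary. The PTV is modelled as its covering sphere (the
#' smallest centroid-centred sphere containing all member voxel centres),
#' so the plan covers the full PTV with the prescription dose by
#' construction, mimicking a plan normalized to the coverage objective.
#'
#' @param phases a `phase4d_set` from [make_phase_set()].
#' @param structures a [structure_set()] containing the plan target
#'   (`PTV_CK` by default).
#' @param plan a [plan_spec()] with `technique = "tracking"`.
#' @return list of N `scalar_volume` dose grids (total physical dose, Gy).
#' @export
paint_dose_tracking <- function(phases, structures, plan) {
  stopifnot(inherits(phases, "phase4d_set"), inherits(plan, "plan_spec"))
  if (plan$technique != "tracking") stop("plan technique must be 'tracking'")
  if (!plan$target %in% names(structures))
    stop("missing target structure '", plan$target, "'")
  ptv <- structures[[plan$target]]
  g <- ptv$geometry
  c0 <- mask_centroid(ptv)
  # covering sphere plus half a voxel of prescription slack: every PTV voxel
  # centre then receives more than the prescription even after the trilinear
  # resampling of the warp step, mimicking a plan normalized to coverage
  r_ptv <- covering_radius_mm(ptv, c0) + max(g$spacing) / 2
  ref_centroid <- phases[[1]]$centroid
  d_max <- plan$prescription_gy / (plan$isodose_pct / 100)
  pts <- voxel_centers(g)
  lapply(phases, function(ph) {
    ck <- c0 + (ph$centroid - ref_centroid)
    d <- sqrt((pts[, 1] - ck[1])^2 + (pts[, 2] - ck[2])^2 +
              (pts[, 3] - ck[3])^2) - r_ptv
    vals <- d_max * plan_profile(d, plan)
    scalar_volume(g, array(vals, dim = g$shape), kind = "dose")
  })
}

#' Per-phase dose for a fixed-geometry plan
#'
#' One static room-coordinate dose cloud is shaped to the PTV at the
#' mid-ventilation phase (an ellipsoid fitted to the mask: centroid plus
#' per-axis half-extents, rescaled so the prescription isodose covers 95%
#' of the PTV voxel centres - the clinical coverage normalization) and the
#' same cloud is evaluated on every phase: the tissue moves through it.
#' The radial penumbra distance is (rho - 1) * r_eq where rho is the
#' normalized ellipsoidal radius and r_eq the geometric-mean semi-axis.
#'
#' @param phases a `phase4d_set`.
#' @param structures a [structure_set()] containing the plan target
#'   (`PTV_VMAT` by default) positioned at the mid-ventilation phase.
#' @param plan a [plan_spec()] with `technique = "fixed"`.
#' @param midv_index 0-based mid-ventilation phase index (provenance).
#' @return list of N `scalar_volume` dose grids (identical clouds).
#' @export
paint_dose_fixed <- function(phases, structures, plan, midv_index = 0L) {
  stopifnot(inherits(phases, "phase4d_set"), inherits(plan, "plan_spec"))
  if (plan$technique != "fixed") stop("plan technique must be 'fixed'")
  if (!plan$target %in% names(structures))
    stop("missing target structure '", plan$target, "'")
  ptv <- structures[[plan$target]]
  g <- ptv$geometry
  ctr <- mask_centroid(ptv)
  ax <- mask_half_extents(ptv)
  # normalize the cloud to the clinical planning objective: scale the
  # prescription isodose ellipsoid so it covers 95% of the PTV voxel centres
  idx <- which(ptv$values, arr.ind = TRUE)
  w <- sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
  rho_mem <- sqrt(((w[, 1] - ctr[1]) / ax[1])^2 +
                  ((w[, 2] - ctr[2]) / ax[2])^2 +
                  ((w[, 3] - ctr[3]) / ax[3])^2)
  ax <- ax * stats::quantile(rho_mem, 0.95, names = FALSE)
  r_eq <- prod(ax)^(1 / 3)
  d_max <- plan$prescription_gy / (plan$isodose_pct / 100)
  pts <- voxel_centers(g)
  rho <- sqrt(((pts[, 1] - ctr[1]) / ax[1])^2 +
              ((pts[, 2] - ctr[2]) / ax[2])^2 +
              ((pts[, 3] - ctr[3]) / ax[3])^2)
  vals <- d_max * plan_profile((rho - 1) * r_eq, plan)
  cloud <- scalar_volume(g, array(vals, dim = g$shape), kind = "dose")
  out <- rep(list(cloud), length(phases))
  attr(out, "midv_index") <- as.integer(midv_index)
  out
}
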