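#' Dose-volume histogram of a structure
#'
#' Exact empirical DVH: the dose samples of all member voxels, unbinned.
#' The cumulative curve V(d) is the fraction of the structure volume
#' receiving at least d; queries interpolate between order statistics.
#'
#' @param dose a `scalar_volume` (Gy).
#' @param mask a non-empty `binary_mask` on the same geometry.
#' @return An object of class `dvh_curve` with sorted (decreasing) dose
#'   samples, the structure volume in cc, and the structure name (taken
#'   from `attr(mask, "name")` if present).
#' @export
dvh <- function(dose, mask) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(mask, "binary_mask"))
  if (!geometry_equal(dose$geometry, mask$geometry))
    stop("dose and mask geometries do not match")
  if (!any(mask$values)) stop("mask is empty: DVH undefined")
  samples <- sort(dose$values[mask$values], decreasing = TRUE)
  structure(list(samples = samples, volume_cc = volume_cc(mask),
                 structure = attr(mask, "name") %||% NA_character_),
            class = "dvh_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d voxels, %.2f cc, dose range [%.2f, %.2f] Gy\n",
              length(x$samples), x$volume_cc,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Dose at volume (Dx%)
#'
#' The largest dose d such that at least x% of the structure volume receives
#' at least d. Computed from the order statistics of the member-voxel doses:
#' with samples sorted decreasing, Dx% is the value at rank x/100 * n,
#' interpolating linearly between adjacent voxel doses at fractional ranks.
#' D99% is the near-minimum, D1% the near-maximum dose.
#'
#' @param curve a [dvh()] curve.
#' @param x volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(curve, x) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.finite(x) || x <= 0 || x > 100) stop("x must be in (0, 100]")
  s <- curve$samples
  n <- length(s)
  r <- x / 100 * n
  if (r <= 1) return(s[1])
  lo <- floor(r); hi <- ceiling(r)
  if (lo == hi) return(s[lo])
  s[lo] + (r - lo) * (s[hi] - s[lo])
}

#' Volume at dose (VxGy / Vx%)
#'
#' Fraction (in %) of the structure volume receiving at least `d` Gy, or the
#' corresponding absolute volume in cc with `absolute = TRUE`.
#'
#' @param curve a [dvh()] curve.
#' @param d dose threshold in Gy (>= 0).
#' @param absolute return cc instead of %.
#' @return percent of structure volume (or cc).
#' @export
volume_at_dose <- function(curve, d, absolute = FALSE) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.finite(d) || d < 0) stop("dose threshold must be >= 0")
  frac <- mean(curve$samples >= d)
  if (absolute) frac * curve$volume_cc else 100 * frac
}

#' New conformity index (nCI)
#'
#' nCI = (PI * PTV) / TVIP^2, where PI is the volume covered by the
#' prescription isodose (restricted to the body, to avoid counting dose in
#' air), PTV the target volume, and TVIP the target volume covered by the
#' prescription isodose. nCI = 1 is ideal; larger values indicate less
#' conformity.
#'
#' @param dose a `scalar_volume`.
#' @param ptv non-empty target `binary_mask`.
#' @param prescription prescription dose in Gy (> 0).
#' @param body optional `binary_mask` restricting the prescription isodose
#'   volume; omit to count the whole grid.
#' @return unitless conformity index.
#' @export
nci <- function(dose, ptv, prescription, body = NULL) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(ptv, "binary_mask"))
  if (prescription <= 0) stop("prescription must be > 0")
  if (!any(ptv$values)) stop("PTV is empty")
  vv <- voxel_volume_mm3(dose$geometry) / 1000
  iso <- dose$values >= prescription
  pi_vox <- if (is.null(body)) iso else iso & body$values
  pi_cc <- sum(pi_vox) * vv
  tvip_cc <- sum(iso & ptv$values) * vv
  if (tvip_cc == 0) stop("prescription isodose does not cover the PTV: nCI undefined")
  ptv_cc <- sum(ptv$values) * vv
  (pi_cc * ptv_cc) / tvip_cc^2
}

#' Convert physical dose to NTD2
#'
#' Normalized total dose in 2 Gy fractions under the linear-quadratic model:
#' with per-fraction dose d = D / fractions,
#' NTD2 = D * (d + alpha/beta) / (2 + alpha/beta). Identity at
#' 2 Gy/fraction; monotone increasing in D for alpha/beta > 0. Used for the
#' lung V20 (NTD2) constraint with alpha/beta = 3 Gy.
#'
#' @param dose a `scalar_volume` of total physical dose (Gy).
#' @param fractions number of fractions (>= 1).
#' @param alpha_beta alpha/beta ratio in Gy (default 3).
#' @return a `scalar_volume` of NTD2 dose.
#' @export
ntd2_volume <- function(dose, fractions, alpha_beta = 3) {
  stopifnot(inherits(dose, "scalar_volume"), fractions >= 1)
  d_fx <- dose$values / fractions
  vals <- dose$values * (d_fx + alpha_beta) / (2 + alpha_beta)
  scalar_volume(dose$geometry, vals, kind = "dose")
}

#' Normal-tissue dose shells
#'
#' Absolute volume (cc) of normal tissue (body minus PTV) receiving at least
#' 80%, 50%, 30% and 10% of the prescription dose.
#'
#' @param dose a `scalar_volume`.
#' @param body,ptv `binary_mask`s on the dose geometry.
#' @param prescription prescription dose in Gy.
#' @param levels percentage levels (default c(80, 50, 30, 10)).
#' @return named numeric vector of cc, names `V80%` etc.
#' @export
normal_tissue_shells <- function(dose, body, ptv, prescription,
                                 levels = c(80, 50, 30, 10)) {
  stopifnot(inherits(dose, "scalar_volume"),
            inherits(body, "binary_mask"), inherits(ptv, "binary_mask"))
  nt <- body$values & !ptv$values
  vv <- voxel_volume_mm3(dose$geometry) / 1000
  out <- vapply(levels, function(L) {
    sum(nt & dose$values >= L / 100 * prescription) * vv
  }, numeric(1))
  names(out) <- sprintf("V%g%%", levels)
  out
}

#' Margin-recipe parameters
#'
#' Error budget for the van Herk nonlinear CTV-to-PTV margin: per-axis
#' systematic SD Sigma (mm), per-axis random SD sigma (mm, excluding
#' breathing), penumbra SD sigma_p (mm), and the breathing-blur coefficient
#' c such that the SD of the breathing position is c times the peak-to-peak
#' amplitude (0.36 for the cos^4 model). Coefficients alpha = 2.5 and
#' beta = 1.64 give 90% minimum-dose coverage for 95% of patients.
#'
#' @param sigma_sys length-3 (or scalar) systematic SD, mm.
#' @param sigma_rand length-3 (or scalar) random SD excluding breathing, mm.
#' @param sigma_p penumbra SD, mm (default 3.2).
#' @param breathing_coef SD of breathing position / peak-to-peak amplitude
#'   (default 0.36).
#' @param alpha,beta recipe coefficients (defaults 2.5 and 1.64).
#' @return An object of class `margin_params`.
#' @export
margin_params <- function(sigma_sys = c(2, 2, 2.5), sigma_rand = c(2, 2, 2),
                          sigma_p = 3.2, breathing_coef = 0.36,
                          alpha = 2.5, beta = 1.64) {
  f3 <- function(x) { x <- as.numeric(x); if (length(x) == 1L) rep(x, 3) else x }
  sigma_sys <- f3(sigma_sys); sigma_rand <- f3(sigma_rand)
  stopifnot(length(sigma_sys) == 3L, length(sigma_rand) == 3L,
            all(sigma_sys >= 0), all(sigma_rand >= 0), sigma_p >= 0,
            breathing_coef >= 0, alpha >= 0, beta >= 0)
  structure(list(sigma_sys = sigma_sys, sigma_rand = sigma_rand,
                 sigma_p = sigma_p, breathing_coef = breathing_coef,
                 alpha = alpha, beta = beta),
            class = "margin_params")
}

#' van Herk nonlinear CTV-to-PTV margin
#'
#' Per axis: sigma_tot^2 = sigma_rand^2 + (c * A)^2 with A the peak-to-peak
#' breathing amplitude, and
#' M = alpha * Sigma + beta * (sqrt(sigma_tot^2 + sigma_p^2) - sigma_p),
#' clamped at >= 0. Breathing enters as a random blur, which makes the
#' margin grow sublinearly with amplitude.
#'
#' @param params a [margin_params()].
#' @param amplitude length-3 (or scalar, taken as SI-only) peak-to-peak
#'   breathing amplitude in mm.
#' @return named numeric length-3 margin (mm) for (LR, AP, SI).
#' @export
van_herk_margin <- function(params, amplitude) {
  stopifnot(inherits(params, "margin_params"))
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) == 1L) amplitude <- c(0, 0, amplitude)
  stopifnot(length(amplitude) == 3L, all(amplitude >= 0))
  s_tot2 <- params$sigma_rand^2 + (params$breathing_coef * amplitude)^2
  m <- params$alpha * params$sigma_sys +
    params$beta * (sqrt(s_tot2 + params$sigma_p^2) - params$sigma_p)
  m <- pmax(m, 0)
  names(m) <- c("LR", "AP", "SI")
  m
}

#' Delivery-efficiency model
#'
#' @param mu_per_gy monitor units per Gy.
#' @param dose_rate_mu_min machine dose rate in MU/min.
#' @param prescription_gy total prescription dose in Gy.
#' @param fractions number of fractions.
#' @return An object of class `delivery_model`.
#' @export
delivery_model <- function(mu_per_gy, dose_rate_mu_min, prescription_gy,
                           fractions = 1L) {
  stopifnot(mu_per_gy >= 0, dose_rate_mu_min > 0, prescription_gy >= 0,
            fractions >= 1)
  structure(list(mu_per_gy = mu_per_gy, dose_rate_mu_min = dose_rate_mu_min,
                 prescription_gy = prescription_gy,
                 fractions = as.integer(fractions)),
            class = "delivery_model")
}

#' Beam-on time of a plan
#'
#' Default relation: (MU per Gy x total prescription dose) / dose rate, in
#' minutes - the relation that reproduces the reference efficiency table
#' (e.g. 167 MU/Gy at 60 Gy and 600 MU/min gives 16.7 min). The literal
#' per-fraction reading (per-fraction MU / dose rate) is available with
#' `per_fraction = TRUE`.
#'
#' @param model a [delivery_model()].
#' @param per_fraction use the per-fraction MU / dose-rate variant.
#' @return minutes.
#' @export
beam_on_time <- function(model, per_fraction = FALSE) {
  stopifnot(inherits(model, "delivery_model"))
  total_mu <- model$mu_per_gy * model$prescription_gy
  if (per_fraction) total_mu <- total_mu / model$fractions
  total_mu / model$dose_rate_mu_min
}

#' Full scalar dosimetric summary of one plan
#'
#' Computes the metrics row used throughout the cohort analysis: nCI, GTV
#' mean dose and D99% (as % of prescription), PTV coverage (V at the
#' prescription dose, %), lung V20Gy on the NTD2-converted dose (%,
#' lung minus PTV), D1% of cord/esophagus/trachea (Gy), normal-tissue
#' V80/50/30/10% shells (cc), MU per Gy and beam-on time.
#'
#' @param dose a `scalar_volume` (total physical dose).
#' @param gtv,ptv,body `binary_mask`s.
#' @param plan a [plan_spec()].
#' @param lungs optional lung mask (lung V20 NTD2 excludes the PTV).
#' @param oars optional named list of OAR masks for D1%.
#' @param label technique/evaluation tag stored in the row.
#' @param nt_exclude mask subtracted from the body to define "normal
#'   tissue" for the Vx% shells; defaults to `ptv`. When plans with
#'   different PTVs are compared on one structure set, pass a common
#'   exclusion volume so the shells are comparable across techniques.
#' @return one-row `data.frame` (a MetricsRecord).
#' @export
compute_metrics <- function(dose, gtv, ptv, body, plan, lungs = NULL,
                            oars = NULL, label = plan$technique,
                            nt_exclude = NULL) {
  presc <- plan$prescription_gy
  if (is.null(nt_exclude)) nt_exclude <- ptv
  gtv_curve <- dvh(dose, gtv)
  ptv_curve <- dvh(dose, ptv)
  shells <- normal_tissue_shells(dose, body, nt_exclude, presc)
  lung_v20 <- NA_real_
  if (!is.null(lungs)) {
    ntd2 <- ntd2_volume(dose, plan$fractions)
    lung_nt <- binary_mask(lungs$geometry, lungs$values & !ptv$values)
    lung_v20 <- volume_at_dose(dvh(ntd2, lung_nt), 20)
  }
  row <- data.frame(
    label = label,
    technique = plan$technique,
    prescription_gy = presc,
    fractions = plan$fractions,
    nci = nci(dose, ptv, presc, body = body),
    gtv_mean_pct = mean(gtv_curve$samples) / presc * 100,
    gtv_d99_pct = dose_at_volume(gtv_curve, 99) / presc * 100,
    ptv_coverage_pct = volume_at_dose(ptv_curve, presc),
    lung_v20_ntd2_pct = lung_v20,
    v80_cc = shells[["V80%"]], v50_cc = shells[["V50%"]],
    v30_cc = shells[["V30%"]], v10_cc = shells[["V10%"]],
    mu_per_gy = plan$mu_per_gy,
    beam_on_min = beam_on_time(delivery_model(plan$mu_per_gy,
                                              plan$dose_rate_mu_min,
                                              presc, plan$fractions)),
    stringsAsFactors = FALSE)
  for (nm in names(oars)) {
    row[[paste0(tolower(nm), "_d1_gy")]] <-
      dose_at_volume(dvh(dose, oars[[nm]]), 1)
  }
  row
}
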