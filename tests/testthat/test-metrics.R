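uniform_curve <- function(d, n = 50) {
  g <- grid_geometry(c(n, 1, 1))
  dvh(scalar_volume(g, array(d, g$shape), "dose"), binary_mask(g, TRUE))
}

ramp_curve <- function() {
  # 100 voxels dosed 1..100 Gy
  g <- grid_geometry(c(100, 1, 1))
  dvh(scalar_volume(g, array(1:100, g$shape), "dose"), binary_mask(g, TRUE))
}

test_that("DVH of uniform and ramp doses matches counting", {
  cu <- uniform_curve(10)
  expect_equal(volume_at_dose(cu, 5), 100)
  expect_equal(volume_at_dose(cu, 10), 100)
  expect_equal(volume_at_dose(cu, 10.0001), 0)
  cr <- ramp_curve()
  expect_equal(volume_at_dose(cr, 20), 81)
  expect_equal(volume_at_dose(cr, 60), 41)
  expect_equal(volume_at_dose(cr, 0), 100)
  g <- grid_geometry(c(4, 4, 4))
  expect_error(dvh(scalar_volume(g, 1, "dose"), binary_mask(g, FALSE)), "empty")
})

test_that("Dx% follows the fractional-rank order-statistic convention", {
  cu <- uniform_curve(12.5)
  for (x in c(1, 37, 99, 100)) expect_equal(dose_at_volume(cu, x), 12.5)
  cr <- ramp_curve()
  expect_equal(dose_at_volume(cr, 99), 2)   # rank 99 of the descending sort
  expect_equal(dose_at_volume(cr, 1), 100)
  expect_gte(dose_at_volume(cr, 1), dose_at_volume(cr, 99))
  expect_error(dose_at_volume(cr, 0), "in \\(0, 100")
  expect_error(dose_at_volume(cr, 101), "in \\(0, 100")
})

test_that("DVH metrics agree with brute-force sort/count oracles on random grids", {
  for (seed in c(41, 42, 43)) {
    v <- random_dose(seed)
    m <- random_mask(v$geometry, seed + 100)
    curve <- dvh(v, m)
    samples <- v$values[m$values]
    for (d in c(0, 10, 35.5, 69)) {
      expect_equal(volume_at_dose(curve, d), 100 * mean(samples >= d))
      expect_equal(volume_at_dose(curve, d, absolute = TRUE),
                   mean(samples >= d) * volume_cc(m))
    }
    s <- sort(samples, decreasing = TRUE)
    n <- length(s)
    for (x in c(1, 25.3, 50, 99)) {
      r <- x / 100 * n
      want <- if (r <= 1) s[1]
              else if (floor(r) == ceiling(r)) s[r]
              else s[floor(r)] + (r - floor(r)) * (s[ceiling(r)] - s[floor(r)])
      expect_equal(dose_at_volume(curve, x), want)
    }
    # cumulative curve is non-increasing
    dd <- seq(0, max(samples) + 1, length.out = 40)
    vv <- vapply(dd, function(d) volume_at_dose(curve, d), numeric(1))
    expect_true(all(diff(vv) <= 0))
  }
})

test_that("nCI reproduces the defining arithmetic and a counting oracle", {
  g <- grid_geometry(c(20, 20, 20), spacing = c(1, 1, 1))
  ptv <- rasterize_sphere(g, c(0, 0, 0), 6)
  # prescription isodose exactly the PTV -> nCI 1
  vals <- array(0, g$shape); vals[ptv$values] <- 50
  d <- scalar_volume(g, vals, "dose")
  expect_equal(nci(d, ptv, 50), 1.0)
  # PI = 2 x PTV with full coverage -> nCI 2 (Eq. arithmetic forced)
  big <- expand_mask(ptv, 2)
  vals2 <- array(0, g$shape); vals2[big$values] <- 50
  pi_cc <- volume_cc(big); ptv_cc <- volume_cc(ptv)
  d2 <- scalar_volume(g, vals2, "dose")
  expect_equal(nci(d2, ptv, 50), (pi_cc * ptv_cc) / ptv_cc^2)
  # random dose: independent voxel-count evaluation
  v <- random_dose(55)
  m <- random_mask(v$geometry, 56)
  body <- binary_mask(v$geometry, TRUE)
  presc <- stats::median(v$values)
  iso <- v$values >= presc
  vv <- voxel_volume_mm3(v$geometry) / 1000
  want <- (sum(iso) * vv * sum(m$values) * vv) / (sum(iso & m$values) * vv)^2
  expect_equal(nci(v, m, presc, body), want, tolerance = 1e-12)
  # undefined when the isodose misses the PTV
  cold <- scalar_volume(g, array(0, g$shape), "dose")
  expect_error(nci(cold, ptv, 50), "undefined")
})

test_that("NTD2 conversion has the right fixed point, values and inverse", {
  g <- grid_geometry(c(2, 2, 2))
  mk <- function(D) scalar_volume(g, array(D, g$shape), "dose")
  # 2 Gy per fraction is the fixed point
  expect_equal(ntd2_volume(mk(20), 10)$values, mk(20)$values)
  # 20 Gy in 3 fractions at alpha/beta 3
  expect_equal(ntd2_volume(mk(20), 3)$values[1], 20 * (20 / 3 + 3) / 5,
               tolerance = 1e-12)
  # quadratic inversion: NTD2 = 20 at 3 fx comes from D = (-9+sqrt(1281))/2
  D <- (-9 + sqrt(1281)) / 2
  expect_equal(ntd2_volume(mk(D), 3)$values[1], 20, tolerance = 1e-9)
  # monotone increasing in D
  expect_true(ntd2_volume(mk(30), 3)$values[1] > ntd2_volume(mk(20), 3)$values[1])
})

test_that("normal-tissue shells count body-minus-PTV voxels at each level", {
  g <- grid_geometry(c(12, 12, 12), spacing = c(2, 2, 2))
  body <- rasterize_sphere(g, c(0, 0, 0), 11)
  ptv <- rasterize_sphere(g, c(0, 0, 0), 4)
  zero <- scalar_volume(g, array(0, g$shape), "dose")
  expect_true(all(normal_tissue_shells(zero, body, ptv, 60) == 0))
  full <- scalar_volume(g, array(60, g$shape), "dose")
  s <- normal_tissue_shells(full, body, ptv, 60)
  expect_true(all(s == volume_cc(body) - volume_cc(ptv)))
  # graded dose: each shell matches direct counting
  v <- random_dose(77)
  b2 <- random_mask(v$geometry, 78, p = 0.8)
  p2 <- random_mask(v$geometry, 79, p = 0.2)
  s2 <- normal_tissue_shells(v, b2, p2, 50)
  vv <- voxel_volume_mm3(v$geometry) / 1000
  for (L in c(80, 50, 30, 10)) {
    want <- sum(b2$values & !p2$values & v$values >= L / 100 * 50) * vv
    expect_equal(s2[[sprintf("V%d%%", L)]], want)
  }
})

test_that("van Herk margin: zero errors give zero, arithmetic case checks out", {
  p0 <- margin_params(sigma_sys = 0, sigma_rand = 0, sigma_p = 3.2)
  expect_equal(unname(van_herk_margin(p0, c(0, 0, 0))), c(0, 0, 0))
  p <- margin_params(sigma_sys = 2, sigma_rand = 2, sigma_p = 3.2)
  m <- van_herk_margin(p, c(0, 0, 0))
  expect_equal(unname(m[3]), 2.5 * 2 + 1.64 * (sqrt(4 + 10.24) - 3.2),
               tolerance = 1e-9)
  expect_equal(unname(m[3]), 5.941, tolerance = 1e-3)
})

test_that("margin grows monotonically and sublinearly with amplitude", {
  p <- margin_params()
  amps <- seq(1, 22.5, by = 0.5)
  si <- vapply(amps, function(a) van_herk_margin(p, c(0, 0, a))[["SI"]],
               numeric(1))
  expect_true(all(diff(si) > 0))
  secant <- (si[length(si)] - si[1]) / (amps[length(amps)] - amps[1])
  expect_lt(secant, 0.5)
})

test_that("beam-on time reproduces the tabulated relation", {
  expect_equal(beam_on_time(delivery_model(167, 600, 60, 3)), 16.7)
  expect_equal(beam_on_time(delivery_model(271, 600, 48, 6)), 21.68)
  expect_equal(beam_on_time(delivery_model(10, 600, 60, 1)), 1.0)
  # literal per-fraction variant divides by the fraction count
  expect_equal(beam_on_time(delivery_model(167, 600, 60, 3), per_fraction = TRUE),
               16.7 / 3)
})

test_that("compute_metrics assembles a consistent record", {
  ph <- small_phantom()
  ps <- make_phase_set(ph, make_trajectory(c(0, 0, 0)))
  st <- ps$structures
  ptv <- expand_mask(st$GTV, 5)
  sa <- structure_set(c(unclass(st), list(PTV_CK = ptv)))
  plan <- plan_spec("tracking")
  dose <- paint_dose_tracking(ps$phases, sa, plan)[[1]]
  row <- compute_metrics(dose, st$GTV, ptv, st$BODY, plan, st$LUNGS,
                         oars = list(CORD = st$CORD))
  expect_equal(row$ptv_coverage_pct, 100)
  expect_gte(row$gtv_d99_pct, 100)
  expect_gte(row$nci, 1)
  expect_true(row$lung_v20_ntd2_pct >= 0 && row$lung_v20_ntd2_pct <= 100)
  expect_true("cord_d1_gy" %in% names(row))
  expect_equal(row$beam_on_min, plan$mu_per_gy * 60 / 600)
})
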