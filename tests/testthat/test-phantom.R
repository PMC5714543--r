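test_that("trajectory offsets have the prescribed peak-to-peak amplitude", {
  tr0 <- make_trajectory(c(0, 0, 0))
  expect_true(all(tr0$offsets == 0))
  tr <- make_trajectory(c(0, 0, 10), n_phases = 10, exponent = 1)
  expect_equal(diff(range(tr$offsets[, 3])), 10)
  expect_equal(tr$offsets[1, 3], 5)   # phase 0 is the exhale extreme
  expect_error(make_trajectory(c(-1, 0, 0)), "amplitude")
  expect_error(make_trajectory(c(0, 0, 5), n_phases = 1), "phases")
})

test_that("cos^4 breathing dwells off-centre: mean offset is negative", {
  tr <- make_trajectory(c(0, 0, 10), exponent = 2)
  expect_lt(mean(tr$offsets[, 3]), 0)
  # and the time-average equals the direct numeric average of the samples
  k <- 0:9
  want <- mean(5 * (2 * cos(pi * k / 10)^4 - 1))
  expect_equal(mean(tr$offsets[, 3]), want)
})

test_that("3D motion is the Euclidean peak-to-peak excursion", {
  tr <- make_trajectory(c(3, 4, 12))
  expect_equal(tr$motion_3d, 13)
})

test_that("mid-ventilation phase selection follows the mean-position rule", {
  expect_equal(select_midv_phase(c(0, 0, 0, 0)), 0)       # tie -> lowest
  expect_equal(select_midv_phase(c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1)), 2)
  tr <- make_trajectory(c(0, 0, 10), n_phases = 10, exponent = 2)
  mid <- select_midv_phase(tr)
  expect_true(mid != 5)                                    # off mid-cycle
  z <- tr$offsets[, 3]
  d <- abs(z - mean(z))
  # argmin up to floating tolerance, ties broken toward the lower index
  expect_equal(mid, min(which(d <= min(d) + 1e-9)) - 1L)
  expect_lte(d[mid + 1], min(d) + 1e-9)
})

test_that("zero-amplitude phase set is static with identity fields", {
  ph <- small_phantom()
  ps <- make_phase_set(ph, make_trajectory(c(0, 0, 0)))
  expect_length(ps$phases, 10)
  expect_true(all(vapply(ps$phases, function(p) all(p$field$u == 0), logical(1))))
  expect_equal(ps$phases[[1]]$density$values, ps$phases[[6]]$density$values)
  w <- vapply(ps$phases, `[[`, numeric(1), "weight")
  expect_equal(sum(w), 1)
  expect_true(all(w == w[1]))
})

test_that("displacement fields move the tumour centroid along the trajectory", {
  ph <- small_phantom()
  tr <- make_trajectory(c(0, 0, 20))
  ps <- make_phase_set(ph, tr)
  deltas <- sweep(tr$offsets, 2, tr$offsets[1, ])
  # phase-0 field is identity
  expect_true(all(ps$phases[[1]]$field$u == 0))
  for (k in c(3, 6)) {
    u <- ps$phases[[k]]$field
    # sample the field at the reference centroid voxel
    idx <- round((ph$gtv_center - u$geometry$origin) / u$geometry$spacing) + 1
    uvec <- u$u[idx[1], idx[2], idx[3], ]
    expect_equal(unname(uvec), deltas[k, ], tolerance = 1e-9)
    expect_equal(ps$phases[[k]]$centroid, ph$gtv_center + deltas[k, ])
  }
  # field magnitude vanishes at the body surface (outermost 2% shell)
  body <- rasterize_ellipsoid(ps$phases[[6]]$field$geometry, c(0, 0, 0),
                              ph$body_semiaxes)
  edge <- body$values & !rasterize_ellipsoid(ps$phases[[6]]$field$geometry,
                                             c(0, 0, 0),
                                             ph$body_semiaxes * 0.98)$values
  expect_gt(sum(edge), 0)
  u6 <- ps$phases[[6]]$field$u
  mag <- sqrt(u6[, , , 1]^2 + u6[, , , 2]^2 + u6[, , , 3]^2)
  expect_lt(max(mag[edge]), 0.01)
})

test_that("a tumour that leaves the lung under motion is rejected", {
  ph <- small_phantom(gtv_radius = 12)
  expect_error(make_phase_set(ph, make_trajectory(c(0, 0, 90))), "leaves the lung")
})

test_that("tracking doses follow the target; static plans do not", {
  ph <- small_phantom()
  tr <- make_trajectory(c(0, 0, 16))
  ps <- make_phase_set(ph, tr)
  st <- ps$structures
  ptv_ck <- expand_mask(st$GTV, 5)
  sa <- structure_set(c(unclass(st), list(PTV_CK = ptv_ck)))
  plan <- plan_spec("tracking")
  doses <- paint_dose_tracking(ps$phases, sa, plan)
  d_max <- plan$prescription_gy / (plan$isodose_pct / 100)
  for (k in c(1, 4, 6)) {
    ck <- ps$phases[[k]]$centroid
    val <- interp_trilinear(doses[[k]], matrix(ck, 1))
    expect_equal(val, d_max, tolerance = 0.01) # D_max at displaced centroid
  }
  # static trajectory: all phase doses identical
  ps0 <- make_phase_set(ph, make_trajectory(c(0, 0, 0)))
  d0 <- paint_dose_tracking(ps0$phases, sa, plan)
  expect_equal(d0[[1]]$values, d0[[7]]$values)
  expect_error(paint_dose_tracking(ps$phases, st, plan), "PTV_CK")
})

test_that("fixed clouds stay in room coordinates while the target moves", {
  ph <- small_phantom()
  plan <- plan_spec("fixed")
  sweep_doses <- function(amp) {
    tr <- make_trajectory(c(0, 0, amp))
    ps <- make_phase_set(ph, tr)
    st <- ps$structures
    midv <- select_midv_phase(tr)
    deltas <- sweep(tr$offsets, 2, tr$offsets[1, ])
    gm <- rasterize_sphere(st$GTV$geometry, ph$gtv_center + deltas[midv + 1, ],
                           ph$gtv_radius)
    pv <- expand_mask(gm, van_herk_margin(margin_params(), tr$amplitude))
    sa <- structure_set(c(unclass(st), list(PTV_VMAT = pv)))
    doses <- paint_dose_fixed(ps$phases, sa, plan, midv)
    # dose at the phase-farthest-from-midv GTV centroid
    far <- which.max(abs(deltas[, 3] - deltas[midv + 1, 3]))
    list(doses = doses,
         at_far = interp_trilinear(doses[[far]],
                                   matrix(ph$gtv_center + deltas[far, ], 1)))
  }
  s0 <- sweep_doses(0)
  expect_equal(s0$doses[[1]]$values, s0$doses[[5]]$values) # static cloud
  s20 <- sweep_doses(20)
  # fixed cloud: dose at the displaced centroid drops as amplitude grows
  expect_lt(s20$at_far, s0$at_far)
  ps <- make_phase_set(ph, make_trajectory(c(0, 0, 5)))
  expect_error(paint_dose_fixed(ps$phases, ps$structures, plan, 0), "PTV_VMAT")
})

test_that("the mid-ventilation fixed plan covers 95% of its PTV by construction", {
  ph <- small_phantom()
  tr <- make_trajectory(c(1, 1, 12))
  ps <- make_phase_set(ph, tr)
  st <- ps$structures
  midv <- select_midv_phase(tr)
  deltas <- sweep(tr$offsets, 2, tr$offsets[1, ])
  gm <- rasterize_sphere(st$GTV$geometry, ph$gtv_center + deltas[midv + 1, ],
                         ph$gtv_radius)
  pv <- expand_mask(gm, van_herk_margin(margin_params(), tr$amplitude))
  sa <- structure_set(c(unclass(st), list(PTV_VMAT = pv)))
  doses <- paint_dose_fixed(ps$phases, sa, plan_spec("fixed"), midv)
  cov <- volume_at_dose(dvh(doses[[midv + 1]], pv), 60)
  expect_gte(cov, 94)
  expect_lte(cov, 100)
})

test_that("cohort sampling is deterministic and respects its ranges", {
  spec <- cohort_spec(n_patients = 14, seed = 3)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)
  expect_length(a, 14)
  # growing the cohort must not reshuffle earlier patients
  big <- sample_cohort(cohort_spec(n_patients = 20, seed = 3))
  expect_identical(big[seq_len(14)], a)
  vols <- vapply(a, function(p) 4 / 3 * pi * p$phantom$gtv_radius^3 / 1000,
                 numeric(1))
  mot <- vapply(a, function(p) p$trajectory$motion_3d, numeric(1))
  expect_true(all(vols >= 0.6 - 1e-6 & vols <= 77.9 + 1e-6))
  expect_true(all(mot >= 2.1 - 1e-6 & mot <= 22.8 + 1e-6))
  expect_error(sample_cohort(cohort_spec(n_patients = 0)), "positive")
  # empirical extremes over a larger draw approach the bounds
  many <- sample_cohort(cohort_spec(n_patients = 200, seed = 9))
  mot200 <- vapply(many, function(p) p$trajectory$motion_3d, numeric(1))
  vol200 <- vapply(many, function(p) 4 / 3 * pi * p$phantom$gtv_radius^3 / 1000,
                   numeric(1))
  expect_lt(min(mot200), 4); expect_gt(max(mot200), 19)
  expect_lt(min(vol200), 2); expect_gt(max(vol200), 40)
})
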