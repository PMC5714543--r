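# dose4d

Four-dimensional (4D) dose accumulation and plan evaluation for moving lung
targets in stereotactic body radiotherapy (SBRT).

## The problem

A free-breathing lung tumour can move more than 2 cm per breathing cycle.
Two clinical strategies deal with this very differently: **real-time
tracking** (robotic delivery) follows the tumour and gets away with a small
uniform GTV-to-PTV margin, while **fixed-beam-geometry** delivery
(gantry/VMAT) plans on the **mid-ventilation** (MidV) phase — the CT phase
closest to the time-averaged tumour position — with a per-patient **van
Herk margin**, and its static dose cloud is smeared over the breathing
cycle. Comparing the two fairly requires 4D dose evaluation: warp each
breathing phase's dose to a common end-exhale reference through
displacement vector fields and average with equal time weights,

    D_4D(p) = (1/N) * sum_k D_k(p + u_k(p)),        N = 10 phases,

then compare DVH metrics of the *accumulated* distributions with paired
nonparametric statistics. `dose4d` implements that pipeline end to end for
medical-physics research use: a raster data model (volumes, masks,
displacement fields, NIfTI I/O), deformable dose warping and equal-weight
accumulation, MidV selection, the van Herk nonlinear margin recipe with a
breathing-amplitude blur term, DVH/Dx%/Vx metrics, the new conformity
index nCI = (PI × PTV) / TVIP², NTD2 conversion, normal-tissue dose
shells, MU/beam-on-time delivery models, exact paired Wilcoxon signed-rank
and Spearman rank tests, and a synthetic 4D breathing phantom cohort that
provides ground truth for all of it.

## Worked example

```r
library(dose4d)

# one synthetic patient: 10-phase breathing phantom, 12 mm SI motion
phantom <- phantom_spec(gtv_radius = 10)           # ~4.2 cc GTV
traj    <- make_trajectory(c(2, 1, 12))            # LR/AP/SI peak-to-peak, mm
ps      <- make_phase_set(phantom, traj)

select_midv_phase(traj)
#> [1] 2                       # cos^4 breathing: MidV is off mid-cycle

van_herk_margin(margin_params(), traj$amplitude)
#>        LR        AP        SI
#>  6.052333  5.968790 10.409141  # mm, grows sublinearly with amplitude

# tracking plan: dose cloud follows the target
st   <- ps$structures
ptv  <- expand_mask(st$GTV, 5)
plans <- structure_set(c(unclass(st), list(PTV_CK = ptv)))
doses  <- paint_dose_tracking(ps$phases, plans, plan_spec("tracking"))
fields <- lapply(ps$phases, `[[`, "field")
acc    <- accumulate_equal_weight(doses, fields)

volume_at_dose(dvh(acc, ptv), 60)   # PTV V60Gy after accumulation
#> [1] 100
nci(acc, ptv, 60, st$BODY)          # conformity (1 = ideal)
#> [1] 1.260417

# full 14-patient cohort comparison (~1 min)
report <- run_pipeline(run_config(n_patients = 14, seed = 1))
report$correlations
#>   metric        rho      p_value  n
#> 1 v80_cc -0.6131868 1.970633e-02 14
#> 2 v50_cc -0.5516484 4.084906e-02 14
#> 3 v30_cc -0.5736264 3.197081e-02 14
#> 4 v10_cc -0.8725275 4.680621e-05 14
```

The correlations are the study's key cohort-level result in miniature: the
larger a tumour's 3D motion, the more the fixed-geometry technique's
margin-driven normal-tissue irradiation exceeds the tracking technique's
(negative Spearman rho between motion and the tracking-minus-fixed
V80/50/30 shell differences). `report$metrics` holds one row per patient ×
technique × {3D, 4D} evaluation; `report$tests` the paired exact Wilcoxon
results.

A packaged reference cohort (tumour characteristics and delivery
efficiency of 14 clinical lung SBRT patients) anchors the arithmetic side:

```r
reference_table_summary()[c("ck_mu_mean_60gy", "vmat_mu_mean_60gy",
                            "ptv_diff_mean_cc")]
#> $ck_mu_mean_60gy
#> [1] 222.5833
#> $vmat_mu_mean_60gy
#> [1] 56.41667
#> $ptv_diff_mean_cc
#> [1] 18.7
```

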