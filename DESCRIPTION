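Package: dose4d
Title: Four-Dimensional Dose Accumulation and Plan Evaluation for Moving
    Lung Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-dimensional (4D) dosimetric evaluation of
    stereotactic body radiotherapy of moving lung tumors. Provides a raster
    data model for dose grids, binary structure masks and displacement
    vector fields; deformable dose warping and equal-weight 4D dose
    accumulation onto an end-exhale reference phase; mid-ventilation phase
    selection; the van Herk nonlinear CTV-to-PTV margin recipe with a
    breathing-amplitude blur term; dose-volume histogram metrics (Dx%, Vx,
    new conformity index, NTD2 conversion, normal-tissue dose shells,
    monitor-unit and beam-on-time models); exact paired Wilcoxon
    signed-rank and Spearman rank statistics for cohort comparison; and a
    synthetic 4D breathing phantom generator that emulates a
    tracking-delivery versus fixed-beam-geometry contrast on a 14-patient
    lung SBRT cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
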