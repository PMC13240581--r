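Package: igsched
Title: Evaluation of CBCT Image-Guidance Schedules in Radiotherapy by Dose
    Accumulation and Radiobiological Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates cone-beam CT (CBCT) image-guidance
    schedules for fractionated radiotherapy, with left-sided postmastectomy
    chest-wall irradiation as the reference scenario. Provides a seeded
    synthetic cohort generator (phantom anatomy, planned dose with sigmoid
    penumbra, per-fraction setup errors and rigid-shift dose emulation),
    schedule-conditional dose accumulation over pre- and post-correction
    fraction doses, cumulative dose-volume histogram (DVH) construction with
    D95/Dmean/Dmax metrics, linear-quadratic Poisson tumour control
    probability (TCP) and Lyman-Kutcher-Burman normal tissue complication
    probability (NTCP) with EQD2 conversion, cumulative imaging-dose and
    imaging-cost accounting linear in imaging frequency, and cohort-level
    statistics (Friedman test, Bonferroni-corrected paired t-tests,
    deviation-versus-daily-guidance tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
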