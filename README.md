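# igsched

How often should a radiotherapy patient be imaged? Daily cone-beam CT (CBCT)
before each fraction corrects setup error almost completely, but every scan
adds imaging dose to nearby organs and a direct fee. `igsched` evaluates this
trade-off for fractionated courses — the reference scenario is left-sided
postmastectomy chest-wall VMAT, 50 Gy in 25 fractions — across six
image-guidance (IG) schedules: `NIG` (first fraction only), `WIG` (weekly),
`TIG` (twice weekly), `THRIG` (thrice weekly), `3D+WIG` (first three days
then weekly) and `DIG` (daily), with imaging frequencies F = 1, 5, 10, 15, 7
and 25.

The package provides, as composable R functions:

- a **seeded synthetic cohort generator**: phantom anatomy (chest-wall and
  supraclavicular targets, heart, ipsilateral lung, contralateral breast), a
  planned dose with sigmoid penumbra, per-fraction rigid setup errors
  (systematic + random before correction, small residual after), and
  per-fraction delivered doses by rigid resampling of the plan;
- **schedule-conditional dose accumulation**: imaged fractions contribute
  their post-correction dose, unimaged fractions their pre-correction dose;
- a **DVH engine** (cumulative DVHs, D95 / Dmean / Dmax);
- **radiobiological models** on EQD2-converted DVHs — Poisson
  linear-quadratic TCP in the Källman form
  `P(D) = 2^(-exp(e·γ·(1 - D/TCD50)))` combined as a volume-weighted
  product, and Lyman–Kutcher–Burman NTCP
  `Φ((gEUD - TD50)/(m·TD50))` with `gEUD = (Σ vᵢ Dᵢ^(1/n))ⁿ`;
- **imaging dose and cost accounting**, exactly linear in frequency:
  `D_cum = D_single · F`, `C_total = C_single · F`;
- **cohort statistics**: Friedman omnibus test, all 15 Bonferroni-corrected
  paired t-tests, Shapiro–Wilk caveat flags, and per-schedule percent
  deviation from a reference schedule (default `DIG`).

## Worked example

Evaluate a 10-patient synthetic cohort on a 24³ grid (4 mm voxels) under all
six schedules:

```r
library(igsched)

cfg <- cohort_config(n_patients = 10, grid_shape = 24, voxel_spacing = 4,
                     seed = 7)
records <- evaluate_cohort(cfg)      # 60 rows: patient x schedule

aggregate(records[c("D95_PTVcw", "TCP_PTVcw")],
          by = list(schedule = records$schedule), mean)
deviation_vs_reference(records, "D95_PTVcw")
compare_schedules(records, "D95_PTVcw")
exposure_report(default_schedules())
```

which prints (cohort means first):

```
 schedule D95_PTVcw TCP_PTVcw
      NIG     42.80    0.7322
      WIG     43.83    0.7506
      TIG     45.22    0.7691
    THRIG     46.75    0.7902
   3D+WIG     44.44    0.7582
      DIG     49.31    0.8148

 schedule    metric mean_pct_dev sd_pct_dev n_patients
      NIG D95_PTVcw        13.21       7.85         10
    THRIG D95_PTVcw         5.20       2.71         10
      DIG D95_PTVcw         0.00       0.00         10   (other rows omitted)

schedule comparison for D95_PTVcw
  Friedman chi-sq = 47.951, df = 5, p = 3.634e-09
  pairwise (Bonferroni, 15 pairs): 11 significant at alpha = 0.05
  caveat: Shapiro-Wilk rejects normality for NIG, WIG, TIG, 3D+WIG

 schedule  F dose_lung_ipsi_mGy dose_breast_contra_mGy cost pct_of_reference
      NIG  1               2.85                   1.26  288                4
      WIG  5              14.25                   6.30 1440               20
      TIG 10              28.50                  12.60 2880               40
    THRIG 15              42.75                  18.90 4320               60
   3D+WIG  7              19.95                   8.82 2016               28
      DIG 25              71.25                  31.50 7200              100
```

Reading this: target coverage (D95) and tumour control probability improve
monotonically with imaging frequency — daily imaging is best, imaging only
the first fraction worst, thrice-weekly in between — while cumulative
imaging dose and direct cost grow linearly with F, so `THRIG` delivers most
of the coverage benefit at 60% of the daily schedule's imaging dose and
cost. Absolute magnitudes are properties of the synthetic cohort (setup
errors 3/3/1 mm systematic/random/residual by default), not of any clinic.

A file-based workflow is available for larger runs and external data:

```r
cmd_simulate("config.yaml", "cohort/")     # write cohort container
cmd_evaluate("cohort/", "results/")        # outcome/deviation/exposure CSVs
cmd_report("results/")                     # summary.md + figures
```

or from a shell via the bundled dispatcher,
`Rscript $(Rscript -e 'cat(system.file("cli", "igsched.R", package = "igsched"))') simulate -c config.yaml -o cohort/`.

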