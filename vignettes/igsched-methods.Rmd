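---
title: "Methods: evaluating CBCT image-guidance schedules on a synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating CBCT image-guidance schedules on a synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsched)
```

## The question

Daily cone-beam CT (CBCT) before every radiotherapy fraction corrects the
patient's setup error almost completely, but each scan deposits imaging dose
in nearby organs and carries a direct fee. Imaging less often saves dose and
money at the price of treating some fractions with the uncorrected setup
error. `igsched` quantifies that trade-off for a fractionated course
(the reference scenario is left-sided postmastectomy chest-wall irradiation,
50 Gy in 25 fractions of 2 Gy, 5 fractions/week) across six schedules:

| schedule | imaging pattern | frequency F (25 fx, 5/wk) |
|---|---|---|
| NIG | first fraction only | 1 |
| WIG | first fraction of each week | 5 |
| TIG | fractions {1, 4} of each week | 10 |
| THRIG | fractions {1, 3, 5} of each week | 15 |
| 3D+WIG | fractions 1–3, then weekly | 7 |
| DIG | every fraction | 25 |

The first fraction is always imaged, whatever the schedule — a safety
invariant enforced by `ig_schedule()`. Weeks are consecutive blocks of
`fractions_per_week` fractions; no calendar gaps are modelled. The within-week
imaging days above are a modelling choice (clinical protocols rarely pin them
down); they were fixed so that the six frequencies come out at 1, 5, 10, 15,
7 and 25, the values that drive the course-level imaging dose and cost
arithmetic.

## The synthetic cohort

Clinical per-fraction dose recalculation requires institutional CBCT images,
so the package replaces that chain with a seeded generator whose output has
the statistical structure the downstream analysis needs.

**Setup-error model.** Rigid 3-D translations only (image guidance corrects
translations; rotations and deformation are out of scope). Pre-correction
shifts follow the standard decomposition: a systematic per-patient offset
drawn once per axis from N(0, `sigma_systematic`²) plus a per-fraction random
term from N(0, `sigma_random`²). Imaged fractions are corrected down to a
per-fraction residual from N(0, `sigma_residual`²). The defaults 3/3/1 mm
are typical published magnitudes for breast/chest-wall setups without daily
imaging; they are configuration values, not measurements, and are fully
configurable.

**Phantom and planned dose.** `build_phantom()` constructs a geometric
stand-in for the planning CT: the chest-wall target (PTVcw) as a
left-anterior shell of a torso cylinder, a small supraclavicular box target
(PTVsc) superior to it, heart and ipsilateral lung ellipsoids deep to the
chest wall, and a right-sided contralateral breast. Structures scale with the
physical grid extent, so a 24³ grid carries the same anatomy as a 48³ grid.
The planned dose is the prescription on the PTV union expanded by
`plan_margin`, falling to 0 Gy through a sigmoid penumbra (a Gaussian-blurred
edge whose 80–20% width is `penumbra_width`, default 6 mm). The margin
(default 8 mm) emulates the conformity margin of a clinical plan: it was set,
together with the penumbra width, so the generated plan passes the standard
plan-quality gate PTV D95 ≥ 95% of prescription — the same acceptance
criterion a physicist would apply to a real plan. Out-of-field background is
0 Gy; organs at risk receive incidental dose by proximity only, which is why
heart NTCP stays negligible throughout, mirroring the clinical situation.

**Dose under error.** `deliver_fraction()` applies the invariant-dose
approximation: the per-fraction delivered dose is the planned dose rigidly
resampled at coordinates translated by −shift (trilinear interpolation,
out-of-grid sampled as background) and scaled by 1/`n_fractions`. This is the
module's central simplification — it stands in for deformable-registration
based per-fraction recalculation, and it is exact for a homogeneous patient
moving rigidly in a static beam. What it does *not* emulate: anatomical
deformation, density changes along the beam path, and surface curvature
effects. Consequently the package's cohort-level numbers (e.g. the THRIG
deviation from DIG) are qualitative reproductions of the trend, not estimates
of any clinic's values.

**Determinism.** The master seed fixes per-patient sub-seeds
(drawn once, so results do not depend on evaluation order); config + seed
determine every emitted byte of the on-disk container, which is raw
little-endian float32 dose arrays plus uint8 masks with JSON headers and a
top-level manifest (written last, so an interrupted run leaves no valid
manifest).

## Dose accumulation and DVH engine

For each schedule the course dose is the voxelwise sum over fractions of the
post-correction dose where the fraction was imaged and the pre-correction
dose otherwise (`select_and_accumulate()`). DVHs are cumulative ("volume
receiving at least dose"), built on uniform bins of 0.05 Gy — fine enough
that binning error (≤ half a bin) is two orders of magnitude below the ~1 Gy
effect sizes of interest. D95 is read off the cumulative curve by linear
interpolation with ties broken towards lower dose; the convention matters
only at the sub-bin level and is documented because DVH engines differ
silently on it. Dmean is the volume-weighted mean of the differential DVH
(adjacent differencing at bin midpoints); Dmax the highest occupied bin edge.

## Radiobiology

All dose-response evaluation happens in the EQD2 domain: each DVH bin dose D
is converted with the linear-quadratic relation EQD2 = D·(d + α/β)/(2 + α/β),
d = D/`n_fractions`, before entering TCP or NTCP. Applying the conversion to
targets *and* organs at risk is a deliberate choice — the parameter registry
supplies α/β for every structure — and is isolated so it can be bypassed by
passing physical-dose DVHs.

**TCP.** The Poisson linear-quadratic response is used in its Källman
(TCD50, γ) form: the uniform-dose response is
P(D) = 2^(−exp(e·γ·(1 − D/TCD50))), which makes P(TCD50) = ½ exact and γ the
normalised slope at that point. Heterogeneous distributions combine as the
volume-weighted product TCP = Π P(Dᵢ)^(vᵢ) over differential-DVH bins
(uniform clonogen density). The functional form is confined to one internal
expression so alternative TCP variants can be swapped. Defaults for both
targets: TCD50 = 39.3 Gy, γ = 1.7, α/β = 4 Gy (a multi-centre adjuvant
breast dose-response parameterisation).

**NTCP.** Lyman–Kutcher–Burman: the generalised equivalent uniform dose
gEUD = (Σ vᵢ·Dᵢ^(1/n))ⁿ reduces the DVH, then NTCP = Φ((gEUD − TD50)/(m·TD50)).
Defaults: heart pericarditis TD50 = 48 Gy, m = 0.1, n = 0.35, α/β = 3;
lung pneumonitis TD50 = 30.8 Gy, m = 0.18, n = 0.87, α/β = 3.

Numerical guards: the TCP exponent is capped so that doses far below TCD50
underflow to 0 instead of overflowing (stable to at least 200 Gy input), and
gEUD is computed on doses scaled by their maximum so D^(1/n) cannot overflow
for small n.

## Imaging dose and cost

Per-scan organ doses are treated as Monte-Carlo-derived constants for the
120 kV half-rotation thorax protocol (ipsilateral lung 2.85 mGy,
contralateral breast 1.26 mGy per scan) and the single-scan direct fee as
288 CNY. Course totals are exactly linear in the imaging frequency:
D_cum = D_single · F and C_total = C_single · F. No patient-size scaling is
applied, no heart per-scan dose is invented (the report simply has no heart
imaging-dose column), and indirect costs (staff time, depreciation) are out
of scope. Scan technique metadata (kV, collimator, filter, mAs) is carried
for provenance only; nothing is computed from it.

## Statistics

`compare_schedules()` mirrors the standard repeated-measures workflow:
Friedman omnibus test over the six related samples (patients as blocks),
then all 15 pairwise paired t-tests with Bonferroni correction
(adjusted p = raw p × 15, capped at 1), α = 0.05. Shapiro–Wilk normality
p-values are attached per schedule as a caveat flag; the t-tests are run
regardless, and the printed summary surfaces the caveat when normality is
rejected. Deviations from the reference schedule are means over patients of
the signed per-patient percent deviation 100·(x_ref − x)/x_ref (per-patient
ratios averaged, not a ratio of cohort means — the two differ for skewed
cohorts; the per-patient form weights every patient equally).

## Problem sizes and what the tests show

The shipped test-suite cohorts use 10 patients on 24³ grids (4 mm voxels)
for trend checks and 2–3 patients on 20³ grids (8 mm voxels) for mechanical
checks — sizes at which the full pipeline runs in seconds while leaving the
per-axis setup-error statistics and DVH resolution intact. The package's
validated claims on these cohorts are *structural*: a zero-setup-error
cohort is exactly schedule-invariant; cohort-mean PTV D95 and TCP are
maximal under DIG, minimal under NIG, with THRIG strictly between; the
family-wise error of the corrected pairwise procedure stays at its nominal
level under a simulated null; and the imaging dose/cost endpoints are exact
arithmetic. Per-patient clinical magnitudes (how many percent a given
clinic's THRIG deviates from DIG) depend on real image data and are outside
what a synthetic cohort can certify.

## Known limitations

- Rigid translations only; no rotations, deformation or anatomical change.
- Invariant-dose approximation instead of per-fraction recalculation.
- Phantom anatomy is schematic; absolute OAR doses are smaller than clinical
  values because scatter and beam-path effects are not modelled.
- Default setup-error magnitudes are literature-typical, not fitted.
- Imaging dose is reported alongside, never added into, the therapeutic dose
  grid.
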