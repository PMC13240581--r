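#' Per-scan imaging dose and cost table
#'
#' Per-CBCT-scan organ doses (Monte-Carlo-derived constants for a 120 kV
#' half-rotation thorax protocol) and the single-scan direct fee. The heart
#' has no tabulated per-scan dose and is deliberately omitted from imaging
#' dose reporting rather than invented. Scan technique settings are carried
#' as metadata only; nothing is computed from them.
#'
#' @param organ_dose_mGy named numeric vector of per-scan organ doses in mGy
#'   (defaults: ipsilateral lung 2.85, contralateral breast 1.26).
#' @param cost_single single-scan direct imaging fee (default 288, CNY).
#' @param currency currency label.
#' @param meta list of scan-technique metadata.
#' @return An object of class `exposure_table`.
#' @export
exposure_table <- function(organ_dose_mGy = c(lung_ipsi = 2.85,
                                              breast_contra = 1.26),
                           cost_single = 288,
                           currency = "CNY",
                           meta = list(kV = 120, collimator = "S20",
                                       filter = "F1", total_mAs = 117.1,
                                       rotation = "half")) {
  if (any(organ_dose_mGy < 0) || cost_single < 0) {
    stop("per-scan doses and cost must be >= 0")
  }
  structure(list(organ_dose_mGy = organ_dose_mGy, cost_single = cost_single,
                 currency = currency, meta = meta),
            class = "exposure_table")
}

#' Cumulative imaging dose over a course
#'
#' The cumulative organ dose is the per-scan dose times the number of scans:
#' `D_cum = D_single * F`. Exact arithmetic, linear in F.
#'
#' @param d_single per-scan organ dose, mGy.
#' @param F imaging frequency (number of scans in the course).
#' @return Cumulative dose in mGy.
#' @examples
#' cumulative_imaging_dose(1.26, 25)  # 31.5 mGy over a daily-imaged course
#' @export
cumulative_imaging_dose <- function(d_single, F) {
  stopifnot(all(d_single >= 0), F >= 0)
  d_single * F
}

#' Total direct imaging-related cost over a course
#'
#' `C_total = C_single * F`: the single-scan fee times the number of scans.
#' Direct costs only; staff time and equipment depreciation are out of scope.
#'
#' @param c_single single-scan fee.
#' @param F imaging frequency.
#' @return Total cost in the same currency unit.
#' @export
total_cost <- function(c_single, F) {
  stopifnot(c_single >= 0, F >= 0)
  c_single * F
}

#' Per-schedule imaging dose and cost report
#'
#' Tabulates, for each schedule, the imaging frequency F, cumulative
#' per-organ imaging dose, total direct cost, and each as a percentage of a
#' reference schedule. Both dose and cost are linear in F, so their
#' percent-of-reference columns coincide with `100 * F / F_ref`.
#'
#' @param schedules list of `ig_schedule`s.
#' @param table an [exposure_table()].
#' @param reference_name name of the reference schedule (default `"DIG"`).
#' @return A data.frame with one row per schedule: `schedule`, `F`, one
#'   `dose_<organ>_mGy` column per organ, `cost`, `pct_of_reference`.
#' @export
exposure_report <- function(schedules, table = exposure_table(),
                            reference_name = "DIG") {
  stopifnot(inherits(table, "exposure_table"))
  nms <- vapply(schedules, function(s) s$name, character(1))
  if (!reference_name %in% nms) {
    stop("reference schedule '", reference_name, "' not among: ",
         paste(nms, collapse = ", "))
  }
  Fs <- vapply(schedules, frequency, numeric(1))
  f_ref <- Fs[match(reference_name, nms)]
  out <- data.frame(schedule = nms, F = Fs, stringsAsFactors = FALSE)
  for (org in names(table$organ_dose_mGy)) {
    out[[paste0("dose_", org, "_mGy")]] <-
      cumulative_imaging_dose(table$organ_dose_mGy[[org]], Fs)
  }
  out$cost <- total_cost(table$cost_single, Fs)
  out$pct_of_reference <- 100 * Fs / f_ref
  rownames(out) <- NULL
  out
}
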