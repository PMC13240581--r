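#' Image-guidance schedule constructor
#'
#' An IG schedule is a boolean imaging mask over the treatment fractions:
#' `TRUE` where a CBCT is acquired (and the couch corrected), `FALSE` where
#' the patient is treated on skin marks alone. The first fraction is always
#' imaged, whatever the schedule. The number of `TRUE` entries is the
#' imaging frequency F that drives cumulative imaging dose and cost.
#'
#' @param name schedule label.
#' @param mask logical vector, one entry per fraction.
#' @return An object of class `ig_schedule`.
#' @export
ig_schedule <- function(name, mask) {
  mask <- as.logical(mask)
  if (length(mask) < 1L || anyNA(mask)) stop("invalid imaging mask")
  mask[1L] <- TRUE   # first-fraction CBCT is mandatory
  structure(list(name = name, mask = mask), class = "ig_schedule")
}

#' @export
print.ig_schedule <- function(x, ...) {
  cat("ig_schedule", x$name, ": F =", frequency(x), "of", length(x$mask),
      "fractions\n")
  invisible(x)
}

#' Names of the six standard schedules
#' @return Character vector: NIG, WIG, TIG, THRIG, 3D+WIG, DIG.
#' @export
schedule_names <- function() {
  c("NIG", "WIG", "TIG", "THRIG", "3D+WIG", "DIG")
}

#' Build one of the six standard IG schedules
#'
#' Weeks are consecutive blocks of `fractions_per_week` fractions (no
#' calendar gaps). Within-week imaging days: WIG images the first fraction
#' of each week; TIG fractions \{1, 4\}; THRIG \{1, 3, 5\}; 3D+WIG images
#' fractions 1--3 and then the first fraction of each later week; NIG only
#' fraction 1; DIG every fraction. With 25 fractions at 5 per week the
#' frequencies are F = 1, 5, 10, 15, 7 and 25 respectively.
#'
#' @param name one of [schedule_names()].
#' @param n_fractions number of fractions (default 25).
#' @param fractions_per_week fractions per week (default 5).
#' @return An `ig_schedule`.
#' @examples
#' frequency(build_schedule("THRIG"))  # 15
#' @export
build_schedule <- function(name, n_fractions = 25L, fractions_per_week = 5L) {
  if (!name %in% schedule_names()) {
    stop("unknown schedule '", name, "'; valid names: ",
         paste(schedule_names(), collapse = ", "))
  }
  n <- as.integer(n_fractions)
  fpw <- as.integer(fractions_per_week)
  stopifnot(n >= 1L, fpw >= 1L)
  day <- ((seq_len(n) - 1L) %% fpw) + 1L   # weekday index within the week
  week_days <- switch(name,
    NIG = integer(0),
    WIG = 1L,
    TIG = c(1L, 4L),
    THRIG = c(1L, 3L, 5L),
    `3D+WIG` = 1L,
    DIG = seq_len(fpw)
  )
  mask <- day %in% pmin(week_days, fpw)
  if (name == "3D+WIG") mask[seq_len(min(3L, n))] <- TRUE
  ig_schedule(name, mask)
}

#' Imaging frequency of a schedule
#'
#' Method for the [stats::frequency()] generic: the number of imaged
#' fractions (count of `TRUE` mask entries), the F of the cumulative
#' imaging-dose and cost relations.
#'
#' @param x an `ig_schedule`.
#' @param ... ignored.
#' @return Number of imaged fractions.
#' @importFrom stats frequency
#' @export
frequency.ig_schedule <- function(x, ...) {
  sum(x$mask)
}

#' The six standard schedules for a given fractionation
#'
#' @param n_fractions,fractions_per_week fractionation (defaults 25, 5).
#' @return Named list of the six `ig_schedule`s.
#' @export
default_schedules <- function(n_fractions = 25L, fractions_per_week = 5L) {
  nms <- schedule_names()
  stats::setNames(
    lapply(nms, build_schedule, n_fractions = n_fractions,
           fractions_per_week = fractions_per_week),
    nms)
}

#' Schedule-conditional dose accumulation
#'
#' For each fraction the post-correction dose distribution is used when the
#' schedule imaged that fraction (setup error corrected to a residual), the
#' pre-correction distribution otherwise; grids are summed voxelwise in the
#' planning frame.
#'
#' @param fractions list of per-fraction records, each with elements
#'   `dose_pre` and `dose_post` (both `dose_grid`s).
#' @param schedule an `ig_schedule` whose mask length equals the number of
#'   fractions.
#' @return Accumulated `dose_grid` for the course.
#' @export
select_and_accumulate <- function(fractions, schedule) {
  stopifnot(inherits(schedule, "ig_schedule"))
  if (length(fractions) != length(schedule$mask)) {
    stop("schedule has ", length(schedule$mask), " fractions but ",
         length(fractions), " fraction doses supplied")
  }
  picked <- lapply(seq_along(fractions), function(f) {
    if (schedule$mask[f]) fractions[[f]]$dose_post else fractions[[f]]$dose_pre
  })
  accumulate(picked)
}
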