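#' Evaluate a cohort under a set of image-guidance schedules
#'
#' The central pipeline: for every patient and every schedule, accumulate
#' the course dose (post-correction fractions where imaged, pre-correction
#' otherwise), build per-structure DVHs, extract target D95 and OAR mean
#' doses, convert to EQD2 and evaluate TCP (targets) and NTCP (OARs).
#' Deterministic given the cohort.
#'
#' `x` may be a `cohort_config` (patients are simulated one at a time and
#' discarded, keeping memory flat), a `sim_cohort` from [simulate_cohort()],
#' or the path of a cohort directory written by [generate_cohort()].
#'
#' @param x cohort source (see Details).
#' @param schedules list of `ig_schedule`s (default: the six standard
#'   schedules for the cohort's fractionation).
#' @param params radiobiological parameter registry
#'   (default [default_radiobio_params()]).
#' @param bin_width DVH bin width, Gy.
#' @return A data.frame of outcome records, one row per patient x schedule:
#'   `patient_id`, `schedule`, `D95_PTVsc`, `D95_PTVcw`, `Dmean_<oar>`,
#'   `TCP_<target>`, `NTCP_<oar>` columns.
#' @export
evaluate_cohort <- function(x, schedules = NULL,
                            params = default_radiobio_params(),
                            bin_width = 0.05) {
  UseMethod("evaluate_cohort")
}

#' @export
evaluate_cohort.cohort_config <- function(x, schedules = NULL,
                                          params = default_radiobio_params(),
                                          bin_width = 0.05) {
  if (is.null(schedules)) {
    schedules <- default_schedules(x$n_fractions, x$fractions_per_week)
  }
  phantom <- build_phantom(x)
  rows <- lapply(seq_len(x$n_patients), function(p) {
    pat <- simulate_patient(x, p, phantom)
    evaluate_patient(pat, phantom$masks, schedules, params,
                     n_fractions = x$n_fractions, bin_width = bin_width)
  })
  do.call(rbind, rows)
}

#' @export
evaluate_cohort.sim_cohort <- function(x, schedules = NULL,
                                       params = default_radiobio_params(),
                                       bin_width = 0.05) {
  cfg <- x$config
  if (is.null(schedules)) {
    schedules <- default_schedules(cfg$n_fractions, cfg$fractions_per_week)
  }
  rows <- lapply(x$patients, evaluate_patient, masks = x$phantom$masks,
                 schedules = schedules, params = params,
                 n_fractions = cfg$n_fractions, bin_width = bin_width)
  do.call(rbind, rows)
}

#' @export
evaluate_cohort.character <- function(x, schedules = NULL,
                                      params = default_radiobio_params(),
                                      bin_width = 0.05) {
  manifest <- read_cohort_manifest(x)
  n_fx <- manifest$n_fractions
  if (is.null(schedules)) {
    schedules <- default_schedules(n_fx, manifest$config$fractions_per_week)
  }
  rows <- lapply(seq_along(manifest$patients), function(p) {
    pat <- read_patient(x, p)
    evaluate_patient(pat, pat$masks, schedules, params,
                     n_fractions = n_fx, bin_width = bin_width)
  })
  do.call(rbind, rows)
}

# one patient x all schedules -> outcome rows
evaluate_patient <- function(patient, masks, schedules, params, n_fractions,
                             bin_width = 0.05) {
  targets <- intersect(names(params$tcp), names(masks))
  oars <- intersect(names(params$ntcp), names(masks))
  dmean_structs <- setdiff(names(masks), targets)
  rows <- lapply(schedules, function(sch) {
    acc <- select_and_accumulate(patient$fractions, sch)
    row <- list(patient_id = patient$patient_id, schedule = sch$name)
    for (t in targets) {
      dvh <- compute_dvh(acc, masks[[t]], bin_width)
      row[[paste0("D95_", t)]] <- dvh_metric(dvh, "D95")
      pt <- params$tcp[[t]]
      row[[paste0("TCP_", t)]] <-
        poisson_tcp(dvh_eqd2(dvh, n_fractions, pt$alpha_beta), pt)
    }
    for (s in dmean_structs) {
      dvh <- compute_dvh(acc, masks[[s]], bin_width)
      row[[paste0("Dmean_", s)]] <- dvh_metric(dvh, "Dmean")
      if (s %in% oars) {
        po <- params$ntcp[[s]]
        row[[paste0("NTCP_", s)]] <-
          lkb_ntcp(dvh_eqd2(dvh, n_fractions, po$alpha_beta), po)
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-schedule percent deviation from a reference schedule
#'
#' For each non-reference schedule and the chosen metric, the mean over
#' patients of the signed per-patient percent deviation
#' `100 * (x_ref - x_sched) / x_ref` (positive = worse coverage than the
#' reference for dose/TCP-type metrics). Patients with a zero reference
#' value are excluded with a warning.
#'
#' @param records outcome data.frame from [evaluate_cohort()].
#' @param metric name of a numeric column of `records`.
#' @param reference reference schedule name (default `"DIG"`).
#' @return data.frame: `schedule`, `metric`, `mean_pct_dev`, `sd_pct_dev`,
#'   `n_patients`.
#' @export
deviation_vs_reference <- function(records, metric, reference = "DIG") {
  if (!metric %in% names(records)) stop("unknown metric column: ", metric)
  if (!reference %in% records$schedule) {
    stop("reference schedule '", reference, "' not present in records")
  }
  ref <- records[records$schedule == reference, c("patient_id", metric)]
  names(ref)[2] <- ".ref"
  out <- lapply(unique(records$schedule), function(s) {
    cur <- merge(records[records$schedule == s, c("patient_id", metric)],
                 ref, by = "patient_id")
    ok <- cur$.ref != 0
    if (any(!ok)) {
      warning("excluding ", sum(!ok), " patient(s) with zero reference ",
              metric, " for schedule ", s)
    }
    dev <- 100 * (cur$.ref[ok] - cur[[metric]][ok]) / cur$.ref[ok]
    data.frame(schedule = s, metric = metric,
               mean_pct_dev = mean(dev),
               sd_pct_dev = stats::sd(dev),
               n_patients = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Omnibus and pairwise schedule comparisons
#'
#' Mirrors the repeated-measures workflow of the reference analysis: a
#' Friedman test across the related schedule samples (patients as blocks),
#' then all pairwise paired t-tests with Bonferroni correction (adjusted
#' p = raw p times the number of pairs, capped at 1). Per-schedule
#' Shapiro-Wilk normality results are attached as a caveat flag; the paired
#' t-tests are run regardless, and readers should weigh them accordingly.
#'
#' @param records outcome data.frame from [evaluate_cohort()] (balanced:
#'   every patient must have every schedule).
#' @param metric name of the numeric column to compare.
#' @param alpha significance threshold recorded in the output (default 0.05).
#' @return A list of class `schedule_comparison`: `metric`, `friedman`
#'   (`htest`), `pairwise` (data.frame with raw and Bonferroni-adjusted p),
#'   `shapiro` (per-schedule p-values), `alpha`.
#' @export
compare_schedules <- function(records, metric, alpha = 0.05) {
  if (!metric %in% names(records)) stop("unknown metric column: ", metric)
  wide <- stats::reshape(
    records[, c("patient_id", "schedule", metric)],
    idvar = "patient_id", timevar = "schedule", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub(paste0("^", metric, "\\."), "", colnames(mat))
  if (anyNA(mat)) {
    stop("unbalanced design: every patient needs a record for every schedule")
  }
  fr <- if (all(mat == mat[, 1])) {
    # identical columns: the rank statistic is 0 by definition, but the
    # tie-correction denominator degenerates, so build the null result
    structure(list(statistic = c(`Friedman chi-squared` = 0),
                   parameter = c(df = ncol(mat) - 1L), p.value = 1,
                   method = "Friedman rank sum test",
                   data.name = metric),
              class = "htest")
  } else {
    stats::friedman.test(mat)
  }
  nms <- colnames(mat)
  pairs <- utils::combn(nms, 2)
  n_pairs <- ncol(pairs)
  pw <- data.frame(
    schedule_a = pairs[1, ], schedule_b = pairs[2, ],
    p_raw = apply(pairs, 2, function(pr) {
      da <- mat[, pr[1]]; db <- mat[, pr[2]]
      if (stats::sd(da - db) == 0) {
        # degenerate paired differences: identical columns carry no
        # evidence; an exactly constant nonzero offset is overwhelming
        return(if (all(da == db)) 1 else 0)
      }
      stats::t.test(da, db, paired = TRUE)$p.value
    }),
    stringsAsFactors = FALSE)
  pw$p_adj <- pmin(pw$p_raw * n_pairs, 1)
  sw <- vapply(nms, function(nm) {
    x <- mat[, nm]
    if (stats::sd(x) == 0 || length(x) < 3) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  structure(list(metric = metric, friedman = fr, pairwise = pw,
                 shapiro = data.frame(schedule = nms, p_shapiro = unname(sw),
                                      stringsAsFactors = FALSE),
                 alpha = alpha),
            class = "schedule_comparison")
}

#' @export
print.schedule_comparison <- function(x, ...) {
  cat("schedule comparison for", x$metric, "\n")
  cat(sprintf("  Friedman chi-sq = %.3f, df = %d, p = %.4g\n",
              unname(x$friedman$statistic), unname(x$friedman$parameter),
              x$friedman$p.value))
  sig <- x$pairwise[x$pairwise$p_adj < x$alpha, , drop = FALSE]
  cat("  pairwise (Bonferroni,", nrow(x$pairwise), "pairs):",
      nrow(sig), "significant at alpha =", x$alpha, "\n")
  if (any(!is.na(x$shapiro$p_shapiro)) &&
      any(x$shapiro$p_shapiro < x$alpha, na.rm = TRUE)) {
    cat("  caveat: Shapiro-Wilk rejects normality for",
        paste(x$shapiro$schedule[which(x$shapiro$p_shapiro < x$alpha)],
              collapse = ", "), "\n")
  }
  invisible(x)
}
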