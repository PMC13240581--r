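#' Simulate a cohort from a configuration file
#'
#' CLI-style entry point: reads and validates the configuration (YAML or
#' JSON), then writes the cohort container via [generate_cohort()].
#'
#' @param config_path path to a config file ([read_cohort_config()]).
#' @param out_dir output cohort directory.
#' @return The cohort directory path, invisibly.
#' @export
cmd_simulate <- function(config_path, out_dir) {
  cfg <- read_cohort_config(config_path)
  message("simulating ", cfg$n_patients, "-patient cohort into ", out_dir)
  generate_cohort(cfg, out_dir)
}

#' Evaluate a cohort directory and write all result tables
#'
#' Runs the full pipeline on an on-disk cohort: outcome records for the six
#' standard schedules, deviation-versus-reference tables for every numeric
#' outcome, the imaging dose/cost report, and the statistical comparisons.
#' Outputs are deterministic given the cohort, and every file set carries a
#' provenance record (config hash + seed).
#'
#' @param cohort_dir cohort directory written by [cmd_simulate()] /
#'   [generate_cohort()].
#' @param out_dir results directory (created if needed).
#' @param reference reference schedule for deviations and exposure ratios.
#' @param exposure an [exposure_table()].
#' @param params radiobiology registry, default [default_radiobio_params()].
#' @return `out_dir`, invisibly.
#' @export
cmd_evaluate <- function(cohort_dir, out_dir, reference = "DIG",
                         exposure = exposure_table(),
                         params = default_radiobio_params()) {
  manifest <- read_cohort_manifest(cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- manifest$config
  schedules <- default_schedules(cfg$n_fractions, cfg$fractions_per_week)

  records <- evaluate_cohort(cohort_dir, schedules, params)
  write_table <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  write_table(records, "outcomes.csv")

  metrics <- setdiff(names(records), c("patient_id", "schedule"))
  dev <- do.call(rbind, lapply(metrics, function(m) {
    withCallingHandlers(
      deviation_vs_reference(records, m, reference),
      warning = function(w) {
        message("note: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }))
  write_table(dev, "deviation_vs_reference.csv")

  exp_rep <- exposure_report(schedules, exposure, reference)
  write_table(exp_rep, "exposure_cost.csv")

  stats_out <- lapply(metrics, function(m) {
    cmp <- compare_schedules(records, m)
    list(metric = m,
         friedman = list(statistic = unname(cmp$friedman$statistic),
                         df = unname(cmp$friedman$parameter),
                         p = cmp$friedman$p.value),
         pairwise = cmp$pairwise,
         shapiro = cmp$shapiro)
  })
  provenance <- list(config_hash = manifest$config_hash,
                     seed = cfg$seed,
                     reference = reference,
                     n_patients = cfg$n_patients,
                     package_version = as.character(utils::packageVersion("igsched")))
  jsonlite::write_json(list(provenance = provenance, comparisons = stats_out),
                       file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Render a human-readable summary of an evaluated run
#'
#' Writes `summary.md` (cohort-mean outcomes per schedule, the
#' THRIG-versus-reference trade-off table, imaging dose/cost) and, where a
#' graphics device is available, boxplot/barplot figures of D95, TCP and
#' exposure by schedule.
#'
#' @param results_dir directory written by [cmd_evaluate()].
#' @param figures attempt PNG figures (default TRUE; skipped with a message
#'   if no device is available).
#' @return Path of the summary file, invisibly.
#' @export
cmd_report <- function(results_dir, figures = TRUE) {
  need <- c("outcomes.csv", "deviation_vs_reference.csv", "exposure_cost.csv",
            "provenance.json")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing)) {
    stop("results directory is missing: ", paste(missing, collapse = ", "))
  }
  records <- utils::read.csv(file.path(results_dir, "outcomes.csv"))
  dev <- utils::read.csv(file.path(results_dir, "deviation_vs_reference.csv"))
  exp_rep <- utils::read.csv(file.path(results_dir, "exposure_cost.csv"))
  prov <- jsonlite::read_json(file.path(results_dir, "provenance.json"),
                              simplifyVector = TRUE)

  metrics <- setdiff(names(records), c("patient_id", "schedule"))
  sched_order <- unique(records$schedule)
  mean_tbl <- stats::aggregate(records[metrics],
                               by = list(schedule = records$schedule), mean)
  mean_tbl <- mean_tbl[match(sched_order, mean_tbl$schedule), ]

  fmt_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
  md <- c(
    "# Image-guidance schedule evaluation",
    "",
    paste0("Config hash `", prov$config_hash, "`, seed ", prov$seed, ", ",
           prov$n_patients, " patients; reference schedule ", prov$reference,
           "."),
    "",
    "## Cohort-mean outcomes by schedule",
    "",
    fmt_row(c("schedule", metrics)),
    fmt_row(rep("---", length(metrics) + 1)),
    vapply(seq_len(nrow(mean_tbl)), function(i) {
      fmt_row(c(mean_tbl$schedule[i],
                sprintf("%.4g", unlist(mean_tbl[i, metrics]))))
    }, character(1)),
    "",
    "## Deviation vs reference (% of reference, mean over patients)",
    "",
    fmt_row(c("schedule", "metric", "mean %", "sd %")),
    fmt_row(rep("---", 4)),
    vapply(seq_len(nrow(dev)), function(i) {
      fmt_row(c(dev$schedule[i], dev$metric[i],
                sprintf("%.3f", dev$mean_pct_dev[i]),
                sprintf("%.3f", dev$sd_pct_dev[i])))
    }, character(1)),
    "",
    "## Imaging dose and cost",
    "",
    fmt_row(names(exp_rep)),
    fmt_row(rep("---", ncol(exp_rep))),
    vapply(seq_len(nrow(exp_rep)), function(i) {
      fmt_row(vapply(exp_rep[i, ], function(v)
        if (is.numeric(v)) sprintf("%.4g", v) else as.character(v),
        character(1)))
    }, character(1)),
    ""
  )
  # the headline trade-off: THRIG vs the reference schedule
  thr <- dev[dev$schedule == "THRIG", , drop = FALSE]
  if (nrow(thr)) {
    ratio <- exp_rep$pct_of_reference[exp_rep$schedule == "THRIG"]
    md <- c(md,
      "## THRIG trade-off",
      "",
      paste0("THRIG keeps mean deviations vs ", prov$reference, " at ",
             paste(sprintf("%s %.2f%%", thr$metric, thr$mean_pct_dev),
                   collapse = ", "),
             " while using ", sprintf("%.1f%%", ratio),
             " of the reference imaging dose and cost."),
      "")
  }
  out <- file.path(results_dir, "summary.md")
  writeLines(unlist(md), out)

  if (figures) {
    ok <- tryCatch({
      fig <- function(name, code) {
        grDevices::png(file.path(results_dir, name), width = 900, height = 600)
        on.exit(grDevices::dev.off())
        code()
      }
      records$schedule <- factor(records$schedule, levels = sched_order)
      for (m in intersect(c("D95_PTVcw", "D95_PTVsc", "TCP_PTVcw", "TCP_PTVsc"),
                          metrics)) {
        local({
          mm <- m
          fig(paste0(mm, "_by_schedule.png"), function() {
            graphics::boxplot(records[[mm]] ~ records$schedule,
                              xlab = "schedule", ylab = mm,
                              main = paste(mm, "by image-guidance schedule"))
          })
        })
      }
      fig("exposure_cost.png", function() {
        graphics::par(mfrow = c(1, 2))
        dose_cols <- grep("^dose_", names(exp_rep), value = TRUE)
        graphics::barplot(t(as.matrix(exp_rep[dose_cols])),
                          beside = TRUE, names.arg = exp_rep$schedule,
                          ylab = "cumulative imaging dose (mGy)",
                          legend.text = sub("_mGy$", "", sub("^dose_", "", dose_cols)),
                          main = "Imaging dose by schedule")
        graphics::barplot(exp_rep$cost, names.arg = exp_rep$schedule,
                          ylab = "total imaging cost",
                          main = "Imaging-related cost by schedule")
      })
      TRUE
    }, error = function(e) {
      message("figures skipped (no usable graphics device): ",
              conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  invisible(out)
}
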