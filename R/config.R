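#' Cohort configuration
#'
#' Bundles every knob of the synthetic cohort: cohort size, fractionation,
#' setup-error magnitudes, phantom grid geometry and penumbra model, and the
#' master seed that fixes all downstream randomness.
#'
#' The default scenario is a 20-patient left-sided postmastectomy cohort
#' treated with 50 Gy in 25 fractions (2 Gy/fraction, 5 fractions/week).
#' Setup errors are rigid 3-D translations with a per-patient systematic
#' component (sd `sigma_systematic` per axis), a per-fraction random component
#' (sd `sigma_random`) and, after image-guided couch correction, a small
#' per-fraction residual (sd `sigma_residual`). All lengths are millimetres.
#'
#' @param n_patients number of patients (default 20).
#' @param n_fractions number of treatment fractions (default 25).
#' @param fractions_per_week fractions per treatment week (default 5).
#' @param prescription prescribed dose to the PTV in Gy (default 50).
#' @param sigma_systematic per-axis sd of the per-patient systematic setup
#'   error, mm (default 3).
#' @param sigma_random per-axis sd of the per-fraction random setup error,
#'   mm (default 3).
#' @param sigma_residual per-axis sd of the post-correction residual error,
#'   mm (default 1).
#' @param grid_shape integer vector of voxel counts `c(nx, ny, nz)`; a single
#'   value is recycled (default 48).
#' @param voxel_spacing isotropic voxel spacing in mm (default 4).
#' @param penumbra_width 80--20% penumbra width of the planned-dose falloff,
#'   mm (default 6).
#' @param plan_margin width of the full-dose plateau beyond the PTV surface,
#'   mm (default 8); emulates the conformity margin of a clinical plan so
#'   that the planned PTV D95 meets the 95%-of-prescription quality gate.
#' @param seed integer master seed; fixes every random draw of the cohort.
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_patients = 2, grid_shape = 24, seed = 1)
#' cfg$n_fractions
#' @export
cohort_config <- function(n_patients = 20L,
                          n_fractions = 25L,
                          fractions_per_week = 5L,
                          prescription = 50,
                          sigma_systematic = 3,
                          sigma_random = 3,
                          sigma_residual = 1,
                          grid_shape = c(48L, 48L, 48L),
                          voxel_spacing = 4,
                          penumbra_width = 6,
                          plan_margin = 8,
                          seed = 20260101L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    n_fractions = as.integer(n_fractions),
    fractions_per_week = as.integer(fractions_per_week),
    prescription = as.numeric(prescription),
    sigma_systematic = as.numeric(sigma_systematic),
    sigma_random = as.numeric(sigma_random),
    sigma_residual = as.numeric(sigma_residual),
    grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    penumbra_width = as.numeric(penumbra_width),
    plan_margin = as.numeric(plan_margin),
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks counts, lengths and geometry; errors name the offending field.
#'
#' @param cfg a `cohort_config` (or plain list with the same fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid cohort config: field '", field, "' ", msg,
                          call. = FALSE)
  }
  counts <- c("n_patients", "n_fractions", "fractions_per_week")
  for (f in counts) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && cfg[[f]] >= 1 &&
          cfg[[f]] == round(cfg[[f]]), f, "must be an integer >= 1")
  }
  lens <- c("sigma_systematic", "sigma_random", "sigma_residual",
            "voxel_spacing", "penumbra_width", "plan_margin")
  for (f in lens) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L && is.finite(cfg[[f]]) &&
          cfg[[f]] >= 0, f, "must be a finite length >= 0 (mm)")
  }
  chk(cfg$voxel_spacing > 0, "voxel_spacing", "must be > 0")
  chk(is.numeric(cfg$prescription) && cfg$prescription > 0,
      "prescription", "must be > 0 (Gy)")
  chk(length(cfg$grid_shape) == 3L && all(cfg$grid_shape >= 8),
      "grid_shape", "must be 3 voxel counts, each >= 8")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "seed", "must be a finite integer")
  invisible(cfg)
}

#' Read a cohort configuration from YAML or JSON
#'
#' Field names mirror [cohort_config()] exactly; unknown fields are rejected
#' so that typos fail loudly before any computation.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         "; valid fields: ", paste(known, collapse = ", "), call. = FALSE)
  }
  do.call(cohort_config, raw)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config:", x$n_patients, "patients,",
      x$n_fractions, "fractions of", x$prescription / x$n_fractions,
      "Gy\n  grid", paste(x$grid_shape, collapse = "x"),
      "voxels @", x$voxel_spacing, "mm; errors (sys/rand/resid)",
      paste(c(x$sigma_systematic, x$sigma_random, x$sigma_residual),
            collapse = "/"),
      "mm; seed", x$seed, "\n")
  invisible(x)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-patient sub-seeds derived from the master seed
patient_seeds <- function(config) {
  with_seed(config$seed, sample.int(.Machine$integer.max, config$n_patients))
}

# stable hash of a configuration, for provenance stamping of outputs
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
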