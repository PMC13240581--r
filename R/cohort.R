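#' Sample per-fraction setup errors for one patient
#'
#' Pre-correction shifts follow the standard systematic + random
#' decomposition: a per-patient systematic offset drawn once per axis from
#' `N(0, sigma_systematic^2)`, plus an independent per-fraction term from
#' `N(0, sigma_random^2)`. Post-correction (image-guided) shifts are small
#' per-fraction residuals from `N(0, sigma_residual^2)`. All draws are fixed
#' by the master seed and the patient id, independent of evaluation order.
#'
#' @param config a [cohort_config()].
#' @param patient_id integer in `1:n_patients`.
#' @return An object of class `setup_error_series`: list with `patient_id`,
#'   `pre_shift` and `post_shift` (`n_fractions` x 3 matrices, mm).
#' @export
sample_setup_errors <- function(config, patient_id) {
  validate_cohort_config(config)
  patient_id <- as.integer(patient_id)
  if (patient_id < 1L || patient_id > config$n_patients) {
    stop("patient_id must be in 1:", config$n_patients)
  }
  seed_p <- patient_seeds(config)[patient_id]
  n <- config$n_fractions
  with_seed(seed_p, {
    mu <- stats::rnorm(3, 0, config$sigma_systematic)
    eps <- matrix(stats::rnorm(3 * n, 0, config$sigma_random), n, 3,
                  byrow = TRUE)
    res <- matrix(stats::rnorm(3 * n, 0, config$sigma_residual), n, 3,
                  byrow = TRUE)
    pre <- sweep(eps, 2, mu, "+")
    colnames(pre) <- colnames(res) <- c("x", "y", "z")
    structure(list(patient_id = patient_id, pre_shift = pre, post_shift = res),
              class = "setup_error_series")
  })
}

#' Simulate one patient of the synthetic cohort
#'
#' Draws the patient's setup-error series and emulates per-fraction dose
#' delivery by rigid translation of the shared planned dose: for each
#' fraction, a pre-correction grid (full setup error) and a post-correction
#' grid (residual error after image-guided couch correction).
#'
#' @param config a [cohort_config()].
#' @param patient_id integer patient index.
#' @param phantom optional precomputed [build_phantom()] result (the phantom
#'   is shared across the cohort; pass it to avoid rebuilding).
#' @return A list with `patient_id`, `errors`, and `fractions` (a list of
#'   `n_fractions` records, each `list(fraction_index, dose_pre, dose_post)`).
#' @export
simulate_patient <- function(config, patient_id, phantom = NULL) {
  if (is.null(phantom)) phantom <- build_phantom(config)
  errs <- sample_setup_errors(config, patient_id)
  n <- config$n_fractions
  fractions <- lapply(seq_len(n), function(f) {
    list(fraction_index = f,
         dose_pre = deliver_fraction(phantom$planned, errs$pre_shift[f, ], n),
         dose_post = deliver_fraction(phantom$planned, errs$post_shift[f, ], n))
  })
  list(patient_id = patient_id, errors = errs, fractions = fractions)
}

#' Simulate the whole cohort in memory
#'
#' Convenience wrapper for small grids; for large cohorts prefer
#' [generate_cohort()] (streams to disk patient by patient) or
#' [evaluate_cohort()] on a config (streams through evaluation).
#'
#' @param config a [cohort_config()].
#' @return A list of class `sim_cohort`: `config`, `phantom`, `patients`.
#' @export
simulate_cohort <- function(config) {
  phantom <- build_phantom(config)
  patients <- lapply(seq_len(config$n_patients), simulate_patient,
                     config = config, phantom = phantom)
  structure(list(config = config, phantom = phantom, patients = patients),
            class = "sim_cohort")
}

# ---- on-disk cohort container -------------------------------------------
# one directory per patient: header.json + raw little-endian float32 dose
# arrays (planned.f32, fx_###_pre.f32, fx_###_post.f32) and uint8 masks
# (mask_<name>.u8); top-level manifest.json ties the cohort together.

write_f32 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
}

read_f32 <- function(path, dim) {
  con <- file(path, "rb")
  on.exit(close(con))
  array(readBin(con, "numeric", n = prod(dim), size = 4L, endian = "little"),
        dim)
}

write_u8 <- function(mask, path) {
  writeBin(as.raw(mask * 1L), path)
}

read_u8 <- function(path, dim) {
  array(as.integer(readBin(path, "raw", n = prod(dim))) > 0L, dim)
}

patient_dirname <- function(id) sprintf("patient_%02d", id)

#' Generate the synthetic cohort on disk
#'
#' Streams the cohort patient by patient into the documented container
#' format: per patient a JSON header, the shared planned dose, uint8
#' structure masks and per-fraction pre/post-correction dose grids as raw
#' little-endian 32-bit floats; a top-level `manifest.json` lists patients,
#' fractions, per-patient seeds and the configuration. Fully deterministic:
#' config + seed fix every emitted byte. The manifest is written last, so a
#' partial write leaves no valid manifest.
#'
#' @param config a [cohort_config()].
#' @param path output directory (created; must be empty or absent).
#' @return `path`, invisibly.
#' @export
generate_cohort <- function(config, path) {
  validate_cohort_config(config)
  if (dir.exists(path) && length(list.files(path)) > 0L) {
    stop("output directory exists and is not empty: ", path)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  phantom <- build_phantom(config)
  d <- config$grid_shape
  seeds <- patient_seeds(config)
  for (p in seq_len(config$n_patients)) {
    pdir <- file.path(path, patient_dirname(p))
    dir.create(pdir)
    pat <- simulate_patient(config, p, phantom)
    header <- list(
      patient_id = p,
      seed = seeds[p],
      grid_shape = d,
      voxel_spacing = config$voxel_spacing,
      origin = phantom$planned$origin,
      axis_order = "x,y,z column-major (x fastest); x lateral, y AP, z SI",
      dtype = "float32 little-endian (doses), uint8 (masks)",
      structures = names(phantom$masks),
      n_fractions = config$n_fractions
    )
    jsonlite::write_json(header, file.path(pdir, "header.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_f32(phantom$planned$values, file.path(pdir, "planned.f32"))
    for (nm in names(phantom$masks)) {
      write_u8(phantom$masks[[nm]]$mask, file.path(pdir, paste0("mask_", nm, ".u8")))
    }
    utils::write.csv(
      data.frame(fraction = seq_len(config$n_fractions),
                 pre_x = pat$errors$pre_shift[, 1],
                 pre_y = pat$errors$pre_shift[, 2],
                 pre_z = pat$errors$pre_shift[, 3],
                 post_x = pat$errors$post_shift[, 1],
                 post_y = pat$errors$post_shift[, 2],
                 post_z = pat$errors$post_shift[, 3]),
      file.path(pdir, "setup_errors.csv"), row.names = FALSE, quote = FALSE)
    for (fx in pat$fractions) {
      base <- sprintf("fx_%03d", fx$fraction_index)
      write_f32(fx$dose_pre$values, file.path(pdir, paste0(base, "_pre.f32")))
      write_f32(fx$dose_post$values, file.path(pdir, paste0(base, "_post.f32")))
    }
  }
  manifest <- list(
    format = "igsched-cohort-v1",
    config = unclass(config),
    config_hash = config_hash(config),
    patients = vapply(seq_len(config$n_patients), patient_dirname, character(1)),
    patient_seeds = seeds,
    n_fractions = config$n_fractions,
    structures = names(phantom$masks)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest
#' @param path cohort directory written by [generate_cohort()].
#' @return The parsed manifest list.
#' @export
read_cohort_manifest <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop("no manifest.json in '", path, "': not a valid cohort directory")
  }
  jsonlite::read_json(mf, simplifyVector = TRUE)
}

#' Read one patient from an on-disk cohort
#'
#' @param path cohort directory.
#' @param patient_id integer patient index.
#' @return Same structure as [simulate_patient()] plus `planned` and `masks`.
#' @export
read_patient <- function(path, patient_id) {
  manifest <- read_cohort_manifest(path)
  pdir <- file.path(path, patient_dirname(patient_id))
  hdr <- jsonlite::read_json(file.path(pdir, "header.json"),
                             simplifyVector = TRUE)
  d <- as.integer(hdr$grid_shape)
  sp <- hdr$voxel_spacing
  planned <- dose_grid(read_f32(file.path(pdir, "planned.f32"), d), sp,
                       hdr$origin)
  masks <- stats::setNames(lapply(hdr$structures, function(nm) {
    structure_mask(nm, read_u8(file.path(pdir, paste0("mask_", nm, ".u8")), d))
  }), hdr$structures)
  errs <- utils::read.csv(file.path(pdir, "setup_errors.csv"))
  n <- hdr$n_fractions
  fractions <- lapply(seq_len(n), function(f) {
    base <- sprintf("fx_%03d", f)
    pre <- file.path(pdir, paste0(base, "_pre.f32"))
    post <- file.path(pdir, paste0(base, "_post.f32"))
    if (!file.exists(pre) || !file.exists(post)) {
      stop("missing fraction data for patient ", patient_id, ", fraction ", f)
    }
    list(fraction_index = f,
         dose_pre = dose_grid(read_f32(pre, d), sp, hdr$origin),
         dose_post = dose_grid(read_f32(post, d), sp, hdr$origin))
  })
  list(patient_id = patient_id,
       planned = planned, masks = masks,
       errors = list(pre_shift = as.matrix(errs[, c("pre_x", "pre_y", "pre_z")]),
                     post_shift = as.matrix(errs[, c("post_x", "post_y", "post_z")])),
       fractions = fractions,
       manifest = manifest)
}
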