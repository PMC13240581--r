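# shared fixtures: everything is generated in code at test time

# small, fast cohort configuration (coarse grid, few patients)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 3, grid_shape = 20, voxel_spacing = 8, seed = 42),
    list(...))
  do.call(cohort_config, args)
}

# dose grid with a constant dose everywhere, plus an all-TRUE mask
uniform_grid <- function(dose, d = c(6, 6, 6), spacing = 4) {
  dose_grid(array(dose, d), spacing)
}

full_mask <- function(d = c(6, 6, 6), name = "S") {
  structure_mask(name, array(TRUE, d))
}

# DVH of a uniform dose (handy for analytic radiobiology checks)
uniform_dvh <- function(dose, bin_width = 0.05) {
  compute_dvh(uniform_grid(dose), full_mask(), bin_width)
}

# memoised scaled-down default cohort evaluation shared across tests:
# 10 patients on a 24^3 grid at the default 4 mm spacing and error model
.eval_cache <- new.env(parent = emptyenv())
scaled_cohort_records <- function() {
  if (is.null(.eval_cache$records)) {
    cfg <- cohort_config(n_patients = 10, grid_shape = 24, voxel_spacing = 4,
                         seed = 314159)
    .eval_cache$records <- evaluate_cohort(cfg)
  }
  .eval_cache$records
}
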