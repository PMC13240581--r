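test_that("setup errors follow the systematic+random decomposition", {
  # degenerate noise: all sigmas zero -> every shift exactly zero
  cfg0 <- tiny_config(sigma_systematic = 0, sigma_random = 0,
                      sigma_residual = 0)
  e0 <- sample_setup_errors(cfg0, 1)
  expect_true(all(e0$pre_shift == 0))
  expect_true(all(e0$post_shift == 0))

  # determinism: same seed and patient -> identical series
  cfg <- cohort_config(seed = 7, grid_shape = 20, voxel_spacing = 8)
  e1 <- sample_setup_errors(cfg, 1)
  e2 <- sample_setup_errors(cfg, 1)
  expect_identical(e1, e2)
  expect_equal(dim(e1$pre_shift), c(cfg$n_fractions, 3))

  # per-axis sd of pre-correction shifts ~ sqrt(3^2 + 3^2) = 4.243 mm;
  # sd of a sample sd over n=25 draws is about sigma/sqrt(2(n-1)) = 0.61,
  # so accept within 3 estimator-sd of the mixture value
  sig <- sqrt(cfg$sigma_systematic^2 + cfg$sigma_random^2)
  tol <- 3 * sig / sqrt(2 * (cfg$n_fractions - 1))
  sds <- apply(e1$pre_shift, 2, sd)
  expect_true(all(abs(sds - sig) < tol))

  # different patients get different draws
  expect_false(identical(e1$pre_shift,
                         sample_setup_errors(cfg, 2)$pre_shift))

  expect_error(sample_setup_errors(cfg, cfg$n_patients + 1), "patient_id")
  expect_error(cohort_config(sigma_random = -1), "sigma_random")
})

test_that("pooled pre-correction variance matches sigma_sys^2 + sigma_rand^2", {
  # > 1e4 draws across many patients (the systematic term varies between
  # patients, so pooling across patients exposes the full mixture variance)
  cfg <- cohort_config(n_patients = 450, n_fractions = 25,
                       grid_shape = 20, voxel_spacing = 8, seed = 99)
  pre <- do.call(rbind, lapply(seq_len(cfg$n_patients), function(p) {
    sample_setup_errors(cfg, p)$pre_shift
  }))
  expect_gte(nrow(pre), 1e4)
  v_target <- cfg$sigma_systematic^2 + cfg$sigma_random^2
  v_hat <- apply(pre, 2, var)
  # sampling error of the variance over ~11k correlated draws; 10% is ample
  expect_true(all(abs(v_hat / v_target - 1) < 0.10))
})

test_that("phantom anatomy and planned dose satisfy the plan-quality gates", {
  cfg <- tiny_config()
  ph <- build_phantom(cfg)
  expect_setequal(names(ph$masks), structure_names())
  # disjoint targets, all structures nonempty and inside the grid
  expect_false(any(ph$masks$PTVsc$mask & ph$masks$PTVcw$mask))
  for (m in ph$masks) expect_true(any(m$mask))

  pl <- ph$planned$values
  for (t in c("PTVcw", "PTVsc")) {
    d95 <- dvh_metric(compute_dvh(ph$planned, ph$masks[[t]]), "D95")
    expect_gte(d95, 0.95 * cfg$prescription)
  }
  ptv <- ph$masks$PTVcw$mask | ph$masks$PTVsc$mask
  expect_lt(mean(pl[ph$masks$heart$mask]), mean(pl[ptv]))

  # penumbra_width -> 0 degenerates to a binary prescription/background field
  ph0 <- build_phantom(tiny_config(penumbra_width = 0))
  expect_true(all(ph0$planned$values %in% c(0, cfg$prescription)))
})

test_that("deliver_fraction shifts the planned dose rigidly", {
  cfg <- tiny_config()
  ph <- build_phantom(cfg)
  n <- cfg$n_fractions

  # identity shift: exactly planned/n
  f0 <- deliver_fraction(ph$planned, c(0, 0, 0), n)
  expect_equal(f0$values, ph$planned$values / n)

  # one-voxel +x translation: interior voxels equal the index-shifted plan
  f1 <- deliver_fraction(ph$planned, c(cfg$voxel_spacing, 0, 0), n)
  d <- dim(ph$planned$values)
  expect_equal(f1$values[2:d[1], , ], ph$planned$values[1:(d[1] - 1), , ] / n,
               tolerance = 1e-12)

  # a 10 mm lateral error strictly degrades the single-fraction PTVcw D95
  f10 <- deliver_fraction(ph$planned, c(10, 0, 0), n)
  d95_0 <- dvh_metric(compute_dvh(f0, ph$masks$PTVcw, 0.01), "D95")
  d95_10 <- dvh_metric(compute_dvh(f10, ph$masks$PTVcw, 0.01), "D95")
  expect_lt(d95_10, d95_0)

  expect_error(deliver_fraction(ph$planned, c(1e4, 0, 0), n), "extent")
})

test_that("cohort container round-trips and is byte-deterministic", {
  cfg <- tiny_config(n_patients = 2, n_fractions = 3)
  dir1 <- file.path(tempdir(), "coh1")
  dir2 <- file.path(tempdir(), "coh2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  generate_cohort(cfg, dir1)
  generate_cohort(cfg, dir2)

  # 2 patients x 3 fractions x 2 positional states = 12 fraction dose grids
  fx_files <- list.files(dir1, pattern = "^fx_.*\\.f32$", recursive = TRUE)
  expect_length(fx_files, 12)

  # identical config -> byte-identical manifests (and dose payloads)
  expect_identical(readLines(file.path(dir1, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))
  f <- file.path("patient_01", "fx_002_pre.f32")
  expect_identical(readBin(file.path(dir1, f), "raw", n = 1e6),
                   readBin(file.path(dir2, f), "raw", n = 1e6))

  # read-back matches the in-memory simulation to float32 precision
  sim <- simulate_patient(cfg, 1)
  rd <- read_patient(dir1, 1)
  expect_equal(rd$fractions[[2]]$dose_pre$values,
               sim$fractions[[2]]$dose_pre$values, tolerance = 1e-6)
  expect_equal(rd$errors$pre_shift, unclass(sim$errors$pre_shift),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_setequal(names(rd$masks), structure_names())

  # refusing to clobber, and no manifest means no cohort
  expect_error(generate_cohort(cfg, dir1), "not empty")
  expect_error(read_cohort_manifest(tempdir()), "manifest")
})
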