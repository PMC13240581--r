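test_that("accumulate sums voxelwise and respects geometry", {
  g <- uniform_grid(2, d = c(5, 4, 3))
  expect_equal(accumulate(list(g))$values, g$values)

  set.seed(1)
  gs <- lapply(1:25, function(i) {
    dose_grid(array(runif(60), c(5, 4, 3)), 4)
  })
  tot <- accumulate(gs)
  # partition of unity: 25 copies of x/25 reassemble x
  parts <- lapply(1:25, function(i) dose_grid(tot$values / 25, 4))
  expect_equal(accumulate(parts)$values, tot$values, tolerance = 1e-6)
  # commutativity
  expect_equal(accumulate(rev(gs))$values, tot$values, tolerance = 1e-9)

  expect_error(accumulate(list()), "non-empty")
  expect_error(accumulate(list(g, uniform_grid(1, d = c(4, 4, 3)))),
               "geometry")
})

test_that("cumulative DVH matches its defining step functions", {
  # uniform dose: volume 1 up to the dose, 0 beyond
  dvh <- uniform_dvh(50)
  expect_equal(dvh$cum_volume[dvh$edges <= 50], rep(1, sum(dvh$edges <= 50)))
  expect_equal(dvh$cum_volume[dvh$edges > 50], rep(0, sum(dvh$edges > 50)))

  # two-level dose: half at 10, half at 30 -> volume 0.5 anywhere in (10, 30]
  vals <- array(rep(c(10, 30), each = 108), c(6, 6, 6))
  dvh2 <- compute_dvh(dose_grid(vals, 4), full_mask())
  mid <- dvh2$edges > 10 & dvh2$edges <= 30
  expect_equal(dvh2$cum_volume[mid], rep(0.5, sum(mid)))

  # DVH invariant block
  expect_equal(dvh2$cum_volume[1], 1)
  expect_true(all(diff(dvh2$cum_volume) <= 0))
  expect_equal(dvh2$cum_volume[length(dvh2$cum_volume)], 0)

  expect_error(compute_dvh(uniform_grid(1), full_mask(d = c(5, 5, 5))),
               "geometry")
})

test_that("random-grid DVHs match the brute-force sorted-voxel curve", {
  set.seed(7)
  for (rep in 1:5) {
    d <- array(runif(12^3, 0, 60), c(12, 12, 12))
    dvh <- compute_dvh(dose_grid(d, 4), full_mask(c(12, 12, 12)))
    # oracle: at each edge, the fraction of voxels with dose >= edge
    oracle <- vapply(dvh$edges, function(e) mean(d >= e), numeric(1))
    expect_equal(dvh$cum_volume, oracle, tolerance = 1e-12)
  }
})

test_that("DVH metrics reproduce direct percentile and mean arithmetic", {
  # 95 voxels at 50 Gy, 5 at 10 Gy (as a 100-voxel grid)
  vals <- array(c(rep(10, 5), rep(50, 95)), c(10, 10, 1))
  dvh <- compute_dvh(dose_grid(vals, 4), full_mask(c(10, 10, 1)))
  expect_equal(dvh_metric(dvh, "D95"), 50)
  expect_equal(dvh_metric(dvh, "Dmean"), 48, tolerance = dvh$bin_width / 2 + 1e-9)
  expect_equal(dvh_metric(dvh, "Dmax"), 50, tolerance = dvh$bin_width)

  u <- uniform_dvh(50)
  for (m in c("D95", "Dmean", "Dmax")) {
    expect_equal(dvh_metric(u, m), 50, tolerance = u$bin_width)
  }
  expect_error(dvh_metric(u, "D42"), "arg")
})

test_that("metrics agree with voxel-level oracles and are bin-stable", {
  set.seed(21)
  for (rep in 1:8) {
    d <- array(runif(10^3, 0, 55), c(10, 10, 10))
    dvh <- compute_dvh(dose_grid(d, 4), full_mask(c(10, 10, 10)))
    # D95 within one bin width of the raw 5th percentile
    expect_equal(dvh_metric(dvh, "D95"),
                 unname(quantile(d, 0.05, type = 4)),
                 tolerance = dvh$bin_width)
    # Dmean within half a bin width of the raw mean
    expect_equal(dvh_metric(dvh, "Dmean"), mean(d),
                 tolerance = dvh$bin_width / 2)
    # refinement changes metrics by less than the coarse bin width
    fine <- compute_dvh(dose_grid(d, 4), full_mask(c(10, 10, 10)), 0.01)
    for (m in c("D95", "Dmean", "Dmax")) {
      expect_equal(dvh_metric(dvh, m), dvh_metric(fine, m),
                   tolerance = dvh$bin_width)
    }
  }
})

test_that("DVH CSV dialect round-trips", {
  dvh <- uniform_dvh(20)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_dvh_csv(dvh, path)
  expect_identical(readLines(path, n = 1), "dose_gy,cum_volume_fraction")
  back <- read_dvh_csv(path, structure = "S")
  expect_equal(back$edges, dvh$edges)
  expect_equal(back$cum_volume, dvh$cum_volume)
  expect_equal(dvh_metric(back, "D95"), dvh_metric(dvh, "D95"))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_dvh_csv(bad), "DVH CSV")
  unlink(bad)
})
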