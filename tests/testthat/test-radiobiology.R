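test_that("EQD2 conversion follows LQ arithmetic", {
  # 2 Gy/fraction is the fixed point for any alpha/beta
  expect_equal(eqd2(50, 25, 4), 50)
  expect_equal(eqd2(50, 25, 3), 50)
  # 60 Gy in 25 fx, alpha/beta 3: 60 * (2.4 + 3) / 5 = 64.8
  expect_equal(eqd2(60, 25, 3), 64.8)
  # vectorised over bin doses, monotone
  expect_equal(eqd2(c(0, 50), 25, 4), c(0, 50))
  expect_true(all(diff(eqd2(seq(0, 80, 0.5), 25, 3)) > 0))
  expect_error(eqd2(50, 0, 4), "n_fractions")

  dvh <- uniform_dvh(60)
  conv <- dvh_eqd2(dvh, 25, 3)
  expect_equal(conv$cum_volume, dvh$cum_volume)
  expect_equal(max(conv$edges[conv$cum_volume > 0]),
               eqd2(max(dvh$edges[dvh$cum_volume > 0]), 25, 3))
})

test_that("Poisson-LQ TCP honours its analytic anchors", {
  p <- tcp_params(tcd50 = 39.3, gamma = 1.7, alpha_beta = 4)
  # TCD50 definition: uniform dose at TCD50 -> exactly half control
  expect_equal(poisson_tcp(39.3, p), 0.5)
  # saturation limits
  expect_gt(poisson_tcp(1e6, p), 1 - 1e-12)
  expect_lt(poisson_tcp(1, p), 1e-12)

  # two-bin DVH: half volume at TCD50, half at 60 Gy; volume-weighted
  # product of per-bin responses computed by hand
  P <- function(D) 2^(-exp(exp(1) * 1.7 * (1 - D / 39.3)))
  hand <- P(39.3)^0.5 * P(60)^0.5
  expect_equal(poisson_tcp(c(39.3, 60), p, volume = c(0.5, 0.5)), hand)

  # the same through a genuine two-level DVH, up to half-bin discretisation
  vals <- array(rep(c(39.3, 60), each = 108), c(6, 6, 6))
  dvh <- compute_dvh(dose_grid(vals, 4), full_mask(), 0.01)
  expect_equal(poisson_tcp(dvh, p), hand, tolerance = 1e-3)

  expect_error(poisson_tcp(c(40, 50), p, volume = c(0.6, 0.6)), "sum to 1")
})

test_that("gEUD is a power mean with the right limits", {
  set.seed(5)
  d <- runif(200, 10, 60)
  v <- rep(1 / 200, 200)
  # n = 1: arithmetic mean
  expect_equal(geud(d, 1, v), mean(d), tolerance = 1e-9)
  # uniform dose: gEUD = D for any n
  for (n in c(0.05, 0.35, 0.87, 1)) expect_equal(geud(rep(20, 4), n), 20)
  # n -> 0+: approaches the maximum dose (two-level distribution)
  two <- c(20, 50)
  expect_equal(geud(two, 0.01, c(0.5, 0.5)), 50, tolerance = 0.5)
  # bounded by [Dmin, Dmax]
  for (n in c(0.1, 0.5, 1)) {
    g <- geud(d, n, v)
    expect_gte(g, min(d)); expect_lte(g, max(d))
  }
  expect_error(geud(d, 0), "in \\(0, 1]")
  expect_error(geud(d, 1.2), "in \\(0, 1]")
})

test_that("LKB NTCP matches the probit form for both OAR parameter rows", {
  heart <- ntcp_params(td50 = 48, m = 0.1, n = 0.35, alpha_beta = 3)
  lung <- ntcp_params(td50 = 30.8, m = 0.18, n = 0.87, alpha_beta = 3)
  # uniform EQD2 at TD50 -> exactly 0.5
  expect_equal(lkb_ntcp(48, heart), 0.5)
  expect_equal(lkb_ntcp(30.8, lung), 0.5)
  # one slope unit above TD50 -> standard normal at 1
  expect_equal(lkb_ntcp(48 * 1.1, heart), pnorm(1), tolerance = 1e-9)
  expect_equal(lkb_ntcp(30.8 * 1.18, lung), pnorm(1), tolerance = 1e-9)
  # typical low OAR dose: complication probability is negligible
  expect_lt(lkb_ntcp(8, heart), 1e-3)
})

test_that("dose-response curves are monotone and numerically stable", {
  p <- tcp_params(39.3, 1.7, 4)
  heart <- ntcp_params(48, 0.1, 0.35, 3)
  doses <- seq(0.5, 200, 0.5)
  tcp <- vapply(doses, poisson_tcp, numeric(1), params = p)
  ntcp <- vapply(doses, lkb_ntcp, numeric(1), params = heart)
  expect_true(all(is.finite(tcp)) && all(is.finite(ntcp)))
  expect_true(all(diff(tcp) >= 0) && all(diff(ntcp) >= 0))
  expect_true(all(tcp >= 0 & tcp <= 1) && all(ntcp >= 0 & ntcp <= 1))
  # a 200 Gy DVH neither overflows nor leaves [0, 1]
  hot <- uniform_dvh(200)
  expect_equal(poisson_tcp(hot, p), 1, tolerance = 1e-6)
  expect_true(lkb_ntcp(hot, heart) <= 1)
})

test_that("the shipped parameter registry carries the reference values", {
  reg <- default_radiobio_params()
  expect_equal(reg$tcp$PTVcw$tcd50, 39.3)
  expect_equal(reg$tcp$PTVsc$gamma, 1.7)
  expect_equal(reg$ntcp$heart$td50, 48)
  expect_equal(reg$ntcp$heart$n, 0.35)
  expect_equal(reg$ntcp$lung_ipsi$td50, 30.8)
  expect_equal(reg$ntcp$lung_ipsi$m, 0.18)
  expect_identical(reg$ntcp$lung_ipsi$endpoint, "pneumonitis")
})
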