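test_that("two-state k_obs follows the exchange scheme", {
  expect_equal(simulate_kobs(ex2_model(1, 999, 1)), 1e-3)
  # k_cl -> 0: every opening exchanges
  expect_equal(simulate_kobs(ex2_model(0.5, 1e-12, 10)), 0.5,
               tolerance = 1e-9)
  # EX2 approximation within 1% when k_cl = 100 k_int
  m <- ex2_model(k_op = 2, k_cl = 100, k_int = 1)
  exact <- simulate_kobs(m)
  ex2 <- m$k_op * m$k_int / m$k_cl
  expect_lt(abs(ex2 - exact) / exact, 0.0100001)
  expect_error(ex2_model(0, 1, 1))
})

test_that("EX2 limit holds across a k_cl/k_int sweep", {
  set.seed(5)
  for (ratio in c(100, 300, 1e3, 1e4, 1e6)) {
    k_int <- 10^runif(1, -2, 1)
    m <- ex2_model(k_op = 10^runif(1, -4, 0), k_cl = ratio * k_int,
                   k_int = k_int)
    rel <- abs(m$k_op * m$k_int / m$k_cl - simulate_kobs(m)) /
      simulate_kobs(m)
    expect_lt(rel, 0.0100001)
  }
  # k_obs is below both k_op and k_int
  m <- ex2_model(0.3, 5, 2)
  expect_lt(simulate_kobs(m), m$k_op)
  expect_lt(simulate_kobs(m), m$k_int)
})

test_that("HX decay fits recover slow rates and flag poor coverage", {
  tgrid <- seq(3600, 10 * 3600, by = 3600)
  cv <- decay_curve(5, tgrid, exp(-1e-4 * tgrid))
  ft <- fit_hx_decay(cv)
  expect_equal(ft$k_obs, 1e-4, tolerance = 1e-9)
  expect_equal(ft$flags, "")
  # sampled only to t = 0.1 / k
  short <- seq(100, 1000, by = 100)
  expect_warning(ft2 <- fit_hx_decay(decay_curve(5, short,
                                                 exp(-1e-4 * short))),
                 "poorly constrained")
  expect_match(ft2$flags, "poorly constrained")
  expect_equal(ft2$k_obs, 1e-4, tolerance = 0.01 * 1e-4)
})

test_that("flat and rising HX curves are flagged, not dropped", {
  expect_warning(ft <- fit_hx_decay(decay_curve(1, 1:5, rep(3, 5) +
                                                  c(0, 1e-15, 0, 0, 0))),
                 "flat")
  expect_equal(ft$k_obs, 0)
  expect_warning(ft2 <- fit_hx_decay(
    decay_curve(1, 1:5, c(1, 1.1, 1.25, 1.33, 1.5))), "increasing")
  expect_match(ft2$flags, "increasing")
})

test_that("CLEANEX initial slope is exact on a line through the origin", {
  tau <- c(0, 0.010, 0.015, 0.020, 0.025)
  cs <- cleanex_initial_slope(data.frame(tau = tau, ratio = 40 * tau))
  expect_equal(cs$k, 40, tolerance = 1e-12)
  expect_error(cleanex_initial_slope(data.frame(tau = 0.01, ratio = 0.4)),
               ">= 2")
  expect_warning(cleanex_initial_slope(
    data.frame(tau = c(0.01, 0.08), ratio = c(0.2, 0.9))), "50 ms")
})

test_that("initial-slope curvature bias on saturating buildup is quantified", {
  tau <- c(0, 0.010, 0.015, 0.020, 0.025)
  k <- 20
  cs <- cleanex_initial_slope(data.frame(tau = tau,
                                         ratio = 1 - exp(-k * tau)))
  # closed-form oracle for the through-origin least-squares slope of a
  # saturating buildup sampled on this grid: 18.0% downward bias
  tt <- tau[-1]
  k_oracle <- sum(tt * (1 - exp(-k * tt))) / sum(tt^2)
  expect_equal(cs$k, k_oracle, tolerance = 1e-9)
  expect_lt(abs(cs$k - k) / k, 0.20)
  expect_lt(cs$k, k)    # curvature always biases the slope downward
})

test_that("intrinsic rates are monotone in pD and temperature", {
  s <- "GANDVLKSTE"
  expect_true(all(intrinsic_rates(s, 7.0, 310)$k_int >
                    intrinsic_rates(s, 6.5, 310)$k_int))
  expect_true(all(intrinsic_rates(s, 6.5, 353)$k_int >
                    intrinsic_rates(s, 6.5, 310)$k_int))
  expect_error(intrinsic_rates("AZA", 7, 310), "unknown residue")
  expect_error(intrinsic_rates("A", 7, 310), ">= 2")
  # prolines carry no amide
  expect_false(3 %in% intrinsic_rates("AAPA", 7, 310)$residue)
})

test_that("poly-alanine interior rate equals the hand-evaluated reference", {
  # independent spreadsheet-style evaluation over the bundled constants:
  # interior Ala/Ala amide has zero side-chain corrections, so
  # k = (10^1.62 * 10^-pD + 10^10.05 * 10^(pD-15.05) + 10^-1.5) / 60
  # at the 293 K reference temperature
  pD <- 7
  expected <- (10^1.62 * 10^(-pD) + 10^10.05 * 10^(pD - 15.05) +
                 10^(-1.5)) / 60
  ki <- intrinsic_rates("AAAAAA", pD, 293)
  expect_equal(ki$k_int[ki$residue == 3], expected, tolerance = 1e-12)
  expect_equal(ki$k_int[ki$residue == 4], expected, tolerance = 1e-12)
})

test_that("protection factors implement logP = log10(k_int / k_obs)", {
  pf <- protection_factors(
    data.frame(residue = c(2, 3), k_obs = c(0.01, 10)),
    data.frame(residue = c(2, 3), k_int = c(10, 10)))
  expect_equal(pf$logP[1], 3)
  expect_equal(pf$logP[2], 0, tolerance = 1e-12)
  # k_obs > k_int flagged but reported
  expect_warning(pf2 <- protection_factors(
    data.frame(residue = 2, k_obs = 20),
    data.frame(residue = 2, k_int = 10)), "EX2")
  expect_equal(pf2$logP, log10(0.5))
  expect_match(pf2$flags, "nonphysical")
})

test_that("logP is invariant under common time-unit rescaling", {
  ko <- data.frame(residue = 2:4, k_obs = c(1e-4, 5e-3, 2e-2))
  ki <- data.frame(residue = 2:4, k_int = c(1, 2, 4))
  p1 <- protection_factors(ko, ki)$logP
  ko$k_obs <- ko$k_obs * 60; ki$k_int <- ki$k_int * 60
  expect_equal(protection_factors(ko, ki)$logP, p1, tolerance = 1e-12)
})

test_that("the EX2 pipeline recovers log10(k_cl/k_op) on synthetic ensembles", {
  ki <- intrinsic_rates("AAAAAAAA", 7, 310)
  set.seed(8)
  for (i in seq_len(nrow(ki))) {
    logP <- runif(1, 2, 4)
    k_cl <- 1e3 * ki$k_int[i]
    k_op <- k_cl * 10^(-logP)
    m <- ex2_model(k_op, k_cl, ki$k_int[i])
    rec <- log10(ki$k_int[i] / simulate_kobs(m))
    expect_equal(rec, log10(k_cl / k_op), tolerance = 1e-3)
  }
})
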