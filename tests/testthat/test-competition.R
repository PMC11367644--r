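test_that("stationary reporter probability matches hand arithmetic and limits", {
  # full symmetry: every state equally likely
  expect_equal(unname(p1_stationary(1, 1, 1, 1)["P1"]), 1 / 3)
  expect_equal(p1_stationary(1, 1, 1, 1, variant = "printed"), 1 / 3)
  # no competitor: two-state occupancy u1/(u1+w1)
  expect_equal(unname(p1_stationary(2, 1, 0, 1)["P1"]), 2 / 3)
  # hand-computed asymmetric case
  expect_equal(p1_stationary(1, 1, 4, 2, variant = "printed"), 1 / 6)
  expect_equal(unname(p1_stationary(1, 1, 4, 2)["P1"]), 1 / 4)
  # probabilities sum to one
  expect_equal(sum(p1_stationary(0.3, 1.7, 2.2, 0.9)), 1)
  expect_error(p1_stationary(1, 0, 1, 0), "dissociation")
  expect_error(p1_stationary(-1, 1, 1, 1), "nonnegative")
})

test_that("detailed-balance variant agrees with brute-force stationary distribution", {
  set.seed(42)
  for (i in 1:1000) {
    r <- runif(4, 0.01, 10)
    mine <- p1_stationary(r[1], r[2], r[3], r[4])
    oracle <- stationary_3state(r[1], r[2], r[3], r[4])
    expect_lt(max(abs(mine - oracle)), 1e-10)
  }
})

test_that("in the printed variant the competitor dissociation rate cancels", {
  set.seed(7)
  for (i in 1:200) {
    r <- runif(4, 0.01, 10)
    expect_equal(p1_stationary(r[1], r[2], r[3], r[4], variant = "printed"),
                 r[1] / (r[2] + r[1] + r[3]), tolerance = 1e-12)
  }
})

test_that("unmodified-competitor displacement isotherm has the right shape", {
  expect_equal(y_unmodified(0.0006, 0), 1)
  expect_equal(y_unmodified(2, 0.5), 0.5)          # a0 * conc = 1
  expect_equal(y_unmodified(0.0006, 1000), 1 / 1.6)
  conc <- c(0, 1, 10, 100, 1000, 1e4)
  expect_true(all(diff(y_unmodified(0.0006, conc)) < 0))
  expect_true(all(y_unmodified(0.0006, conc) > 0 &
                    y_unmodified(0.0006, conc) <= 1))
  expect_error(y_unmodified(0.0006, -1), ">= 0")
})

test_that("phosphorylated-competitor isotherm applies the Boltzmann factor", {
  p <- competition_params(a0 = 0.0006, dE = 9.4, temperature = 300)
  # degenerate case: no barrier difference
  p0 <- competition_params(a0 = 0.0006, dE = 0)
  conc <- c(0, 5, 50, 500, 5000)
  expect_equal(y_phospho(p0, conc), y_unmodified(0.0006, conc))
  # enhancing convention: factor exp(+|dE|/kT) ~ 43.3 at 300 K
  f <- exp(9.4 / kT_kJ(300))
  expect_equal(f, 43.3, tolerance = 2e-3)
  expect_equal(y_phospho(p, 100), 1 / (1 + 0.0006 * f * 100))
  expect_equal(y_phospho(p, 100), 0.278, tolerance = 2e-3)
  # phosphorylation always strengthens competition
  expect_true(all(y_phospho(p, conc) <= y_unmodified(0.0006, conc)))
  # printed convention weakens it instead, as typeset
  pp <- competition_params(0.0006, 9.4, 300, sign_convention = "printed")
  expect_true(all(y_phospho(pp, conc[-1]) > y_unmodified(0.0006, conc[-1])))
})

test_that("displacement isotherms are scale-consistent and obey the half-shift law", {
  p <- competition_params(a0 = 0.0006, dE = 9.4, temperature = 300)
  for (s in c(0.1, 3, 100)) {
    expect_equal(y_unmodified(0.0006, 700), y_unmodified(0.0006 * s, 700 / s))
  }
  # concentration at half displacement: c2/c1 = exp(-|dE|/kT)
  c1 <- 1 / p$a0
  c2 <- 1 / (p$a0 * exp(abs(p$dE) / kT_kJ(p$temperature)))
  expect_equal(y_unmodified(p$a0, c1), 0.5, tolerance = 1e-12)
  expect_equal(y_phospho(p, c2), 0.5, tolerance = 1e-12)
  expect_equal(c2 / c1, exp(-abs(p$dE) / kT_kJ(p$temperature)), tolerance = 1e-9)
})

test_that("a0 fitting recovers truth, matches the closed form, and flags no displacement", {
  d <- gen_competition_series(a0 = 0.0006,
                              concentrations = c(50, 200, 1000, 5000, 2e4),
                              cfg = generator_config(seed = 3, noise_sd = 0))
  f <- fit_a0(d)
  expect_lt(abs(f$a0 - 0.0006) / 0.0006, 1e-9)
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(glance(f)$nobs, 5)
  # exactly identified single observation: a0 = (1/y - 1)/c
  y1 <- 0.4; c1 <- 1200
  f1 <- fit_a0(conc = c1, fraction = y1)
  expect_equal(f1$a0, (1 / y1 - 1) / c1, tolerance = 1e-9)
  expect_error(fit_a0(conc = c(10, 20), fraction = c(1, 1)), "unidentifiable")
  expect_error(fit_a0(conc = 10, fraction = 1.2), "\\(0, 1\\]")
})

test_that("a0 estimate is accurate under measurement noise (simulation study)", {
  ests <- vapply(1:100, function(s) {
    d <- gen_competition_series(a0 = 0.0006,
                                concentrations = c(100, 300, 1000, 3000, 10000),
                                cfg = generator_config(seed = s, noise_sd = 0.02))
    fit_a0(d)$a0
  }, numeric(1))
  expect_lt(abs(median(ests) - 0.0006) / 0.0006, 0.15)
})

test_that("displacement-curve table is consistent with pointwise evaluation", {
  p <- competition_params(a0 = 0.0006, dE = 9.4, temperature = 300)
  expect_equal(nrow(predict_displacement_curve(p, numeric(0))), 0)
  tab0 <- predict_displacement_curve(p, 0)
  expect_equal(tab0$y1, 1)
  set.seed(11)
  conc <- sort(runif(20, 0, 2e4))
  tab <- predict_displacement_curve(p, conc)
  expect_identical(tab$y1, y_unmodified(0.0006, conc))
  expect_identical(tab$y2, y_phospho(p, conc))
  expect_identical(attr(tab, "params")$sign_convention, "enhancing")
})
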