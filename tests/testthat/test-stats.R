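test_that("min-max normalization matches its closed form", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(41)
  x <- rnorm(100)
  expect_equal(minmax_normalize(x), (x - min(x)) / (max(x) - min(x)))
})

test_that("normality gate routes to the right test", {
  set.seed(42)
  expect_equal(normality_gate(rnorm(200), rnorm(200)), "t_test")
  expect_equal(normality_gate(rexp(200), rnorm(200)), "mann_whitney")
  # tiny ties-heavy input: returns a decision, no crash
  expect_true(normality_gate(c(1, 1, 2), c(3, 3, 3)) %in%
                c("t_test", "mann_whitney"))
})

test_that("Mann-Whitney U uses exact enumeration for small samples", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")

  same <- mann_whitney(1:10, 1:10)
  expect_gt(same$p, 0.9)

  set.seed(43)
  big <- mann_whitney(rnorm(200), rnorm(200) + 2)
  expect_lt(big$p, 1e-6)
})

test_that("partial Spearman residualizes ranks on covariates", {
  set.seed(44)
  n <- 300
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  covars <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  res <- partial_spearman(x, y, covars)
  plain <- cor(x, y, method = "spearman")
  expect_lt(abs(res$rho - plain), 0.02)
  expect_equal(res$n, n)

  # monotone-transform invariance and exact rho = 1 for y = f(x)
  res1 <- partial_spearman(x, exp(x))
  expect_equal(res1$rho, 1)
  res2a <- partial_spearman(x, y, covars)
  res2b <- partial_spearman(exp(x), y^3, covars)
  expect_equal(res2a$rho, res2b$rho, tolerance = 1e-12)

  # y fully determined by a covariate, x independent -> rho ~ 0
  c3 <- rnorm(n)
  res3 <- partial_spearman(rnorm(n), 2 * c3, data.frame(c3 = c3))
  expect_lt(abs(res3$rho), 0.1)

  expect_error(partial_spearman(x, y, data.frame(a = c3, b = 2 * c3)),
               "rank-deficient")
  expect_error(partial_spearman(1:5, 1:5), "complete cases")
})

test_that("segmented fit recovers a hinge and degrades gracefully", {
  set.seed(45)
  x <- runif(200, 0, 10)
  y <- 0.02 * pmax(0, x - 7) + rnorm(200, 0, 0.005)
  fit <- segmented_fit(x, y)
  expect_lt(abs(fit$breakpoint - 7), 0.5)
  expect_lt(abs(fit$slope_below), 0.004)
  expect_lt(abs(fit$slope_above_combined - 0.02), 0.004)
  expect_lt(fit$davies_p, 0.01)
  expect_true(fit$supported)

  # noiseless linear data: hinge adds nothing, R2 = 1
  xl <- seq(0, 10, length.out = 50)
  fl <- segmented_fit(xl, 2 * xl + 1)
  expect_equal(fl$r2, 1, tolerance = 1e-9)
  expect_lt(abs(fl$slope_above_combined - 2), 1e-6)

  # hinge survives a covariate confound when the covariate is included
  set.seed(46)
  cv <- rnorm(200)
  y2 <- 0.02 * pmax(0, x - 7) + 0.01 * cv + rnorm(200, 0, 0.005)
  fit2 <- segmented_fit(x, y2, data.frame(cv = cv))
  expect_lt(abs(fit2$breakpoint - 7), 0.5)
  expect_error(segmented_fit(1:10, 1:10), "n >= 15")
})

test_that("segmented model never fits worse than the plain linear model", {
  set.seed(47)
  for (k in 1:5) {
    x <- runif(60, 0, 10)
    y <- 0.1 * x + rnorm(60)
    fit <- segmented_fit(x, y)
    r2_lin <- summary(lm(y ~ x))$r.squared
    expect_gte(fit$r2 + 1e-12, r2_lin)
  }
})

test_that("Davies test rejects hinge signal and not pure noise", {
  set.seed(48)
  x <- runif(200, 0, 10)
  y <- 0.02 * pmax(0, x - 7) + rnorm(200, 0, 0.005)
  expect_lt(davies_test(x, y), 0.01)

  meds <- replicate(100, {
    xn <- runif(50, 0, 10)
    davies_test(xn, rnorm(50))
  })
  expect_gt(median(meds), 0.3)
  expect_lt(median(meds), 0.8)
})

test_that("bootstrap mediation recovers full and null mediation", {
  set.seed(49)
  n <- 500
  x <- rnorm(n)
  m <- 0.8 * x + rnorm(n, 0, 0.6)
  y <- 0.8 * m + rnorm(n, 0, 0.6)
  res <- mediation_bootstrap(x, m, y, n_boot = 1000, seed = 7)
  expect_lt(abs(res$indirect - 0.64), 0.05)
  expect_lte(res$direct_ci95[1], 0)
  expect_gte(res$direct_ci95[2], 0)
  expect_lt(abs(res$total - res$direct - res$indirect), 1e-8)

  # same seed -> bit-identical CIs
  res2 <- mediation_bootstrap(x, m, y, n_boot = 1000, seed = 7)
  expect_identical(res$indirect_ci95, res2$indirect_ci95)

  # null: y unrelated to x and m
  yn <- rnorm(n)
  resn <- mediation_bootstrap(x, m, yn, n_boot = 500, seed = 8)
  expect_lte(resn$indirect_ci95[1], 0)
  expect_gte(resn$indirect_ci95[2], 0)

  # no mediation: direct path only
  mn <- rnorm(n)
  yd <- 0.8 * x + rnorm(n, 0, 0.6)
  resd <- mediation_bootstrap(x, mn, yd, n_boot = 500, seed = 9)
  expect_lt(abs(resd$indirect), 0.05)
  expect_lt(abs(resd$direct - 0.8 / sd(yd)), 0.1)
})

test_that("BH adjustment matches the hand-rolled step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(50)
  for (k in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
  }
})
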