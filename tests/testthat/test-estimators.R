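test_that("the Wald ratio follows the delta-method closed form and sign rule", {
  h <- makeHset(bx = 0.1, by = 0.05, sey = 0.01)
  w <- waldRatio(h)
  expect_equal(estimate(w), 0.5)
  expect_equal(stdError(w), 0.1)

  h0 <- makeHset(bx = 0.1, by = 0, sey = 0.01)
  w0 <- waldRatio(h0)
  expect_equal(estimate(w0), 0)
  expect_equal(pValue(w0), 1)

  expect_error(waldRatio(makeHset(bx = 0, by = 0.1, sey = 0.01)),
               "zero")

  set.seed(2)
  for (i in 1:20) {
    bx <- rnorm(1); by <- rnorm(1)
    if (bx == 0) next
    w <- waldRatio(makeHset(bx = bx, by = by, sey = 0.01))
    expect_equal(sign(estimate(w)), sign(bx) * sign(by))
  }
})

test_that("single-instrument IVW equals the Wald ratio to machine precision", {
  h <- makeHset(bx = 0.12, by = 0.07, sey = 0.013)
  expect_equal(estimate(ivw(h, "fixed")), estimate(waldRatio(h)),
               tolerance = 1e-15)
  expect_equal(stdError(ivw(h, "fixed")), stdError(waldRatio(h)),
               tolerance = 1e-15)
  expect_warning(ivw(h, "multiplicative_random"), "single instrument")
})

test_that("IVW equals the explicit weighted-least-squares normal equations", {
  # five fixed rows
  bx <- c(0.10, 0.08, 0.12, 0.05, 0.09)
  by <- c(0.051, 0.038, 0.062, 0.024, 0.047)
  sey <- c(0.010, 0.012, 0.009, 0.015, 0.011)
  h <- makeHset(bx, by, sey)
  o <- wlsOracle(matrix(bx), by, 1 / sey^2)
  est <- ivw(h, "fixed")
  expect_equal(estimate(est), o$coef, tolerance = 1e-12)
  expect_equal(stdError(est), sqrt(o$cov[1, 1]), tolerance = 1e-12)

  # zero heterogeneity: exact line gives Q = 0 and mre se = fixed se
  hz <- makeHset(bx, 0.4 * bx, sey)
  fe <- ivw(hz, "fixed"); mre <- ivw(hz, "multiplicative_random")
  expect_equal(estimate(fe), 0.4, tolerance = 1e-12)
  expect_equal(attr(fe, "Q"), 0, tolerance = 1e-20)
  expect_equal(stdError(mre), stdError(fe))
})

test_that("IVW agrees with a fixed-effect meta-analysis of Wald ratios", {
  skip_if_not_installed("metafor")
  set.seed(7)
  bx <- rnorm(8, 0.1, 0.02); by <- 0.3 * bx + rnorm(8, 0, 0.01)
  sey <- runif(8, 0.008, 0.015)
  h <- makeHset(bx, by, sey)
  m <- metafor::rma(yi = by / bx, sei = sey / abs(bx), method = "FE")
  expect_equal(estimate(ivw(h, "fixed")), as.numeric(m$beta),
               tolerance = 1e-10)
  expect_equal(stdError(ivw(h, "fixed")), m$se, tolerance = 1e-10)
})

test_that("IVW invariances: SNP duplication acts as weight doubling; scaling is equivariant; MRE p >= FE p", {
  set.seed(12)
  bx <- rnorm(6, 0.1, 0.03); by <- 0.2 * bx + rnorm(6, 0, 0.012)
  sey <- runif(6, 0.008, 0.015)
  h <- makeHset(bx, by, sey)

  dup <- makeHset(c(bx, bx[1]), c(by, by[1]), c(sey, sey[1]))
  w <- 1 / sey^2; w[1] <- 2 * w[1]
  o <- wlsOracle(matrix(bx), by, w)
  expect_equal(estimate(ivw(dup, "fixed")), o$coef, tolerance = 1e-12)

  h2 <- makeHset(bx, 3 * by, 3 * sey)
  expect_equal(estimate(ivw(h2, "fixed")), 3 * estimate(ivw(h, "fixed")))
  expect_equal(stdError(ivw(h2, "multiplicative_random")),
               3 * stdError(ivw(h, "multiplicative_random")))

  expect_gte(pValue(ivw(h, "multiplicative_random")),
             pValue(ivw(h, "fixed")))
})

test_that("Egger recovers exact linear data to machine precision and matches weighted lm", {
  bx <- c(0.05, 0.08, 0.11, 0.14, 0.2)
  sey <- c(0.01, 0.012, 0.009, 0.011, 0.01)
  by <- 0.1 + 0.5 * bx
  e <- mrEgger(makeHset(bx, by, sey))
  expect_equal(estimate(e), 0.5, tolerance = 1e-12)
  expect_equal(eggerIntercept(e)[["intercept"]], 0.1, tolerance = 1e-12)

  # independent route: stats::lm with weights (after beta_x >= 0
  # orientation, a no-op here)
  set.seed(3)
  by2 <- 0.1 + 0.5 * bx + rnorm(5, 0, 0.02)
  e2 <- mrEgger(makeHset(bx, by2, sey))
  fit <- lm(by2 ~ bx, weights = 1 / sey^2)
  expect_equal(estimate(e2), unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(eggerIntercept(e2)[["intercept"]], unname(coef(fit)[1]),
               tolerance = 1e-12)
  # lm's summary rescales by residual variance; compare through the
  # same multiplicative factor, floored at 1 in our convention
  J <- 5
  Qp <- sum((1 / sey^2) * residuals(fit)^2)
  lm_se <- summary(fit)$coefficients[, 2] / sqrt(Qp / (J - 2))
  ours <- c(eggerIntercept(e2)[["se"]], stdError(e2)) /
    max(1, sqrt(Qp / (J - 2)))
  expect_equal(ours, unname(lm_se), tolerance = 1e-10)

  expect_error(mrEgger(makeHset(bx[1:2], by[1:2], sey[1:2])),
               "at least 3")
})

test_that("Egger orientation makes the fit invariant to per-SNP sign conventions", {
  set.seed(9)
  bx <- rnorm(10, 0.1, 0.04); by <- 0.05 + 0.3 * bx + rnorm(10, 0, 0.01)
  sey <- runif(10, 0.008, 0.012)
  e1 <- mrEgger(makeHset(bx, by, sey))
  flip <- rep(c(1, -1), 5)
  e2 <- mrEgger(makeHset(bx * flip, by * flip, sey))
  expect_equal(estimate(e2), estimate(e1), tolerance = 1e-12)
  expect_equal(eggerIntercept(e2), eggerIntercept(e1), tolerance = 1e-12)
})

test_that("the weighted median interpolates cumulative weights correctly", {
  # equal weights (bx = 1, sey = 1): ratios are the by values
  h3 <- makeHset(bx = c(1, 1, 1), by = c(1, 2, 3), sey = c(1, 1, 1))
  expect_equal(estimate(weightedMedian(h3, nBoot = 50, seed = 1)), 2)
  h4 <- makeHset(bx = rep(1, 4), by = c(1, 2, 3, 4), sey = rep(1, 4))
  expect_equal(estimate(weightedMedian(h4, nBoot = 50, seed = 1)), 2.5)

  # hand-computed unequal weights: w = (bx/sey)^2 = (4, 1, 1) on ratios
  # (1, 2, 3): standardized cumulative weights p = (1/3, 3/4, 11/12), so
  # the 0.5 quantile interpolates between r=1 (p=1/3) and r=2 (p=3/4)
  h5 <- makeHset(bx = c(2, 1, 1), by = c(2, 2, 3), sey = c(1, 1, 1))
  expect_equal(estimate(weightedMedian(h5, nBoot = 50, seed = 1)),
               1 + (0.5 - 1 / 3) / (3 / 4 - 1 / 3), tolerance = 1e-12)

  # bootstrap SE is seed-reproducible
  set.seed(31)
  h <- makeHset(rnorm(8, 0.1, 0.02), rnorm(8, 0.02, 0.01),
                runif(8, 0.008, 0.015))
  expect_identical(stdError(weightedMedian(h, 200, seed = 5)),
                   stdError(weightedMedian(h, 200, seed = 5)))
})

test_that("multivariable IVW reduces to IVW, solves exact linear data, and matches the WLS oracle", {
  set.seed(15)
  bx <- rnorm(7, 0.1, 0.03); by <- 0.25 * bx + rnorm(7, 0, 0.01)
  sey <- runif(7, 0.008, 0.015)
  uni <- mvIvw(matrix(bx), by, sey)
  expect_equal(estimate(uni[[1]]), estimate(ivw(makeHset(bx, by, sey),
                                                "fixed")),
               tolerance = 1e-14)

  X <- cbind(x1 = rnorm(10, 0.1, 0.05), x2 = rnorm(10, 0.05, 0.04))
  y <- 0.3 * X[, 1] + 0 * X[, 2]
  mv <- mvIvw(X, y, rep(0.01, 10))
  expect_equal(unname(estimate(mv[[1]])), 0.3, tolerance = 1e-12)
  expect_equal(unname(estimate(mv[[2]])), 0, tolerance = 1e-12)

  for (rep in 1:10) {
    set.seed(100 + rep)
    J <- sample(6:15, 1)
    X <- matrix(rnorm(J * 3, 0.1, 0.05), J)
    y <- drop(X %*% c(0.2, -0.1, 0)) + rnorm(J, 0, 0.01)
    sey <- runif(J, 0.005, 0.02)
    o <- wlsOracle(X, y, 1 / sey^2)
    mv <- mvIvw(X, y, sey)
    expect_equal(unname(vapply(mv, estimate, numeric(1))), unname(o$coef),
                 tolerance = 1e-12)
  }

  expect_error(mvIvw(cbind(bx, bx), by, sey), "collinear")
  expect_error(mvIvw(matrix(rnorm(4), 2), rnorm(2), c(0.01, 0.01)),
               "more SNPs than exposures")
})

test_that("binary outcomes carry OR = exp(beta) with consistently exponentiated CI", {
  h <- makeHset(bx = c(0.1, 0.12, 0.09), by = c(0.05, 0.06, 0.04),
                sey = c(0.01, 0.011, 0.012), outcomeType = "binary",
                caseFraction = 0.2)
  est <- ivw(h, "multiplicative_random")
  expect_equal(oddsRatio(est), exp(estimate(est)))
  ci <- confInt(est)
  expect_equal(exp(ci), c(exp(ci[1]), exp(ci[2])))
  expect_true(exp(ci[1]) <= oddsRatio(est) &&
              oddsRatio(est) <= exp(ci[2]))
})

test_that("the Egger intercept detects directional pleiotropy", {
  hits <- vapply(1:30, function(seed) {
    s <- simulatePair(simConfig(nSnps = 50L, causalBeta = 0.2,
                                pleiotropyMode = "directional",
                                invalidFraction = 0.3,
                                pleiotropySd = 0.05, seed = seed))
    ic <- eggerIntercept(mrEgger(hsetFromSim(s)))
    ic[["intercept"]] > 0 && ic[["pval"]] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
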