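test_that("Cochran's Q is zero on an exact line and calibrated under the null", {
  bx <- c(0.1, 0.08, 0.12, 0.07)
  h <- makeHset(bx, 0.3 * bx, sey = rep(0.01, 4))
  q <- cochranQ(h, theta = 0.3)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 3L)

  # null calibration: E[Q/(J-1)] ~ 1 over simulated homogeneous data
  ratios <- vapply(1:80, function(seed) {
    s <- simulatePair(simConfig(nSnps = 30L, causalBeta = 0.2,
                                seed = seed))
    q <- cochranQ(hsetFromSim(s))
    q$Q / q$df
  }, numeric(1))
  # slight inflation (~ theta^2 se_x^2 / se_y^2) is expected because Q
  # ignores exposure-side sampling noise
  expect_equal(mean(ratios), 1, tolerance = 0.1)

  # a gross outlier inflates Q decisively
  rej <- vapply(1:40, function(seed) {
    s <- simulatePair(simConfig(nSnps = 30L, causalBeta = 0.2,
                                seed = seed))
    h <- hsetFromSim(s)
    st <- snpTable(h)
    st$beta_y[1] <- st$beta_y[1] + 10 * st$se_y[1]
    cochranQ(harmonizedSet(st))$pval < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("leave-one-out produces one estimate per SNP and flags dominant instruments", {
  h <- makeHset(bx = c(0.1, 0.11, 0.09), by = c(0.03, 0.033, 0.027),
                sey = rep(0.01, 3))
  loo <- leaveOneOut(h)
  expect_equal(nrow(loo), 3)
  expect_setequal(loo$snp_id, snpTable(h)$snp_id)

  # independent oracle: drop each row and refit IVW
  for (j in 1:3) {
    st <- snpTable(h)[-j, ]
    expect_equal(loo$beta[j], estimate(ivw(harmonizedSet(st), "fixed")),
                 tolerance = 1e-12)
  }

  # homogeneous simulated data: every LOO estimate within 2 SE of full
  s <- simulatePair(simConfig(nSnps = 40L, causalBeta = 0.2, seed = 13))
  hs <- hsetFromSim(s)
  full <- ivw(hs, "fixed")
  loo2 <- leaveOneOut(hs)
  expect_true(all(abs(loo2$beta - estimate(full)) <= 2 * loo2$se))

  # one SNP carrying ~90% of weight whose removal kills significance
  hd <- makeHset(bx = c(1, 0.05, 0.05, 0.05),
                 by = c(0.3, 0.001, -0.002, 0.002),
                 sey = c(0.05, 0.01, 0.01, 0.01))
  looD <- leaveOneOut(hd)
  expect_true(looD$flag[1])
})

test_that("MR-PRESSO is seed-reproducible, returns valid p-values, and is row-order invariant", {
  s <- simulatePair(simConfig(nSnps = 25L, causalBeta = 0.2, seed = 17))
  h <- hsetFromSim(s)
  a <- mrPresso(h, nSim = 300, seed = 5)
  b <- mrPresso(h, nSim = 300, seed = 5)
  expect_identical(globalPval(a), globalPval(b))
  expect_identical(a@outlierPvals, b@outlierPvals)
  expect_true(globalPval(a) > 0 && globalPval(a) <= 1)
  expect_true(all(a@outlierPvals > 0 & a@outlierPvals <= 1))

  st <- snpTable(h)
  hperm <- harmonizedSet(st[sample(nrow(st)), ])
  cperm <- mrPresso(hperm, nSim = 300, seed = 5)
  expect_identical(globalPval(cperm), globalPval(a))
  expect_identical(cperm@outlierPvals, a@outlierPvals)

  # no outliers detected: distortion absent, corrected equals raw
  expect_length(outlierIds(a), 0)
  expect_true(is.na(a@distortionPval))
  expect_identical(estimate(a@betaCorrected), estimate(a@betaRaw))

  expect_error(mrPresso(makeHset(1:3 / 10, 1:3 / 20, rep(0.01, 3))),
               "at least 4")
})

test_that("MR-PRESSO detects injected gross outliers and the distortion test reports them", {
  s <- simulatePair(simConfig(nSnps = 30L, causalBeta = 0.2, seed = 23))
  st <- snpTable(hsetFromSim(s))
  bad <- c(3, 11, 20)
  st$beta_y[bad] <- st$beta_y[bad] + 10 * st$se_y[bad]
  h <- harmonizedSet(st)
  pr <- mrPresso(h, nSim = 1000, seed = 7)
  expect_setequal(outlierIds(pr), st$snp_id[bad])
  expect_lt(globalPval(pr), 0.05)
  expect_false(is.na(pr@distortionPval))
  expect_equal(pr@distortionCoef,
               100 * (estimate(pr@betaRaw) - estimate(pr@betaCorrected)) /
                 abs(estimate(pr@betaCorrected)))
  # corrected estimate is computed on the non-outlying SNPs
  expect_equal(nSnps(pr@betaCorrected), nrow(st) - 3)
})

test_that("Steiger compares instrument r2 on both traits with Fisher's z", {
  # tie: equal r2 on both sides gives z = 0, p = 1, direction not OK
  h <- makeHset(bx = c(0.1, 0.12), by = c(0.1, 0.12),
                sey = rep(0.01, 2), eafx = c(0.3, 0.4),
                eafy = c(0.3, 0.4))
  st <- steiger(h)
  expect_equal(st@zval, 0)
  expect_equal(pValue(st), 1)
  expect_false(directionOk(st))

  # antisymmetry: exchanging roles negates z
  h2 <- makeHset(bx = c(0.15, 0.2, 0.1), by = c(0.04, 0.05, 0.02),
                 sey = rep(0.01, 3))
  s1 <- steiger(h2); s2 <- steiger(flipDirection(h2))
  expect_equal(s2@zval, -s1@zval)
  expect_true(directionOk(s1))
  expect_false(directionOk(s2))

  # missing EAF or n must error, never silently pass
  h3 <- makeHset(bx = 0.1 * 1:3, by = 0.02 * 1:3, sey = rep(0.01, 3))
  h3@snps$eaf_y <- NA_real_
  expect_error(steiger(h3), "EAF")

  # binary outcomes use the observed-scale r2 (case-fraction scaled)
  hb <- makeHset(bx = c(0.1, 0.12, 0.09), by = c(0.3, 0.35, 0.2),
                 sey = rep(0.05, 3), outcomeType = "binary",
                 caseFraction = 0.1)
  hc <- makeHset(bx = c(0.1, 0.12, 0.09), by = c(0.3, 0.35, 0.2),
                 sey = rep(0.05, 3))
  sb <- steiger(hb); sc <- steiger(hc)
  expect_equal(sb@r2Outcome, sc@r2Outcome * 0.1 * 0.9)

  # forward-causal simulations: direction recovered, improving with n
  ok_small <- 0; ok_large <- 0
  for (seed in 1:30) {
    s_small <- simulatePair(simConfig(nSnps = 20L, causalBeta = 0.2,
                                      nExposure = 2e4, nOutcome = 2e4,
                                      exposureH2 = 0.05, seed = seed))
    s_large <- simulatePair(simConfig(nSnps = 20L, causalBeta = 0.2,
                                      nExposure = 2e5, nOutcome = 2e5,
                                      exposureH2 = 0.05, seed = seed))
    ok_small <- ok_small + directionOk(steiger(hsetFromSim(s_small)))
    ok_large <- ok_large + directionOk(steiger(hsetFromSim(s_large)))
  }
  expect_gte(ok_large, ok_small)
  expect_equal(ok_large, 30)
})

test_that("power follows the NCP approximation, equals alpha at beta = 0, and matches Monte Carlo", {
  expect_equal(mrPower(0.05, 1e5, 0)@power, 0.05)
  expect_equal(mrPower(0.05, 1e5, 0, alpha = 0.1)@power, 0.1)

  # monotone in n, r2 and |beta|
  p0 <- mrPower(0.02, 5e4, 0.1)@power
  expect_gt(mrPower(0.02, 1e5, 0.1)@power, p0)
  expect_gt(mrPower(0.04, 5e4, 0.1)@power, p0)
  expect_gt(mrPower(0.02, 5e4, 0.2)@power, p0)
  expect_equal(mrPower(0.5, 1e7, 1)@power, 1)

  # binary outcome scales the NCP by cf(1-cf) and requires cf
  expect_error(mrPower(0.05, 1e5, 0.2, outcomeType = "binary"),
               "caseFraction")
  pb <- mrPower(0.05, 1e5, 0.2, outcomeType = "binary",
                caseFraction = 0.2)
  expect_equal(pb@ncp, 1e5 * 0.05 * 0.04 * 0.2 * 0.8)

  # Monte-Carlo oracle: Wald test of the causal estimate whose sampling
  # variance is 1/(n r2) under the design model
  r2 <- 0.03; n <- 2e4; beta <- 0.02
  set.seed(99)
  theta_hat <- rnorm(2e5, beta, 1 / sqrt(n * r2))
  mc <- mean(abs(theta_hat) * sqrt(n * r2) > qnorm(0.975))
  expect_equal(mrPower(r2, n, beta)@power, mc, tolerance = 0.01)
})

test_that("BH adjustment matches the hand-computed step-up and its invariances", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(numeric(0)), numeric(0))
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # hand-computed unequal case: p=(0.001, 0.04, 0.5) ->
  # q = (0.003, 0.06, 0.5)
  expect_equal(bhFdr(c(0.001, 0.04, 0.5)), c(0.003, 0.06, 0.5))

  set.seed(4)
  p <- runif(25)
  q <- bhFdr(p)
  perm <- sample(25)
  expect_equal(bhFdr(p[perm]), q[perm])             # permutation invariant
  expect_true(all(diff(q[order(p)]) >= -1e-15))     # monotone in sorted order
  expect_true(all(q <= 1) && all(q >= p))
  expect_error(bhFdr(c(0.1, 0)), "\\(0,1\\]")
})
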