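test_that("the significance filter is strict at 5e-8", {
  ss <- makeStats(3, pval = c(4.9e-8, 5e-8, 5.1e-8))
  kept <- significanceFilter(ss)
  expect_equal(snpTable(kept)$snp_id, "rs1")  # boundary value dropped

  set.seed(41)
  p <- c(runif(3, 1e-12, 4e-8), runif(7, 1e-7, 0.5))
  ss10 <- makeStats(10, pval = sample(p))
  expect_equal(nSnps(significanceFilter(ss10)),
               sum(snpTable(ss10)$pval < 5e-8))
})

test_that("clumping keeps the lower-p SNP of a correlated pair and all independent SNPs", {
  ss <- makeStats(2, pval = c(1e-9, 1e-10))
  ld <- ldTable(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  expect_equal(snpTable(clumpInstruments(ss, ld))$snp_id, "rs2")
  expect_equal(nSnps(clumpInstruments(ss, ldTable())), 2)
})

test_that("greedy clumping matches step-by-step rule evaluation on random small instances", {
  # independent oracle: re-evaluate the greedy acceptance rule literally
  greedyOracle <- function(ids, pvals, M, r2max) {
    ord <- order(pvals, ids)
    acc <- character(0)
    for (i in ord) {
      if (all(M[ids[i], acc] < r2max)) acc <- c(acc, ids[i])
    }
    sort(acc)
  }
  for (rep in 1:25) {
    set.seed(rep)
    J <- sample(3:10, 1)
    ids <- sprintf("rs%d", 1:J)
    p <- runif(J, 1e-12, 1e-8)
    M <- diag(J); dimnames(M) <- list(ids, ids)
    for (i in seq_len(J - 1)) for (j in (i + 1):J)
      if (runif(1) < 0.4) M[i, j] <- M[j, i] <- runif(1)
    entries <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
    ld <- ldTable(data.frame(snp_a = ids[entries[, 1]],
                             snp_b = ids[entries[, 2]],
                             r2 = M[entries]))
    ss <- makeStats(J, pval = p)
    got <- sort(snpTable(clumpInstruments(ss, ld, 0.1))$snp_id)
    expect_equal(got, greedyOracle(ids, p, M, 0.1))
    # row-order invariance
    shuf <- summaryStats(snpTable(ss)[sample(J), ], traitType = "continuous")
    expect_equal(sort(snpTable(clumpInstruments(shuf, ld, 0.1))$snp_id),
                 got)
  }
})

test_that("proxy search picks highest r2 above the strict 0.8 bound with p then id tie-breaks", {
  outcome <- makeStats(3, snp_id = c("rsA", "rsB", "rsC"),
                       pval = c(1e-9, 1e-6, 1e-6))
  ld <- ldTable(data.frame(snp_a = rep("rsM", 3),
                           snp_b = c("rsA", "rsB", "rsC"),
                           r2 = c(0.85, 0.95, 0.9)))
  pr <- findProxies("rsM", outcome, ld)
  expect_equal(unname(pr$map["rsM"]), "rsB")
  expect_equal(unname(pr$r2["rsM"]), 0.95)

  # boundary: exactly 0.8 is not a proxy
  ld2 <- ldTable(data.frame(snp_a = "rsM", snp_b = "rsA", r2 = 0.8))
  pr2 <- findProxies("rsM", outcome, ld2)
  expect_length(pr2$map, 0)
  expect_equal(pr2$dropped, "rsM")

  # tie on r2 -> smaller p wins; tie on p -> lexicographic id
  ld3 <- ldTable(data.frame(snp_a = rep("rsM", 2),
                            snp_b = c("rsA", "rsB"), r2 = c(0.9, 0.9)))
  expect_equal(unname(findProxies("rsM", outcome, ld3)$map["rsM"]), "rsA")
  ld4 <- ldTable(data.frame(snp_a = rep("rsM", 2),
                            snp_b = c("rsB", "rsC"), r2 = c(0.9, 0.9)))
  expect_equal(unname(findProxies("rsM", outcome, ld4)$map["rsM"]), "rsB")
})

test_that("MAF/palindrome filter removes complementary pairs and rare variants, keeping the 0.01 boundary", {
  ss <- makeStats(5,
                  effect_allele = c("A", "A", "A", "A", "C"),
                  other_allele = c("T", "G", "G", "G", "A"),
                  eaf = c(0.30, 0.005, 0.99, 0.01, 0.5))
  kept <- mafPalindromeFilter(ss)
  # rs1 palindromic A/T; rs2 maf 0.005 < 0.01; rs3 eaf 0.99 has maf
  # exactly 0.01 and is kept, as is rs4 (eaf 0.01); rs5 common C/A kept
  expect_equal(snpTable(kept)$snp_id, c("rs3", "rs4", "rs5"))

  ssCG <- makeStats(1, effect_allele = "C", other_allele = "G", eaf = 0.4)
  expect_equal(nSnps(mafPalindromeFilter(ssCG)), 0)
  expect_error(mafPalindromeFilter(makeStats(2, eaf = c(0.3, NA))),
               "frequency is missing")
})

test_that("variance explained and F statistics follow their closed forms", {
  expect_equal(varianceExplained(0.5, 0.1), 2 * 0.25 * 0.01)
  expect_equal(varianceExplained(0.5, 0), 0)
  expect_equal(varianceExplained(0.9, 0.2), varianceExplained(0.1, 0.2))
  expect_error(varianceExplained(NA, 0.1), "required")

  expect_equal(fStatistic(0.01, 1002), 1000 * 0.01 / 0.99)
  expect_equal(fStatistic(0, 100), 0)
  expect_error(fStatistic(1, 100), "r2")
  expect_error(fStatistic(0.1, 2), "n")
})

test_that("selection pipeline retains F = 10 exactly and drops weaker instruments", {
  # r2 = 0.5 with n = 12 gives F = (12-2)*0.5/0.5 = 10 exactly
  ss <- makeStats(2, eaf = 0.5, beta = c(1, 0.3), n = 12,
                  pval = c(1e-10, 1e-10))
  iv <- selectInstruments(ss, fMin = 10)
  expect_equal(instruments(iv)$snp_id, "rs1")
  expect_equal(instruments(iv)$f_stat, 10)
})

test_that("on biobank-scale synthetic data the weak-instrument filter is non-binding", {
  s <- simulatePair(simConfig(nSnps = 60L, exposureH2 = 0.1,
                              nExposure = 2e5, seed = 8,
                              causalBeta = 0.1))
  iv <- selectInstruments(s$exposure, s$ld, s$outcome)
  expect_gt(nSnps(iv), 0)
  expect_true(all(instruments(iv)$f_stat > 10))
  # total variance explained tracks the generator's h2
  expect_equal(totalR2(iv), 0.1, tolerance = 0.15)
  # stage log: counts never increase after selection starts
  lg <- stageLog(iv)
  expect_true(all(lg$n_out <= lg$n_in))
})

test_that("proxy substitution replaces outcome-missing instruments with their proxies", {
  # rs1 is a significant instrument missing from the outcome; rsP is a
  # sub-significant exposure SNP in high LD with it and present in the
  # outcome, strong enough (F > 10) to serve as its proxy
  exposure <- makeStats(3, snp_id = c("rs1", "rs2", "rsP"),
                        beta = c(0.1, 0.09, 0.046),
                        se = c(0.01, 0.01, 0.014),
                        pval = c(1e-10, 1e-10, 1e-3),
                        eaf = 0.5, n = 10000)
  outcome <- makeStats(2, snp_id = c("rs2", "rsP"),
                       beta = c(0.02, 0.01), pval = c(1e-3, 0.02))
  ld <- ldTable(data.frame(snp_a = "rs1", snp_b = "rsP", r2 = 0.9))
  iv <- selectInstruments(exposure, ld, outcome)
  expect_setequal(instruments(iv)$snp_id, c("rs2", "rsP"))
  pr <- instruments(iv)[instruments(iv)$snp_id == "rsP", ]
  expect_true(pr$is_proxy)
  expect_equal(pr$proxy_for, "rs1")
  # the proxy carries its own effect estimate, not the original SNP's
  expect_equal(pr$beta, 0.046)
})
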