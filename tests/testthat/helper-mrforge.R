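# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

# minimal per-SNP table with sensible defaults, overridable per column
makeSnps <- function(J = 3, ...) {
  base <- data.frame(
    snp_id = sprintf("rs%d", seq_len(J)),
    chrom = "1", pos = seq_len(J) * 100L,
    effect_allele = "A", other_allele = "G",
    eaf = rep(0.3, J), beta = seq_len(J) / 100,
    se = rep(0.01, J), pval = rep(1e-10, J), n = rep(1e5, J),
    n_cases = NA_real_, n_controls = NA_real_,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

makeStats <- function(J = 3, traitName = "trait",
                      traitType = "continuous", caseFraction = NA_real_,
                      ...) {
  summaryStats(makeSnps(J, ...), traitName = traitName,
               traitType = traitType, caseFraction = caseFraction)
}

# harmonized set straight from effect vectors
makeHset <- function(bx, by, sey, sex = rep(0.005, length(bx)),
                     eafx = rep(0.3, length(bx)), eafy = eafx,
                     nx = rep(2e5, length(bx)), ny = nx,
                     outcomeType = "continuous",
                     caseFraction = NA_real_) {
  harmonizedSet(data.frame(
    snp_id = sprintf("rs%d", seq_along(bx)),
    beta_x = bx, se_x = sex, beta_y = by, se_y = sey,
    eaf_x = eafx, eaf_y = eafy, r2_x = NA_real_,
    n_x = nx, n_y = ny, stringsAsFactors = FALSE),
    outcomeType = outcomeType, caseFraction = caseFraction)
}

# harmonized set from a simulated pair's tables, joined on snp_id with no
# selection (all SNPs retained) -- used when a criterion fixes the SNP set
hsetFromSim <- function(sim) {
  ex <- snpTable(sim$exposure)
  oy <- snpTable(sim$outcome)
  m <- match(ex$snp_id, oy$snp_id)
  harmonizedSet(data.frame(
    snp_id = ex$snp_id, beta_x = ex$beta, se_x = ex$se,
    beta_y = oy$beta[m], se_y = oy$se[m],
    eaf_x = ex$eaf, eaf_y = oy$eaf[m], r2_x = NA_real_,
    n_x = ex$n, n_y = oy$n[m], stringsAsFactors = FALSE),
    exposureName = traitName(sim$exposure),
    outcomeName = traitName(sim$outcome),
    outcomeType = traitType(sim$outcome),
    caseFraction = caseFraction(sim$outcome))
}

# independent weighted-least-squares oracle: explicit normal equations
wlsOracle <- function(X, y, w) {
  X <- as.matrix(X)
  xtwx <- t(X * w) %*% X
  coef <- solve(xtwx, t(X * w) %*% y)
  list(coef = drop(coef), cov = solve(xtwx))
}
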