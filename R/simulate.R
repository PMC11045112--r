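## Evaluate expr with the RNG seeded locally, restoring the caller's
## RNG state afterwards so library code never perturbs user randomness.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Configure the synthetic summary-statistics generator
#'
#' Defaults describe a biobank-scale two-sample design: 50 independent
#' instruments explaining 10 percent of a standardized exposure in GWAS
#' of 200,000 individuals per trait.
#'
#' @param nSnps number of SNPs.
#' @param nExposure,nOutcome GWAS sample sizes.
#' @param causalBeta true causal effect of exposure on outcome.
#' @param pleiotropyMode \code{"none"}, \code{"balanced"} (direct effects
#'   mean zero) or \code{"directional"} (half-normal, positive mean).
#' @param pleiotropySd SD of the direct effects.
#' @param invalidFraction fraction of SNPs given a direct effect.
#' @param exposureH2 total variance explained on the (standardized)
#'   exposure by all SNPs jointly.
#' @param mafRange range the minor allele frequencies are drawn from.
#' @param ldBlockSize,ldRho LD block size and adjacent-pair correlation;
#'   block-diagonal AR(1) structure written to the LD table only.
#' @param outcomeType \code{"continuous"} or \code{"binary"}.
#' @param caseFraction case fraction for a binary outcome.
#' @param seed integer seed controlling all randomness.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSnps = 50L, nExposure = 2e5, nOutcome = 2e5,
                      causalBeta = 0, pleiotropyMode = c("none", "balanced",
                                                         "directional"),
                      pleiotropySd = 0.05, invalidFraction = 0,
                      exposureH2 = 0.1, mafRange = c(0.05, 0.5),
                      ldBlockSize = 1L, ldRho = 0,
                      outcomeType = c("continuous", "binary"),
                      caseFraction = NA_real_, seed = 1L) {
  new("SimConfig", nSnps = as.integer(nSnps), nExposure = nExposure,
      nOutcome = nOutcome, causalBeta = causalBeta,
      pleiotropyMode = match.arg(pleiotropyMode),
      pleiotropySd = pleiotropySd, invalidFraction = invalidFraction,
      exposureH2 = exposureH2, mafRange = mafRange,
      ldBlockSize = as.integer(ldBlockSize), ldRho = ldRho,
      outcomeType = match.arg(outcomeType), caseFraction = caseFraction,
      seed = as.integer(seed))
}

## Shared internals: SNP panel, effect scaling, sampling-noise model.
.simPanel <- function(cfg) {
  J <- cfg@nSnps
  maf <- stats::runif(J, cfg@mafRange[1], cfg@mafRange[2])
  ids <- sprintf("rs%d", seq_len(J) * 7 + 100000)
  list(maf = maf, ids = ids, var_g = 2 * maf * (1 - maf))
}

.simAlpha <- function(cfg, J) {
  alpha <- numeric(J)
  invalid <- integer(0)
  if (cfg@pleiotropyMode != "none" && cfg@invalidFraction > 0) {
    n_inv <- round(cfg@invalidFraction * J)
    if (n_inv > 0) {
      invalid <- sample.int(J, n_inv)
      draw <- stats::rnorm(n_inv, 0, cfg@pleiotropySd)
      alpha[invalid] <- if (cfg@pleiotropyMode == "directional") abs(draw)
                        else draw
    }
  }
  list(alpha = alpha, invalid = sort(invalid))
}

.simTable <- function(ids, maf, beta_hat, se, n, traitName, traitType,
                      caseFraction) {
  pval <- 2 * stats::pnorm(-abs(beta_hat / se))
  pval <- pmax(pval, .Machine$double.xmin)
  snps <- data.frame(snp_id = ids, chrom = "1",
                     pos = seq_along(ids) * 1000L,
                     effect_allele = "A", other_allele = "G",
                     eaf = maf, beta = beta_hat, se = se, pval = pval,
                     n = n,
                     n_cases = if (traitType == "binary")
                       round(caseFraction * n) else NA_real_,
                     n_controls = if (traitType == "binary")
                       n - round(caseFraction * n) else NA_real_,
                     stringsAsFactors = FALSE)
  summaryStats(snps, traitName = traitName, traitType = traitType,
               caseFraction = if (traitType == "binary") caseFraction
                              else NA_real_)
}

.simLd <- function(ids, block, rho) {
  if (block <= 1 || rho == 0)
    return(ldTable())
  J <- length(ids)
  a <- character(0); b <- character(0); r2 <- numeric(0)
  starts <- seq(1, J, by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1, J)
    if (length(idx) < 2) next
    pr <- utils::combn(idx, 2)
    a <- c(a, ids[pr[1, ]]); b <- c(b, ids[pr[2, ]])
    r2 <- c(r2, (rho^(pr[2, ] - pr[1, ]))^2)
  }
  ldTable(data.frame(snp_a = a, snp_b = b, r2 = r2))
}

#' Simulate a two-sample exposure/outcome summary-statistics pair
#'
#' Per-SNP true exposure effects \eqn{\gamma_j} are drawn and rescaled so
#' that \eqn{\sum_j 2 p_j (1-p_j) \gamma_j^2} equals the target
#' heritability.  Estimated effects are the truths plus sampling noise
#' with the standardized-trait standard error
#' \eqn{se = 1/\sqrt{2 p (1-p) n}} (inflated by
#' \eqn{1/\sqrt{cf(1-cf)}} for a binary outcome on the log-odds scale).
#' True outcome effects are \eqn{\Gamma_j = \theta \gamma_j + \alpha_j},
#' with direct effects \eqn{\alpha_j} zero for valid SNPs, normal for
#' balanced pleiotropy and half-normal for directional pleiotropy.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return list with components \code{exposure} and \code{outcome}
#'   (\linkS4class{SummaryStats}), \code{ld} (\linkS4class{LdTable}) and
#'   \code{truth} (\linkS4class{SimTruth}).
#' @export
simulatePair <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  .withSeed(cfg@seed, {
    panel <- .simPanel(cfg)
    J <- cfg@nSnps
    ## effect alleles are reported as the exposure-increasing allele (the
    ## per-allele sign is an arbitrary labelling), so true exposure
    ## effects are non-negative and half-normal direct effects are
    ## genuinely directional relative to the instruments
    raw <- abs(stats::rnorm(J))
    gamma <- raw * sqrt(cfg@exposureH2 / sum(panel$var_g * raw^2))
    pl <- .simAlpha(cfg, J)
    se_x <- 1 / sqrt(panel$var_g * cfg@nExposure)
    beta_x <- stats::rnorm(J, gamma, se_x)
    Gamma <- cfg@causalBeta * gamma + pl$alpha
    se_y <- 1 / sqrt(panel$var_g * cfg@nOutcome)
    if (cfg@outcomeType == "binary")
      se_y <- se_y / sqrt(cfg@caseFraction * (1 - cfg@caseFraction))
    beta_y <- stats::rnorm(J, Gamma, se_y)

    z_max <- max(abs(gamma) / se_x)
    if (z_max + 3 < stats::qnorm(1 - 2.5e-8))
      warning("exposureH2 so small at this sample size that no SNP is ",
              "likely to reach genome-wide significance")

    exposure <- .simTable(panel$ids, panel$maf, beta_x, se_x,
                          cfg@nExposure, "sim_exposure", "continuous",
                          NA_real_)
    outcome <- .simTable(panel$ids, panel$maf, beta_y, se_y,
                         cfg@nOutcome, "sim_outcome", cfg@outcomeType,
                         cfg@caseFraction)
    truth <- new("SimTruth", causalBeta = cfg@causalBeta,
                 alpha = pl$alpha,
                 gamma = matrix(gamma, ncol = 1,
                                dimnames = list(panel$ids, "exposure1")),
                 maf = panel$maf, invalidIds = panel$ids[pl$invalid])
    list(exposure = exposure, outcome = outcome,
         ld = .simLd(panel$ids, cfg@ldBlockSize, cfg@ldRho),
         truth = truth)
  })
}

#' Simulate correlated exposures for multivariable MR
#'
#' All exposures share one SNP panel and one set of allele frequencies
#' (the single-consortium design of lipid GWASs).  Per-SNP true effects
#' on the K exposures are drawn jointly with the given correlation and
#' each column rescaled to the target heritability; outcome effects are
#' \eqn{\Gamma_j = \sum_k \theta_k \gamma_{jk} + \alpha_j}.
#'
#' @param cfg a \linkS4class{SimConfig} (its \code{causalBeta} slot is
#'   ignored in favour of \code{causalBetas}).
#' @param nExposures number of exposures K.
#' @param exposureCorr K x K positive semi-definite correlation matrix of
#'   the true per-SNP effects.
#' @param causalBetas length-K vector of true causal effects.
#' @return list with \code{exposures} (list of
#'   \linkS4class{SummaryStats}), \code{outcome}, \code{ld} and
#'   \code{truth}.
#' @export
simulateMultivariable <- function(cfg, nExposures = 2,
                                  exposureCorr = diag(nExposures),
                                  causalBetas = rep(0, nExposures)) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  exposureCorr <- as.matrix(exposureCorr)
  if (nrow(exposureCorr) != nExposures || ncol(exposureCorr) != nExposures)
    stop("exposureCorr must be ", nExposures, " x ", nExposures)
  if (length(causalBetas) != nExposures)
    stop("causalBetas must have length ", nExposures)
  ev <- eigen(exposureCorr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    stop("exposureCorr must be positive semi-definite")

  .withSeed(cfg@seed, {
    panel <- .simPanel(cfg)
    J <- cfg@nSnps
    ch <- chol(exposureCorr + diag(1e-12, nExposures))
    gamma <- matrix(stats::rnorm(J * nExposures), J) %*% ch
    for (k in seq_len(nExposures))
      gamma[, k] <- gamma[, k] *
        sqrt(cfg@exposureH2 / sum(panel$var_g * gamma[, k]^2))
    dimnames(gamma) <- list(panel$ids, paste0("exposure", seq_len(nExposures)))
    pl <- .simAlpha(cfg, J)
    se_x <- 1 / sqrt(panel$var_g * cfg@nExposure)
    exposures <- lapply(seq_len(nExposures), function(k) {
      bx <- stats::rnorm(J, gamma[, k], se_x)
      .simTable(panel$ids, panel$maf, bx, se_x, cfg@nExposure,
                paste0("sim_exposure", k), "continuous", NA_real_)
    })
    Gamma <- drop(gamma %*% causalBetas) + pl$alpha
    se_y <- 1 / sqrt(panel$var_g * cfg@nOutcome)
    if (cfg@outcomeType == "binary")
      se_y <- se_y / sqrt(cfg@caseFraction * (1 - cfg@caseFraction))
    beta_y <- stats::rnorm(J, Gamma, se_y)
    outcome <- .simTable(panel$ids, panel$maf, beta_y, se_y, cfg@nOutcome,
                         "sim_outcome", cfg@outcomeType, cfg@caseFraction)
    truth <- new("SimTruth", causalBeta = as.numeric(causalBetas),
                 alpha = pl$alpha, gamma = gamma, maf = panel$maf,
                 invalidIds = panel$ids[pl$invalid])
    list(exposures = exposures, outcome = outcome,
         ld = .simLd(panel$ids, cfg@ldBlockSize, cfg@ldRho),
         truth = truth)
  })
}
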