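#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (\beta_{Yj} - \theta \beta_{Xj})^2} with
#' \eqn{w_j = 1/se_{Yj}^2}, referred to a chi-square with J-1 degrees of
#' freedom.  Large Q indicates heterogeneity among per-SNP causal
#' estimates (possible pleiotropy), the trigger for the multiplicative
#' random-effects IVW model.
#'
#' @param hset a \linkS4class{HarmonizedSet} with at least 2 SNPs.
#' @param theta causal effect at which to evaluate Q; defaults to the
#'   fixed-effect IVW estimate.
#' @return list with \code{Q}, \code{df}, \code{pval}.
#' @export
cochranQ <- function(hset, theta = NULL) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  J <- nrow(s)
  if (J < 2) stop("Cochran's Q needs at least 2 instruments")
  w <- 1 / s$se_y^2
  if (is.null(theta))
    theta <- sum(w * s$beta_x * s$beta_y) / sum(w * s$beta_x^2)
  Q <- sum(w * (s$beta_y - theta * s$beta_x)^2)
  list(Q = Q, df = J - 1L,
       pval = stats::pchisq(Q, J - 1L, lower.tail = FALSE))
}

## leave-one-out IVW estimates and SEs via downdated sums, O(J)
.looIvw <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  sxx_j <- sxx - w * bx^2
  theta <- (sxy - w * bx * by) / sxx_j
  list(theta = theta, se = 1 / sqrt(sxx_j),
       full = sxy / sxx, full_se = 1 / sqrt(sxx))
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate excluding each SNP in turn and flags any
#' SNP whose removal changes the estimate's sign or moves its p-value
#' across the 0.05 boundary.
#'
#' @param hset a \linkS4class{HarmonizedSet} with at least 3 SNPs.
#' @return data.frame with one row per excluded SNP: \code{snp_id},
#'   \code{beta}, \code{se}, \code{pval}, \code{flag}.
#' @export
leaveOneOut <- function(hset) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  J <- nrow(s)
  if (J < 3) stop("leave-one-out needs at least 3 instruments")
  w <- 1 / s$se_y^2
  loo <- .looIvw(s$beta_x, s$beta_y, w)
  p <- .normP(loo$theta / loo$se)
  p_full <- .normP(loo$full / loo$full_se)
  flag <- sign(loo$theta) != sign(loo$full) |
    ((p < 0.05) != (p_full < 0.05))
  data.frame(snp_id = s$snp_id, beta = loo$theta, se = loo$se, pval = p,
             flag = flag, stringsAsFactors = FALSE)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Residual-sum-of-squares framework for horizontal pleiotropy.  The
#' observed statistic is \eqn{RSS = \sum_j w_j (\beta_{Yj} -
#' \hat\theta_{-j}\beta_{Xj})^2} with \eqn{\hat\theta_{-j}} the
#' leave-one-out IVW estimate; its null distribution comes from
#' parametric simulation under the fitted model
#' (\eqn{\beta^*_{Xj} \sim N(\beta_{Xj}, se_{Xj}^2)},
#' \eqn{\beta^*_{Yj} \sim N(\hat\theta_{-j}\beta_{Xj}, se_{Yj}^2)}).
#' Per-SNP observed terms tested against their simulated counterparts
#' give the outlier test (flagged at the Bonferroni level sig/J); when
#' outliers exist the distortion test compares the causal estimate
#' before and after their removal against re-estimates with random
#' same-sized SNP subsets removed.  Empirical p-values use the add-one
#' convention (k+1)/(n+1) so they are never exactly zero.
#'
#' @param hset a \linkS4class{HarmonizedSet} with at least 4 SNPs.
#' @param nSim number of parametric simulations, default 1000.
#' @param sig significance level for outlier flagging (Bonferroni
#'   divided by J), default 0.05.
#' @param seed integer seed.
#' @return a \linkS4class{PressoReport}.
#' @export
mrPresso <- function(hset, nSim = 1000, sig = 0.05, seed = 1) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  J <- nrow(s)
  if (J < 4) stop("MR-PRESSO needs at least 4 instruments")
  s <- s[order(s$snp_id), , drop = FALSE]  # row-order invariance of the
  w <- 1 / s$se_y^2                        # seeded simulation
  loo <- .looIvw(s$beta_x, s$beta_y, w)
  term_obs <- w * (s$beta_y - loo$theta * s$beta_x)^2
  rss_obs <- sum(term_obs)

  sim <- .withSeed(seed, {
    BX <- matrix(stats::rnorm(J * nSim, s$beta_x, s$se_x), J)
    BY <- matrix(stats::rnorm(J * nSim, loo$theta * s$beta_x, s$se_y), J)
    sxy <- colSums(w * BX * BY)
    sxx <- colSums(w * BX^2)
    theta_j <- (rep(sxy, each = J) - w * BX * BY) /
               (rep(sxx, each = J) - w * BX^2)
    term <- w * (BY - theta_j * BX)^2
    list(term = term, rss = colSums(term))
  })

  global_p <- (sum(sim$rss >= rss_obs) + 1) / (nSim + 1)
  outlier_p <- (rowSums(sim$term >= term_obs) + 1) / (nSim + 1)
  names(outlier_p) <- s$snp_id
  flagged <- s$snp_id[outlier_p < sig / J]

  model <- if (J >= 2) "multiplicative_random" else "fixed"
  beta_raw <- ivw(hset, model)
  distortion <- NA_real_; dist_p <- NA_real_
  beta_corr <- beta_raw
  if (length(flagged) > 0) {
    if (length(flagged) == J)
      stop("all instruments flagged as outliers; no corrected estimate")
    keep <- !s$snp_id %in% flagged
    corr_set <- harmonizedSet(s[keep, , drop = FALSE],
                              exposureName = hset@exposureName,
                              outcomeName = hset@outcomeName,
                              outcomeType = hset@outcomeType,
                              caseFraction = hset@caseFraction)
    beta_corr <- ivw(corr_set, if (sum(keep) >= 2) "multiplicative_random"
                               else "fixed")
    distortion <- 100 * (beta_raw@beta - beta_corr@beta) /
      abs(beta_corr@beta)
    k <- length(flagged)
    dist_null <- .withSeed(seed + 1L, {
      vapply(seq_len(nSim), function(b) {
        drop_idx <- sample.int(J, k)
        wk <- w[-drop_idx]
        th <- sum(wk * s$beta_x[-drop_idx] * s$beta_y[-drop_idx]) /
              sum(wk * s$beta_x[-drop_idx]^2)
        100 * (beta_raw@beta - th) / abs(th)
      }, numeric(1))
    })
    dist_p <- (sum(abs(dist_null) >= abs(distortion)) + 1) / (nSim + 1)
  }

  new("PressoReport", globalRss = rss_obs, globalPval = global_p,
      outlierPvals = outlier_p, outlierIds = flagged,
      distortionCoef = distortion, distortionPval = dist_p,
      betaRaw = beta_raw, betaCorrected = beta_corr,
      nSim = as.integer(nSim))
}

#' Steiger directionality test
#'
#' Compares the total variance the instruments explain in the exposure
#' versus the outcome.  The implied correlations \eqn{r = \sqrt{r^2}}
#' are Fisher z-transformed and compared with
#' \eqn{z = (z_X - z_Y)/\sqrt{1/(n_X-3) + 1/(n_Y-3)}}.  The assumed
#' causal direction holds iff the exposure r-squared exceeds the outcome
#' r-squared.  For a binary outcome the per-SNP r-squared is computed on
#' the observed 0/1 scale, \eqn{2 maf(1-maf)\,\beta^2\,cf(1-cf)}, using
#' the case fraction.
#'
#' @param hset a \linkS4class{HarmonizedSet} with EAF and sample sizes
#'   for both traits.
#' @return a \linkS4class{SteigerResult}.
#' @export
steiger <- function(hset) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  if (any(is.na(s$eaf_x)) || any(is.na(s$eaf_y)) ||
      any(is.na(s$n_x)) || any(is.na(s$n_y)))
    stop("Steiger test requires EAF and sample size for both traits; ",
         "results failing this test must be excluded, so it cannot be ",
         "skipped silently")
  r2x <- sum(varianceExplained(s$eaf_x, s$beta_x))
  r2y_per <- varianceExplained(s$eaf_y, s$beta_y)
  if (hset@outcomeType == "binary") {
    if (is.na(hset@caseFraction))
      stop("binary outcome requires caseFraction for observed-scale r2")
    r2y_per <- r2y_per * hset@caseFraction * (1 - hset@caseFraction)
  }
  r2y <- sum(r2y_per)
  r2x <- min(r2x, 1 - 1e-12)
  r2y <- min(r2y, 1 - 1e-12)
  nx <- mean(s$n_x); ny <- mean(s$n_y)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  new("SteigerResult", r2Exposure = r2x, r2Outcome = r2y,
      directionOk = r2x > r2y, zval = z, pval = .normP(z))
}

#' Statistical power of a two-sample MR design
#'
#' Non-centrality-parameter approximation for the two-sided Wald test of
#' the causal effect: \eqn{NCP = n\,r^2\,\beta^2} for a continuous
#' outcome, additionally scaled by \eqn{cf(1-cf)} for a binary outcome
#' (log-odds scale), with
#' \eqn{power = 1 - \Phi(z_{1-\alpha/2} - \sqrt{NCP}) +
#' \Phi(-z_{1-\alpha/2} - \sqrt{NCP})}.
#'
#' @param totalR2 variance the instruments explain in the exposure.
#' @param nOutcome outcome GWAS sample size.
#' @param assumedBeta assumed true causal effect (SD or log-odds units).
#' @param alpha significance level, default 0.05.
#' @param outcomeType \code{"continuous"} or \code{"binary"}.
#' @param caseFraction required for binary outcomes.
#' @return a \linkS4class{PowerResult}; \code{assumedBeta = 0} gives
#'   power exactly alpha.
#' @export
mrPower <- function(totalR2, nOutcome, assumedBeta, alpha = 0.05,
                    outcomeType = c("continuous", "binary"),
                    caseFraction = NA_real_) {
  outcomeType <- match.arg(outcomeType)
  if (totalR2 <= 0 || totalR2 >= 1) stop("totalR2 must be in (0,1)")
  if (nOutcome <= 0) stop("nOutcome must be positive")
  ncp <- nOutcome * totalR2 * assumedBeta^2
  if (outcomeType == "binary") {
    if (is.na(caseFraction)) stop("binary outcome requires caseFraction")
    ncp <- ncp * caseFraction * (1 - caseFraction)
  }
  zq <- stats::qnorm(1 - alpha / 2)
  pow <- 1 - stats::pnorm(zq - sqrt(ncp)) + stats::pnorm(-zq - sqrt(ncp))
  new("PowerResult", ncp = ncp, power = pow, alpha = alpha,
      assumedBeta = assumedBeta, totalR2 = totalR2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values \eqn{q_{(i)} = \min_{k \ge i} m p_{(k)}/k} capped at
#' 1, returned in input order.
#'
#' @param pvals numeric vector of p-values in (0,1].
#' @return q-values in input order (empty in, empty out).
#' @export
bhFdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must be in (0,1]")
  stats::p.adjust(pvals, method = "BH")
}
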