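## Normal-reference p and 95% CI are used throughout, the summary-data
## MR convention (not t).
.normP <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

.mrEst <- function(method, beta, se, nSnps, outcomeType = "continuous",
                   intercept = NA_real_, interceptSe = NA_real_,
                   exposure = "", outcome = "") {
  zq <- stats::qnorm(0.975)
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - zq * se, ciHigh = beta + zq * se,
      pval = .normP(beta / se),
      orValue = if (outcomeType == "binary") exp(beta) else NA_real_,
      nSnps = as.integer(nSnps), intercept = intercept,
      interceptSe = interceptSe,
      interceptPval = if (is.na(intercept)) NA_real_
                      else .normP(intercept / interceptSe),
      exposure = exposure, outcome = outcome)
}

#' Wald ratio for a single instrument
#'
#' Causal estimate \eqn{\beta_Y/\beta_X} with first-order delta-method
#' standard error \eqn{se_Y/|\beta_X|} (the exposure-side uncertainty is
#' ignored, standard when instruments pass F >= 10).
#'
#' @param hset a \linkS4class{HarmonizedSet} containing exactly one SNP.
#' @return an \linkS4class{MREstimate} with method \code{"wald"}.
#' @export
waldRatio <- function(hset) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  if (nrow(s) != 1) stop("waldRatio needs exactly one SNP")
  if (s$beta_x == 0) stop("undefined Wald ratio: exposure effect is zero")
  .mrEst("wald", s$beta_y / s$beta_x, s$se_y / abs(s$beta_x), 1,
         hset@outcomeType, exposure = hset@exposureName,
         outcome = hset@outcomeName)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through
#' the origin with weights \eqn{1/se_Y^2}:
#' \deqn{\hat\theta = \sum w_j \beta_{Xj} \beta_{Yj} / \sum w_j \beta_{Xj}^2.}
#' The fixed-effect SE is \eqn{1/\sqrt{\sum w_j \beta_{Xj}^2}}; the
#' multiplicative random-effects model multiplies it by
#' \eqn{\sqrt{Q/(J-1)}} (Cochran's Q of the fit), floored at 1 so the
#' random-effects SE never falls below the fixed-effect one.
#'
#' @param hset a \linkS4class{HarmonizedSet}.
#' @param model \code{"fixed"} or \code{"multiplicative_random"}.
#' @return an \linkS4class{MREstimate} (method \code{ivw_fe} or
#'   \code{ivw_mre}) with attributes \code{Q} and \code{seMultiplier}.
#' @export
ivw <- function(hset, model = c("fixed", "multiplicative_random")) {
  stopifnot(is(hset, "HarmonizedSet"))
  model <- match.arg(model)
  s <- hset@snps
  J <- nrow(s)
  if (J == 1 && model == "multiplicative_random") {
    warning("single instrument: falling back to fixed-effect IVW")
    model <- "fixed"
  }
  w <- 1 / s$se_y^2
  sxx <- sum(w * s$beta_x^2)
  theta <- sum(w * s$beta_x * s$beta_y) / sxx
  se <- 1 / sqrt(sxx)
  Q <- sum(w * (s$beta_y - theta * s$beta_x)^2)
  mult <- 1
  method <- "ivw_fe"
  if (model == "multiplicative_random") {
    mult <- max(1, sqrt(Q / (J - 1)))
    se <- se * mult
    method <- "ivw_mre"
  }
  est <- .mrEst(method, theta, se, J, hset@outcomeType,
                exposure = hset@exposureName, outcome = hset@outcomeName)
  attr(est, "Q") <- Q
  attr(est, "seMultiplier") <- mult
  est
}

#' MR-Egger regression
#'
#' Weighted regression \eqn{\beta_Y = \alpha + \theta \beta_X} with
#' weights \eqn{1/se_Y^2}, after re-signing each SNP so
#' \eqn{\beta_X \ge 0} (required for identifiability of the intercept).
#' The intercept estimates the average directional pleiotropic effect;
#' its p-value is the pleiotropy test.  Both SEs are multiplied by
#' \eqn{\max(1, \sqrt{Q'/(J-2)})} where Q' is the residual weighted sum
#' of squares; the unscaled SEs are available via the
#' \code{seMultiplier} attribute.
#'
#' @param hset a \linkS4class{HarmonizedSet} with at least 3 SNPs.
#' @return an \linkS4class{MREstimate} with method \code{"egger"},
#'   carrying the intercept, its SE and its p-value.
#' @export
mrEgger <- function(hset) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  J <- nrow(s)
  if (J < 3) stop("MR-Egger needs at least 3 instruments")
  sgn <- ifelse(s$beta_x < 0, -1, 1)
  bx <- s$beta_x * sgn
  by <- s$beta_y * sgn
  w <- 1 / s$se_y^2
  X <- cbind(intercept = 1, slope = bx)
  xtw <- t(X * w)
  xtwx <- xtw %*% X
  coef <- drop(solve(xtwx, xtw %*% by))
  resid <- by - drop(X %*% coef)
  Qp <- sum(w * resid^2)
  mult <- max(1, sqrt(Qp / (J - 2)))
  covm <- solve(xtwx)
  se <- sqrt(diag(covm)) * mult
  est <- .mrEst("egger", coef[["slope"]], se[["slope"]], J,
                hset@outcomeType, intercept = coef[["intercept"]],
                interceptSe = se[["intercept"]],
                exposure = hset@exposureName, outcome = hset@outcomeName)
  attr(est, "Q") <- Qp
  attr(est, "seMultiplier") <- mult
  est
}

## weighted-median point estimate on raw vectors (shared with bootstrap)
.wmPoint <- function(bx, by, sey) {
  r <- by / bx
  w <- (bx / sey)^2
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cw <- cumsum(w)
  p <- (cw - w / 2) / cw[length(cw)]
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Per-SNP Wald ratios are ordered and the median taken in the metric of
#' standardized cumulative inverse-variance weights
#' \eqn{w_j = (\beta_{Xj}/se_{Yj})^2}, with linear interpolation at
#' cumulative weight 0.5.  Consistent when instruments carrying at least
#' half the weight are valid.  The SE comes from a parametric bootstrap:
#' effect estimates are resampled from their normal sampling
#' distributions and the estimator recomputed.
#'
#' @param hset a \linkS4class{HarmonizedSet} with at least 3 SNPs.
#' @param nBoot bootstrap replicates, default 1000.
#' @param seed integer seed for the bootstrap.
#' @return an \linkS4class{MREstimate} with method
#'   \code{"weighted_median"}.
#' @export
weightedMedian <- function(hset, nBoot = 1000, seed = 1) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  J <- nrow(s)
  if (J < 3) stop("weighted median needs at least 3 instruments")
  s <- s[order(s$snp_id), , drop = FALSE]  # row-order invariant bootstrap
  theta <- .wmPoint(s$beta_x, s$beta_y, s$se_y)
  se <- .withSeed(seed, {
    boots <- vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(J, s$beta_x, s$se_x)
      by <- stats::rnorm(J, s$beta_y, s$se_y)
      .wmPoint(bx, by, s$se_y)
    }, numeric(1))
    stats::sd(boots)
  })
  .mrEst("weighted_median", theta, se, J, hset@outcomeType,
         exposure = hset@exposureName, outcome = hset@outcomeName)
}

#' Multivariable IVW regression
#'
#' Weighted multiple regression (no intercept) of outcome effects on K
#' exposure-effect columns with weights \eqn{1/se_Y^2}, estimating each
#' exposure's direct effect conditional on the others.  Per-coefficient
#' SEs come from the weighted normal equations, multiplicatively
#' inflated by \eqn{\sqrt{Q/(J-K)}} floored at 1.
#'
#' @param betaX J x K matrix of exposure effects on shared SNPs (or a
#'   list of K \linkS4class{HarmonizedSet}s on the same outcome, merged
#'   on snp_id).
#' @param betaY,seY outcome effects and SEs (ignored when \code{betaX}
#'   is a list).
#' @param exposureNames optional exposure labels.
#' @param outcomeType,outcomeName,caseFraction outcome metadata.
#' @return list of K \linkS4class{MREstimate}s with method
#'   \code{"mv_ivw"}, one per exposure.
#' @export
mvIvw <- function(betaX, betaY = NULL, seY = NULL, exposureNames = NULL,
                  outcomeType = "continuous", outcomeName = "",
                  caseFraction = NA_real_) {
  if (is.list(betaX) && !is.matrix(betaX)) {
    hsets <- betaX
    stopifnot(all(vapply(hsets, is, logical(1), "HarmonizedSet")))
    ids <- Reduce(intersect, lapply(hsets, function(h) h@snps$snp_id))
    if (length(ids) == 0) stop("no shared SNPs across exposures")
    betaX <- vapply(hsets, function(h) {
      s <- h@snps
      s$beta_x[match(ids, s$snp_id)]
    }, numeric(length(ids)))
    s1 <- hsets[[1]]@snps
    betaY <- s1$beta_y[match(ids, s1$snp_id)]
    seY <- s1$se_y[match(ids, s1$snp_id)]
    if (is.null(exposureNames))
      exposureNames <- vapply(hsets, exposureName, character(1))
    outcomeType <- hsets[[1]]@outcomeType
    outcomeName <- hsets[[1]]@outcomeName
    caseFraction <- hsets[[1]]@caseFraction
  }
  betaX <- as.matrix(betaX)
  J <- nrow(betaX); K <- ncol(betaX)
  if (J <= K) stop("need more SNPs than exposures (", J, " <= ", K, ")")
  if (is.null(exposureNames))
    exposureNames <- colnames(betaX)
  if (is.null(exposureNames))
    exposureNames <- paste0("exposure", seq_len(K))
  qrX <- qr(betaX)
  if (qrX$rank < K) {
    dep <- exposureNames[qrX$pivot[(qrX$rank + 1):K]]
    stop("collinear exposure effects: ", paste(dep, collapse = ", "))
  }
  w <- 1 / seY^2
  xtw <- t(betaX * w)
  xtwx <- xtw %*% betaX
  coef <- drop(solve(xtwx, xtw %*% betaY))
  resid <- betaY - drop(betaX %*% coef)
  Q <- sum(w * resid^2)
  mult <- max(1, sqrt(Q / (J - K)))
  se <- sqrt(diag(solve(xtwx))) * mult
  out <- lapply(seq_len(K), function(k) {
    est <- .mrEst("mv_ivw", coef[k], se[k], J, outcomeType,
                  exposure = exposureNames[k], outcome = outcomeName)
    attr(est, "Q") <- Q
    attr(est, "seMultiplier") <- mult
    est
  })
  names(out) <- exposureNames
  out
}
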