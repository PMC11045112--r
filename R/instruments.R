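.subsetStats <- function(ss, keep) {
  s <- ss@snps[keep, , drop = FALSE]
  rownames(s) <- NULL
  initialize(ss, snps = s)
}

#' Genome-wide significance filter
#'
#' Keeps records with p strictly below the threshold (a SNP at exactly
#' 5e-8 is not genome-wide significant).
#'
#' @param ss a \linkS4class{SummaryStats}.
#' @param pThreshold significance threshold, default 5e-8.
#' @return a filtered \linkS4class{SummaryStats} (possibly empty).
#' @export
significanceFilter <- function(ss, pThreshold = 5e-8) {
  stopifnot(is(ss, "SummaryStats"))
  .subsetStats(ss, ss@snps$pval < pThreshold)
}

#' Greedy LD clumping
#'
#' Sorts records ascending by p-value (ties broken by snp_id so the
#' result is invariant to input row order) and accepts each SNP iff its
#' LD r-squared with every already-accepted SNP is strictly below
#' \code{r2Max}.  Pairs absent from the LD table count as r-squared 0.
#'
#' @param ss a significance-filtered \linkS4class{SummaryStats}.
#' @param ld an \linkS4class{LdTable}.
#' @param r2Max clumping threshold, default 0.01.
#' @return the clumped \linkS4class{SummaryStats}.
#' @export
clumpInstruments <- function(ss, ld = ldTable(), r2Max = 0.01) {
  stopifnot(is(ss, "SummaryStats"), is(ld, "LdTable"))
  s <- ss@snps
  if (nrow(s) <= 1) return(ss)
  ord <- order(s$pval, s$snp_id)
  accepted <- character(0)
  for (i in ord) {
    id <- s$snp_id[i]
    if (length(accepted) == 0 ||
        all(ldR2(ld, rep(id, length(accepted)), accepted) < r2Max))
      accepted <- c(accepted, id)
  }
  .subsetStats(ss, s$snp_id %in% accepted)
}

#' Find proxy SNPs for instruments missing from the outcome data
#'
#' For each missing SNP, the proxy is the outcome-present SNP with the
#' highest LD r-squared among those with r-squared strictly above
#' \code{r2Min}; ties are broken by smaller proxy p-value, then
#' lexicographic id.  SNPs with no qualifying proxy are reported as
#' dropped.
#'
#' @param missingIds character vector of SNP ids absent from the outcome.
#' @param outcome \linkS4class{SummaryStats} of the outcome trait.
#' @param ld an \linkS4class{LdTable}.
#' @param r2Min minimum LD for a proxy, default 0.8 (strict inequality).
#' @return list with \code{map} (named character vector original ->
#'   proxy), \code{r2} (named numeric of the chosen proxies' LD) and
#'   \code{dropped} (unproxied ids).
#' @export
findProxies <- function(missingIds, outcome, ld, r2Min = 0.8) {
  stopifnot(is(outcome, "SummaryStats"), is(ld, "LdTable"))
  cand <- outcome@snps
  map <- character(0); r2s <- numeric(0); dropped <- character(0)
  for (id in missingIds) {
    r2 <- ldR2(ld, rep(id, nrow(cand)), cand$snp_id)
    ok <- which(r2 > r2Min & cand$snp_id != id)
    if (length(ok) == 0) { dropped <- c(dropped, id); next }
    ord <- ok[order(-r2[ok], cand$pval[ok], cand$snp_id[ok])]
    best <- ord[1]
    map[id] <- cand$snp_id[best]
    r2s[id] <- r2[best]
  }
  list(map = map, r2 = r2s, dropped = dropped)
}

#' Minor-allele-frequency and palindrome filter
#'
#' Removes records whose minor allele frequency is strictly below
#' \code{mafMin} (exactly 0.01 is kept) and records whose allele pair is
#' complementary (A/T or C/G), which cannot be strand-resolved from
#' alleles alone.
#'
#' @param ss a \linkS4class{SummaryStats}; every record must carry EAF.
#' @param mafMin MAF threshold, default 0.01.
#' @return the filtered \linkS4class{SummaryStats}.
#' @export
mafPalindromeFilter <- function(ss, mafMin = 0.01) {
  stopifnot(is(ss, "SummaryStats"))
  s <- ss@snps
  if (any(is.na(s$eaf)))
    stop("effect allele frequency is missing for ",
         sum(is.na(s$eaf)), " SNP(s) in '", ss@traitName,
         "'; the MAF/palindrome filter requires EAF -- supply it or ",
         "drop those records explicitly")
  maf <- pmin(s$eaf, 1 - s$eaf)
  palin <- .isPalindromic(s$effect_allele, s$other_allele)
  .subsetStats(ss, maf >= mafMin & !palin)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(a1, a2) unname(.COMPLEMENT[a1] == a2)

#' Variance in a standardized trait explained by a SNP
#'
#' \eqn{r^2 = 2\,maf(1-maf)\,\beta^2} with \eqn{maf = \min(eaf, 1-eaf)},
#' valid when the trait is standardized (SD units).
#'
#' @param eaf effect-allele frequency (vectorized).
#' @param beta per-allele effect in SD units.
#' @return per-SNP r-squared.
#' @export
varianceExplained <- function(eaf, beta) {
  if (any(is.na(eaf)))
    stop("effect allele frequency is required to compute variance explained")
  maf <- pmin(eaf, 1 - eaf)
  2 * maf * (1 - maf) * beta^2
}

#' Per-instrument F statistic
#'
#' \eqn{F = (n-2)\,r^2/(1-r^2)}; instruments with F < 10 are
#' conventionally weak and are excluded by
#' \code{\link{selectInstruments}} (exactly 10 is retained).
#'
#' @param r2 variance explained, in [0,1).
#' @param n exposure GWAS sample size (> 2).
#' @return F statistic (vectorized).
#' @export
fStatistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must be in [0,1)")
  if (any(n <= 2)) stop("n must exceed 2")
  (n - 2) * r2 / (1 - r2)
}

#' Select instrumental variables for an exposure
#'
#' Runs the fixed selection pipeline: genome-wide significance filter,
#' greedy LD clumping, proxy substitution for instruments missing from
#' the outcome data (when an outcome table is given), MAF/palindrome
#' filter, then exclusion of weak instruments (F < 10).  The order is
#' fixed because reordering changes results; per-stage SNP counts are
#' recorded in the stage log.
#'
#' Proxy instruments use the proxy SNP's own exposure record (its own
#' alleles and effects) downstream; a proxy absent from the exposure
#' table is unusable and the original SNP is dropped.
#'
#' @param exposure \linkS4class{SummaryStats} of the exposure.
#' @param ld \linkS4class{LdTable} for clumping and proxy search.
#' @param outcome optional \linkS4class{SummaryStats} of the outcome,
#'   enabling the missingness check and proxy search.
#' @param pThreshold,clumpR2,proxyR2,mafMin,fMin pipeline thresholds.
#' @return an \linkS4class{IVSet}.
#' @export
selectInstruments <- function(exposure, ld = ldTable(), outcome = NULL,
                              pThreshold = 5e-8, clumpR2 = 0.01,
                              proxyR2 = 0.8, mafMin = 0.01, fMin = 10) {
  stopifnot(is(exposure, "SummaryStats"))
  log <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer())
  note <- function(stage, n_in, n_out)
    log <<- rbind(log, data.frame(stage = stage, n_in = n_in,
                                  n_out = n_out))

  sig <- significanceFilter(exposure, pThreshold)
  note("significance", nSnps(exposure), nSnps(sig))
  cl <- clumpInstruments(sig, ld, clumpR2)
  note("clump", nSnps(sig), nSnps(cl))

  s <- cl@snps
  s$is_proxy <- logical(nrow(s))
  s$proxy_for <- NA_character_

  if (!is.null(outcome)) {
    n_in <- nrow(s)
    missing <- setdiff(s$snp_id, outcome@snps$snp_id)
    if (length(missing)) {
      pr <- findProxies(missing, outcome, ld, proxyR2)
      keep <- s[!s$snp_id %in% missing, , drop = FALSE]
      add <- NULL
      for (orig in names(pr$map)) {
        prox <- pr$map[[orig]]
        row <- exposure@snps[exposure@snps$snp_id == prox, , drop = FALSE]
        if (nrow(row) == 0 || prox %in% keep$snp_id) next
        row$is_proxy <- TRUE
        row$proxy_for <- orig
        add <- rbind(add, row)
      }
      s <- rbind(keep, add)
      rownames(s) <- NULL
    }
    note("proxy", n_in, nrow(s))
  }

  cl2 <- initialize(cl, snps = s[, .SNP_COLS])
  mf <- mafPalindromeFilter(cl2, mafMin)
  s <- s[s$snp_id %in% mf@snps$snp_id, , drop = FALSE]
  note("maf_palindrome", nSnps(cl2), nrow(s))

  n_in <- nrow(s)
  if (nrow(s)) {
    s$r2_exposure <- varianceExplained(s$eaf, s$beta)
    s$f_stat <- fStatistic(s$r2_exposure, s$n)
    s <- s[s$f_stat >= fMin, , drop = FALSE]
  } else {
    s$r2_exposure <- numeric(0)
    s$f_stat <- numeric(0)
  }
  rownames(s) <- NULL
  note("f_filter", n_in, nrow(s))

  new("IVSet", exposureName = exposure@traitName, instruments = s,
      stageLog = log)
}
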