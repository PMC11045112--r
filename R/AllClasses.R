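#' @import methods
NULL

.VALID_BASES <- c("A", "C", "G", "T")

## canonical column order for per-SNP association records
.SNP_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
               "eaf", "beta", "se", "pval", "n", "n_cases", "n_controls")

.emptySnpTable <- function() {
  data.frame(snp_id = character(), chrom = character(), pos = integer(),
             effect_allele = character(), other_allele = character(),
             eaf = numeric(), beta = numeric(), se = numeric(),
             pval = numeric(), n = numeric(), n_cases = numeric(),
             n_controls = numeric(), stringsAsFactors = FALSE)
}

#' GWAS summary statistics for one trait
#'
#' Per-SNP association records (effect/other allele, effect-allele
#' frequency, beta, standard error, p-value, sample size) for a single
#' trait.  Continuous-trait effects are in SD units; binary-trait effects
#' are log odds ratios.
#'
#' @slot traitName character trait label.
#' @slot traitType \code{"continuous"} or \code{"binary"}.
#' @slot snps data.frame of per-SNP records (see \code{\link{snpTable}}).
#' @slot caseFraction case fraction in (0,1) for binary traits, else
#'   \code{NA}.
#' @slot dropLog data.frame of rows dropped on read with a machine-readable
#'   reason code.
#' @export
setClass("SummaryStats",
  representation(traitName = "character", traitType = "character",
                 snps = "data.frame", caseFraction = "numeric",
                 dropLog = "data.frame"),
  prototype(traitName = "", traitType = "continuous",
            snps = .emptySnpTable(), caseFraction = NA_real_,
            dropLog = data.frame(snp_id = character(),
                                 reason = character())))

setValidity("SummaryStats", function(object) {
  msg <- character()
  if (!object@traitType %in% c("continuous", "binary"))
    msg <- c(msg, "traitType must be 'continuous' or 'binary'")
  s <- object@snps
  if (!all(.SNP_COLS %in% names(s)))
    msg <- c(msg, paste("snps missing columns:",
                        paste(setdiff(.SNP_COLS, names(s)), collapse = ", ")))
  if (nrow(s) > 0 && all(.SNP_COLS %in% names(s))) {
    if (anyDuplicated(s$snp_id))
      msg <- c(msg, "snp_id must be unique within a table")
    if (any(!s$effect_allele %in% .VALID_BASES) ||
        any(!s$other_allele %in% .VALID_BASES))
      msg <- c(msg, "alleles must be single bases A/C/G/T")
    if (any(s$effect_allele == s$other_allele))
      msg <- c(msg, "effect and other allele must differ")
    if (any(s$se <= 0)) msg <- c(msg, "all se must be > 0")
    if (any(s$pval <= 0 | s$pval > 1)) msg <- c(msg, "pval must be in (0,1]")
    eaf <- s$eaf[!is.na(s$eaf)]
    if (any(eaf <= 0 | eaf >= 1)) msg <- c(msg, "eaf must be in (0,1)")
    cc <- !is.na(s$n_cases)
    if (any(cc) && any(abs(s$n_cases[cc] + s$n_controls[cc] - s$n[cc]) > 0.5))
      msg <- c(msg, "n_cases + n_controls must equal n")
  }
  if (object@traitType == "binary" &&
      is.na(object@caseFraction) && nrow(s) > 0 && all(is.na(s$n_cases)))
    msg <- c(msg, "binary trait needs caseFraction or per-record case counts")
  if (!is.na(object@caseFraction) &&
      (object@caseFraction <= 0 || object@caseFraction >= 1))
    msg <- c(msg, "caseFraction must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Pairwise LD table
#'
#' Sparse pairwise r-squared entries with symmetric lookup; absent pairs
#' have r-squared 0 by convention and self-pairs r-squared 1.
#'
#' @slot entries data.frame with columns \code{snp_a}, \code{snp_b},
#'   \code{r2}.
#' @export
setClass("LdTable",
  representation(entries = "data.frame"),
  prototype(entries = data.frame(snp_a = character(), snp_b = character(),
                                 r2 = numeric())))

setValidity("LdTable", function(object) {
  e <- object@entries
  if (!all(c("snp_a", "snp_b", "r2") %in% names(e)))
    return("entries must have columns snp_a, snp_b, r2")
  if (nrow(e) > 0 && any(e$r2 < 0 | e$r2 > 1))
    return("r2 must be in [0,1]")
  TRUE
})

#' Selected instrumental variables for one exposure
#'
#' @slot exposureName character.
#' @slot instruments per-SNP records plus \code{r2_exposure},
#'   \code{f_stat}, \code{is_proxy}, \code{proxy_for} columns.
#' @slot stageLog data.frame of SNP counts entering/leaving each selection
#'   stage.
#' @export
setClass("IVSet",
  representation(exposureName = "character", instruments = "data.frame",
                 stageLog = "data.frame"),
  prototype(exposureName = "", instruments = .emptySnpTable(),
            stageLog = data.frame(stage = character(), n_in = integer(),
                                  n_out = integer())))

setValidity("IVSet", function(object) {
  iv <- object@instruments
  need <- c("r2_exposure", "f_stat", "is_proxy", "proxy_for")
  if (nrow(iv) > 0) {
    if (!all(need %in% names(iv)))
      return(paste("instruments missing columns:",
                   paste(setdiff(need, names(iv)), collapse = ", ")))
    if (any(iv$is_proxy & is.na(iv$proxy_for)))
      return("is_proxy requires proxy_for")
    if (any(iv$r2_exposure < 0 | iv$r2_exposure >= 1))
      return("r2_exposure must be in [0,1)")
  }
  TRUE
})

#' Exposure/outcome effects on a common effect allele
#'
#' The per-SNP paired dataset consumed by every estimator: exposure and
#' outcome effects aligned to the same effect allele.
#'
#' @slot exposureName,outcomeName character labels.
#' @slot snps data.frame with columns \code{snp_id}, \code{beta_x},
#'   \code{se_x}, \code{beta_y}, \code{se_y}, \code{eaf_x}, \code{eaf_y},
#'   \code{r2_x}, \code{n_x}, \code{n_y}, \code{action}.
#' @slot outcomeType \code{"continuous"} or \code{"binary"}.
#' @slot caseFraction outcome case fraction (binary) or \code{NA}.
#' @export
setClass("HarmonizedSet",
  representation(exposureName = "character", outcomeName = "character",
                 snps = "data.frame", outcomeType = "character",
                 caseFraction = "numeric"),
  prototype(outcomeType = "continuous", caseFraction = NA_real_))

setValidity("HarmonizedSet", function(object) {
  s <- object@snps
  need <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y",
            "eaf_x", "eaf_y", "r2_x", "n_x", "n_y")
  if (!all(need %in% names(s)))
    return(paste("snps missing columns:",
                 paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s) < 1) return("harmonized set must contain at least one SNP")
  if (anyDuplicated(s$snp_id)) return("snp_id must be unique")
  if (any(s$se_x <= 0) || any(s$se_y <= 0)) return("se_x and se_y must be > 0")
  if (!object@outcomeType %in% c("continuous", "binary"))
    return("outcomeType must be 'continuous' or 'binary'")
  TRUE
})

#' A causal-effect estimate
#'
#' @slot method one of \code{wald}, \code{ivw_fe}, \code{ivw_mre},
#'   \code{egger}, \code{weighted_median}, \code{mv_ivw}.
#' @slot beta causal estimate (log OR when the outcome is binary).
#' @slot se standard error.
#' @slot ciLow,ciHigh 95 percent confidence limits.
#' @slot pval two-sided p-value from the normal reference.
#' @slot orValue \code{exp(beta)} for binary outcomes, else \code{NA}.
#' @slot nSnps number of instruments used.
#' @slot intercept,interceptSe,interceptPval Egger intercept terms
#'   (\code{NA} for other methods).
#' @slot exposure,outcome trait labels.
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 orValue = "numeric", nSnps = "integer",
                 intercept = "numeric", interceptSe = "numeric",
                 interceptPval = "numeric",
                 exposure = "character", outcome = "character"),
  prototype(orValue = NA_real_, intercept = NA_real_,
            interceptSe = NA_real_, interceptPval = NA_real_,
            exposure = "", outcome = ""))

setValidity("MREstimate", function(object) {
  msg <- character()
  ok <- c("wald", "ivw_fe", "ivw_mre", "egger", "weighted_median", "mv_ivw")
  if (!object@method %in% ok)
    msg <- c(msg, paste("method must be one of", paste(ok, collapse = ", ")))
  if (is.finite(object@se) && object@se <= 0) msg <- c(msg, "se must be > 0")
  if (is.finite(object@ciLow) &&
      (object@ciLow > object@beta || object@beta > object@ciHigh))
    msg <- c(msg, "ciLow <= beta <= ciHigh must hold")
  if (!is.na(object@orValue) &&
      abs(object@orValue - exp(object@beta)) > 1e-12 * max(1, exp(object@beta)))
    msg <- c(msg, "orValue must equal exp(beta)")
  if (length(msg)) msg else TRUE
})

#' MR-PRESSO report
#'
#' Global residual-sum-of-squares pleiotropy test, per-SNP outlier test,
#' and distortion test comparing the causal estimate before and after
#' outlier removal.
#'
#' @slot globalRss observed residual sum of squares.
#' @slot globalPval empirical p of the global test.
#' @slot outlierPvals named per-SNP empirical p-values.
#' @slot outlierIds SNPs flagged at the Bonferroni-adjusted level.
#' @slot distortionCoef percent distortion 100*(raw-corrected)/|corrected|,
#'   \code{NA} when no outliers.
#' @slot distortionPval two-sided empirical p, \code{NA} when no outliers.
#' @slot betaRaw,betaCorrected IVW estimates before/after removal.
#' @slot nSim number of parametric simulations.
#' @export
setClass("PressoReport",
  representation(globalRss = "numeric", globalPval = "numeric",
                 outlierPvals = "numeric", outlierIds = "character",
                 distortionCoef = "numeric", distortionPval = "numeric",
                 betaRaw = "MREstimate", betaCorrected = "MREstimate",
                 nSim = "integer"),
  prototype(distortionCoef = NA_real_, distortionPval = NA_real_))

setValidity("PressoReport", function(object) {
  if (!all(object@outlierIds %in% names(object@outlierPvals)))
    return("outlierIds must be a subset of the tested SNPs")
  TRUE
})

#' Steiger directionality test result
#'
#' @slot r2Exposure,r2Outcome total instrument variance explained on each
#'   trait.
#' @slot directionOk TRUE iff the instruments explain more variance in the
#'   exposure than in the outcome.
#' @slot zval Fisher-z comparison statistic.
#' @slot pval two-sided p-value.
#' @export
setClass("SteigerResult",
  representation(r2Exposure = "numeric", r2Outcome = "numeric",
                 directionOk = "logical", zval = "numeric",
                 pval = "numeric"))

setValidity("SteigerResult", function(object) {
  if (object@directionOk != (object@r2Exposure > object@r2Outcome))
    return("directionOk must equal r2Exposure > r2Outcome")
  TRUE
})

#' Statistical power of an MR design
#'
#' @slot ncp non-centrality parameter.
#' @slot power power at the given alpha.
#' @slot alpha significance level.
#' @slot assumedBeta assumed true causal effect.
#' @slot totalR2 instrument variance explained on the exposure.
#' @export
setClass("PowerResult",
  representation(ncp = "numeric", power = "numeric", alpha = "numeric",
                 assumedBeta = "numeric", totalR2 = "numeric"))

#' Configuration of the synthetic summary-statistics generator
#'
#' Encodes the data-generating assumptions of two-sample MR: per-SNP
#' exposure effects scaled to a target heritability, a linear causal
#' effect on the outcome, optional balanced or directional horizontal
#' pleiotropy on a configurable fraction of invalid instruments, and
#' optional block-AR(1) LD.
#'
#' @slot nSnps number of SNPs.
#' @slot nExposure,nOutcome GWAS sample sizes.
#' @slot causalBeta true causal effect.
#' @slot pleiotropyMode \code{"none"}, \code{"balanced"} or
#'   \code{"directional"}.
#' @slot pleiotropySd SD of direct (pleiotropic) effects.
#' @slot invalidFraction fraction of SNPs with a direct effect.
#' @slot exposureH2 total variance in the exposure explained by the SNPs.
#' @slot mafRange minor-allele-frequency range, within (0, 0.5].
#' @slot ldBlockSize,ldRho LD block size and within-block adjacent-pair
#'   correlation (AR(1)).
#' @slot outcomeType \code{"continuous"} or \code{"binary"}.
#' @slot caseFraction outcome case fraction when binary.
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
  representation(nSnps = "integer", nExposure = "numeric",
                 nOutcome = "numeric", causalBeta = "numeric",
                 pleiotropyMode = "character", pleiotropySd = "numeric",
                 invalidFraction = "numeric", exposureH2 = "numeric",
                 mafRange = "numeric", ldBlockSize = "integer",
                 ldRho = "numeric", outcomeType = "character",
                 caseFraction = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSnps < 1) msg <- c(msg, "nSnps must be >= 1")
  if (object@nExposure <= 0 || object@nOutcome <= 0)
    msg <- c(msg, "sample sizes must be positive")
  if (!object@pleiotropyMode %in% c("none", "balanced", "directional"))
    msg <- c(msg, "pleiotropyMode must be none|balanced|directional")
  if (object@pleiotropySd < 0) msg <- c(msg, "pleiotropySd must be >= 0")
  if (object@invalidFraction < 0 || object@invalidFraction > 1)
    msg <- c(msg, "invalidFraction must be in [0,1]")
  if (object@exposureH2 <= 0 || object@exposureH2 >= 1)
    msg <- c(msg, "exposureH2 must be in (0,1)")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be (low, high) within (0, 0.5]")
  if (object@ldBlockSize < 1) msg <- c(msg, "ldBlockSize must be >= 1")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must be in [0,1)")
  if (!object@outcomeType %in% c("continuous", "binary"))
    msg <- c(msg, "outcomeType must be continuous|binary")
  if (object@outcomeType == "binary" &&
      (is.na(object@caseFraction) || object@caseFraction <= 0 ||
       object@caseFraction >= 1))
    msg <- c(msg, "binary outcome needs caseFraction in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Generating parameters of a synthetic dataset
#'
#' The ground truth behind a simulated pair (or multivariable set) of
#' summary-statistics tables, retained for parameter-recovery tests.
#'
#' @slot causalBeta true causal effect(s), one per exposure.
#' @slot alpha per-SNP direct (pleiotropic) effects on the outcome.
#' @slot gamma nSnps x nExposures matrix of true exposure effects.
#' @slot maf per-SNP minor allele frequencies.
#' @slot invalidIds ids of SNPs with a nonzero direct effect.
#' @export
setClass("SimTruth",
  representation(causalBeta = "numeric", alpha = "numeric",
                 gamma = "matrix", maf = "numeric",
                 invalidIds = "character"))

setValidity("SimTruth", function(object) {
  if (length(object@alpha) != nrow(object@gamma) ||
      length(object@maf) != nrow(object@gamma))
    return("alpha, maf and gamma rows must have equal length")
  if (length(object@causalBeta) != ncol(object@gamma))
    return("causalBeta length must equal number of exposures")
  TRUE
})

setClassUnion("PressoReportOrNULL", c("PressoReport", "NULL"))
setClassUnion("SteigerResultOrNULL", c("SteigerResult", "NULL"))

#' Result of one exposure-outcome MR analysis
#'
#' @slot direction label "exposure -> outcome".
#' @slot estimates list of \linkS4class{MREstimate}.
#' @slot presso \linkS4class{PressoReport} or NULL when fewer than 4 SNPs.
#' @slot steiger \linkS4class{SteigerResult} or NULL.
#' @slot q list with Q, df, pval from Cochran's Q at the IVW estimate.
#' @slot loo leave-one-out table.
#' @slot qval FDR-adjusted q-value of the primary estimate.
#' @slot verdict \code{"reported"}, \code{"excluded_steiger"},
#'   \code{"excluded_pleiotropy"} or \code{"not_estimable"}.
#' @slot stageLog per-stage SNP counts.
#' @export
setClass("PairResult",
  representation(direction = "character", estimates = "list",
                 presso = "PressoReportOrNULL",
                 steiger = "SteigerResultOrNULL",
                 q = "list", loo = "data.frame", qval = "numeric",
                 verdict = "character", stageLog = "data.frame"),
  prototype(qval = NA_real_, verdict = "reported",
            loo = data.frame(), q = list()))

setValidity("PairResult", function(object) {
  ok <- c("reported", "excluded_steiger", "excluded_pleiotropy",
          "not_estimable")
  if (!object@verdict %in% ok)
    return(paste("verdict must be one of", paste(ok, collapse = ", ")))
  if (object@verdict == "excluded_steiger" &&
      (is.null(object@steiger) || object@steiger@directionOk))
    return("excluded_steiger requires a failed Steiger test")
  TRUE
})
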