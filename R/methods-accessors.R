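#' @rdname accessors
#' @export
setMethod("traitName", "SummaryStats", function(x) x@traitName)

#' @rdname accessors
#' @export
setMethod("traitType", "SummaryStats", function(x) x@traitType)

#' @rdname accessors
#' @export
setMethod("snpTable", "SummaryStats", function(x) x@snps)

#' @rdname accessors
#' @export
setMethod("caseFraction", "SummaryStats", function(x) x@caseFraction)

#' @rdname accessors
#' @export
setMethod("caseFraction", "HarmonizedSet", function(x) x@caseFraction)

#' @rdname accessors
#' @export
setMethod("dropLog", "SummaryStats", function(x) x@dropLog)

#' @rdname accessors
#' @export
setMethod("nSnps", "SummaryStats", function(x) nrow(x@snps))

#' @rdname accessors
#' @export
setMethod("nSnps", "IVSet", function(x) nrow(x@instruments))

#' @rdname accessors
#' @export
setMethod("nSnps", "HarmonizedSet", function(x) nrow(x@snps))

#' @rdname accessors
#' @export
setMethod("nSnps", "MREstimate", function(x) x@nSnps)

#' @rdname accessors
#' @export
setMethod("instruments", "IVSet", function(x) x@instruments)

#' @rdname accessors
#' @export
setMethod("totalR2", "IVSet", function(x) sum(x@instruments$r2_exposure))

#' @rdname accessors
#' @export
setMethod("stageLog", "IVSet", function(x) x@stageLog)

#' @rdname accessors
#' @export
setMethod("stageLog", "PairResult", function(x) x@stageLog)

#' @rdname accessors
#' @export
setMethod("exposureName", "IVSet", function(x) x@exposureName)

#' @rdname accessors
#' @export
setMethod("exposureName", "HarmonizedSet", function(x) x@exposureName)

#' @rdname accessors
#' @export
setMethod("outcomeName", "HarmonizedSet", function(x) x@outcomeName)

#' @rdname accessors
#' @export
setMethod("snpTable", "HarmonizedSet", function(x) x@snps)

#' @rdname accessors
#' @export
setMethod("snpTable", "IVSet", function(x) x@instruments)

#' @rdname accessors
#' @export
setMethod("mrMethod", "MREstimate", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("estimate", "MREstimate", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("stdError", "MREstimate", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("confInt", "MREstimate", function(x) c(x@ciLow, x@ciHigh))

#' @rdname accessors
#' @export
setMethod("pValue", "MREstimate", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "MREstimate", function(x) x@orValue)

#' @rdname accessors
#' @export
setMethod("eggerIntercept", "MREstimate", function(x)
  c(intercept = x@intercept, se = x@interceptSe, pval = x@interceptPval))

#' @rdname accessors
#' @export
setMethod("outlierIds", "PressoReport", function(x) x@outlierIds)

#' @rdname accessors
#' @export
setMethod("globalPval", "PressoReport", function(x) x@globalPval)

#' @rdname accessors
#' @export
setMethod("directionOk", "SteigerResult", function(x) x@directionOk)

#' @rdname accessors
#' @export
setMethod("pValue", "SteigerResult", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("verdict", "PairResult", function(x) x@verdict)

#' @rdname accessors
#' @export
setMethod("estimates", "PairResult", function(x) x@estimates)

#' @rdname accessors
#' @export
setMethod("trueBeta", "SimTruth", function(x) x@causalBeta)

#' @rdname accessors
#' @export
setMethod("invalidIds", "SimTruth", function(x) x@invalidIds)

#' @rdname ldR2
#' @export
setMethod("ldR2", "LdTable", function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  e <- ld@entries
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  map <- e$r2
  names(map) <- key(e$snp_a, e$snp_b)
  out <- unname(map[key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats '%s' (%s): %d SNPs", object@traitName,
              object@traitType, nrow(object@snps)))
  if (nrow(object@dropLog) > 0)
    cat(sprintf(", %d rows dropped on read", nrow(object@dropLog)))
  cat("\n")
})

setMethod("show", "LdTable", function(object) {
  cat(sprintf("LdTable: %d pairwise entries\n", nrow(object@entries)))
})

setMethod("show", "IVSet", function(object) {
  cat(sprintf("IVSet for '%s': %d instruments (total r2 = %.4g)\n",
              object@exposureName, nrow(object@instruments),
              sum(object@instruments$r2_exposure)))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet %s -> %s (%s outcome): %d SNPs\n",
              object@exposureName, object@outcomeName,
              object@outcomeType, nrow(object@snps)))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] %s -> %s\n", object@method,
              object@exposure, object@outcome))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, %d SNPs\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pval, object@nSnps))
  if (!is.na(object@orValue))
    cat(sprintf("  OR = %.4g [%.4g, %.4g]\n", object@orValue,
                exp(object@ciLow), exp(object@ciHigh)))
  if (!is.na(object@intercept))
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                object@intercept, object@interceptSe, object@interceptPval))
})

setMethod("show", "PressoReport", function(object) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, p = %.3g (%d sims)\n",
              object@globalRss, object@globalPval, object@nSim))
  cat(sprintf("  outliers: %s\n",
              if (length(object@outlierIds)) paste(object@outlierIds,
                                                   collapse = ", ")
              else "none"))
  if (!is.na(object@distortionPval))
    cat(sprintf("  distortion = %.3g%%, p = %.3g\n", object@distortionCoef,
                object@distortionPval))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf("Steiger: r2(exposure) = %.4g, r2(outcome) = %.4g, %s (z = %.3g, p = %.3g)\n",
              object@r2Exposure, object@r2Outcome,
              if (object@directionOk) "direction OK" else "direction FAILS",
              object@zval, object@pval))
})

setMethod("show", "PowerResult", function(object) {
  cat(sprintf("Power: %.3f at alpha %.3g (NCP %.3g, assumed beta %.3g, r2 %.3g)\n",
              object@power, object@alpha, object@ncp, object@assumedBeta,
              object@totalR2))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d SNPs, n = %g/%g, theta = %s, h2 = %g, pleiotropy %s (sd %g, fraction %g)\n",
              object@nSnps, object@nExposure, object@nOutcome,
              paste(signif(object@causalBeta, 3), collapse = ","),
              object@exposureH2, object@pleiotropyMode,
              object@pleiotropySd, object@invalidFraction))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: theta = %s, %d SNPs, %d invalid\n",
              paste(signif(object@causalBeta, 3), collapse = ","),
              nrow(object@gamma), length(object@invalidIds)))
})

setMethod("show", "PairResult", function(object) {
  cat(sprintf("PairResult %s [%s]\n", object@direction, object@verdict))
  for (e in object@estimates) show(e)
})
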