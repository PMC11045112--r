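#' Pipeline configuration
#'
#' Thresholds and switches for \code{\link{runPair}},
#' \code{\link{runBidirectional}} and \code{\link{runMvmr}}.
#'
#' @param pThreshold genome-wide significance threshold for instrument
#'   selection.
#' @param clumpR2 LD clumping threshold.
#' @param proxyR2 minimum LD for proxy substitution.
#' @param mafMin minor-allele-frequency floor.
#' @param fMin weak-instrument F cutoff.
#' @param pressoNsim,pressoSig MR-PRESSO simulations and significance
#'   level.
#' @param nBoot weighted-median bootstrap replicates.
#' @param alpha significance level for pleiotropy and FDR calls.
#' @param hetPval Cochran-Q p below which the multiplicative
#'   random-effects IVW is reported instead of fixed-effect.
#' @param methods estimators to run (\code{"ivw"} always primary).
#' @param seed integer seed for all stochastic stages (mandatory).
#' @param fdrScope label for the FDR family definition (the default
#'   family is all primary p-values in one run).
#' @return a validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(pThreshold = 5e-8, clumpR2 = 0.01, proxyR2 = 0.8,
                      mafMin = 0.01, fMin = 10, pressoNsim = 1000,
                      pressoSig = 0.05, nBoot = 1000, alpha = 0.05,
                      hetPval = 0.05,
                      methods = c("ivw", "egger", "weighted_median"),
                      seed = 1L, fdrScope = "run") {
  stopifnot(pThreshold > 0, pThreshold < 1, clumpR2 >= 0, clumpR2 <= 1,
            proxyR2 >= 0, proxyR2 <= 1, mafMin >= 0, mafMin < 0.5,
            fMin >= 0, pressoNsim >= 1, pressoSig > 0, pressoSig < 1,
            nBoot >= 1, alpha > 0, alpha < 1, hetPval > 0, hetPval <= 1,
            length(methods) >= 1, !is.na(seed))
  structure(list(pThreshold = pThreshold, clumpR2 = clumpR2,
                 proxyR2 = proxyR2, mafMin = mafMin, fMin = fMin,
                 pressoNsim = pressoNsim, pressoSig = pressoSig,
                 nBoot = nBoot, alpha = alpha, hetPval = hetPval,
                 methods = methods, seed = as.integer(seed),
                 fdrScope = fdrScope),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.emptyPair <- function(direction, log, why) {
  new("PairResult", direction = direction, estimates = list(),
      presso = NULL, steiger = NULL, q = list(), loo = data.frame(),
      verdict = "not_estimable",
      stageLog = rbind(log, data.frame(stage = paste0("halt:", why),
                                       n_in = 0L, n_out = 0L)))
}

#' Run one exposure-outcome MR analysis
#'
#' Executes the fixed stage order: instrument selection (significance,
#' clumping, proxies, MAF/palindrome, F filter), harmonization,
#' MR-PRESSO outlier removal, estimation, heterogeneity, leave-one-out
#' and Steiger gate.  When the Cochran Q p-value falls below
#' \code{hetPval} the reported IVW is the multiplicative random-effects
#' model.  A failed Steiger test sets the verdict to
#' \code{excluded_steiger}; an Egger intercept still significant after
#' outlier removal (pleiotropy that removal could not eliminate) sets
#' \code{excluded_pleiotropy}.
#'
#' @param exposure,outcome \linkS4class{SummaryStats} tables.
#' @param ld an \linkS4class{LdTable}.
#' @param config a \code{\link{runConfig}}.
#' @return a \linkS4class{PairResult}.
#' @export
runPair <- function(exposure, outcome, ld = ldTable(),
                    config = runConfig()) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"),
            inherits(config, "RunConfig"))
  direction <- paste(exposure@traitName, "->", outcome@traitName)

  ivs <- .stage("select", selectInstruments(
    exposure, ld, outcome, pThreshold = config$pThreshold,
    clumpR2 = config$clumpR2, proxyR2 = config$proxyR2,
    mafMin = config$mafMin, fMin = config$fMin))
  log <- ivs@stageLog
  if (nSnps(ivs) == 0)
    return(.emptyPair(direction, log, "no_instruments"))

  h <- .stage("harmonize", harmonize(ivs, outcome))
  log <- rbind(log, data.frame(stage = "harmonize", n_in = nSnps(ivs),
                               n_out = nSnps(h)))

  presso <- NULL
  if (nSnps(h) >= 4) {
    presso <- .stage("presso", mrPresso(h, nSim = config$pressoNsim,
                                        sig = config$pressoSig,
                                        seed = config$seed))
    if (length(presso@outlierIds) > 0) {
      s <- h@snps
      h <- harmonizedSet(s[!s$snp_id %in% presso@outlierIds, ,
                           drop = FALSE],
                         exposureName = h@exposureName,
                         outcomeName = h@outcomeName,
                         outcomeType = h@outcomeType,
                         caseFraction = h@caseFraction)
    }
  }
  log <- rbind(log, data.frame(stage = "presso_outlier_removal",
                               n_in = if (is.null(presso)) nSnps(h)
                                      else length(presso@outlierPvals),
                               n_out = nSnps(h)))

  q <- if (nSnps(h) >= 2) .stage("cochran_q", cochranQ(h)) else list()
  ivw_model <- if (length(q) && q$pval < config$hetPval)
    "multiplicative_random" else "fixed"

  ests <- list()
  if ("ivw" %in% config$methods)
    ests <- c(ests, list(.stage("ivw",
      if (nSnps(h) == 1) waldRatio(h)
      else ivw(h, if (nSnps(h) >= 2) ivw_model else "fixed"))))
  if ("egger" %in% config$methods && nSnps(h) >= 3)
    ests <- c(ests, list(.stage("egger", mrEgger(h))))
  if ("weighted_median" %in% config$methods && nSnps(h) >= 3)
    ests <- c(ests, list(.stage("weighted_median",
      weightedMedian(h, nBoot = config$nBoot, seed = config$seed))))

  loo <- if (nSnps(h) >= 3) .stage("leave_one_out", leaveOneOut(h))
         else data.frame()
  st <- .stage("steiger", steiger(h))

  verdict <- "reported"
  if (!st@directionOk) {
    verdict <- "excluded_steiger"
  } else {
    eg <- Filter(function(e) e@method == "egger", ests)
    if (length(eg) && eg[[1]]@interceptPval < config$alpha)
      verdict <- "excluded_pleiotropy"
  }

  new("PairResult", direction = direction, estimates = ests,
      presso = presso, steiger = st, q = q, loo = loo,
      verdict = verdict, stageLog = log)
}

#' Run both causal directions between two traits
#'
#' Instruments for each direction are selected independently from that
#' direction's own exposure table; nothing is reused.  A direction whose
#' exposure has no eligible instruments is returned as not-estimable
#' while the other is still analysed.
#'
#' @param traitA,traitB \linkS4class{SummaryStats} tables.
#' @param ld an \linkS4class{LdTable}.
#' @param config a \code{\link{runConfig}}.
#' @return list with elements \code{forward} (A -> B) and \code{reverse}
#'   (B -> A).
#' @export
runBidirectional <- function(traitA, traitB, ld = ldTable(),
                             config = runConfig()) {
  safe <- function(x, y) {
    tryCatch(runPair(x, y, ld, config), error = function(e) {
      .emptyPair(paste(x@traitName, "->", y@traitName),
                 data.frame(stage = character(), n_in = integer(),
                            n_out = integer()),
                 conditionMessage(e))
    })
  }
  list(forward = safe(traitA, traitB), reverse = safe(traitB, traitA))
}

#' Multivariable MR across several exposures
#'
#' Instrument selection uses the union-then-clump strategy: every SNP
#' genome-wide significant for at least one exposure enters, the union
#' is clumped on its best (smallest) p-value across exposures, then the
#' MAF/palindrome filter applies.  All exposures and the outcome are
#' harmonized on the shared SNPs and the direct effects estimated by
#' \code{\link{mvIvw}}.
#'
#' @param exposures list of \linkS4class{SummaryStats} (at least 2).
#' @param outcome \linkS4class{SummaryStats}.
#' @param ld an \linkS4class{LdTable}.
#' @param config a \code{\link{runConfig}}.
#' @return a \linkS4class{PairResult} whose \code{estimates} hold one
#'   \code{mv_ivw} row per exposure.
#' @export
runMvmr <- function(exposures, outcome, ld = ldTable(),
                    config = runConfig()) {
  stopifnot(is.list(exposures), length(exposures) >= 1,
            all(vapply(exposures, is, logical(1), "SummaryStats")),
            is(outcome, "SummaryStats"))
  K <- length(exposures)
  log <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer())

  sig_ids <- unique(unlist(lapply(exposures, function(e)
    significanceFilter(e, config$pThreshold)@snps$snp_id)))
  if (length(sig_ids) == 0)
    stop("stage 'select': no SNP is genome-wide significant for any exposure")
  log <- rbind(log, data.frame(stage = "significance_union",
                               n_in = nSnps(exposures[[1]]),
                               n_out = length(sig_ids)))

  ## clump the union on the best p across exposures
  pmin_tab <- exposures[[1]]@snps[match(sig_ids,
                                        exposures[[1]]@snps$snp_id), ]
  best_p <- Reduce(pmin, lapply(exposures, function(e) {
    p <- e@snps$pval[match(sig_ids, e@snps$snp_id)]
    p[is.na(p)] <- 1
    p
  }))
  pmin_tab$pval <- best_p
  union_ss <- initialize(exposures[[1]], snps = pmin_tab)
  clumped <- .stage("clump", clumpInstruments(union_ss, ld, config$clumpR2))
  clumped <- .stage("maf_palindrome",
                    mafPalindromeFilter(clumped, config$mafMin))
  ids <- clumped@snps$snp_id
  log <- rbind(log, data.frame(stage = "clump_maf", n_in = length(sig_ids),
                               n_out = length(ids)))

  hsets <- lapply(exposures, function(e) {
    s <- e@snps[e@snps$snp_id %in% ids, , drop = FALSE]
    s$is_proxy <- FALSE; s$proxy_for <- NA_character_
    s$r2_exposure <- varianceExplained(s$eaf, s$beta)
    s$f_stat <- fStatistic(s$r2_exposure, s$n)
    iv <- new("IVSet", exposureName = e@traitName, instruments = s,
              stageLog = data.frame(stage = character(),
                                    n_in = integer(), n_out = integer()))
    .stage("harmonize", harmonize(iv, outcome))
  })
  ests <- .stage("mv_ivw", mvIvw(hsets))
  shared <- ests[[1]]@nSnps
  log <- rbind(log, data.frame(stage = "mv_ivw", n_in = length(ids),
                               n_out = shared))
  new("PairResult",
      direction = paste(paste(vapply(exposures, traitName, character(1)),
                              collapse = "+"), "->", outcome@traitName),
      estimates = unname(ests), presso = NULL, steiger = NULL,
      q = list(), loo = data.frame(), verdict = "reported",
      stageLog = log)
}

#' FDR adjustment across a family of results
#'
#' Benjamini-Hochberg q-values over the primary p-value of every
#' reported result in the family (the default family is all results of
#' one run together); the q-value is written back into each reported
#' \linkS4class{PairResult}.  Excluded results get no q-value.
#'
#' @param results list of \linkS4class{PairResult}.
#' @param alpha significance level for the q < alpha flag.
#' @return the input list with \code{qval} slots filled; the
#'   \code{"significant"} attribute carries the q < alpha flags.
#' @export
applyFdr <- function(results, alpha = 0.05) {
  stopifnot(is.list(results),
            all(vapply(results, is, logical(1), "PairResult")))
  primary_p <- function(r) {
    if (length(r@estimates) == 0) return(NA_real_)
    r@estimates[[1]]@pval
  }
  rep_idx <- which(vapply(results, function(r)
    r@verdict == "reported" && length(r@estimates) > 0, logical(1)))
  if (length(rep_idx) == 0) return(results)
  q <- bhFdr(vapply(results[rep_idx], primary_p, numeric(1)))
  for (i in seq_along(rep_idx))
    results[[rep_idx[i]]]@qval <- q[i]
  attr(results, "significant") <- vapply(results, function(r)
    !is.na(r@qval) && r@qval < alpha, logical(1))
  results
}

.estimateRow <- function(e, qval = NA_real_, notes = "") {
  data.frame(exposure = e@exposure, outcome = e@outcome,
             method = e@method, n_snps = e@nSnps, beta = e@beta,
             se = e@se, ci_low = e@ciLow, ci_high = e@ciHigh,
             pval = e@pval, qval = qval, or_value = e@orValue,
             notes = notes, stringsAsFactors = FALSE)
}

#' Tabulate pair results
#'
#' One row per estimate across a list of \linkS4class{PairResult}s, in
#' the standard report-column order.
#'
#' @param results list of \linkS4class{PairResult}.
#' @return data.frame.
#' @export
resultsTable <- function(results) {
  if (is(results, "PairResult")) results <- list(results)
  rows <- lapply(results, function(r) {
    if (length(r@estimates) == 0)
      return(NULL)
    do.call(rbind, lapply(seq_along(r@estimates), function(i)
      .estimateRow(r@estimates[[i]],
                   qval = if (i == 1) r@qval else NA_real_,
                   notes = r@verdict)))
  })
  do.call(rbind, rows)
}

.pairToList <- function(r) {
  sig <- function(x) if (is.null(x) || length(x) == 0) NULL else x
  out <- list(
    direction = r@direction, verdict = r@verdict, qval = r@qval,
    estimates = lapply(r@estimates, function(e) list(
      method = e@method, n_snps = e@nSnps, beta = e@beta, se = e@se,
      ci_low = e@ciLow, ci_high = e@ciHigh, pval = e@pval,
      or_value = e@orValue, intercept = e@intercept,
      intercept_se = e@interceptSe, intercept_pval = e@interceptPval)),
    cochran_q = sig(r@q),
    stage_log = r@stageLog)
  if (!is.null(r@steiger))
    out$steiger <- list(r2_exposure = r@steiger@r2Exposure,
                        r2_outcome = r@steiger@r2Outcome,
                        direction_ok = r@steiger@directionOk,
                        zval = r@steiger@zval, pval = r@steiger@pval)
  if (!is.null(r@presso))
    out$presso <- list(global_rss = r@presso@globalRss,
                       global_pval = r@presso@globalPval,
                       outlier_ids = as.list(r@presso@outlierIds),
                       distortion_coef = r@presso@distortionCoef,
                       distortion_pval = r@presso@distortionPval,
                       n_sim = r@presso@nSim)
  if (nrow(r@loo) > 0)
    out$leave_one_out <- r@loo
  out
}

#' Write the full audit report
#'
#' Writes \code{results.tsv} (one row per estimate), \code{report.json}
#' (estimates, MR-PRESSO, Steiger, Cochran Q, leave-one-out and the
#' per-stage SNP counts) and, when leave-one-out tables exist,
#' \code{loo.tsv}.  Output is a deterministic function of the inputs and
#' seed: identical runs produce byte-identical files.
#'
#' @param results list of \linkS4class{PairResult}.
#' @param dir output directory (created if needed).
#' @return invisibly, the report list.
#' @export
writeReport <- function(results, dir) {
  if (is(results, "PairResult")) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- resultsTable(results)
  if (!is.null(tab))
    writeResults(tab, file.path(dir, "results.tsv"))
  report <- lapply(results, .pairToList)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  loo <- do.call(rbind, lapply(results, function(r)
    if (nrow(r@loo) > 0)
      cbind(direction = r@direction, r@loo) else NULL))
  if (!is.null(loo))
    utils::write.table(loo, file.path(dir, "loo.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(report)
}
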