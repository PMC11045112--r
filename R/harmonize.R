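#' Construct a HarmonizedSet from paired per-SNP effects
#'
#' Low-level constructor used by \code{\link{harmonize}} and by
#' simulation-based tests that already have aligned effects.
#'
#' @param snps data.frame with columns \code{snp_id}, \code{beta_x},
#'   \code{se_x}, \code{beta_y}, \code{se_y} and optionally
#'   \code{eaf_x}, \code{eaf_y}, \code{r2_x}, \code{n_x}, \code{n_y},
#'   \code{action}.
#' @param exposureName,outcomeName trait labels.
#' @param outcomeType \code{"continuous"} or \code{"binary"}.
#' @param caseFraction outcome case fraction when binary.
#' @return a validated \linkS4class{HarmonizedSet}.
#' @export
harmonizedSet <- function(snps, exposureName = "exposure",
                          outcomeName = "outcome",
                          outcomeType = c("continuous", "binary"),
                          caseFraction = NA_real_) {
  outcomeType <- match.arg(outcomeType)
  for (col in c("eaf_x", "eaf_y", "r2_x", "n_x", "n_y"))
    if (is.null(snps[[col]])) snps[[col]] <- NA_real_
  if (is.null(snps$action)) snps$action <- "kept"
  snps$snp_id <- as.character(snps$snp_id)
  rownames(snps) <- NULL
  new("HarmonizedSet", exposureName = exposureName,
      outcomeName = outcomeName, snps = snps, outcomeType = outcomeType,
      caseFraction = caseFraction)
}

#' Harmonize exposure instruments with outcome effects
#'
#' Places exposure and outcome effects on the same effect allele, SNP by
#' SNP: a direct allele match copies both effects; swapped alleles
#' (effect/other exchanged) negate the outcome effect and reflect its
#' EAF; a strand-complement match (A/T, C/G applied to both outcome
#' alleles) is attempted only when direct and swapped matching both fail,
#' then the same logic applies; irreconcilable allele pairs are dropped
#' with a reason code.  Palindromic pairs were removed upstream; should
#' one remain it is dropped (reason \code{"dropped:palindromic"}) rather
#' than frequency-resolved.  An EAF disagreement above 0.2 after
#' alignment triggers a warning, not removal.
#'
#' @param ivs an \linkS4class{IVSet}.
#' @param outcome \linkS4class{SummaryStats} of the outcome trait.
#' @return a \linkS4class{HarmonizedSet}; the per-SNP \code{action}
#'   column records kept/flipped/complemented/dropped decisions.
#' @export
harmonize <- function(ivs, outcome) {
  stopifnot(is(ivs, "IVSet"), is(outcome, "SummaryStats"))
  iv <- ivs@instruments
  out <- outcome@snps
  common <- intersect(iv$snp_id, out$snp_id)
  if (length(common) == 0)
    stop("no shared SNPs between exposure '", ivs@exposureName,
         "' instruments and outcome '", outcome@traitName, "'")

  rows <- vector("list", length(common))
  for (i in seq_along(common)) {
    id <- common[i]
    x <- iv[iv$snp_id == id, ]
    y <- out[out$snp_id == id, ]
    act <- NA_character_
    flip <- FALSE
    if (.isPalindromic(x$effect_allele, x$other_allele)) {
      act <- "dropped:palindromic"
    } else if (y$effect_allele == x$effect_allele &&
               y$other_allele == x$other_allele) {
      act <- "kept"
    } else if (y$effect_allele == x$other_allele &&
               y$other_allele == x$effect_allele) {
      act <- "flipped"; flip <- TRUE
    } else {
      ce <- unname(.COMPLEMENT[y$effect_allele])
      co <- unname(.COMPLEMENT[y$other_allele])
      if (ce == x$effect_allele && co == x$other_allele) {
        act <- "complemented"
      } else if (ce == x$other_allele && co == x$effect_allele) {
        act <- "complemented_flipped"; flip <- TRUE
      } else {
        act <- "dropped:allele_mismatch"
      }
    }
    beta_y <- if (flip) -y$beta else y$beta
    eaf_y <- if (flip && !is.na(y$eaf)) 1 - y$eaf else y$eaf
    rows[[i]] <- data.frame(
      snp_id = id, beta_x = x$beta, se_x = x$se, beta_y = beta_y,
      se_y = y$se, eaf_x = x$eaf, eaf_y = eaf_y,
      r2_x = if ("r2_exposure" %in% names(x)) x$r2_exposure else NA_real_,
      n_x = x$n, n_y = y$n, action = act, stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, rows)
  kept <- snps[!startsWith(snps$action, "dropped"), , drop = FALSE]
  if (nrow(kept) == 0)
    stop("all shared SNPs dropped during harmonization of '",
         ivs@exposureName, "' -> '", outcome@traitName, "'")
  bad <- !is.na(kept$eaf_x) & !is.na(kept$eaf_y) &
    abs(kept$eaf_x - kept$eaf_y) > 0.2
  if (any(bad))
    warning(sum(bad), " SNP(s) with |eaf_x - eaf_y| > 0.2 after ",
            "alignment (possible strand or build mismatch): ",
            paste(utils::head(kept$snp_id[bad], 5), collapse = ", "))
  harmonizedSet(kept, exposureName = ivs@exposureName,
                outcomeName = outcome@traitName,
                outcomeType = outcome@traitType,
                caseFraction = outcome@caseFraction)
}

#' Exchange exposure and outcome roles in a harmonized set
#'
#' Label-level plumbing for the bidirectional pipeline: x and y columns
#' and trait names are swapped.  Actual reverse-direction analyses
#' re-select instruments from the former outcome's own summary
#' statistics; this function never substitutes for that.
#'
#' @param hset a \linkS4class{HarmonizedSet}.
#' @return the role-exchanged \linkS4class{HarmonizedSet}.
#' @export
flipDirection <- function(hset) {
  stopifnot(is(hset, "HarmonizedSet"))
  s <- hset@snps
  flipped <- data.frame(snp_id = s$snp_id,
                        beta_x = s$beta_y, se_x = s$se_y,
                        beta_y = s$beta_x, se_y = s$se_x,
                        eaf_x = s$eaf_y, eaf_y = s$eaf_x,
                        r2_x = if (is.null(s$r2_y)) NA_real_ else s$r2_y,
                        r2_y = s$r2_x, n_x = s$n_y, n_y = s$n_x,
                        action = s$action, stringsAsFactors = FALSE)
  harmonizedSet(flipped, exposureName = hset@outcomeName,
                outcomeName = hset@exposureName,
                outcomeType = "continuous",
                caseFraction = NA_real_)
}
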