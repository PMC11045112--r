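#' Construct a SummaryStats object from a per-SNP data frame
#'
#' Rows violating the per-SNP invariants (valid alleles, se > 0, p in
#' (0,1], eaf in (0,1) when present, case counts summing to n) are dropped
#' and recorded in the drop log with a machine-readable reason code, so
#' that n_in = n_kept + n_dropped always holds.
#'
#' @param snps data.frame with (a superset of) the canonical columns
#'   \code{snp_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#'   \code{n}, \code{n_cases}, \code{n_controls}; missing optional columns
#'   are filled with \code{NA}.
#' @param traitName trait label.
#' @param traitType \code{"continuous"} or \code{"binary"}.
#' @param caseFraction case fraction for binary traits (may be derived
#'   from per-record case counts if omitted).
#' @return a validated \linkS4class{SummaryStats}.
#' @export
summaryStats <- function(snps, traitName = "trait",
                         traitType = c("continuous", "binary"),
                         caseFraction = NA_real_) {
  traitType <- match.arg(traitType)
  for (col in c("chrom", "pos", "eaf", "n_cases", "n_controls"))
    if (is.null(snps[[col]])) snps[[col]] <- NA
  missing_cols <- setdiff(.SNP_COLS, names(snps))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  snps <- snps[, .SNP_COLS]
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$effect_allele <- toupper(as.character(snps$effect_allele))
  snps$other_allele <- toupper(as.character(snps$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n", "n_cases", "n_controls"))
    snps[[col]] <- suppressWarnings(as.numeric(snps[[col]]))

  reason <- rep(NA_character_, nrow(snps))
  flag <- function(bad, code) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- code
  }
  flag(is.na(snps$snp_id) | snps$snp_id == "", "missing_id")
  flag(!snps$effect_allele %in% .VALID_BASES |
       !snps$other_allele %in% .VALID_BASES, "invalid_allele")
  flag(snps$effect_allele == snps$other_allele, "identical_alleles")
  flag(is.na(snps$beta), "missing_beta")
  flag(is.na(snps$se) | snps$se <= 0, "invalid_se")
  flag(is.na(snps$pval) | snps$pval <= 0 | snps$pval > 1, "invalid_pval")
  flag(is.na(snps$n) | snps$n <= 0, "invalid_n")
  flag(!is.na(snps$eaf) & (snps$eaf <= 0 | snps$eaf >= 1), "invalid_eaf")
  flag(!is.na(snps$n_cases) & !is.na(snps$n_controls) &
       abs(snps$n_cases + snps$n_controls - snps$n) > 0.5,
       "case_count_mismatch")
  flag(duplicated(snps$snp_id), "duplicate_id")

  dropped <- !is.na(reason)
  log <- data.frame(snp_id = snps$snp_id[dropped],
                    reason = reason[dropped], stringsAsFactors = FALSE)
  kept <- snps[!dropped, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0)
    stop("no valid rows after validation for trait '", traitName, "'")

  if (traitType == "binary" && is.na(caseFraction) &&
      any(!is.na(kept$n_cases)))
    caseFraction <- stats::median(kept$n_cases / kept$n, na.rm = TRUE)

  new("SummaryStats", traitName = traitName, traitType = traitType,
      snps = kept, caseFraction = caseFraction, dropLog = log)
}

.DEFAULT_COLMAP <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                     effect_allele = "effect_allele",
                     other_allele = "other_allele", eaf = "eaf",
                     beta = "beta", se = "se", pval = "pval", n = "n",
                     n_cases = "n_cases", n_controls = "n_controls")

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path file path (TSV by default).
#' @param columnMap named character vector or list mapping the canonical
#'   field names (\code{snp_id}, \code{effect_allele}, \code{other_allele},
#'   \code{beta}, \code{se}, \code{pval}, \code{n}, optionally
#'   \code{chrom}, \code{pos}, \code{eaf}, \code{n_cases},
#'   \code{n_controls}) to column names in the file.  Defaults to identity.
#' @param traitType \code{"continuous"} or \code{"binary"}.
#' @param traitName trait label; defaults to the file name.
#' @param sep field separator, tab by default.
#' @param caseFraction optional case fraction for binary traits.
#' @return a \linkS4class{SummaryStats}; invalid rows are dropped and
#'   logged (see \code{\link{dropLog}}).
#' @export
readSumstats <- function(path, columnMap = NULL,
                         traitType = c("continuous", "binary"),
                         traitName = NULL, sep = "\t",
                         caseFraction = NA_real_) {
  traitType <- match.arg(traitType)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(traitName))
    traitName <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  cmap <- .DEFAULT_COLMAP
  if (!is.null(columnMap)) {
    columnMap <- unlist(columnMap)
    cmap[names(columnMap)] <- columnMap
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                 "pval", "n")
  miss <- mandatory[!cmap[mandatory] %in% names(raw)]
  if (length(miss))
    stop("mandatory column(s) not found in ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", miss, cmap[miss]),
               collapse = ", "))
  snps <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(cmap))
    snps[[field]] <- if (cmap[[field]] %in% names(raw))
      raw[[cmap[[field]]]] else NA
  summaryStats(snps, traitName = traitName, traitType = traitType,
               caseFraction = caseFraction)
}

#' Construct an LD table from pairwise entries
#'
#' @param entries data.frame with columns \code{snp_a}, \code{snp_b},
#'   \code{r2}.  Self-pairs are ignored (self-LD is 1 by construction);
#'   duplicate unordered pairs keep the first occurrence.
#' @return an \linkS4class{LdTable}.
#' @export
ldTable <- function(entries = data.frame(snp_a = character(),
                                         snp_b = character(),
                                         r2 = numeric())) {
  entries$snp_a <- as.character(entries$snp_a)
  entries$snp_b <- as.character(entries$snp_b)
  entries$r2 <- as.numeric(entries$r2)
  if (any(is.na(entries$r2) | entries$r2 < 0 | entries$r2 > 1))
    stop("LD r2 values must be in [0,1]")
  entries <- entries[entries$snp_a != entries$snp_b, , drop = FALSE]
  key <- paste(pmin(entries$snp_a, entries$snp_b),
               pmax(entries$snp_a, entries$snp_b))
  entries <- entries[!duplicated(key), , drop = FALSE]
  rownames(entries) <- NULL
  new("LdTable", entries = entries)
}

#' Read a pairwise LD table from a 3-column delimited file
#'
#' @param path path to a file with columns snp_a, snp_b, r2 (header
#'   optional; detected from the third field of the first line).
#' @param sep field separator.
#' @return an \linkS4class{LdTable}; absent pairs look up as 0,
#'   self-pairs as 1.
#' @export
readLdTable <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  raw <- utils::read.table(path, header = has_header, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("LD table must have three columns")
  names(raw)[1:3] <- c("snp_a", "snp_b", "r2")
  ldTable(raw[, 1:3])
}

#' Write MR results to a delimited text file
#'
#' Writes one row per estimate with the standard report header
#' (exposure, outcome, method, n_snps, beta, se, ci_low, ci_high, pval,
#' qval, notes); binary-outcome rows additionally carry
#' \code{or_value = exp(beta)}.  Numeric fields are written with 10
#' significant digits so that a read-back reproduces them.
#'
#' @param results a list of \linkS4class{MREstimate} (optionally with a
#'   \code{qval} attribute each) or a data.frame already in report shape.
#' @param path output path.
#' @param qvals optional numeric vector of FDR-adjusted q-values, one per
#'   estimate.
#' @param notes optional character vector of notes, one per estimate.
#' @param sep field separator.
#' @return invisibly, the written data.frame.
#' @export
writeResults <- function(results, path, qvals = NULL, notes = NULL,
                         sep = "\t") {
  if (is.data.frame(results)) {
    df <- results
  } else {
    if (length(results) == 0) stop("no results to write")
    rows <- lapply(seq_along(results), function(i) {
      e <- results[[i]]
      stopifnot(is(e, "MREstimate"))
      data.frame(exposure = e@exposure, outcome = e@outcome,
                 method = e@method, n_snps = e@nSnps, beta = e@beta,
                 se = e@se, ci_low = e@ciLow, ci_high = e@ciHigh,
                 pval = e@pval, qval = if (is.null(qvals)) NA_real_
                                else qvals[i],
                 or_value = e@orValue,
                 notes = if (is.null(notes)) "" else notes[i],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (all(is.na(df$or_value))) df$or_value <- NULL
  }
  if (nrow(df) == 0) stop("no results to write")
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.10g", x))
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ",
                        conditionMessage(ok))
  invisible(df)
}
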