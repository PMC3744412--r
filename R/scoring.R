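## Fine-mapping statistics on individually genotyped segregants.

#' Exact two-sided binomial test against 1:1 segregation
#'
#' With k superior-parent calls among n segregants and X ~ Binomial(n, 1/2),
#' p = min(1, 2 min(P(X <= k), P(X >= k))), tails by exact summation.
#' This doubling convention is symmetric (p(k, n) = p(n - k, n)) and, for
#' the symmetric null of this test, coincides with the minimum-likelihood
#' two-sided convention of \code{binom.test}.
#'
#' @param k number of superior-parent calls (vectorised)
#' @param n number of non-missing calls
#' @return two-sided exact p-value(s) in (0, 1]
#' @examples
#' binomExactTwoSided(46, 46)   # 2 * 0.5^46
#' binomExactTwoSided(31, 62)   # 1 at the null mean
#' @export
binomExactTwoSided <- function(k, n) {
  if (length(n) == 1L) n <- rep(n, length(k))
  if (any(n < 1L)) stop("n must be >= 1")
  if (any(k < 0L) || any(k > n)) stop("need 0 <= k <= n")
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependency:
#' adjusted_i = min over j with p_j >= p_i of min(1, p_j m c(m) / rank_j),
#' with c(m) the m-th harmonic number (delegates to
#' \code{stats::p.adjust(method = "BY")}).
#'
#' @param p raw p-values in [0, 1]
#' @return adjusted p-values (order-preserving, never below the raw value)
#' @export
byFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BY")
}

#' Score SNPs in individually genotyped segregants
#'
#' For each scored SNP: the association percentage to the superior parent
#' (share of "S" calls among non-missing calls), the exact binomial test
#' against 1:1 segregation, and BY-FDR adjustment across the scored SNP
#' set.  Missing calls are excluded per SNP (pairwise deletion), matching
#' designs where the genotyped segregant count varies by locus.
#'
#' @param genotypes character matrix (segregants x SNPs) with calls "S",
#'   "I" or NA; column names "chrom:pos"
#' @param snps SNP ids to score (default: all columns)
#' @param fdrAcross "scored" adjusts across the scored set (default);
#'   "all" adjusts across every column of the matrix before subsetting,
#'   for designs where all genotyped SNPs form one family
#' @return data.frame (sorted by position): snp, chrom, pos, n, k,
#'   association (percent, 2 decimals), p_raw, p_fdr
#' @export
scoreRegion <- function(genotypes, snps = NULL,
                        fdrAcross = c("scored", "all")) {
  fdrAcross <- match.arg(fdrAcross)
  if (is.null(colnames(genotypes)))
    stop("genotype matrix must have 'chrom:pos' column names")
  if (is.null(snps)) snps <- colnames(genotypes)
  absent <- setdiff(snps, colnames(genotypes))
  if (length(absent))
    stop("SNP(s) not in the genotype matrix: ", paste(absent, collapse = ", "))
  scoreCols <- if (fdrAcross == "all") colnames(genotypes) else snps
  sub <- genotypes[, scoreCols, drop = FALSE]
  n <- colSums(!is.na(sub))
  if (any(n == 0L))
    stop("SNP(s) with no genotype calls: ",
         paste(scoreCols[n == 0L], collapse = ", "))
  k <- colSums(sub == "S", na.rm = TRUE)
  pRaw <- binomExactTwoSided(k, n)
  pFdr <- byFdr(pRaw)
  cp <- .splitIds(scoreCols)
  out <- data.frame(snp = scoreCols, chrom = cp$chrom, pos = cp$pos,
                    n = as.integer(n), k = as.integer(k),
                    association = round(100 * k / n, 2),
                    p_raw = pRaw, p_fdr = pFdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$snp %in% snps, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a fine-mapping score table
#'
#' Table-style TSV: snp, n, k, association_pct, p_raw, p_fdr.
#'
#' @param scores data.frame from \code{\link{scoreRegion}}
#' @param path output file
#' @export
writeScoreTable <- function(scores, path) {
  d <- scores[, c("snp", "n", "k", "association", "p_raw", "p_fdr")]
  names(d)[4] <- "association_pct"
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
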