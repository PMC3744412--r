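## Monte-Carlo simultaneous inference on the selected-vs-unselected contrast.
##
## The contrast c(x) = eta_q(x) - eta_0(x) is the log odds ratio between a
## selected pool q and the unselected pool 0.  Null coefficient errors are
## drawn from N(0, Vq) and N(0, V0) (independent pools); the sup over the
## grid of |B(x) (dq - d0)| / SE(x) gives both the simultaneous critical
## value z* and, re-used, the null distribution for threshold-adjusted
## p-values p(x) = P( sup-statistic >= max(0, |c(x)| - delta) / SE(x) ).
## V is the total coefficient covariance (penalised information plus the
## finite-pool segregant-sampling component), so the band is calibrated for
## pools of a known number of recombinant genomes.

#' Construct an InferenceConfig
#'
#' @param delta biological-relevance threshold on the log odds ratio.  The
#'   default 0.4088 is the conventional printed value for an odds ratio
#'   outside [2/3, 3/2] (pool frequency outside [40\%, 60\%] against an
#'   unselected pool at 50\%); note ln(3/2) = 0.4055.
#' @param alpha complement of the simultaneous confidence level.
#' @param nSims Monte-Carlo draws; 1e6 for publication-grade profiles,
#'   1e4 for desk-scale runs.
#' @param seed integer seed; NA continues the current RNG stream.
#' @param mask \code{GRanges} excluded from QTL calling (e.g. subtelomeres).
#' @return an \code{InferenceConfig}
#' @export
InferenceConfig <- function(delta = 0.4088, alpha = 0.05, nSims = 1e6,
                            seed = NA_integer_, mask = GRanges()) {
  new("InferenceConfig", delta = delta, alpha = alpha,
      nSims = as.integer(nSims), seed = as.integer(seed), mask = mask)
}

.checkSameFrame <- function(fitQ, fit0) {
  if (!identical(fitQ@chrom, fit0@chrom))
    stop("fits are on different chromosomes (", fitQ@chrom, " vs ",
         fit0@chrom, ")")
  if (length(fitQ@grid) != length(fit0@grid) ||
      any(fitQ@grid != fit0@grid) ||
      length(fitQ@knots) != length(fit0@knots) ||
      any(fitQ@knots != fit0@knots))
    stop("fits use different grids/bases; fit both pools on the same ",
         "marker frame")
}

.gridDesign <- function(fit, positions = NULL) {
  if (is.null(positions)) positions <- fit@grid
  splineDesign(fit@knots, positions, ord = fit@degree + 1L)
}

.cholOrFail <- function(V, what) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    V <- V + diag(1e-10 * max(diag(V)), nrow(V))
    L <- tryCatch(chol(V), error = function(e) NULL)
  }
  if (is.null(L))
    stop("covariance of ", what, " is not positive semi-definite")
  L
}

#' Contrast between a selected pool and the unselected pool
#'
#' @param fitQ,fit0 \code{\link{FrequencyFit}} objects for the selected and
#'   the unselected pool, fitted on the same marker frame
#' @param positions optional positions (default: the fits' grid)
#' @return list(grid, contrast, se): the log odds ratio and its standard
#'   error (variances add; the pools are independent)
#' @export
computeContrast <- function(fitQ, fit0, positions = NULL) {
  .checkSameFrame(fitQ, fit0)
  B <- .gridDesign(fitQ, positions)
  contrast <- drop(B %*% (fitQ@coef - fit0@coef))
  se <- sqrt(pmax(rowSums((B %*% fitQ@vcovTotal) * B) +
                  rowSums((B %*% fit0@vcovTotal) * B), 1e-24))
  list(grid = if (is.null(positions)) fitQ@grid else positions,
       contrast = contrast, se = se)
}

## sup-statistic draws for one chromosome (chunked for memory).  One pass
## yields both standardisations from the same normal deviates:
##   - "wald": coefficient errors from the two pools' own covariances,
##     standardised by the Wald SE -> the band's critical value;
##   - "null": both pools drawn from the unselected pool's covariance,
##     standardised by the null SE -> the p-value null distribution
##     (under the segregation null a selected pool is statistically a
##     second unselected pool).
.supDraws <- function(fitQ, fit0, se, seNull, nSims, positions = NULL,
                      chunk = 2000L) {
  B <- .gridDesign(fitQ, positions)
  p <- ncol(B)
  Lq <- .cholOrFail(fitQ@vcovTotal, paste0("pool '", fitQ@pool, "'"))
  L0 <- .cholOrFail(fit0@vcovTotal, paste0("pool '", fit0@pool, "'"))
  wald <- nullS <- numeric(nSims)
  done <- 0L
  while (done < nSims) {
    m <- min(chunk, nSims - done)
    Zq <- matrix(rnorm(p * m), p)
    Z0 <- matrix(rnorm(p * m), p)
    Mw <- abs(B %*% (crossprod(Lq, Zq) - crossprod(L0, Z0))) / se
    wald[done + seq_len(m)] <- apply(Mw, 2L, max)
    Mn <- abs(B %*% crossprod(L0, Zq - Z0)) / seNull
    nullS[done + seq_len(m)] <- apply(Mn, 2L, max)
    done <- done + m
  }
  list(wald = wald, null = nullS)
}

## null-standardisation SE: both pools fluctuate like the unselected pool
.seNull <- function(fit0, positions = NULL) {
  B <- .gridDesign(fit0, positions)
  sqrt(pmax(2 * rowSums((B %*% fit0@vcovTotal) * B), 1e-24))
}

#' Simultaneous confidence band for the pool contrast
#'
#' Draws \code{nSims} null coefficient errors from the two fits' sampling
#' distributions, takes the (1 - alpha) quantile z* of the sup over the
#' grid of |simulated contrast| / SE, and returns the band
#' contrast +/- z* SE.  On a single-point grid z* reduces to the two-sided
#' pointwise normal critical value.
#'
#' @inheritParams computeContrast
#' @param config an \code{\link{InferenceConfig}}
#' @return a \code{\link{ContrastProfile}} (p-values not yet filled;
#'   see \code{\link{adjustedPvalues}})
#' @export
simultaneousBand <- function(fitQ, fit0, config = InferenceConfig(),
                             positions = NULL) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  cc <- computeContrast(fitQ, fit0, positions)
  seNull <- .seNull(fit0, positions)
  s <- .supDraws(fitQ, fit0, cc$se, seNull, config@nSims, positions)
  zStar <- quantile(s$wald, 1 - config@alpha, names = FALSE)
  new("ContrastProfile", pool = fitQ@pool, baseline = fit0@pool,
      chrom = fitQ@chrom, grid = cc$grid, contrast = cc$contrast,
      se = cc$se, seNull = seNull,
      lo = cc$contrast - zStar * cc$se,
      hi = cc$contrast + zStar * cc$se,
      pAdj = numeric(0), zStar = zStar, delta = config@delta,
      alpha = config@alpha, nSims = config@nSims, supDraws = s$wald,
      supDrawsNull = s$null)
}

## p(x) from the observed exceedance statistic and null sup draws
.pFromDraws <- function(contrast, se, delta, draws) {
  t <- pmax(0, abs(contrast) - delta) / se
  vapply(t, function(tt) if (tt <= 0) 1 else mean(draws >= tt), numeric(1))
}

#' Threshold-adjusted two-sided p-value profile
#'
#' The observed statistic at x is the distance of |contrast| beyond the
#' biological threshold delta, standardised by the contrast's standard
#' error under the random-segregation null (both pools fluctuating like
#' the unselected pool); its adjusted p-value is the Monte-Carlo
#' probability that the null sup-statistic (computed in the same pass as
#' the band's draws) exceeds it.  Null (score-type) standardisation is
#' used because at a strongly selected locus the pool frequency
#' saturates and the Wald variance of a near-infinite log odds ratio
#' blows up, which would void power exactly where the signal is
#' strongest; under the null both standardisations coincide, so
#' calibration is unaffected.  Inside the threshold region
#' (|contrast| <= delta) the p-value is 1 by definition: such differences
#' are not biologically relevant regardless of significance.
#'
#' @inheritParams simultaneousBand
#' @param band optional \code{\link{ContrastProfile}} from
#'   \code{\link{simultaneousBand}} whose null draws are re-used (one
#'   Monte-Carlo pass serves both band and p-values)
#' @return a \code{\link{ContrastProfile}} with \code{pAdj} filled
#' @export
adjustedPvalues <- function(fitQ, fit0, config = InferenceConfig(),
                            band = NULL, positions = NULL) {
  if (is.null(band)) band <- simultaneousBand(fitQ, fit0, config, positions)
  band@pAdj <- .pFromDraws(band@contrast, band@seNull, band@delta,
                           band@supDrawsNull)
  band
}

#' Genome-wide contrast inference for one selected pool
#'
#' Runs \code{\link{simultaneousBand}} per chromosome and computes
#' p-values against the genome-wide null sup-distribution (the per-draw
#' maximum of the chromosome sup-statistics), so one p < alpha anywhere
#' controls the familywise error over the whole genome.
#'
#' @param fitsQ,fits0 named lists (by chromosome) of \code{FrequencyFit}
#' @param config an \code{\link{InferenceConfig}}
#' @return named list (by chromosome) of \code{\link{ContrastProfile}}
#' @export
contrastInference <- function(fitsQ, fits0, config = InferenceConfig()) {
  stopifnot(identical(names(fitsQ), names(fits0)))
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  cfgChrom <- config
  cfgChrom@seed <- NA_integer_    # one stream across chromosomes
  profiles <- lapply(names(fitsQ), function(ch)
    simultaneousBand(fitsQ[[ch]], fits0[[ch]], cfgChrom))
  names(profiles) <- names(fitsQ)
  supGenome <- Reduce(pmax, lapply(profiles, slot, "supDrawsNull"))
  for (ch in names(profiles)) {
    pr <- profiles[[ch]]
    pr@pAdj <- .pFromDraws(pr@contrast, pr@seNull, pr@delta, supGenome)
    profiles[[ch]] <- pr
  }
  profiles
}

setMethod("show", "ContrastProfile", function(object) {
  cat(sprintf(
    "ContrastProfile: pool '%s' vs '%s', chromosome %s\n  %d grid points, z* = %.3f (alpha = %.2f, %d draws), delta = %.4f\n",
    object@pool, object@baseline, object@chrom, length(object@grid),
    object@zStar, object@alpha, object@nSims, object@delta))
  if (length(object@pAdj))
    cat(sprintf("  min adjusted p = %.3g\n", min(object@pAdj)))
})

#' Call QTL regions from adjusted p-value profiles
#'
#' Maximal runs of consecutive grid points with adjusted p < alpha and a
#' constant contrast sign become calls; runs separated by a single
#' non-significant grid point (same sign) are merged; grid points inside
#' masked intervals are removed before run finding.  The peak is the grid
#' point with the smallest adjusted p (ties: largest |contrast|); the
#' direction is "superior" for a positive contrast at the peak (causative
#' allele from the superior parent) and "inferior" otherwise.
#'
#' @param profiles a \code{\link{ContrastProfile}} or list of them (several
#'   pools and/or chromosomes)
#' @param config an \code{\link{InferenceConfig}} (alpha and mask are used)
#' @return \code{GRanges} of calls (1-based closed, grid-snapped) with
#'   metadata columns pool, direction, peak, minP, maxAbsContrast, sorted
#'   by minP
#' @export
callQtls <- function(profiles, config = InferenceConfig()) {
  if (is(profiles, "ContrastProfile")) profiles <- list(profiles)
  calls <- list()
  for (pr in profiles) {
    if (!length(pr@pAdj))
      stop("profile for chromosome ", pr@chrom, " has no adjusted p-values")
    keep <- rep(TRUE, length(pr@grid))
    if (length(config@mask)) {
      gr <- GRanges(pr@chrom, IRanges(pr@grid, width = 1L))
      keep[S4Vectors::queryHits(findOverlaps(gr, config@mask))] <- FALSE
    }
    idx <- which(keep)
    if (!length(idx)) next
    sig <- pr@pAdj[idx] < config@alpha
    sgn <- sign(pr@contrast[idx])
    runs <- list()
    i <- 1L
    while (i <= length(idx)) {
      if (!sig[i]) { i <- i + 1L; next }
      j <- i
      while (j < length(idx) && sig[j + 1L] && sgn[j + 1L] == sgn[i])
        j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    }
    if (!length(runs)) next
    ## merge runs separated by fewer than 2 grid steps with the same sign
    merged <- list(runs[[1L]])
    for (r in runs[-1L]) {
      last <- merged[[length(merged)]]
      gap <- r[1L] - last[2L] - 1L
      if (gap < 2L && sgn[r[1L]] == sgn[last[1L]])
        merged[[length(merged)]] <- c(last[1L], r[2L])
      else merged[[length(merged) + 1L]] <- r
    }
    for (r in merged) {
      sel <- idx[r[1L]:r[2L]]
      pk <- sel[order(pr@pAdj[sel], -abs(pr@contrast[sel]))][1L]
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = pr@chrom, start = pr@grid[idx[r[1L]]],
        end = pr@grid[idx[r[2L]]], pool = pr@pool,
        direction = if (pr@contrast[pk] > 0) "superior" else "inferior",
        peak = pr@grid[pk], minP = min(pr@pAdj[sel]),
        maxAbsContrast = max(abs(pr@contrast[sel])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(GRanges(pool = character(), direction = character(),
                   peak = numeric(), minP = numeric(),
                   maxAbsContrast = numeric()))
  d <- do.call(rbind, calls)
  d <- d[order(d$minP, -d$maxAbsContrast), , drop = FALSE]
  GRanges(d$chrom, IRanges(d$start, d$end), pool = d$pool,
          direction = d$direction, peak = d$peak, minP = d$minP,
          maxAbsContrast = d$maxAbsContrast)
}

#' Write a contrast profile TSV
#'
#' Columns: chrom, pos, contrast, se, lo, hi, p_adj.
#'
#' @param profile a \code{\link{ContrastProfile}}
#' @param path output file
#' @export
writeContrastProfile <- function(profile, path) {
  d <- data.frame(chrom = profile@chrom, pos = profile@grid,
                  contrast = profile@contrast, se = profile@se,
                  lo = profile@lo, hi = profile@hi,
                  p_adj = if (length(profile@pAdj)) profile@pAdj else NA_real_)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
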