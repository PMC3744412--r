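#' Construct a PoolCountsExperiment
#'
#' @param markers \code{GRanges} of width-1 marker positions (sorted), or a
#'   data.frame with columns \code{chrom} and \code{pos}.
#' @param variantCount,totalCount integer matrices (markers x samples) with
#'   identical column names.
#' @param role character vector per sample: "parent", "selected" or
#'   "unselected".
#' @param nSegregants numeric vector per sample: number of segregants in
#'   the pool (\code{Inf} for a parent strain sample).
#' @return a \code{PoolCountsExperiment}
#' @export
PoolCountsExperiment <- function(markers, variantCount, totalCount,
                                 role = rep("selected", ncol(variantCount)),
                                 nSegregants = rep(Inf, ncol(variantCount))) {
  if (is.data.frame(markers))
    markers <- GRanges(markers$chrom, IRanges(markers$pos, width = 1L))
  variantCount <- as.matrix(variantCount)
  totalCount <- as.matrix(totalCount)
  if (is.null(colnames(variantCount)))
    colnames(variantCount) <- colnames(totalCount) <-
      paste0("pool", seq_len(ncol(variantCount)) - 1L)
  se <- SummarizedExperiment(
    assays = list(variantCount = variantCount, totalCount = totalCount),
    rowRanges = markers,
    colData = DataFrame(role = role, nSegregants = nSegregants,
                        row.names = colnames(variantCount)))
  new("PoolCountsExperiment", se)
}

#' @rdname PoolCountsExperiment-class
#' @aliases variantCounts,PoolCountsExperiment-method
setMethod("variantCounts", "PoolCountsExperiment",
          function(x) assay(x, "variantCount"))

#' @rdname PoolCountsExperiment-class
#' @aliases totalCounts,PoolCountsExperiment-method
setMethod("totalCounts", "PoolCountsExperiment",
          function(x) assay(x, "totalCount"))

#' @rdname PoolCountsExperiment-class
#' @aliases variantFrequency,PoolCountsExperiment-method
setMethod("variantFrequency", "PoolCountsExperiment", function(x) {
  v <- assay(x, "variantCount"); t <- assay(x, "totalCount")
  f <- v / t
  f[t == 0] <- NA_real_
  f
})

setMethod("show", "PoolCountsExperiment", function(object) {
  cat("PoolCountsExperiment:", nrow(object), "markers x", ncol(object),
      "samples\n")
  cat("  samples:", paste(sprintf("%s (%s)", colnames(object),
                                  colData(object)$role), collapse = ", "), "\n")
  lg <- metadata(object)$filterLog
  if (!is.null(lg)) cat("  filter:", lg$kept, "of", lg$input, "markers kept\n")
})
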