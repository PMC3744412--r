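#' @rdname GenomeLayout-class
#' @param x a \code{GenomeLayout}
#' @export
setGeneric("chromInfo", function(x) standardGeneric("chromInfo"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname GenomeLayout-class
#' @param chrom chromosome name
#' @export
setGeneric("markerPositions", function(x, chrom) standardGeneric("markerPositions"))

#' @rdname SegregantGenome-class
#' @param genome a \code{SegregantGenome}
#' @param chrom chromosome name
#' @param positions positions (bp) at which the parental origin is queried
#' @export
setGeneric("originAt", function(genome, chrom, positions) standardGeneric("originAt"))

#' @rdname PoolCountsExperiment-class
#' @param x a \code{PoolCountsExperiment}
#' @export
setGeneric("variantCounts", function(x) standardGeneric("variantCounts"))

#' @rdname PoolCountsExperiment-class
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname PoolCountsExperiment-class
#' @export
setGeneric("variantFrequency", function(x) standardGeneric("variantFrequency"))

#' @rdname FrequencyFit-class
#' @param object a \code{FrequencyFit}
#' @export
setGeneric("fittedLogit", function(object) standardGeneric("fittedLogit"))

#' @rdname FrequencyFit-class
#' @export
setGeneric("fittedFrequency", function(object) standardGeneric("fittedFrequency"))
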