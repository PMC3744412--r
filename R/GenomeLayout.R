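#' Construct a GenomeLayout
#'
#' @param chromosomes data.frame with columns \code{name}, \code{lengthBp},
#'   \code{geneticLengthM}.
#' @param markerPositions named list, one integer vector of strictly
#'   increasing 1-based marker positions per chromosome.
#' @return a \code{GenomeLayout}
#' @examples
#' gl <- GenomeLayout(
#'   data.frame(name = "chrI", lengthBp = 2e5, geneticLengthM = 0.8),
#'   list(chrI = seq(1000, 199000, by = 2000)))
#' length(markers(gl))
#' @export
GenomeLayout <- function(chromosomes, markerPositions = list()) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  chromosomes$name <- as.character(chromosomes$name)
  bad <- setdiff(names(markerPositions), chromosomes$name)
  if (length(bad))
    stop("marker positions given for unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  grl <- lapply(chromosomes$name, function(nm) {
    p <- markerPositions[[nm]]
    if (is.null(p) || !length(p)) return(GRanges())
    p <- as.integer(sort(unique(p)))
    GRanges(nm, IRanges(p, width = 1L))
  })
  mk <- suppressWarnings(do.call(c, grl))
  new("GenomeLayout", chromosomes = chromosomes, markers = mk)
}

#' @rdname GenomeLayout-class
#' @aliases chromInfo,GenomeLayout-method
setMethod("chromInfo", "GenomeLayout", function(x) x@chromosomes)

#' @rdname GenomeLayout-class
#' @aliases markers,GenomeLayout-method
setMethod("markers", "GenomeLayout", function(x) x@markers)

#' @rdname GenomeLayout-class
#' @aliases markerPositions,GenomeLayout-method
setMethod("markerPositions", "GenomeLayout", function(x, chrom) {
  start(x@markers)[as.character(seqnames(x@markers)) == chrom]
})

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout:", nrow(object@chromosomes), "chromosome(s),",
      length(object@markers), "markers\n")
  cat("  physical:", sum(object@chromosomes$lengthBp), "bp; genetic:",
      round(sum(object@chromosomes$geneticLengthM), 2), "Morgans\n")
})

## internal: chromosome record lookup
.chromRec <- function(layout, chrom) {
  i <- match(chrom, layout@chromosomes$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  layout@chromosomes[i, ]
}
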