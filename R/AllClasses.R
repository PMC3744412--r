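## S4 classes for the cross model, the count container and the fitted objects.

#' GenomeLayout: coordinate frame of a cross
#'
#' Chromosome sizes (physical and genetic) together with the catalogue of
#' parent-distinguishing SNP marker positions.  Coordinates are 1-based and
#' intervals closed, as in the per-QTL tables of pooled-segregant studies.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{lengthBp}
#'   (physical length), \code{geneticLengthM} (genetic length in Morgans;
#'   0 is allowed and yields no crossovers).
#' @slot markers \code{GRanges} of width-1 marker positions, sorted.
#' @export
setClass("GenomeLayout",
  slots = c(chromosomes = "data.frame", markers = "GRanges"))

setValidity("GenomeLayout", function(object) {
  ch <- object@chromosomes
  msg <- character()
  if (nrow(ch) < 1L) msg <- c(msg, "at least one chromosome is required")
  need <- c("name", "lengthBp", "geneticLengthM")
  if (!all(need %in% names(ch)))
    return(paste("chromosomes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(ch$name)) msg <- c(msg, "duplicated chromosome names")
  if (any(ch$lengthBp < 1)) msg <- c(msg, "chromosome lengths must be >= 1 bp")
  if (any(!is.finite(ch$geneticLengthM)) || any(ch$geneticLengthM < 0))
    msg <- c(msg, "genetic lengths must be finite and >= 0 Morgans")
  mk <- object@markers
  if (length(mk)) {
    sn <- as.character(seqnames(mk))
    if (!all(sn %in% ch$name))
      msg <- c(msg, "markers on unknown chromosomes")
    len <- ch$lengthBp[match(sn, ch$name)]
    if (any(start(mk) < 1L) || any(start(mk) > len))
      msg <- c(msg, "marker positions outside [1, chromosome length]")
    sp <- split(start(mk), sn)
    if (any(vapply(sp, function(p) is.unsorted(p, strictly = TRUE), logical(1))))
      msg <- c(msg, "marker positions must be strictly increasing per chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' SegregantGenome: one haploid meiotic product
#'
#' The recombinant mosaic of a haploid segregant, stored per chromosome as
#' crossover breakpoints plus the parental origin ("S" superior / "I"
#' inferior) of the leftmost interval; origins alternate across breakpoints.
#'
#' @slot blocks named list (one element per chromosome) of
#'   \code{list(breaks = numeric, first = "S"|"I")}.
#' @export
setClass("SegregantGenome", slots = c(blocks = "list"))

setValidity("SegregantGenome", function(object) {
  for (b in object@blocks) {
    if (!is.list(b) || !all(c("breaks", "first") %in% names(b)))
      return("each chromosome needs 'breaks' and 'first'")
    if (is.unsorted(b$breaks, strictly = TRUE)) return("breakpoints must be strictly increasing")
    if (!b$first %in% c("S", "I")) return("first origin must be 'S' or 'I'")
  }
  TRUE
})

#' PhenotypeModel: quantitative trait model of a cross
#'
#' Additive QTL effects on a latent continuous phenotype with Gaussian
#' environmental noise.  A positive effect means the superior-parent allele
#' increases the phenotype; a negative effect models a QTL linked to the
#' inferior parent (its allele is the beneficial one).  A QTL can carry an
#' allele-specific epistatic mask: its effect is nullified whenever the
#' masking locus carries the superior-parent allele.  Downgraded loci
#' (\code{fixed}) behave as if every segregant carried the inferior allele,
#' emulating replacement of the superior allele in the parent strain.
#'
#' @slot qtls data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{effect}, \code{maskedBy} (id or NA), \code{fixed} (logical).
#' @slot baseline numeric baseline phenotype.
#' @slot noiseSd  numeric standard deviation of environmental noise (>= 0).
#' @export
setClass("PhenotypeModel",
  slots = c(qtls = "data.frame", baseline = "numeric", noiseSd = "numeric"))

setValidity("PhenotypeModel", function(object) {
  q <- object@qtls
  msg <- character()
  need <- c("id", "chrom", "pos", "effect", "maskedBy", "fixed")
  if (!all(need %in% names(q)))
    return(paste("qtls must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(q$id)) msg <- c(msg, "duplicated QTL ids")
  if (any(!is.finite(q$effect))) msg <- c(msg, "QTL effects must be finite")
  refs <- q$maskedBy[!is.na(q$maskedBy)]
  if (!all(refs %in% q$id)) msg <- c(msg, "maskedBy references unknown QTL id")
  ## acyclicity of the mask graph
  if (nrow(q)) {
    for (i in seq_len(nrow(q))) {
      seen <- character(); cur <- q$id[i]
      while (!is.na(cur)) {
        if (cur %in% seen) { msg <- c(msg, "mask references form a cycle"); break }
        seen <- c(seen, cur)
        cur <- q$maskedBy[match(cur, q$id)]
      }
    }
  }
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single value >= 0")
  if (length(msg)) unique(msg) else TRUE
})

#' CrossConfig: design of one mapping experiment
#'
#' @slot nSegregants number of phenotyped segregants.
#' @slot poolSize pool size (58 in the emulated design).
#' @slot selection list(type = "top"|"threshold", value = numeric threshold).
#' @slot meanCoverage mean sequencing reads per marker (Poisson).
#' @slot seqError per-read probability of reporting the wrong parental allele.
#' @export
setClass("CrossConfig",
  slots = c(nSegregants = "integer", poolSize = "integer", selection = "list",
            meanCoverage = "numeric", seqError = "numeric"))

setValidity("CrossConfig", function(object) {
  msg <- character()
  if (object@nSegregants < 1L) msg <- c(msg, "nSegregants must be >= 1")
  if (object@poolSize < 1L) msg <- c(msg, "poolSize must be >= 1")
  if (object@poolSize > object@nSegregants)
    msg <- c(msg, "poolSize must be <= nSegregants")
  if (!object@selection$type %in% c("top", "threshold"))
    msg <- c(msg, "selection type must be 'top' or 'threshold'")
  if (object@meanCoverage <= 0) msg <- c(msg, "meanCoverage must be > 0")
  if (object@seqError < 0 || object@seqError >= 0.5)
    msg <- c(msg, "seqError must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' PoolCountsExperiment: per-marker allele counts for parents and pools
#'
#' A \code{RangedSummarizedExperiment} whose rows are SNP markers and whose
#' columns are sequenced samples (the superior parent and the segregant
#' pools), with assays \code{variantCount} (reads carrying the
#' superior-parent, i.e. non-reference, allele) and \code{totalCount}.
#' \code{colData} carries \code{role} ("parent", "selected", "unselected")
#' and \code{nSegregants} (pool size; \code{Inf} for the parent), which the
#' inference layer uses for the segregant-sampling variance component.
#'
#' @export
setClass("PoolCountsExperiment",
  contains = "RangedSummarizedExperiment")

setValidity("PoolCountsExperiment", function(object) {
  msg <- character()
  an <- names(assays(object))
  if (!all(c("variantCount", "totalCount") %in% an))
    return("assays 'variantCount' and 'totalCount' are required")
  v <- assay(object, "variantCount"); t <- assay(object, "totalCount")
  if (any(v < 0, na.rm = TRUE) || any(t < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (any(v > t, na.rm = TRUE))
    msg <- c(msg, "variantCount must not exceed totalCount")
  if (!all(c("role", "nSegregants") %in% names(colData(object))))
    msg <- c(msg, "colData needs 'role' and 'nSegregants'")
  if (length(msg)) msg else TRUE
})

#' FrequencyFit: smoothed logit variant frequency of one pool on one chromosome
#'
#' Result of the penalised binomial B-spline fit: coefficients, the
#' inverse-penalised-information (Bayesian) covariance used for pointwise
#' prediction, and a total covariance that additionally carries the
#' segregant-sampling component used for pool contrasts.
#'
#' @slot pool,chrom identifiers.
#' @slot knots full B-spline knot vector (boundary knots repeated).
#' @slot degree spline degree (3).
#' @slot coef,vcov coefficients and inverse penalised information.
#' @slot vcovTotal coefficient covariance including the finite-pool
#'   (segregant sampling) component; equals \code{vcov} for a parent sample.
#' @slot lambda,edf,deviance,converged fit summaries.
#' @slot grid,eta,se evaluation grid (marker positions plus a regular grid),
#'   fitted logit curve and its model-based standard error.
#' @slot etaCap reporting cap on |eta| used when mapping to frequencies.
#' @slot markerPos,markerV,markerN the data the fit was computed from.
#' @slot nSegregants,morgansPerBp pool size and assumed recombination rate
#'   behind the segregant-sampling covariance.
#' @export
setClass("FrequencyFit",
  slots = c(pool = "character", chrom = "character",
            knots = "numeric", degree = "integer",
            coef = "numeric", vcov = "matrix", vcovTotal = "matrix",
            lambda = "numeric", edf = "numeric", deviance = "numeric",
            converged = "logical",
            grid = "numeric", eta = "numeric", se = "numeric",
            etaCap = "numeric",
            markerPos = "numeric", markerV = "numeric", markerN = "numeric",
            nSegregants = "numeric", morgansPerBp = "numeric"))

setValidity("FrequencyFit", function(object) {
  msg <- character()
  if (length(object@coef) != nrow(object@vcov))
    msg <- c(msg, "coef/vcov dimension mismatch")
  if (!isTRUE(all.equal(object@vcov, t(object@vcov), tolerance = 1e-6)))
    msg <- c(msg, "vcov must be symmetric")
  if (is.unsorted(object@grid)) msg <- c(msg, "grid must be sorted")
  if (length(object@grid) != length(object@eta) ||
      length(object@grid) != length(object@se))
    msg <- c(msg, "grid/eta/se length mismatch")
  if (length(msg)) msg else TRUE
})

#' InferenceConfig: settings of the Monte-Carlo simultaneous inference
#'
#' @slot delta biological-relevance threshold on the log odds ratio
#'   (default 0.4088, i.e. an odds ratio outside [2/3, 3/2]).
#' @slot alpha complement of the simultaneous confidence level (0.05).
#' @slot nSims Monte-Carlo draws (production default 1e6; desk-scale
#'   analyses and the test-suite use 1e4).
#' @slot seed integer seed; NA means "continue the current RNG stream".
#' @slot mask \code{GRanges} of intervals excluded from QTL calling
#'   (e.g. subtelomeric repeat regions).
#' @export
setClass("InferenceConfig",
  slots = c(delta = "numeric", alpha = "numeric", nSims = "integer",
            seed = "integer", mask = "GRanges"))

setValidity("InferenceConfig", function(object) {
  msg <- character()
  if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (object@nSims < 100L) msg <- c(msg, "nSims must be >= 100")
  if (length(msg)) msg else TRUE
})

#' ContrastProfile: log odds ratio of a selected pool against pool 0
#'
#' The contrast curve with pointwise standard errors, the simultaneous
#' confidence band, and two-sided threshold-adjusted p-values.  The null
#' sup-statistic draws are retained so that band construction and p-value
#' computation share one Monte-Carlo pass.
#'
#' @export
setClass("ContrastProfile",
  slots = c(pool = "character", baseline = "character", chrom = "character",
            grid = "numeric", contrast = "numeric", se = "numeric",
            seNull = "numeric",
            lo = "numeric", hi = "numeric", pAdj = "numeric",
            zStar = "numeric", delta = "numeric", alpha = "numeric",
            nSims = "integer", supDraws = "numeric",
            supDrawsNull = "numeric"))

setValidity("ContrastProfile", function(object) {
  msg <- character()
  n <- length(object@grid)
  if (any(lengths(list(object@contrast, object@se, object@lo, object@hi)) != n))
    msg <- c(msg, "profile vectors must match the grid length")
  if (length(object@pAdj) && (any(object@pAdj < 0) || any(object@pAdj > 1)))
    msg <- c(msg, "adjusted p-values must lie in [0,1]")
  if (length(object@lo) && any(object@lo > object@contrast + 1e-8))
    msg <- c(msg, "lower band above the contrast")
  if (length(object@hi) && any(object@hi < object@contrast - 1e-8))
    msg <- c(msg, "upper band below the contrast")
  if (length(msg)) msg else TRUE
})

#' MappingReport: full result of one mapping round
#'
#' @slot fits list (by pool, then chromosome) of \code{FrequencyFit}.
#' @slot profiles list (by selected pool, then chromosome) of
#'   \code{ContrastProfile} with genome-wide adjusted p-values.
#' @slot calls \code{GRanges} of called QTL regions.
#' @slot provenance list: seed, configuration, package version, config hash.
#' @export
setClass("MappingReport",
  slots = c(fits = "list", profiles = "list", calls = "GRanges",
            provenance = "list"))
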