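## Synthetic cross generator: meiosis, phenotypes, selection, pooled sequencing.
##
## All functions take an optional integer `seed`; NULL continues the current
## RNG stream so that a whole cross can be simulated reproducibly from one
## top-level seed.

.maybeSeed <- function(seed) if (!is.null(seed) && !is.na(seed)) set.seed(seed)

#' Construct a PhenotypeModel
#'
#' @param qtls data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{effect}; optionally \code{maskedBy} (NA = no epistatic mask) and
#'   \code{fixed} (TRUE for downgraded loci).
#' @param baseline baseline phenotype value.
#' @param noiseSd standard deviation of the Gaussian environmental noise.
#' @return a \code{PhenotypeModel}
#' @export
PhenotypeModel <- function(qtls = data.frame(), baseline = 0, noiseSd = 1) {
  qtls <- as.data.frame(qtls, stringsAsFactors = FALSE)
  if (nrow(qtls)) {
    if (is.null(qtls$maskedBy)) qtls$maskedBy <- NA_character_
    if (is.null(qtls$fixed)) qtls$fixed <- FALSE
    qtls$id <- as.character(qtls$id)
    qtls$chrom <- as.character(qtls$chrom)
    qtls$maskedBy <- as.character(qtls$maskedBy)
  } else {
    qtls <- data.frame(id = character(), chrom = character(), pos = numeric(),
                       effect = numeric(), maskedBy = character(),
                       fixed = logical(), stringsAsFactors = FALSE)
  }
  new("PhenotypeModel", qtls = qtls, baseline = baseline, noiseSd = noiseSd)
}

#' Construct a CrossConfig
#'
#' @param nSegregants number of segregants phenotyped.
#' @param poolSize number of segregants per sequenced pool (default 58).
#' @param selection \code{list(type = "top")} to take the top
#'   \code{poolSize} phenotypes, or \code{list(type = "threshold", value = t)}
#'   to take all segregants with phenotype >= t.
#' @param meanCoverage mean reads per marker.
#' @param seqError per-read probability of reporting the wrong allele.
#' @return a \code{CrossConfig}
#' @export
CrossConfig <- function(nSegregants, poolSize = 58L,
                        selection = list(type = "top"),
                        meanCoverage = 100, seqError = 0.002) {
  new("CrossConfig", nSegregants = as.integer(nSegregants),
      poolSize = as.integer(poolSize), selection = selection,
      meanCoverage = meanCoverage, seqError = seqError)
}

#' Simulate one meiosis
#'
#' Crossovers per chromosome are Poisson with mean equal to the genetic
#' length in Morgans (Haldane's no-interference model) and fall uniformly
#' along the physical length; the parental origin of the leftmost interval
#' is a fair coin.
#'
#' @param layout a \code{GenomeLayout}
#' @param seed optional integer seed (NULL = use current RNG stream)
#' @return a \code{SegregantGenome}
#' @examples
#' gl <- GenomeLayout(data.frame(name = "c1", lengthBp = 1e5,
#'                               geneticLengthM = 1), list(c1 = c(1L, 99999L)))
#' g <- simulateMeiosis(gl, seed = 1)
#' originAt(g, "c1", c(1, 99999))
#' @export
simulateMeiosis <- function(layout, seed = NULL) {
  if (!is(layout, "GenomeLayout")) stop("layout must be a GenomeLayout")
  validObject(layout)
  .maybeSeed(seed)
  ch <- layout@chromosomes
  blocks <- lapply(seq_len(nrow(ch)), function(i) {
    k <- rpois(1L, ch$geneticLengthM[i])
    breaks <- if (k > 0) sort(runif(k, min = 0, max = ch$lengthBp[i])) else numeric()
    list(breaks = breaks, first = if (runif(1) < 0.5) "S" else "I")
  })
  names(blocks) <- ch$name
  new("SegregantGenome", blocks = blocks)
}

#' @rdname SegregantGenome-class
#' @aliases originAt,SegregantGenome-method
setMethod("originAt", "SegregantGenome", function(genome, chrom, positions) {
  b <- genome@blocks[[chrom]]
  if (is.null(b)) stop("unknown chromosome: ", chrom)
  idx <- findInterval(positions, b$breaks)
  other <- if (b$first == "S") "I" else "S"
  ifelse(idx %% 2L == 0L, b$first, other)
})

setMethod("show", "SegregantGenome", function(object) {
  nxo <- sum(vapply(object@blocks, function(b) length(b$breaks), numeric(1)))
  cat("SegregantGenome:", length(object@blocks), "chromosome(s),",
      nxo, "crossovers\n")
})

#' Simulate a cohort of segregants
#'
#' @inheritParams simulateMeiosis
#' @param n cohort size
#' @return list of \code{SegregantGenome}
#' @export
simulateSegregants <- function(layout, n, seed = NULL) {
  if (n < 1L) stop("need at least one segregant (n >= 1)")
  .maybeSeed(seed)
  lapply(seq_len(n), function(i) simulateMeiosis(layout))
}

#' Genotypes of segregants at the marker catalogue
#'
#' @param genomes list of \code{SegregantGenome}
#' @param layout the \code{GenomeLayout} the genomes were simulated on
#' @return character matrix (segregants x markers) of "S"/"I" calls, with
#'   column names "chrom:pos"
#' @export
segregantGenotypes <- function(genomes, layout) {
  mk <- markers(layout)
  sn <- as.character(seqnames(mk)); ps <- start(mk)
  out <- matrix(NA_character_, nrow = length(genomes), ncol = length(mk))
  for (chrom in unique(sn)) {
    j <- which(sn == chrom)
    for (i in seq_along(genomes))
      out[i, j] <- originAt(genomes[[i]], chrom, ps[j])
  }
  rownames(out) <- sprintf("seg%04d", seq_along(genomes))
  colnames(out) <- paste0(sn, ":", ps)
  out
}

## genotype of one genome at the model's QTL loci, honouring downgraded loci
.qtlGenotype <- function(genome, model) {
  q <- model@qtls
  g <- character(nrow(q))
  for (i in seq_len(nrow(q))) g[i] <- originAt(genome, q$chrom[i], q$pos[i])
  g[q$fixed] <- "I"
  g
}

#' Assign a phenotype to one segregant
#'
#' phenotype = baseline + sum of active QTL contributions + Gaussian noise.
#' A QTL contributes |effect| when the segregant carries its beneficial
#' allele (superior-parent allele for positive effects, inferior-parent
#' allele for negative effects) and 0 otherwise; a QTL whose masking locus
#' carries the superior-parent allele contributes 0 regardless.
#'
#' @param genome a \code{SegregantGenome}
#' @param model a \code{PhenotypeModel}
#' @param seed optional seed (NULL = current RNG stream)
#' @return numeric phenotype value
#' @export
assignPhenotype <- function(genome, model, seed = NULL) {
  validObject(model)
  .maybeSeed(seed)
  q <- model@qtls
  value <- model@baseline
  if (nrow(q)) {
    g <- .qtlGenotype(genome, model)
    beneficial <- ifelse(q$effect >= 0, "S", "I")
    contrib <- abs(q$effect) * (g == beneficial)
    maskIdx <- match(q$maskedBy, q$id)
    masked <- !is.na(maskIdx) & g[ifelse(is.na(maskIdx), 1L, maskIdx)] == "S"
    contrib[masked] <- 0
    value <- value + sum(contrib)
  }
  value + rnorm(1L, 0, model@noiseSd)
}

#' Assign phenotypes to a cohort
#'
#' @param genomes list of \code{SegregantGenome}
#' @inheritParams assignPhenotype
#' @return numeric vector of phenotypes
#' @export
assignPhenotypes <- function(genomes, model, seed = NULL) {
  .maybeSeed(seed)
  vapply(genomes, assignPhenotype, numeric(1), model = model)
}

#' Select the extreme pool and draw the unselected pool
#'
#' Selection takes the top \code{poolSize} phenotypes (ties broken by a
#' seeded random draw) or, in threshold mode, every segregant at or above
#' the threshold.  The unselected pool ("pool 0") is a simple random sample
#' of \code{poolSize} segregants, emulating a sequenced unselected pool.
#'
#' @param phenotypes numeric vector of phenotypes
#' @param config a \code{CrossConfig}
#' @param seed optional seed (NULL = current RNG stream)
#' @return list(selected = integer ids, unselected = integer ids)
#' @export
selectAndPool <- function(phenotypes, config, seed = NULL) {
  validObject(config)
  n <- length(phenotypes)
  if (config@poolSize > n)
    stop("poolSize (", config@poolSize, ") exceeds the number of segregants (", n, ")")
  .maybeSeed(seed)
  tie <- sample.int(n)
  ord <- order(-phenotypes, tie)
  sel <- config@selection
  if (identical(sel$type, "threshold")) {
    selected <- which(phenotypes >= sel$value)
    if (length(selected) < config@poolSize)
      stop("threshold ", sel$value, " leaves only ", length(selected),
           " segregants; ", config@poolSize - length(selected),
           " short of the pool size ", config@poolSize)
  } else {
    selected <- ord[seq_len(config@poolSize)]
  }
  unselected <- sample(n, config@poolSize)
  list(selected = sort(selected), unselected = sort(unselected))
}

#' Sequence a pool of segregants
#'
#' Per marker, total coverage is Poisson(meanCoverage); each read reports
#' the superior-parent allele with probability f(1-e) + (1-f)e, where f is
#' the pool's true superior-allele frequency and e the per-read error.
#'
#' @param genotypes character matrix (members x markers) of "S"/"I" calls,
#'   as from \code{\link{segregantGenotypes}}, or a list of
#'   \code{SegregantGenome} (then \code{layout} is required).
#' @param config a \code{CrossConfig}
#' @param layout needed when \code{genotypes} is a list of genomes
#' @param seed optional seed (NULL = current RNG stream)
#' @return data.frame(chrom, pos, variantCount, totalCount)
#' @export
sequencePool <- function(genotypes, config, layout = NULL, seed = NULL) {
  if (is.list(genotypes)) {
    if (is.null(layout)) stop("layout required to genotype the pool members")
    genotypes <- segregantGenotypes(genotypes, layout)
  }
  if (nrow(genotypes) < 1L) stop("cannot sequence an empty pool")
  .maybeSeed(seed)
  f <- colMeans(genotypes == "S")
  m <- length(f)
  tot <- rpois(m, config@meanCoverage)
  pread <- f * (1 - config@seqError) + (1 - f) * config@seqError
  v <- rbinom(m, tot, pread)
  cp <- .splitIds(colnames(genotypes))
  data.frame(chrom = cp$chrom, pos = cp$pos,
             variantCount = v, totalCount = tot, stringsAsFactors = FALSE)
}

#' Sequence the superior parent
#'
#' The superior parent is homozygous for the variant allele at every
#' marker, so its counts only reflect coverage and sequencing error.
#'
#' @inheritParams sequencePool
#' @param layout a \code{GenomeLayout}
#' @return data.frame(chrom, pos, variantCount, totalCount)
#' @export
sequenceParent <- function(layout, config, seed = NULL) {
  .maybeSeed(seed)
  mk <- markers(layout)
  m <- length(mk)
  tot <- rpois(m, config@meanCoverage)
  v <- rbinom(m, tot, 1 - config@seqError)
  data.frame(chrom = as.character(seqnames(mk)), pos = start(mk),
             variantCount = v, totalCount = tot, stringsAsFactors = FALSE)
}

#' Downgrade QTLs in a phenotype model
#'
#' Emulates replacement of a superior allele in the parent strain: the named
#' QTLs behave as if every segregant carried the inferior-parent allele, so
#' their effects no longer segregate.  Marker inheritance is untouched --
#' flanking markers still segregate 1:1, which is why a fully downgraded
#' QTL shows no linkage in a second mapping round.
#'
#' @param model a \code{PhenotypeModel}
#' @param ids character ids of QTLs to neutralise
#' @return the downgraded \code{PhenotypeModel}
#' @export
downgradeModel <- function(model, ids) {
  unknown <- setdiff(ids, model@qtls$id)
  if (length(unknown))
    stop("unknown QTL id(s): ", paste(unknown, collapse = ", "))
  model@qtls$fixed[model@qtls$id %in% ids] <- TRUE
  validObject(model)
  model
}

#' Simulate a full mapping experiment
#'
#' Runs meiosis for all segregants, assigns phenotypes, selects the extreme
#' pool, draws the unselected pool, and sequences the parent and both pools.
#'
#' @param layout a \code{GenomeLayout}
#' @param model a \code{PhenotypeModel}
#' @param config a \code{CrossConfig}
#' @param seed integer seed for the whole experiment
#' @return list with elements \code{phenotypes}, \code{selected},
#'   \code{unselected} (indices), \code{counts} (a
#'   \code{\link{PoolCountsExperiment}} with columns parent / selected /
#'   unselected), \code{genotypesSelected} and \code{genotypesUnselected}
#'   (character matrices).
#' @export
simulateCross <- function(layout, model, config, seed = 1L) {
  validObject(layout); validObject(model); validObject(config)
  q <- model@qtls
  if (nrow(q)) {
    for (i in seq_len(nrow(q))) {
      rec <- .chromRec(layout, q$chrom[i])
      if (q$pos[i] < 1 || q$pos[i] > rec$lengthBp)
        stop("QTL ", q$id[i], " lies off chromosome ", q$chrom[i])
    }
  }
  set.seed(seed)
  genomes <- simulateSegregants(layout, config@nSegregants)
  phen <- assignPhenotypes(genomes, model)
  pools <- selectAndPool(phen, config)
  gSel <- segregantGenotypes(genomes[pools$selected], layout)
  gUns <- segregantGenotypes(genomes[pools$unselected], layout)
  parent <- sequenceParent(layout, config)
  selCnt <- sequencePool(gSel, config)
  unsCnt <- sequencePool(gUns, config)
  counts <- PoolCountsExperiment(
    markers = markers(layout),
    variantCount = cbind(parent = parent$variantCount,
                         selected = selCnt$variantCount,
                         unselected = unsCnt$variantCount),
    totalCount = cbind(parent = parent$totalCount,
                       selected = selCnt$totalCount,
                       unselected = unsCnt$totalCount),
    role = c("parent", "selected", "unselected"),
    nSegregants = c(Inf, config@poolSize, config@poolSize))
  list(phenotypes = phen, selected = pools$selected,
       unselected = pools$unselected, counts = counts,
       genotypesSelected = gSel, genotypesUnselected = gUns)
}
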