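## shared in-code fixtures

suppressPackageStartupMessages(library(SummarizedExperiment))

## one chromosome, evenly spaced markers
oneChromLayout <- function(lengthBp = 3e5, morgans = 1.2, nMarkers = 300L,
                           name = "c1") {
  pos <- as.integer(round(seq(1000, lengthBp - 1000, length.out = nMarkers)))
  GenomeLayout(data.frame(name = name, lengthBp = lengthBp,
                          geneticLengthM = morgans),
               stats::setNames(list(pos), name))
}

## several chromosomes with identical marker spacing
multiChromLayout <- function(nChrom = 4L, lengthBp = 150000L, morgans = 0.6,
                             nMarkers = 150L) {
  nm <- paste0("c", seq_len(nChrom))
  pos <- as.integer(round(seq(1000, lengthBp - 1000, length.out = nMarkers)))
  GenomeLayout(data.frame(name = nm, lengthBp = lengthBp,
                          geneticLengthM = morgans),
               stats::setNames(rep(list(pos), nChrom), nm))
}

## a segregant genome built by hand: no crossovers, given origin per chrom
flatGenome <- function(origins) {
  new("SegregantGenome",
      blocks = lapply(origins, function(o) list(breaks = numeric(), first = o)))
}

## fit both pools of a simulated null contrast on one chromosome
nullContrastFits <- function(layout = oneChromLayout(), nSeg = 58L,
                             coverage = 100, seqError = 0.002) {
  cfg <- CrossConfig(nSeg, nSeg, meanCoverage = coverage, seqError = seqError)
  mpb <- chromInfo(layout)$geneticLengthM[1] / chromInfo(layout)$lengthBp[1]
  gq <- segregantGenotypes(simulateSegregants(layout, nSeg), layout)
  g0 <- segregantGenotypes(simulateSegregants(layout, nSeg), layout)
  cq <- sequencePool(gq, cfg)
  c0 <- sequencePool(g0, cfg)
  ch <- chromInfo(layout)$name[1]
  list(
    q = fitPoolChromosome(cq$pos, cq$variantCount, cq$totalCount,
                          pool = "q", chrom = ch, nSegregants = nSeg,
                          morgansPerBp = mpb),
    p0 = fitPoolChromosome(c0$pos, c0$variantCount, c0$totalCount,
                           pool = "p0", chrom = ch, nSegregants = nSeg,
                           morgansPerBp = mpb))
}

## constant-frequency fit: every marker shows v/n = p exactly
constantFit <- function(p, n = 100L, nMarkers = 60L, lengthBp = 1.2e5,
                        pool = "pool", chrom = "c1", k = 10L, ...) {
  pos <- as.integer(round(seq(1000, lengthBp, length.out = nMarkers)))
  fitPoolChromosome(pos, rep(round(n * p), nMarkers), rep(n, nMarkers),
                    pool = pool, chrom = chrom, k = k, ...)
}

## hand-built ContrastProfile for call-logic tests
madeProfile <- function(grid, contrast, pAdj, chrom = "c1", pool = "q",
                        se = rep(0.1, length(grid))) {
  zStar <- 3
  new("ContrastProfile", pool = pool, baseline = "p0", chrom = chrom,
      grid = as.numeric(grid), contrast = contrast, se = se, seNull = se,
      lo = contrast - zStar * se, hi = contrast + zStar * se, pAdj = pAdj,
      zStar = zStar, delta = 0.4088, alpha = 0.05, nSims = 1000L,
      supDraws = numeric(1000), supDrawsNull = numeric(1000))
}
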