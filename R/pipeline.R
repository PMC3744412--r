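## End-to-end pipeline: simulate a two-round mapping study, map pools, score
## segregants.  The default scenario emulates the shape of a two-parent
## yeast cross study: 16 chromosomes, ~2,000 markers, two major and two
## minor QTLs (one linked to the inferior parent, one epistatically masked),
## a first cross of 950 segregants and a second, downgraded-parent cross of
## 2,464 segregants, 58-segregant pools, ~100x pooled coverage.

#' Default simulation scenario
#'
#' A flat list of scenario settings (serialisable with
#' \code{\link{writeScenario}}).  The genome is a stylised 16-chromosome
#' layout (300 kb and 1.2 Morgans per chromosome, 125 evenly spaced markers
#' each, i.e. 0.4 cM/kb, a yeast-like recombination rate).  QTLs:
#' \describe{
#'   \item{qtl1}{major, superior-linked (chrXIV), also the epistatic
#'     masking locus of qtl5}
#'   \item{qtl2}{minor, superior-linked (chrII)}
#'   \item{qtl3}{inferior-linked (chrIV): the beneficial allele comes from
#'     the inferior parent}
#'   \item{qtl5}{masked by qtl1's superior allele (chrXII); invisible in
#'     the first cross, detectable after downgrading qtl1}
#' }
#' The second cross downgrades qtl1 and qtl3 (one per parent).
#'
#' @return named list of scenario settings
#' @export
defaultScenario <- function() {
  list(
    nChromosomes = 16L,
    chromLengthBp = 300000L,
    markersPerChrom = 125L,
    morgansPerChrom = 1.2,
    qtlId = c("qtl1", "qtl2", "qtl3", "qtl5"),
    qtlChrom = c("chrXIV", "chrII", "chrIV", "chrXII"),
    qtlPos = c(150000L, 150000L, 150000L, 150000L),
    qtlEffect = c(2.0, 0.35, -1.2, 0.8),
    qtlMaskedBy = c(NA, NA, NA, "qtl1"),
    baseline = 0,
    noiseSd = 0.3,
    nSegregants1 = 950L,
    nSegregants2 = 2464L,
    poolSize = 58L,
    downgrade = c("qtl1", "qtl3"),
    meanCoverage = 100,
    seqError = 0.002,
    minCoverage = 20L,
    minRatio = 0.80,
    knots = 20L,
    gridBp = 1000L,
    delta = 0.4088,
    alpha = 0.05,
    nSims = 10000L)
}

#' Read / write a scenario file (flat key-value YAML)
#'
#' @param path scenario file
#' @export
readScenario <- function(path) {
  sc <- yaml::read_yaml(path)
  miss <- setdiff(names(defaultScenario()), names(sc))
  if (length(miss))
    stop("scenario file is missing key(s): ", paste(miss, collapse = ", "))
  sc
}

#' @rdname readScenario
#' @param scenario scenario list
#' @export
writeScenario <- function(scenario, path) {
  yaml::write_yaml(scenario, path)
  invisible(path)
}

.romanChroms <- function(n)
  paste0("chr", as.character(utils::as.roman(seq_len(n))))

#' Build the GenomeLayout and PhenotypeModel of a scenario
#'
#' @param scenario scenario list (see \code{\link{defaultScenario}})
#' @return list(layout, model)
#' @export
scenarioGenome <- function(scenario) {
  nm <- .romanChroms(scenario$nChromosomes)
  len <- scenario$chromLengthBp
  step <- len / (scenario$markersPerChrom + 1L)
  pos <- as.integer(round(step * seq_len(scenario$markersPerChrom)))
  layout <- GenomeLayout(
    data.frame(name = nm, lengthBp = len,
               geneticLengthM = scenario$morgansPerChrom),
    stats::setNames(rep(list(pos), length(nm)), nm))
  model <- PhenotypeModel(
    data.frame(id = scenario$qtlId, chrom = scenario$qtlChrom,
               pos = scenario$qtlPos, effect = scenario$qtlEffect,
               maskedBy = scenario$qtlMaskedBy, stringsAsFactors = FALSE),
    baseline = scenario$baseline, noiseSd = scenario$noiseSd)
  bad <- setdiff(model@qtls$chrom, nm)
  if (length(bad))
    stop("scenario places QTLs on unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  list(layout = layout, model = model)
}

#' Simulate the two-round mapping study of a scenario
#'
#' Round 1 crosses the original parents (pool 1 = selected extreme pool).
#' Round 2 crosses the downgraded parents (the scenario's \code{downgrade}
#' QTLs are neutralised) and contributes pool 2 (selected) and pool 0 (the
#' unselected baseline pool).  Writes count TSVs for parent and pools,
#' genotype matrices of both selected pools, and the scenario file.
#'
#' @param scenario scenario list (see \code{\link{defaultScenario}})
#' @param outDir output directory (created)
#' @param seed integer seed for the whole simulation
#' @return (invisibly) list with the \code{PoolCountsExperiment}, the two
#'   cross results, the layout/model and the written file paths
#' @export
runSimulate <- function(scenario = defaultScenario(), outDir, seed = 1L) {
  g <- scenarioGenome(scenario)      # validates before any file is written
  cfg1 <- CrossConfig(scenario$nSegregants1, scenario$poolSize,
                      meanCoverage = scenario$meanCoverage,
                      seqError = scenario$seqError)
  cfg2 <- CrossConfig(scenario$nSegregants2, scenario$poolSize,
                      meanCoverage = scenario$meanCoverage,
                      seqError = scenario$seqError)
  model2 <- downgradeModel(g$model, scenario$downgrade)
  cross1 <- simulateCross(g$layout, g$model, cfg1, seed = seed)
  cross2 <- simulateCross(g$layout, model2, cfg2, seed = seed + 1L)
  counts <- PoolCountsExperiment(
    markers = markers(g$layout),
    variantCount = cbind(
      parent = variantCounts(cross1$counts)[, "parent"],
      pool0 = variantCounts(cross2$counts)[, "unselected"],
      pool1 = variantCounts(cross1$counts)[, "selected"],
      pool2 = variantCounts(cross2$counts)[, "selected"]),
    totalCount = cbind(
      parent = totalCounts(cross1$counts)[, "parent"],
      pool0 = totalCounts(cross2$counts)[, "unselected"],
      pool1 = totalCounts(cross1$counts)[, "selected"],
      pool2 = totalCounts(cross2$counts)[, "selected"]),
    role = c("parent", "unselected", "selected", "selected"),
    nSegregants = c(Inf, rep(scenario$poolSize, 3L)))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in colnames(counts)) {
    p <- file.path(outDir, paste0(s, ".tsv"))
    writePoolCounts(counts, s, p, seed = seed)
    paths[s] <- p
  }
  paths["geno_pool1"] <- writeGenotypeMatrix(
    cross1$genotypesSelected, file.path(outDir, "geno_pool1.tsv"), seed)
  paths["geno_pool2"] <- writeGenotypeMatrix(
    cross2$genotypesSelected, file.path(outDir, "geno_pool2.tsv"), seed)
  paths["scenario"] <- writeScenario(scenario, file.path(outDir, "scenario.yaml"))
  invisible(list(counts = counts, cross1 = cross1, cross2 = cross2,
                 layout = g$layout, model = g$model, model2 = model2,
                 paths = paths))
}

#' Map QTLs from pool counts
#'
#' The core mapping round: filter markers on the parent, fit the smoothed
#' variant-frequency curve of every pool per chromosome, contrast each
#' selected pool against the unselected pool with genome-wide Monte-Carlo
#' inference, and call QTL regions.
#'
#' @param counts a \code{\link{PoolCountsExperiment}} including a parent
#'   sample and an unselected pool
#' @param filter see \code{\link{FilterConfig}}
#' @param config an \code{\link{InferenceConfig}}
#' @param knots,gridBp smoothing settings (see \code{\link{makeSmoothBasis}})
#' @param morgansPerBp assumed recombination rate used for the
#'   segregant-sampling variance component
#' @param parent,baseline column names of the parent sample and the
#'   unselected pool
#' @param seed integer seed for the Monte-Carlo inference
#' @return a \code{\link{MappingReport}}
#' @export
mapCross <- function(counts, filter = FilterConfig(),
                     config = InferenceConfig(nSims = 1e4),
                     knots = 20L, gridBp = 1000,
                     morgansPerBp = 4e-6,
                     parent = "parent", baseline = "pool0",
                     seed = 1L) {
  if (!baseline %in% colnames(counts))
    stop("no unselected pool '", baseline, "': the contrast design needs ",
         "an unselected baseline pool to absorb systematic frequency waves")
  counts <- filterMarkers(counts, parent = parent, config = filter)
  gr <- rowRanges(counts)
  chroms <- unique(as.character(seqnames(gr)))
  poolCols <- setdiff(colnames(counts), parent)
  selCols <- setdiff(poolCols, baseline)
  nseg <- colData(counts)$nSegregants
  names(nseg) <- colnames(counts)
  fits <- list()
  for (pool in poolCols) {
    fits[[pool]] <- list()
    for (ch in chroms) {
      i <- as.character(seqnames(gr)) == ch
      fits[[pool]][[ch]] <- fitPoolChromosome(
        start(gr)[i], assay(counts, "variantCount")[i, pool],
        assay(counts, "totalCount")[i, pool],
        pool = pool, chrom = ch, k = knots, gridBp = gridBp,
        nSegregants = nseg[[pool]], morgansPerBp = morgansPerBp)
    }
  }
  set.seed(seed)
  cfg <- config
  cfg@seed <- NA_integer_
  profiles <- list()
  for (pool in selCols)
    profiles[[pool]] <- contrastInference(fits[[pool]], fits[[baseline]], cfg)
  calls <- callQtls(unlist(profiles, recursive = FALSE), config)
  cfgList <- list(filter = filter, delta = config@delta,
                  alpha = config@alpha, nSims = config@nSims,
                  knots = knots, gridBp = gridBp,
                  morgansPerBp = morgansPerBp, seed = seed)
  new("MappingReport", fits = fits, profiles = profiles, calls = calls,
      provenance = list(seed = seed, config = cfgList,
                        configHash = .fnv1a(.configString(cfgList)),
                        version = as.character(packageVersion("pooledQTL"))))
}

setMethod("show", "MappingReport", function(object) {
  cat("MappingReport:", length(object@fits), "pool fit set(s),",
      length(object@profiles), "contrast(s),",
      length(object@calls), "QTL call(s)\n")
  cat("  seed", object@provenance$seed, " config", object@provenance$configHash,
      " version", object@provenance$version, "\n")
  if (length(object@calls)) {
    d <- as.data.frame(object@calls)
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %s:%d-%d  pool=%s  %s  minP=%.3g\n",
                  d$seqnames[i], d$start[i], d$end[i], d$pool[i],
                  d$direction[i], d$minP[i]))
  }
})

#' Run a full mapping round from files
#'
#' Reads count TSVs (as written by \code{\link{runSimulate}}), maps, and
#' writes per-pool frequency profiles, contrast profiles, QTL calls (BED
#' and a table-style TSV) and a log file.
#'
#' @param countFiles named character vector of count TSVs; must include a
#'   \code{parent} entry and a \code{pool0} (unselected) entry
#' @param outDir output directory
#' @param maskBed optional BED file of intervals excluded from calling
#' @param ... passed on to \code{\link{mapCross}}
#' @param seed Monte-Carlo seed
#' @return the \code{\link{MappingReport}} (invisibly)
#' @export
runMap <- function(countFiles, outDir, maskBed = NULL, seed = 1L, ...) {
  if (!"parent" %in% names(countFiles))
    stop("countFiles must include a 'parent' sample")
  if (!"pool0" %in% names(countFiles))
    stop("countFiles must include the unselected pool 'pool0': selected ",
         "pools are contrasted against it to absorb systematic waves")
  roles <- ifelse(names(countFiles) == "parent", "parent",
                  ifelse(names(countFiles) == "pool0", "unselected",
                         "selected"))
  counts <- readPoolCounts(countFiles, format = "tsv", role = roles)
  args <- list(...)
  if (!is.null(maskBed)) {
    mask <- rtracklayer::import(maskBed, format = "BED")
    cfg <- if (!is.null(args$config)) args$config else InferenceConfig(nSims = 1e4)
    cfg@mask <- GRanges(seqnames(mask), IRanges(start(mask), end(mask)))
    args$config <- cfg
  }
  report <- do.call(mapCross, c(list(counts = counts, seed = seed), args))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (pool in names(report@fits))
    for (ch in names(report@fits[[pool]]))
      writeFrequencyProfile(report@fits[[pool]][[ch]],
        file.path(outDir, sprintf("freq_%s_%s.tsv", pool, ch)))
  for (pool in names(report@profiles))
    for (ch in names(report@profiles[[pool]]))
      writeContrastProfile(report@profiles[[pool]][[ch]],
        file.path(outDir, sprintf("contrast_%s_%s.tsv", pool, ch)))
  writeQtlCalls(report@calls, file.path(outDir, "calls.tsv"),
                file.path(outDir, "calls.bed"))
  log <- c(sprintf("pooledQTL mapping run (%s)", format(Sys.time())),
           sprintf("seed=%d configHash=%s version=%s",
                   report@provenance$seed, report@provenance$configHash,
                   report@provenance$version),
           sprintf("pools: %s", paste(names(report@fits), collapse = ", ")),
           sprintf("calls: %d", length(report@calls)))
  writeLines(log, file.path(outDir, "run.log"))
  invisible(report)
}

#' Write QTL calls as a table TSV and as BED
#'
#' The TSV mirrors the publication-style per-QTL table (location as
#' "start-end on chromosome", direction of parental linkage, minimum
#' adjusted p, peak |contrast|); the BED uses 0-based half-open intervals.
#'
#' @param calls \code{GRanges} from \code{\link{callQtls}}
#' @param tsvPath,bedPath output paths (either may be NULL)
#' @export
writeQtlCalls <- function(calls, tsvPath = NULL, bedPath = NULL) {
  d <- as.data.frame(calls)
  if (!is.null(tsvPath)) {
    tab <- data.frame(
      qtl = if (nrow(d)) sprintf("QTL%d", seq_len(nrow(d))) else character(),
      location = if (nrow(d))
        sprintf("%d-%d on %s", d$start, d$end, d$seqnames) else character(),
      pool = d$pool, direction = d$direction, peak = d$peak,
      min_adj_p = d$minP, max_abs_contrast = d$maxAbsContrast)
    write.table(tab, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bedPath)) {
    if (length(calls)) {
      bed <- calls
      names(bed) <- sprintf("QTL%d_%s_%s", seq_along(bed),
                            mcols(bed)$pool, mcols(bed)$direction)
      mcols(bed) <- S4Vectors::DataFrame(name = names(bed),
                                         score = pmin(1000, round(-10 * log10(
                                           pmax(mcols(calls)$minP, 1e-100)))))
      rtracklayer::export(bed, bedPath, format = "BED")
    } else {
      file.create(bedPath)
    }
  }
  invisible(list(tsv = tsvPath, bed = bedPath))
}

#' Score a genotype matrix file and write the fine-mapping table
#'
#' @param genotypeFile TSV written by \code{\link{writeGenotypeMatrix}}
#' @param outDir output directory
#' @param snps optional SNP ids to score (default: all)
#' @return the score data.frame (invisibly)
#' @export
runScore <- function(genotypeFile, outDir, snps = NULL) {
  g <- readGenotypeMatrix(genotypeFile)
  if (!nrow(g) || !ncol(g)) stop("empty genotype matrix: ", genotypeFile)
  scores <- scoreRegion(g, snps = snps)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeScoreTable(scores, file.path(outDir, "scores.tsv"))
  invisible(scores)
}
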