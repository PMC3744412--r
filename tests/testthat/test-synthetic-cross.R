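test_that("crossover counts follow the genetic map", {
  gl <- oneChromLayout(lengthBp = 1e5, morgans = 1, nMarkers = 50L)
  set.seed(1)
  nxo <- vapply(seq_len(10000L), function(i) {
    g <- simulateMeiosis(gl)
    length(g@blocks$c1$breaks)
  }, numeric(1))
  expect_true(all(nxo >= 0 & nxo == round(nxo)))
  ## mean within 3 standard errors of the 1-Morgan rate
  expect_lt(abs(mean(nxo) - 1), 3 * sqrt(1 / 10000))
  ## zero genetic length: one parental block, no crossovers
  gl0 <- GenomeLayout(data.frame(name = "z", lengthBp = 1e5,
                                 geneticLengthM = 0),
                      list(z = c(1L, 50000L, 99999L)))
  g0 <- simulateMeiosis(gl0, seed = 2)
  expect_length(g0@blocks$z$breaks, 0)
  expect_length(unique(originAt(g0, "z", c(1, 50000, 99999))), 1L)
})

test_that("unselected segregants segregate 1:1 at markers", {
  gl <- oneChromLayout(nMarkers = 100L)
  set.seed(3)
  geno <- segregantGenotypes(simulateSegregants(gl, 2000L), gl)
  f <- mean(geno[, 50] == "S")
  expect_lt(abs(f - 0.5), 4 * sqrt(0.25 / 2000))
  ## marker-wise counts are Binomial(N, 1/2): >= 98% of markers inside the
  ## exact 99% interval, averaged over seeds
  insideFrac <- vapply(4:6, function(s) {
    set.seed(s)
    g <- segregantGenotypes(simulateSegregants(gl, 100L), gl)
    cnt <- colSums(g == "S")
    lo <- qbinom(0.005, 100, 0.5); hi <- qbinom(0.995, 100, 0.5)
    mean(cnt >= lo & cnt <= hi)
  }, numeric(1))
  expect_gte(mean(insideFrac), 0.98)
})

test_that("phenotypes are additive with allele-specific epistatic masking", {
  model <- PhenotypeModel(
    data.frame(id = c("a", "b"), chrom = c("cA", "cB"), pos = c(100, 100),
               effect = c(2, 1)), baseline = 5, noiseSd = 0)
  allS <- flatGenome(list(cA = "S", cB = "S"))
  expect_equal(assignPhenotype(allS, model), 5 + 3)
  ## mask: b contributes nothing when a carries the superior allele
  masked <- PhenotypeModel(
    data.frame(id = c("a", "b"), chrom = c("cA", "cB"), pos = c(100, 100),
               effect = c(2, 1), maskedBy = c(NA, "a")),
    baseline = 0, noiseSd = 0)
  SS <- flatGenome(list(cA = "S", cB = "S"))
  SI <- flatGenome(list(cA = "S", cB = "I"))
  IS <- flatGenome(list(cA = "I", cB = "S"))
  II <- flatGenome(list(cA = "I", cB = "I"))
  expect_equal(assignPhenotype(SS, masked) - assignPhenotype(SI, masked), 0)
  expect_equal(assignPhenotype(IS, masked) - assignPhenotype(II, masked), 1)
})

test_that("downgrading a locus fixes its allele and removes its effect", {
  gl <- oneChromLayout(nMarkers = 40L)
  model <- PhenotypeModel(
    data.frame(id = "q", chrom = "c1", pos = 150000, effect = 2),
    baseline = 0, noiseSd = 0)
  set.seed(7)
  genomes <- simulateSegregants(gl, 400L)
  ph <- assignPhenotypes(genomes, model)
  phDg <- assignPhenotypes(genomes, downgradeModel(model, "q"))
  ## random segregants carry the superior allele half the time
  expect_lt(abs((mean(ph) - mean(phDg)) - 2 * 0.5), 0.2)
  expect_true(all(phDg == 0))
  expect_error(downgradeModel(model, "nope"), "unknown QTL id")
})

test_that("selection picks the phenotypic extreme and pools are sized", {
  cfg <- CrossConfig(100L, 58L)
  sel <- selectAndPool(1:100, cfg, seed = 1)
  expect_equal(min((1:100)[sel$selected]), 43)
  expect_length(sel$unselected, 58L)
  ## pool == cohort: everyone selected
  cfgAll <- CrossConfig(10L, 10L)
  expect_setequal(selectAndPool(rnorm(10), cfgAll, seed = 1)$selected, 1:10)
  ## threshold shortfall names the gap
  cfgT <- CrossConfig(100L, 58L, selection = list(type = "threshold", value = 90))
  expect_error(selectAndPool(1:100, cfgT, seed = 1), "short of the pool size")
})

test_that("pool sequencing reflects pool composition and error rate", {
  gl <- oneChromLayout(nMarkers = 400L)
  allS <- segregantGenotypes(lapply(1:5, function(i) flatGenome(list(c1 = "S"))), gl)
  cfg0 <- CrossConfig(5L, 5L, meanCoverage = 80, seqError = 0)
  cnt0 <- sequencePool(allS, cfg0, seed = 11)
  expect_true(all(cnt0$variantCount == cnt0$totalCount))
  cfgE <- CrossConfig(5L, 5L, meanCoverage = 80, seqError = 0.1)
  cntE <- sequencePool(allS, cfgE, seed = 12)
  fr <- sum(cntE$variantCount) / sum(cntE$totalCount)
  expect_lt(abs(fr - 0.9), 0.01)
  expect_error(sequencePool(allS[0, , drop = FALSE], cfg0), "empty pool")
})

test_that("strong selection drives the QTL allele frequency towards fixation", {
  gl <- oneChromLayout(nMarkers = 101L)
  qpos <- markerPositions(gl, "c1")[51]    # QTL on a marker
  model <- PhenotypeModel(
    data.frame(id = "q", chrom = "c1", pos = qpos, effect = 5),
    baseline = 0, noiseSd = 0)
  for (s in 1:3) {
    cr <- simulateCross(gl, model, CrossConfig(200L, 40L, meanCoverage = 100,
                                               seqError = 0), seed = s)
    fSel <- colMeans(cr$genotypesSelected == "S")
    expect_equal(unname(fSel[51]), 1.0)            # zero noise: fixation
    expect_gt(fSel[51], max(fSel[c(1, 101)]))      # exceeds unlinked markers
  }
})

test_that("identical seeds reproduce identical simulations", {
  gl <- multiChromLayout(nChrom = 2L, nMarkers = 40L)
  model <- PhenotypeModel(
    data.frame(id = "q", chrom = "c1", pos = 75000, effect = 1),
    baseline = 0, noiseSd = 0.5)
  a <- simulateCross(gl, model, CrossConfig(50L, 10L), seed = 42)
  b <- simulateCross(gl, model, CrossConfig(50L, 10L), seed = 42)
  expect_identical(variantCounts(a$counts), variantCounts(b$counts))
  expect_identical(a$genotypesSelected, b$genotypesSelected)
  expect_identical(a$phenotypes, b$phenotypes)
})
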