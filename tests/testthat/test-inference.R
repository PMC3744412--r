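test_that("contrast is zero against itself, closed-form for constants, antisymmetric", {
  f6 <- constantFit(0.6, pool = "q")
  f5 <- constantFit(0.5, pool = "p0")
  self <- computeContrast(f6, f6)
  expect_equal(max(abs(self$contrast)), 0)
  cc <- computeContrast(f6, f5)
  expect_equal(unname(cc$contrast), rep(qlogis(0.6) - qlogis(0.5),
                                        length(cc$grid)), tolerance = 1e-4)
  expect_equal(cc$contrast, -computeContrast(f5, f6)$contrast)
  expect_true(all(cc$se > 0))
})

test_that("grid mismatch between fits is refused", {
  a <- constantFit(0.5, nMarkers = 60L)
  b <- constantFit(0.5, nMarkers = 50L)
  expect_error(computeContrast(a, b), "different grids")
  d <- constantFit(0.5, chrom = "c2")
  expect_error(computeContrast(a, d), "different chromosomes")
})

test_that("sup-t critical value reduces to the pointwise normal on one point", {
  f <- constantFit(0.5, pool = "q")
  g <- constantFit(0.5, pool = "p0")
  pr1 <- simultaneousBand(f, g, InferenceConfig(nSims = 2e4, seed = 1L),
                          positions = 60000)
  expect_lt(abs(pr1@zStar - qnorm(0.975)), 0.05)
  ## more grid points can only increase the critical value
  prAll <- simultaneousBand(f, g, InferenceConfig(nSims = 2e4, seed = 1L))
  expect_gte(prAll@zStar, pr1@zStar)
})

test_that("p-values are 1 inside the threshold and invert the null quantile", {
  f <- constantFit(0.55, pool = "q")
  g <- constantFit(0.5, pool = "p0")
  ## |contrast| ~ 0.2 < delta = 0.4088 everywhere
  pr <- adjustedPvalues(f, g, InferenceConfig(nSims = 5000, seed = 2L))
  expect_true(all(pr@pAdj == 1))
  ## a statistic at the null (1 - alpha) quantile has p ~ alpha
  zN <- quantile(pr@supDrawsNull, 0.95, names = FALSE)
  pAt <- mean(pr@supDrawsNull >= zN)
  expect_lt(abs(pAt - 0.05), 0.01)
})

test_that("a larger threshold never decreases a p-value", {
  set.seed(33)
  fits <- nullContrastFits(oneChromLayout(nMarkers = 120L))
  cfg1 <- InferenceConfig(delta = 0.4088, nSims = 4000, seed = 5L)
  cfg2 <- InferenceConfig(delta = 0.8, nSims = 4000, seed = 5L)
  p1 <- adjustedPvalues(fits$q, fits$p0, cfg1)
  p2 <- adjustedPvalues(fits$q, fits$p0, cfg2)
  expect_true(all(p2@pAdj >= p1@pAdj - 1e-12))
})

test_that("inference is invariant to relabelling variant and reference", {
  set.seed(34)
  layout <- oneChromLayout(nMarkers = 120L)
  cfg <- CrossConfig(40L, 40L, meanCoverage = 80, seqError = 0)
  mpb <- 1.2 / 3e5
  gq <- segregantGenotypes(simulateSegregants(layout, 40L), layout)
  g0 <- segregantGenotypes(simulateSegregants(layout, 40L), layout)
  cq <- sequencePool(gq, cfg); c0 <- sequencePool(g0, cfg)
  fit <- function(cnt, flip = FALSE) {
    v <- if (flip) cnt$totalCount - cnt$variantCount else cnt$variantCount
    fitPoolChromosome(cnt$pos, v, cnt$totalCount, chrom = "c1",
                      nSegregants = 40L, morgansPerBp = mpb)
  }
  icfg <- InferenceConfig(nSims = 4000, seed = 8L)
  p <- adjustedPvalues(fit(cq), fit(c0), icfg)
  pFlip <- adjustedPvalues(fit(cq, TRUE), fit(c0, TRUE), icfg)
  expect_equal(p@pAdj, pFlip@pAdj, tolerance = 1e-10)
  expect_equal(p@contrast, -pFlip@contrast, tolerance = 1e-8)
})

test_that("the same seed reproduces bands and p-values exactly", {
  set.seed(35)
  fits <- nullContrastFits(oneChromLayout(nMarkers = 120L))
  cfg <- InferenceConfig(nSims = 3000, seed = 77L)
  a <- adjustedPvalues(fits$q, fits$p0, cfg)
  b <- adjustedPvalues(fits$q, fits$p0, cfg)
  expect_identical(a@lo, b@lo)
  expect_identical(a@pAdj, b@pAdj)
})

test_that("QTL calling finds runs, merges over single gaps and respects masks", {
  grid <- seq(1000, 20000, by = 1000)
  cfg <- InferenceConfig(nSims = 1000)
  ## nothing significant
  pr <- madeProfile(grid, contrast = rep(1, 20), pAdj = rep(0.5, 20))
  expect_length(callQtls(pr, cfg), 0L)
  ## one positive run -> one superior call
  p <- rep(1, 20); p[5:8] <- 0.01
  pr <- madeProfile(grid, contrast = rep(1, 20), pAdj = p)
  calls <- callQtls(pr, cfg)
  expect_length(calls, 1L)
  expect_equal(mcols(calls)$direction, "superior")
  expect_equal(start(calls), 5000)
  expect_equal(end(calls), 8000)
  ## negative contrast -> inferior
  prNeg <- madeProfile(grid, contrast = rep(-1, 20), pAdj = p)
  expect_equal(mcols(callQtls(prNeg, cfg))$direction, "inferior")
  ## single-gap runs merge; two-point gaps do not
  p2 <- rep(1, 20); p2[c(5, 6, 8, 9)] <- 0.01
  expect_length(callQtls(madeProfile(grid, rep(1, 20), p2), cfg), 1L)
  p3 <- rep(1, 20); p3[c(5, 6, 9, 10)] <- 0.01
  expect_length(callQtls(madeProfile(grid, rep(1, 20), p3), cfg), 2L)
  ## opposite signs never merge
  ct <- rep(1, 20); ct[8:9] <- -1
  p4 <- rep(1, 20); p4[c(5:6, 8:9)] <- 0.01
  expect_length(callQtls(madeProfile(grid, ct, p4), cfg), 2L)
  ## masked intervals are removed before calling
  cfgMask <- InferenceConfig(nSims = 1000,
    mask = GRanges("c1", IRanges(4000, 9000)))
  expect_length(callQtls(madeProfile(grid, rep(1, 20), p), cfgMask), 0L)
  ## calls come back sorted by minimum p
  p5 <- rep(1, 20); p5[3:4] <- 0.04; p5[15:16] <- 0.001
  calls5 <- callQtls(madeProfile(grid, rep(1, 20), p5), cfg)
  expect_equal(start(calls5), c(15000, 3000))
})
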