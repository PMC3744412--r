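test_that("constant symmetric counts give a flat curve at 50%", {
  f <- constantFit(0.5)
  expect_lt(max(abs(f@eta)), 1e-3)
  expect_equal(unname(fittedFrequency(f)), rep(0.5, length(f@grid)),
               tolerance = 1e-3)
})

test_that("saturated counts stay finite and report near-certain frequency", {
  f <- constantFit(1, n = 100L)
  expect_true(all(fittedFrequency(f) >= 0.99))
  expect_true(all(is.finite(f@eta)))
})

test_that("the fit recovers a known smooth frequency step", {
  L <- 3e5
  pos <- round(seq(1000, L - 1000, length.out = 300))
  truth <- function(x) 0.5 + 0.4 * plogis((x - L / 2) / 15000)
  set.seed(21)
  n <- rep(200L, 300)
  v <- rbinom(300, n, truth(pos))
  f <- fitPoolChromosome(pos, v, n, chrom = "c1")
  expect_lt(max(abs(fittedFrequency(f) - truth(f@grid))), 0.05)
  ## independent oracle: windowed raw-frequency MLE agrees with the truth
  win <- vapply(pos, function(x) {
    i <- abs(pos - x) <= 15000
    sum(v[i]) / sum(n[i])
  }, numeric(1))
  expect_lt(max(abs(win - truth(pos))), 0.05)
  ## and the smooth tracks the windowed oracle
  expect_lt(max(abs(predictFit(f, pos)$eta - qlogis(win))), 0.5)
})

test_that("prediction is consistent with the stored grid and has positive SE", {
  f <- constantFit(0.3)
  pr <- predictFit(f, f@grid[c(3, 10)])
  expect_equal(pr$eta, f@eta[c(3, 10)])
  expect_true(all(predictFit(f, f@grid)$se > 0))
  expect_error(predictFit(f, max(f@grid) + 10), "outside the fitted range")
})

test_that("doubling counts preserves the curve and scales the SE by 1/sqrt(2)", {
  L <- 1e5
  pos <- round(seq(1000, L, length.out = 80))
  set.seed(5)
  n <- rep(60L, 80)
  v <- rbinom(80, n, 0.5 + 0.3 * sin(pos / L * pi))
  f1 <- fitPoolChromosome(pos, v, n, k = 10L, lambda = 1)
  f2 <- fitPoolChromosome(pos, 2L * v, 2L * n, k = 10L, lambda = 2)
  expect_equal(f1@eta, f2@eta, tolerance = 1e-6)
  expect_equal(f2@se / f1@se, rep(1 / sqrt(2), length(f1@se)),
               tolerance = 1e-6)
})

test_that("relabelling variant and reference flips the curve exactly", {
  pos <- round(seq(1000, 1e5, length.out = 80))
  set.seed(6)
  n <- rep(50L, 80)
  v <- rbinom(80, n, 0.6)
  f <- fitPoolChromosome(pos, v, n, k = 10L)
  g <- fitPoolChromosome(pos, n - v, n, k = 10L)
  expect_equal(f@eta, -g@eta, tolerance = 1e-6)
})

test_that("extreme smoothing collapses to the pooled frequency for flat data", {
  pos <- round(seq(1000, 1e5, length.out = 60))
  f <- fitPoolChromosome(pos, rep(3L, 60), rep(10L, 60), k = 10L,
                         lambda = 1e12)
  expect_lt(max(abs(f@eta - qlogis(0.3))), 1e-3)
})

test_that("markers without coverage have no influence on the fit", {
  pos <- round(seq(1000, 1e5, length.out = 80))
  set.seed(8)
  n <- rep(40L, 80)
  v <- rbinom(80, n, 0.55)
  f1 <- fitPoolChromosome(pos, v, n, k = 10L, lambda = 5)
  extraPos <- c(pos, 1500, 70500)
  f2 <- fitPoolChromosome(extraPos, c(v, 0L, 0L), c(n, 0L, 0L), k = 10L,
                          lambda = 5)
  expect_equal(predictFit(f2, f1@grid)$eta, f1@eta, tolerance = 1e-8)
})

test_that("the penalised fit agrees with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  L <- 2e5
  pos <- round(seq(1000, L, length.out = 200))
  set.seed(31)
  n <- rpois(200, 120)
  v <- rbinom(200, n, 0.5 + 0.25 * sin(2 * pi * pos / L))
  f <- fitPoolChromosome(pos, v, n, chrom = "c1")
  g <- mgcv::gam(cbind(v, n - v) ~ s(pos, k = 24, bs = "ps"),
                 family = stats::binomial())
  pg <- as.numeric(plogis(predict(g, newdata = data.frame(pos = f@grid))))
  expect_lt(max(abs(fittedFrequency(f) - pg)), 0.05)
})

test_that("too few markers for the requested knots is a clear error", {
  expect_error(fitPoolChromosome(1:10 * 100, rep(1L, 10), rep(2L, 10)),
               "smaller k")
})
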