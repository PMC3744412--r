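writeCountTsv <- function(df, path, extra = character()) {
  writeLines(c("# seed=7", "# nSegregants=58",
               "chrom\tpos\tvariant_count\ttotal_count",
               sprintf("%s\t%d\t%d\t%d", df$chrom, df$pos, df$v, df$t),
               extra), path)
  path
}

test_that("count TSVs parse in order and carry their header metadata", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountTsv(data.frame(chrom = "c1", pos = c(100L, 200L, 300L),
                           v = c(5L, 6L, 7L), t = c(10L, 12L, 14L)), f)
  x <- readPoolCounts(c(poolA = f))
  expect_equal(nrow(x), 3L)
  expect_equal(unname(variantCounts(x)[, "poolA"]), c(5L, 6L, 7L))
  expect_equal(unname(colData(x)$nSegregants), 58)
  ## malformed row reports its line number
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeCountTsv(data.frame(chrom = "c1", pos = 100L, v = 5L, t = 10L), f2,
                extra = "c1\t200\tnope\t10")
  expect_error(readPoolCounts(c(p = f2)), "malformed line 5")
  ## variant > total rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeCountTsv(data.frame(chrom = "c1", pos = 100L, v = 11L, t = 10L), f3)
  expect_error(readPoolCounts(c(p = f3)), "variant_count <= total_count")
})

test_that("minimal VCF reading extracts allele depths and skips non-SNVs", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpoolA",
    "c1\t100\t.\tA\tT\t.\tPASS\t.\tAD\t12,30",
    "c1\t200\t.\tA\tT,G\t.\tPASS\t.\tAD\t5,5,5",   # multiallelic: skipped
    "c1\t300\t.\tA\tT\t.\tPASS\t.\tAD\t20,20",
    "c1\t400\t.\tAT\tA\t.\tPASS\t.\tAD\t9,9",      # indel: skipped
    "c1\t500\t.\tG\tC\t.\tPASS\t.\tAD\t0,40"), f)
  expect_message(x <- readPoolCounts(f, format = "vcf"), "skipped 2")
  expect_equal(nrow(x), 3L)
  expect_equal(unname(variantCounts(x)[1, 1]), 30L)
  expect_equal(unname(totalCounts(x)[1, 1]), 42L)
})

test_that("our VCF writer round-trips through the standard VCF reader", {
  gr <- GenomicRanges::GRanges(c("c1", "c1", "c2"),
                               IRanges::IRanges(c(10L, 20L, 30L), width = 1L))
  x <- PoolCountsExperiment(gr,
    variantCount = cbind(p1 = c(3L, 0L, 9L), p2 = c(1L, 2L, 3L)),
    totalCount = cbind(p1 = c(10L, 5L, 9L), p2 = c(4L, 4L, 4L)))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeVcfCounts(x, f, seed = 1)
  y <- readPoolCounts(f, format = "vcf")
  expect_equal(unname(variantCounts(y)), unname(variantCounts(x)))
  expect_equal(unname(totalCounts(y)), unname(totalCounts(x)))
})

test_that("marker filter applies inclusive coverage and ratio thresholds", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(seq_len(6) * 100L, width = 1L))
  cov <- c(10L, 20L, 25L, 40L, 50L, 60L)
  ratio <- c(0.9, 0.79, 0.8, 0.95, 0.5, 1.0)
  x <- PoolCountsExperiment(gr,
    variantCount = cbind(parent = as.integer(floor(cov * ratio)),
                         pool0 = rep(1L, 6)),
    totalCount = cbind(parent = cov, pool0 = rep(2L, 6)),
    role = c("parent", "unselected"), nSegregants = c(Inf, 58))
  y <- filterMarkers(x)
  expect_equal(nrow(y), 3L)                       # rows 3, 4, 6 survive
  expect_equal(start(rowRanges(y)), c(300L, 400L, 600L))
  ## boundary: exactly (20, 0.80) is kept, (19, 1.00) is not
  xb <- PoolCountsExperiment(GenomicRanges::GRanges("c1",
          IRanges::IRanges(c(100L, 200L), width = 1L)),
    variantCount = cbind(parent = c(16L, 19L)),
    totalCount = cbind(parent = c(20L, 19L)),
    role = "parent", nSegregants = Inf)
  yb <- filterMarkers(xb)
  expect_equal(start(rowRanges(yb)), 100L)
  ## idempotent
  expect_equal(nrow(filterMarkers(y)), nrow(y))
  ## retained count non-increasing in both thresholds
  n1 <- nrow(filterMarkers(x, config = FilterConfig(10L, 0.5)))
  n2 <- nrow(filterMarkers(x, config = FilterConfig(30L, 0.5)))
  n3 <- nrow(filterMarkers(x, config = FilterConfig(10L, 0.9)))
  expect_gte(n1, n2)
  expect_gte(n1, n3)
})

test_that("pool count TSVs round-trip through write and read", {
  gl <- oneChromLayout(nMarkers = 30L)
  cfg <- CrossConfig(20L, 10L)
  cr <- simulateCross(gl, PhenotypeModel(noiseSd = 1), cfg, seed = 9)
  d <- withr::local_tempdir()
  p <- file.path(d, "sel.tsv")
  writePoolCounts(cr$counts, "selected", p, seed = 9)
  y <- readPoolCounts(c(selected = p))
  expect_equal(unname(variantCounts(y)[, 1]),
               unname(variantCounts(cr$counts)[, "selected"]))
  expect_equal(start(rowRanges(y)), start(rowRanges(cr$counts)))
})

test_that("genotype matrices round-trip with missing calls", {
  g <- matrix(c("S", "I", NA, "S"), nrow = 2,
              dimnames = list(c("s1", "s2"), c("c1:100", "c1:200")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeMatrix(g, f, seed = 3)
  expect_identical(readGenotypeMatrix(f), g)
})
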