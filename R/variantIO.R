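## Reading and writing per-marker allele counts, and the marker quality filter.
##
## TSV dialect: optional '#'-prefixed comment lines (the writers emit
## '# seed=<seed>' and '# nSegregants=<N>'), then a header
## 'chrom  pos  variant_count  total_count' and one row per marker.

#' Marker quality filter settings
#'
#' Defaults follow common BSA-seq practice: a marker is a usable parental
#' SNP only if the superior parent's sequencing shows sufficient coverage
#' (>= 20 reads) and a sufficiently pure variant ratio (>= 80\%).  Both
#' comparisons are inclusive.
#'
#' @param minCoverage minimum parent read depth (reads, >= 1)
#' @param minRatio minimum parent variant-read fraction (0 < r <= 1)
#' @return a list used by \code{\link{filterMarkers}}
#' @export
FilterConfig <- function(minCoverage = 20L, minRatio = 0.80) {
  if (minCoverage < 1) stop("minCoverage must be >= 1")
  if (minRatio <= 0 || minRatio > 1) stop("minRatio must be in (0, 1]")
  list(minCoverage = minCoverage, minRatio = minRatio)
}

## parse one count TSV; returns data.frame plus attributes seed/nSegregants
.readCountsTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  isComment <- startsWith(lines, "#")
  meta <- lines[isComment]
  seed <- sub("^# *seed=", "", grep("^# *seed=", meta, value = TRUE))
  nseg <- sub("^# *nSegregants=", "",
              grep("^# *nSegregants=", meta, value = TRUE))
  body <- which(!isComment & nzchar(lines))
  if (!length(body)) stop("no data rows in ", path)
  hdr <- strsplit(lines[body[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("chrom", "pos", "variant_count", "total_count")
  if (!identical(hdr[seq_along(need)], need))
    stop("bad header in ", path, " (expected '",
         paste(need, collapse = "\t"), "')")
  rows <- body[-1L]
  out <- data.frame(chrom = character(length(rows)), pos = NA_integer_,
                    variantCount = NA_integer_, totalCount = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(rows)) {
    f <- strsplit(lines[rows[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L)
      stop("malformed line ", rows[k], " in ", path,
           ": expected 4 tab-separated fields")
    pos <- suppressWarnings(as.integer(f[2L]))
    v <- suppressWarnings(as.integer(f[3L]))
    t <- suppressWarnings(as.integer(f[4L]))
    if (is.na(pos) || is.na(v) || is.na(t) || pos < 1L || v < 0L || t < 0L || v > t)
      stop("malformed line ", rows[k], " in ", path,
           ": need pos >= 1 and 0 <= variant_count <= total_count")
    out$chrom[k] <- f[1L]; out$pos[k] <- pos
    out$variantCount[k] <- v; out$totalCount[k] <- t
  }
  attr(out, "seed") <- if (length(seed)) as.integer(seed[1L]) else NA_integer_
  attr(out, "nSegregants") <- if (length(nseg)) as.numeric(nseg[1L]) else Inf
  out
}

## read a (minimal) VCF with per-sample allele depths; biallelic SNVs only
.readCountsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(altL)
  alt1 <- rep(NA_character_, length(nAlt))
  alt1[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
  keep <- nAlt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L
  nSkipped <- sum(!keep)
  if (nSkipped)
    message("skipped ", nSkipped, " multiallelic/indel record(s)")
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD (allele depth) FORMAT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  samples <- colnames(vcf)
  m <- sum(keep)
  vC <- tC <- matrix(0L, m, length(samples),
                     dimnames = list(NULL, samples))
  idx <- which(keep)
  for (j in seq_along(samples)) {
    for (i in seq_along(idx)) {
      d <- ad[[idx[i], j]]
      if (is.null(d) || length(d) < 2L || anyNA(d))
        stop("missing allele depths for record ", names(vcf)[idx[i]],
             " sample ", samples[j])
      vC[i, j] <- d[2L]
      tC[i, j] <- d[1L] + d[2L]
    }
  }
  list(gr = GRanges(seqnames(rr), IRanges(start(rr), width = 1L)),
       variantCount = vC, totalCount = tC, nSkipped = nSkipped)
}

#' Read per-marker allele counts into a PoolCountsExperiment
#'
#' For \code{format = "tsv"}, \code{paths} is a named character vector
#' (sample name -> file); each file holds one sample in the package's count
#' TSV dialect.  Samples are merged on the union of (chrom, pos); a marker
#' absent from a sample gets (0, 0) counts and therefore no likelihood
#' weight.  For \code{format = "vcf"}, \code{paths} is a single VCF whose
#' per-sample AD field carries (reference, variant) depths; multiallelic
#' and indel records are skipped with a message.
#'
#' @param paths named file path(s)
#' @param format "tsv" or "vcf"
#' @param role,nSegregants optional per-sample annotations; for TSV input
#'   the default \code{nSegregants} comes from the files'
#'   '# nSegregants=' header (Inf when absent).
#' @return a \code{\link{PoolCountsExperiment}}
#' @export
readPoolCounts <- function(paths, format = c("tsv", "vcf"),
                           role = NULL, nSegregants = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    p <- .readCountsVcf(paths[[1L]])
    nm <- colnames(p$variantCount)
    out <- PoolCountsExperiment(p$gr, p$variantCount, p$totalCount,
      role = if (is.null(role)) rep("selected", length(nm)) else role,
      nSegregants = if (is.null(nSegregants)) rep(Inf, length(nm)) else nSegregants)
    metadata(out)$nSkipped <- p$nSkipped
    return(out)
  }
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("TSV paths must be named by sample")
  tabs <- lapply(paths, .readCountsTsv)
  key <- unique(do.call(rbind, lapply(tabs, function(d) d[c("chrom", "pos")])))
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  m <- nrow(key)
  kid <- paste0(key$chrom, ":", key$pos)
  vC <- tC <- matrix(0L, m, length(tabs),
                     dimnames = list(NULL, names(tabs)))
  for (j in seq_along(tabs)) {
    d <- tabs[[j]]
    i <- match(paste0(d$chrom, ":", d$pos), kid)
    vC[i, j] <- d$variantCount
    tC[i, j] <- d$totalCount
  }
  nseg <- vapply(tabs, attr, numeric(1), "nSegregants")
  if (!is.null(nSegregants)) nseg <- nSegregants
  PoolCountsExperiment(
    GRanges(key$chrom, IRanges(key$pos, width = 1L)), vC, tC,
    role = if (is.null(role)) rep("selected", length(tabs)) else role,
    nSegregants = nseg)
}

#' Apply the marker quality filter
#'
#' A marker is retained iff the parent sample shows
#' \code{totalCount >= minCoverage} and
#' \code{variantCount/totalCount >= minRatio} (both inclusive).  The filter
#' is applied to the parent only: the pools' frequencies are the quantity
#' under study and stay unconstrained.  Duplicated positions keep the first
#' record.  Idempotent by construction.
#'
#' @param x a \code{\link{PoolCountsExperiment}} containing a parent sample
#' @param parent column name of the parent sample
#' @param config see \code{\link{FilterConfig}}
#' @return the filtered \code{PoolCountsExperiment}; a \code{filterLog}
#'   entry in \code{metadata()} records input/kept/duplicate counts.
#' @export
filterMarkers <- function(x, parent = "parent", config = FilterConfig()) {
  if (!parent %in% colnames(x))
    stop("no parent sample '", parent, "' in the experiment")
  ids <- paste0(as.character(seqnames(rowRanges(x))), ":",
                start(rowRanges(x)))
  dup <- duplicated(ids)
  v <- assay(x, "variantCount")[, parent]
  t <- assay(x, "totalCount")[, parent]
  ratio <- ifelse(t > 0, v / t, 0)
  keep <- !dup & t >= config$minCoverage & ratio >= config$minRatio
  out <- x[keep, ]
  ord <- order(as.character(seqnames(rowRanges(out))), start(rowRanges(out)))
  out <- out[ord, ]
  metadata(out)$filterLog <- list(input = length(ids), kept = sum(keep),
                                  duplicates = sum(dup), config = config)
  if (!sum(keep)) message("marker filter removed every marker")
  out
}

#' Write one sample of a PoolCountsExperiment as a count TSV
#'
#' @param x a \code{\link{PoolCountsExperiment}}
#' @param sample column name to write
#' @param path output file
#' @param seed seed recorded in the header
#' @export
writePoolCounts <- function(x, sample, path, seed = NA_integer_) {
  gr <- rowRanges(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", seed), con)
  writeLines(sprintf("# nSegregants=%s", colData(x)[sample, "nSegregants"]), con)
  writeLines("chrom\tpos\tvariant_count\ttotal_count", con)
  writeLines(sprintf("%s\t%d\t%d\t%d", as.character(seqnames(gr)), start(gr),
                     assay(x, "variantCount")[, sample],
                     assay(x, "totalCount")[, sample]), con)
  invisible(path)
}

#' Write the marker frame with per-pool counts as one TSV
#'
#' Header: \code{#chrom pos} followed by \code{<sample>.variant} /
#' \code{<sample>.total} column pairs.
#'
#' @inheritParams writePoolCounts
#' @export
writeMarkerSet <- function(x, path, seed = NA_integer_) {
  gr <- rowRanges(x)
  v <- assay(x, "variantCount"); t <- assay(x, "totalCount")
  cols <- character(0)
  mat <- NULL
  for (s in colnames(x)) {
    cols <- c(cols, paste0(s, ".variant"), paste0(s, ".total"))
    mat <- cbind(mat, v[, s], t[, s])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", seed), con)
  writeLines(paste(c("#chrom", "pos", cols), collapse = "\t"), con)
  writeLines(paste(as.character(seqnames(gr)), start(gr),
                   apply(mat, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Write pool counts as a minimal VCF
#'
#' One sample per pool; the AD FORMAT field carries (reference, variant)
#' depths.  REF/ALT are placeholder bases (the counts, not the substituted
#' nucleotides, are the data of this analysis).
#'
#' @inheritParams writePoolCounts
#' @export
writeVcfCounts <- function(x, path, seed = NA_integer_) {
  gr <- rowRanges(x)
  v <- assay(x, "variantCount"); t <- assay(x, "totalCount")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=pooledQTL(seed=%s)", seed),
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x)), collapse = "\t")), con)
  ad <- sapply(colnames(x), function(s)
    sprintf("%d,%d", t[, s] - v[, s], v[, s]))
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = nrow(x))
  writeLines(paste(as.character(seqnames(gr)), start(gr), ".", "A", "T",
                   ".", "PASS", ".", "AD",
                   apply(ad, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Write / read a segregant genotype matrix
#'
#' TSV with rows = segregants, columns = markers named \code{chrom:pos},
#' calls "S" (superior-parent allele), "I" (inferior) or "." (missing).
#'
#' @param genotypes character matrix as from \code{\link{segregantGenotypes}}
#' @param path file path
#' @param seed seed recorded in the header
#' @export
writeGenotypeMatrix <- function(genotypes, path, seed = NA_integer_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", seed), con)
  writeLines(paste(c("segregant", colnames(genotypes)), collapse = "\t"), con)
  g <- genotypes
  g[is.na(g)] <- "."
  writeLines(paste(rownames(g), apply(g, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname writeGenotypeMatrix
#' @export
readGenotypeMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(hdr))
  if (length(bad))
    stop("malformed genotype row ", bad[1L] + 1L, " in ", path)
  g <- do.call(rbind, lapply(rows, `[`, -1L))
  rownames(g) <- vapply(rows, `[`, character(1), 1L)
  colnames(g) <- hdr[-1L]
  g[g == "."] <- NA_character_
  bad <- !is.na(g) & !g %in% c("S", "I")
  if (any(bad)) stop("invalid genotype call(s) in ", path,
                     " (expected S, I or .)")
  g
}
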