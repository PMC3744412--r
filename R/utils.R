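## small internal helpers

## split "chrom:pos" ids
.splitIds <- function(ids) {
  sp <- regmatches(ids, regexpr(":(?=[0-9]+$)", ids, perl = TRUE), invert = TRUE)
  bad <- which(lengths(sp) != 2L)
  if (length(bad))
    stop("malformed marker id (expected 'chrom:pos'): ", ids[bad[1L]])
  list(chrom = vapply(sp, `[`, character(1), 1L),
       pos = as.integer(vapply(sp, `[`, character(1), 2L)))
}

## polynomial rolling hash of a character scalar (provenance config hashes);
## double arithmetic keeps every intermediate below 2^53
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 4294967296
  format(as.hexmode(h %/% 65536), width = 4) |>
    paste0(format(as.hexmode(h %% 65536), width = 4))
}

## deterministic textual form of a (nested) config list
.configString <- function(x) {
  flat <- unlist(x)
  paste(names(flat), vapply(flat, format, character(1)), sep = "=", collapse = ";")
}
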