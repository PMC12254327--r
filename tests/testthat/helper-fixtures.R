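# Small in-code fixtures shared across the suite.

# A fixed tiny pool: collision-free by construction (checked once here).
tinyPool <- function() UMIPool(c("ACCGTCAG", "GGATCCTA", "TTGGCCAA",
                                 "CAGTACTG"))

# Fragments with minimal boilerplate.
makeFrags <- function(contig, start, end, stream, umi1, umi2,
                      flag1 = NULL, flag2 = NULL, ...) {
  if (is.null(flag1)) flag1 <- ifelse(stream == "GENET", 99L, 67L)
  if (is.null(flag2)) flag2 <- ifelse(stream == "GENET", 147L, 131L)
  MMFragments(contig, start, end, stream, umi1, umi2, flag1, flag2, ...)
}

# Methylation fragments with explicit per-CpG observations.
makeMethFrags <- function(start, end, pos, state, contig = "chr1",
                          umi1 = "ATTGTTAG", umi2 = "AAATTTAA", ...) {
  n <- length(start)
  MMFragments(rep(contig, n), start, end, rep("METH", n),
              rep_len(umi1, n), rep_len(umi2, n), rep(67L, n), rep(131L, n),
              methPos = IRanges::IntegerList(pos),
              methState = IRanges::LogicalList(state), ...)
}

# Independent brute-force two-sided Fisher p: enumerate all tables with the
# observed margins and sum hypergeometric probabilities no larger than the
# observed table's (with the conventional relative tolerance).
bruteFisherP <- function(tab) {
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  if (m + n == 0L) return(NA_real_)
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= d[support == x] * (1 + 1e-7)])
}

expect_fragments_equal <- function(a, b) {
  expect_equal(as.character(GenomicRanges::seqnames(a)),
               as.character(GenomicRanges::seqnames(b)))
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
  expect_equal(S4Vectors::mcols(a)$umi1, S4Vectors::mcols(b)$umi1)
  expect_equal(S4Vectors::mcols(a)$umi2, S4Vectors::mcols(b)$umi2)
}
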