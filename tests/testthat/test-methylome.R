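test_that("duplicate clustering follows the coordinate/UMI definitions", {
  # identical coords, UMIs differing at one base, QC preset -> duplicates
  fr <- makeFrags("chr1", c(100L, 100L), c(180L, 180L), c("GENET", "GENET"),
                  c("ACCGTCAG", "ACCGTCAT"), c("GGATCCTA", "GGATCCTA"))
  dd <- deduplicateFragments(fr, coordTolerance = 5L, umiAware = TRUE,
                             maxUmiMismatch = 1L)
  expect_equal(length(dd$unique), 1L)
  # two mismatches -> distinct molecules
  fr2 <- makeFrags("chr1", c(100L, 100L), c(180L, 180L), c("GENET", "GENET"),
                   c("ACCGTCAG", "ACCGTCTT"), c("GGATCCTA", "GGATCCTA"))
  dd2 <- deduplicateFragments(fr2, coordTolerance = 5L, umiAware = TRUE)
  expect_equal(length(dd2$unique), 2L)
  # coordinates differing by 6 bp exceed the 5 bp tolerance
  fr3 <- makeFrags("chr1", c(100L, 106L), c(180L, 186L), c("GENET", "GENET"),
                   c("ACCGTCAG", "ACCGTCAG"), c("GGATCCTA", "GGATCCTA"))
  expect_equal(length(deduplicateFragments(fr3, coordTolerance = 5L,
                                           umiAware = TRUE)$unique), 2L)
  # within 5 bp -> duplicates
  fr4 <- makeFrags("chr1", c(100L, 105L), c(180L, 185L), c("GENET", "GENET"),
                   c("ACCGTCAG", "ACCGTCAG"), c("GGATCCTA", "GGATCCTA"))
  expect_equal(length(deduplicateFragments(fr4, coordTolerance = 5L,
                                           umiAware = TRUE)$unique), 1L)
  # n identical fragments -> duplicate rate (n-1)/n
  n <- 7L
  fr5 <- makeFrags("chr1", rep(100L, n), rep(180L, n), rep("METH", n),
                   rep("ATTGTTAG", n), rep("AAATCCTA", n))
  expect_equal(deduplicateFragments(fr5)$duplicateRate, (n - 1) / n)
  expect_error(deduplicateFragments(
    makeFrags("chr1", c(200L, 100L), c(280L, 180L), c("METH", "METH"),
              "A", "B")), "sorted")
})

test_that("duplicates never merge across duplex strand classes", {
  # same coords but Watson-original vs Crick-original methylation strands
  fr <- MMFragments(rep("chr1", 2), c(100L, 100L), c(180L, 180L),
                    rep("METH", 2), c("ATTGTTAG", "TTGGTTAA"),
                    c("AAATCCTA", "CAATACTA"), c(67L, 115L), c(131L, 179L))
  expect_equal(length(deduplicateFragments(fr)$unique), 2L)
})

test_that("deduplication is deterministic for sorted input", {
  set.seed(31)
  n <- 60L
  st <- sort(sample(100:130, n, replace = TRUE))
  fr <- makeFrags("chr1", st, st + 80L, rep("GENET", n),
                  sample(c("ACCGTCAG", "ACCGTCAT", "TTGGCCAA"), n, TRUE),
                  rep("GGATCCTA", n))
  a <- deduplicateFragments(fr, coordTolerance = 5L, umiAware = TRUE)
  b <- deduplicateFragments(fr, coordTolerance = 5L, umiAware = TRUE)
  expect_identical(a$clusters, b$clusters)
  # representatives are the first member of each cluster in sort order
  expect_true(all(diff(which(!duplicated(a$clusters))) > 0))
})

test_that("methylation calling aggregates counts, betas and contexts", {
  #            1234567890123
  ref <- Biostrings::DNAStringSet(c(chr1 = "TACGTCAGGCTAA"))
  # Watson C of the CpG at 3; Crick partner G at 4; CHG C at 6 (C-A-G);
  # G at 9 is CHG on the minus strand (C at 7: G-G-C read on minus)
  frW <- makeMethFrags(rep(1L, 10), rep(13L, 10),
                       pos = rep(list(c(3L, 6L)), 10),
                       state = c(rep(list(c(TRUE, FALSE)), 3),
                                 rep(list(c(FALSE, FALSE)), 7)))
  calls <- callMethylation(frW, ref)
  cpg <- calls[calls$context == "CpG"]
  expect_equal(GenomicRanges::start(cpg), 3L)
  expect_equal(cpg$nMeth, 3L)
  expect_equal(cpg$nUnmeth, 7L)
  expect_equal(cpg$beta, 0.3)
  chg <- calls[calls$context == "CHG"]
  expect_equal(GenomicRanges::start(chg), 6L)
  expect_equal(chg$beta, 0)

  # fully methylated site
  fr1 <- makeMethFrags(rep(1L, 10), rep(13L, 10), rep(list(3L), 10),
                       rep(list(TRUE), 10))
  expect_equal(callMethylation(fr1, ref)$beta, 1.0)

  # dyad merge: minus-strand observation at the G (pos 4) lands on site 3
  frC <- MMFragments("chr1", 1L, 13L, "METH", "TTGGTTAA", "CAATACTA",
                     115L, 179L, methPos = IRanges::IntegerList(4L),
                     methState = IRanges::LogicalList(TRUE))
  both <- callMethylation(c(frW[1], frC), ref)
  cpg <- both[both$context == "CpG"]
  expect_equal(GenomicRanges::start(cpg), 3L)  # keyed at the plus-strand C
  expect_equal(cpg$nMeth, 2L)                  # one call from each strand
  expect_equal(cpg$nUnmeth, 0L)

  expect_error(callMethylation(frW, Biostrings::DNAStringSet(c(x = "AAA"))),
               "not in reference")
})

test_that("per-site counts conserve the deduplicated covering fragments", {
  cfg <- SimConfig(contigLengths = c(chr1 = 8000), nMolecules = 800,
                   pcrDuplicateRate = 0.2, seed = 32)
  sim <- simulateLibrary(cfg, emitReads = FALSE)
  meth <- sort(sim$fragments[S4Vectors::mcols(sim$fragments)$stream ==
                               "METH"])
  dd <- deduplicateFragments(meth)
  calls <- callMethylation(dd$unique, sim$reference)
  mc <- S4Vectors::mcols(dd$unique)
  expect_equal(sum(calls$nMeth) + sum(calls$nUnmeth),
               sum(lengths(mc$methPos)))
})

test_that("called betas track simulated truth", {
  cfg <- SimConfig(contigLengths = c(chr1 = 30000), nMolecules = 6000,
                   seed = 33)
  sim <- simulateLibrary(cfg, emitReads = FALSE)
  meth <- sort(sim$fragments[S4Vectors::mcols(sim$fragments)$stream ==
                               "METH"])
  calls <- callMethylation(deduplicateFragments(meth)$unique, sim$reference)
  cg <- calls[calls$context == "CpG"]
  m <- match(GenomicRanges::start(cg), GenomicRanges::start(sim$cpgTruth))
  cov <- cg$nMeth + cg$nUnmeth
  keep <- !is.na(m) & cov >= 5
  expect_gt(cor(cg$beta[keep], sim$cpgTruth$truthBeta[m[keep]]), 0.95)
})

test_that("conversion QC is exact in the noise-free limit", {
  cfg <- SimConfig(contigLengths = c(lambda = 4000, puc19 = 4000),
                   methLevel = c(lambda = 0, puc19 = 1),
                   conversionSensitivity = 1, conversionSpecificity = 1,
                   analogResistance = 1, strandSurvival = 1,
                   pcrDuplicateRate = 0, nMolecules = 400, seed = 34)
  sim <- simulateLibrary(cfg, emitReads = FALSE)
  fr <- sim$fragments
  meth <- sort(fr[S4Vectors::mcols(fr)$stream == "METH"])
  calls <- callMethylation(deduplicateFragments(meth)$unique, sim$reference)
  qc <- conversionQC(calls, "lambda", "puc19",
                     genetFrags = fr[S4Vectors::mcols(fr)$stream == "GENET"],
                     reference = sim$reference)
  expect_equal(qc$sensitivity, 1.0)
  expect_equal(qc$specificity, 1.0)
  expect_equal(qc$ctga_substitution_rate, 0.0)
})

test_that("conversion QC estimates the chemistry parameters consistently", {
  for (pars in list(c(0.999, 0.97), c(0.98, 0.99), c(0.95, 0.9))) {
    cfg <- SimConfig(contigLengths = c(lambda = 3000, puc19 = 3000),
                     methLevel = c(lambda = 0, puc19 = 1),
                     conversionSensitivity = pars[1],
                     conversionSpecificity = pars[2],
                     strandSurvival = 1, pcrDuplicateRate = 0,
                     nMolecules = 1500, seed = 35)
    sim <- simulateLibrary(cfg, emitReads = FALSE)
    meth <- sort(sim$fragments[S4Vectors::mcols(sim$fragments)$stream ==
                                 "METH"])
    calls <- callMethylation(deduplicateFragments(meth)$unique,
                             sim$reference)
    qc <- conversionQC(calls, "lambda", "puc19")
    lam <- calls[as.character(GenomicRanges::seqnames(calls)) == "lambda"]
    nLam <- sum(lam$nMeth) + sum(lam$nUnmeth)
    puc <- calls[as.character(GenomicRanges::seqnames(calls)) == "puc19" &
                   calls$context == "CpG"]
    nPuc <- sum(puc$nMeth) + sum(puc$nUnmeth)
    expect_lt(abs(qc$sensitivity - pars[1]),
              2.576 * sqrt(pars[1] * (1 - pars[1]) / nLam) + 1e-6)
    expect_lt(abs(qc$specificity - pars[2]),
              2.576 * sqrt(pars[2] * (1 - pars[2]) / nPuc) + 1e-6)
  }
})

test_that("flagged-undefined QC when spike-ins are uncovered", {
  calls <- GRanges <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 1),
                                             nMeth = 1L, nUnmeth = 0L,
                                             beta = 1, context = "CpG")
  qc <- conversionQC(calls, "lambda", "puc19")
  expect_true(is.na(qc$sensitivity))
  expect_true(is.na(qc$specificity))
})

test_that("dilution series recovery correlates with configured levels", {
  levels <- c(d5 = 0.05, d2 = 0.02, d1 = 0.01, d05 = 0.005, d02 = 0.002,
              d0 = 0)
  cfg <- SimConfig(contigLengths = setNames(rep(2000L, 6), names(levels)),
                   methLevel = levels, nMolecules = 3000,
                   strandSurvival = 1, pcrDuplicateRate = 0, seed = 36)
  sim <- simulateLibrary(cfg, emitReads = FALSE)
  meth <- sort(sim$fragments[S4Vectors::mcols(sim$fragments)$stream ==
                               "METH"])
  calls <- callMethylation(deduplicateFragments(meth)$unique, sim$reference)
  rec <- dilutionRecovery(calls, levels)
  expect_gte(rec$pearsonR, 0.99)
  expect_equal(rec$perLevel$truth, unname(levels))
  # degenerate: all levels identical -> flagged undefined
  recDeg <- dilutionRecovery(calls, c(d5 = 0, d2 = 0))
  expect_true(is.na(recDeg$pearsonR))
  expect_error(dilutionRecovery(calls, c(d5 = 0.05)), "two dilution")
})

test_that("methylation call TSV round-trips", {
  calls <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3, 9), width = 1),
                                  nMeth = c(3L, 1L), nUnmeth = c(7L, 0L),
                                  beta = c(0.3, 1), context = c("CpG", "CHH"))
  path <- tempfile(fileext = ".tsv")
  writeCpGCallsTSV(calls, path)
  back <- readCpGCallsTSV(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(calls))
  expect_equal(back$beta, calls$beta)
  expect_equal(back$context, calls$context)
})

test_that("the base-call path reproduces state-based methylation calls", {
  cfg <- SimConfig(contigLengths = c(chr1 = 6000), nMolecules = 400,
                   seed = 37)
  sim <- simulateLibrary(cfg, emitReads = FALSE)
  meth <- sort(sim$fragments[S4Vectors::mcols(sim$fragments)$stream ==
                               "METH"])
  dd <- deduplicateFragments(meth)$unique
  direct <- callMethylation(dd, sim$reference)
  # write observed bases to SAM, read back, call from base calls
  sam <- tempfile(fileext = ".sam")
  writeFragmentsSAM(dd, sam, sim$reference)
  back <- readFragmentsSAM(sam)
  viaBases <- callMethylation(back, sim$reference)
  expect_equal(length(viaBases), length(direct))
  expect_equal(viaBases$nMeth, direct$nMeth)
  expect_equal(viaBases$nUnmeth, direct$nUnmeth)
  expect_equal(viaBases$context, direct$context)
})
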