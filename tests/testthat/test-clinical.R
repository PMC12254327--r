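test_that("ctDNA fraction counts fully methylated eligible fragments", {
  sim <- simulateCtdnaFragments(nFragments = 4000, ctdnaFrac = 0.00125,
                                seed = 61)
  res <- ctdnaFraction(sim$frags, sim$markers)
  expect_equal(res$n_eligible, 4000L)
  expect_equal(res$n_ctdna, sum(sim$truth$isTumor))
  expect_equal(res$fraction, res$n_ctdna / 4000)

  # hand-built edge cases around the >= 5 CpG eligibility rule
  mk <- GenomicRanges::GRanges("ctdna", IRanges::IRanges(1000, 1200))
  mk$cpgPos <- IRanges::IntegerList(list(seq(1020, 1120, by = 20)))  # 6 CpGs
  frag <- function(pos, state) makeMethFrags(1000L, 1200L, list(pos),
                                             list(state), contig = "ctdna")
  # 4 covered CpGs, all methylated: excluded from both counts
  r <- ctdnaFraction(frag(seq(1020, 1080, 20), rep(TRUE, 4)), mk)
  expect_equal(r$n_eligible, 0L)
  expect_true(is.na(r$fraction))
  # 6 CpGs, 5 methylated: eligible but not tumor-derived
  r <- ctdnaFraction(frag(seq(1020, 1120, 20), c(rep(TRUE, 5), FALSE)), mk)
  expect_equal(c(r$n_eligible, r$n_ctdna), c(1L, 0L))
  # 6 CpGs, all methylated: a ctDNA fragment
  r <- ctdnaFraction(frag(seq(1020, 1120, 20), rep(TRUE, 6)), mk)
  expect_equal(c(r$n_eligible, r$n_ctdna), c(1L, 1L))
})

test_that("ctDNA positivity equals the documented boolean rule everywhere", {
  # brute-force truth table over boundary-adjacent inputs
  for (nElig in c(0L, 2999L, 3000L, 3001L, 4000L))
    for (nCt in c(0L, 2L, 3L, 4L, 6L))
      for (nSom in c(0L, 1L)) {
        if (nCt > nElig) next
        frac <- if (nElig) nCt / nElig else NA_real_
        got <- callCtdnaStatus(list(n_eligible = nElig, n_ctdna = nCt,
                                    fraction = frac), nSomatic = nSom)
        want <- nSom >= 1 ||
          (!is.na(frac) && frac > 0.001 && nCt >= 3 && nElig >= 3000)
        expect_equal(got == "POSITIVE", want,
                     info = sprintf("nElig=%d nCt=%d nSom=%d",
                                    nElig, nCt, nSom))
      }
  # worked arithmetic examples
  expect_equal(callCtdnaStatus(list(n_eligible = 4000L, n_ctdna = 5L,
                                    fraction = 5 / 4000), 0), "POSITIVE")
  expect_equal(callCtdnaStatus(list(n_eligible = 4000L, n_ctdna = 2L,
                                    fraction = 2 / 4000), 0), "NEGATIVE")
  expect_equal(callCtdnaStatus(list(n_eligible = 2500L, n_ctdna = 5L,
                                    fraction = 5 / 2500), 0), "NEGATIVE")
  expect_equal(callCtdnaStatus(list(n_eligible = 0L, n_ctdna = 0L,
                                    fraction = NA_real_), 1), "POSITIVE")
})

test_that("immune fractions average marker proportions per cell type", {
  mk <- GenomicRanges::GRanges("immune", IRanges::IRanges(c(100, 400),
                                                          width = 100),
                               name = c("m1", "m2"),
                               cellType = c("tcell", "tcell"))
  mk$cpgPos <- IRanges::IntegerList(list(c(120L, 140L), c(420L, 440L)))
  frags <- function(startPos, cpg, states)
    makeMethFrags(rep(startPos, length(states)),
                  rep(startPos + 99L, length(states)),
                  rep(list(cpg), length(states)), states,
                  contig = "immune")
  # marker 1: 1 of 10 fragments fully unmethylated; marker 2: 2 of 10
  f1 <- frags(100L, c(120L, 140L),
              c(rep(list(c(TRUE, TRUE)), 9), list(c(FALSE, FALSE))))
  f2 <- frags(400L, c(420L, 440L),
              c(rep(list(c(TRUE, TRUE)), 8), rep(list(c(FALSE, FALSE)), 2)))
  raw <- immuneFractions(c(f1, f2), mk)
  expect_equal(unname(raw["tcell"]), mean(c(0.1, 0.2)))
  # a fragment reporting only 1 of 2 marker CpGs is not a covering fragment
  f3 <- makeMethFrags(100L, 199L, list(120L), list(FALSE), contig = "immune")
  raw2 <- immuneFractions(c(f1, f3), mk[1])
  expect_equal(unname(raw2["tcell"]), 0.1)
})

test_that("calibration is linear per cell type and renormalizes to one", {
  raw <- c(a = 0.3, b = 0.5)
  # identity training: calibrated equals raw renormalized
  tr <- data.frame(cell_type = rep(c("a", "b"), each = 2),
                   raw = c(0.1, 0.4, 0.2, 0.6), cbc = c(0.1, 0.4, 0.2, 0.6))
  cal <- calibrateFractions(raw, tr)
  expect_equal(unname(cal$calibrated), unname(raw / sum(raw)))
  # slope-2 training doubles before renormalizing
  tr2 <- transform(tr, cbc = 2 * raw)
  cal2 <- calibrateFractions(raw, tr2)
  expect_equal(unname(cal2$calibrated), unname(2 * raw / sum(2 * raw)))
  expect_equal(sum(cal2$calibrated), 1)
  # degenerate training is rejected
  tr3 <- data.frame(cell_type = "a", raw = c(0.2, 0.2), cbc = c(0.1, 0.3))
  expect_error(calibrateFractions(c(a = 0.3), tr3), "zero variance")
})

test_that("flow-cytometry proportions rescale to blood-count group totals", {
  fcm <- c(cd4 = 0.2, cd8 = 0.2, neu = 0.5, eos = 0.05, mono = 0.05)
  groups <- list(lymphoid = c("cd4", "cd8"),
                 myeloid = c("neu", "eos", "mono"))
  out <- normalizeFCM(fcm, groups, c(lymphoid = 0.3, myeloid = 0.7))
  expect_equal(unname(out[c("cd4", "cd8")]), c(0.15, 0.15))
  expect_equal(sum(out), 1)
  # already matching totals: identity
  out2 <- normalizeFCM(fcm, groups, c(lymphoid = 0.4, myeloid = 0.6))
  expect_equal(out2, fcm)
  expect_error(normalizeFCM(c(cd4 = 0, cd8 = 0), list(l = c("cd4", "cd8")),
                            c(l = 0.3)), "zero total")
})

test_that("simulated immune mixtures are recovered after calibration", {
  mix <- simulateImmuneMixture(fragsPerMarker = 2000, seed = 62)
  raw <- immuneFractions(mix$frags, mix$markers)
  tr <- do.call(rbind, lapply(1:5, function(i) {
    f <- mix$truth + stats::rnorm(length(mix$truth), 0, 0.01) *
      (seq_along(mix$truth) %% 2 * 2 - 1)
    f <- pmax(f, 0.01); f <- f / sum(f)
    m <- simulateImmuneMixture(fractions = f, fragsPerMarker = 800,
                               seed = 70 + i)
    r <- immuneFractions(m$frags, m$markers)
    data.frame(cell_type = names(r), raw = as.numeric(r),
               cbc = as.numeric(f))
  }))
  cal <- calibrateFractions(raw, tr)
  expect_equal(sum(cal$calibrated), 1)
  expect_lt(max(abs(cal$calibrated - mix$truth)), 0.02)
  expect_gt(computeNLR(cal$calibrated), 0)
})

test_that("promoter CpG selection applies all three criteria", {
  em <- simulateExpressionMethylation(nSamples = 300, nGenes = 3, seed = 63)
  sel <- selectCorrelatedCpGs(em$meth, em$expr, em$cpgAnnotation,
                              em$tssTable)
  # planted promoter CpGs (dense, r = -0.6) are recovered
  expect_gte(mean(em$plantedCpgs %in% sel$candidates$cpg_id), 0.9)
  # uncorrelated, non-promoter and sparse CpGs stay out:
  # null promoter CpGs can only enter through the r < -0.15 null rate
  extra <- setdiff(sel$candidates$cpg_id, em$plantedCpgs)
  nNullPromoter <- sum(grepl("cpg0", rownames(em$meth))) # upper bound
  expect_lte(length(extra), 0.05 * nNullPromoter)
  # sparse CpGs planted with strong correlation still fail the neighbor
  # criterion; outside-promoter CpGs fail the location criterion
  ann <- em$cpgAnnotation
  sparseIds <- vapply(split(ann$cpg_id, ann$gene), function(ids)
    ids[length(ids)], character(1))
  expect_false(any(sparseIds %in% sel$candidates$cpg_id))
  expect_error(selectCorrelatedCpGs(em$meth[, 1:2], em$expr[, 1:2],
                                    em$cpgAnnotation, em$tssTable),
               "shared samples")
})

test_that("candidate clustering equals a brute-force interval union", {
  mkData <- function(pos) {
    nS <- 60
    z <- stats::rnorm(nS)
    meth <- t(vapply(seq_along(pos), function(i)
      0.5 - 0.08 * z + stats::rnorm(nS, 0, 0.01), numeric(nS)))
    rownames(meth) <- paste0("c", seq_along(pos))
    colnames(meth) <- paste0("s", 1:nS)
    expr <- matrix(z, 1, dimnames = list("g1", colnames(meth)))
    ann <- data.frame(cpg_id = rownames(meth), contig = "x", pos = pos,
                      gene = "g1")
    tss <- data.frame(gene = "g1", contig = "x", tss = min(pos), strand = "+")
    list(meth = meth, expr = expr, ann = ann, tss = tss)
  }
  set.seed(64)
  for (rep in 1:10) {
    base <- sort(sample(1000:1600, 9))
    # densify so the neighbor criterion passes: 7 CpGs within 10 bp each
    pos <- sort(unique(as.integer(outer(base, 0:6, `+`))))
    d <- mkData(pos)
    sel <- selectCorrelatedCpGs(d$meth, d$expr, d$ann, d$tss,
                                promoterDown = 10000)
    got <- sel$clusters[order(sel$clusters$start), ]
    # oracle: chained flank overlap (|pi - pj| <= 200 merges)
    cand <- sort(sel$candidates$pos)
    grp <- cumsum(c(TRUE, diff(cand) > 200))
    for (k in unique(grp)) {
      mem <- cand[grp == k]
      expect_equal(sort(got$members[[k]]), mem)
      if (length(mem) > 1) {
        expect_equal(got$start[k], min(mem) - 100)
        expect_equal(got$end[k], max(mem) + 100)
      } else {
        expect_equal(c(got$start[k], got$end[k]), c(mem - 75, mem + 75))
      }
    }
  }
  # worked merge arithmetic: 150 bp apart merges, 250 bp does not
  d <- mkData(sort(unique(as.integer(outer(c(1000, 1150, 1400), 0:6, `+`)))))
  sel <- selectCorrelatedCpGs(d$meth, d$expr, d$ann, d$tss,
                              promoterDown = 10000)
  expect_equal(nrow(sel$clusters), 2L)
})

test_that("gene hypermethylation uses a strict mean-beta threshold", {
  calls <- GenomicRanges::GRanges("x", IRanges::IRanges(c(100, 200),
                                                        width = 1),
                                  nMeth = c(1L, 3L), nUnmeth = c(19L, 17L),
                                  beta = c(0.05, 0.15),
                                  context = c("CpG", "CpG"))
  cl <- list(contig = "x", members = c(100L, 200L))
  expect_true(geneMethylationStatus(calls, cl))          # mean 0.10 > 0.07
  calls$beta <- c(0, 0)
  expect_false(geneMethylationStatus(calls, cl))
  calls$beta <- c(0.07, 0.07)                            # exactly 0.07
  expect_false(geneMethylationStatus(calls, cl))
  expect_true(is.na(geneMethylationStatus(calls,
                                          list(contig = "y",
                                               members = c(100L)))))
})

test_that("LOH model expectations and grid recovery", {
  # worked expectation: p = 0.5, (M, N) = (1, 0) gives BAF 2/3, depth 3/4
  e <- lohExpected(1, 0, 0.5, 2)
  expect_equal(e$baf, 2 / 3)
  expect_equal(e$depth, 0.75)
  # noise-free recovery across the copy-number grid and purity levels
  for (p in c(0.3, 0.6, 1.0)) for (M in 0:4) for (N in 0:M) {
    tr <- lohExpected(M, N, p, 2)
    fit <- fitLOH(tr$depth, tr$baf, p, 2)
    expect_equal(c(fit$M, fit$N), c(M, N),
                 info = sprintf("p=%.1f M=%d N=%d", p, M, N))
    expect_equal(fit$loh, N == 0 && M >= 1)
  }
  # diploid heterozygous locus is not LOH
  fit <- fitLOH(1, 0.5, 1, 2)
  expect_equal(c(fit$M, fit$N), c(1L, 1L))
  expect_false(fit$loh)
  expect_error(fitLOH(1, 0.5, 0), "purity")
  # noisy observations still recover a planted (2, 0) LOH
  set.seed(65)
  tr <- lohExpected(2, 0, 0.6, 2)
  fit <- fitLOH(tr$depth + stats::rnorm(5, 0, 0.03),
                tr$baf + stats::rnorm(5, 0, 0.02), 0.6, 2)
  expect_equal(c(fit$M, fit$N), c(2L, 0L))
})

test_that("biallelic classification fires on exactly the four rules", {
  ev <- data.frame(
    loh = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    promoter_methylated = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    deleterious_mutations = c(0L, 1L, 2L, 0L, 0L, 1L),
    homozygous_deletion = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(classifyBiallelic(ev),
               c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("biallelic-HRD association matches its permutation oracle", {
  # the cohort worked example
  got <- hrdAssociation(c(rep(TRUE, 12), rep(FALSE, 4), TRUE,
                          rep(FALSE, 10)),
                        rep(c(TRUE, FALSE), c(16, 11)))
  expect_equal(got$table["biallelic", "HRD"], 12)
  expect_lte(got$p, 0.01)
  # identical rates in both groups
  same <- hrdAssociation(rep(c(TRUE, FALSE), 10), rep(c(TRUE, FALSE),
                                                      each = 10))
  expect_equal(same$p, 1.0)
  expect_error(hrdAssociation(c(TRUE, FALSE), c(TRUE, TRUE)), "both")
  # simulated cohort: exact p agrees with a label-permutation estimate
  sim <- simulateGeneEvents(seed = 66)
  perPatient <- tapply(classifyBiallelic(sim$events),
                       sim$events$patient, any)
  bi <- unname(perPatient[sim$labels$patient])
  res <- hrdAssociation(bi, sim$labels$hrd)
  expect_lt(res$p, 0.05)
  set.seed(67)
  B <- 4000
  obs <- sum(bi & sim$labels$hrd)
  extreme <- replicate(B, {
    perm <- sample(sim$labels$hrd)
    tab <- matrix(c(sum(bi & perm), sum(bi & !perm),
                    sum(!bi & perm), sum(!bi & !perm)), 2, byrow = TRUE)
    bruteFisherP(tab) <= bruteFisherP(res$table) * (1 + 1e-7)
  })
  permP <- mean(extreme)
  se <- sqrt(permP * (1 - permP) / B) + 1 / B
  expect_lt(abs(permP - res$p), 4 * se + 0.005)
})

test_that("greedy panel design matches the hand-worked example", {
  inc <- matrix(0L, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  inc[1:2, "A"] <- 1L; inc[3, "B"] <- 1L; inc[1, "C"] <- 1L
  expect_warning(sel <- designPanelGreedy(inc, target = 0.75),
                 "unreachable")
  expect_equal(as.character(sel), c("A", "B"))
  expect_equal(unname(attr(sel, "coverage")), 0.75)
  # a base panel already past the target is returned unchanged
  inc2 <- matrix(1L, 10, 2, dimnames = list(NULL, c("A", "B")))
  sel2 <- designPanelGreedy(inc2, baseExons = "A", target = 0.85)
  expect_equal(as.character(sel2), "A")
})

test_that("greedy selection equals exhaustive greedy on small instances", {
  oracle <- function(mats, base, target) {
    exons <- colnames(mats[[1]])
    cov <- function(sel) min(vapply(mats, function(m)
      if (length(sel)) mean(rowSums(m[, sel, drop = FALSE]) > 0) else 0,
      numeric(1)))
    sel <- intersect(exons, base)
    repeat {
      if (cov(sel) > target) break
      cand <- setdiff(exons, sel)
      if (!length(cand)) break
      gains <- vapply(cand, function(e) cov(c(sel, e)), numeric(1))
      if (max(gains) <= cov(sel)) break
      sel <- c(sel, cand[which.max(gains)])
    }
    sel
  }
  set.seed(68)
  for (rep in 1:25) {
    nE <- sample(2:6, 1); nP <- sample(3:8, 1)
    mats <- lapply(seq_len(sample(1:2, 1)), function(i) {
      m <- matrix(rbinom(nP * nE, 1, 0.3), nP, nE,
                  dimnames = list(NULL, LETTERS[1:nE]))
      m
    })
    names(mats) <- paste0("cohort", seq_along(mats))
    target <- sample(c(0.5, 0.75, 0.85), 1)
    got <- suppressWarnings(designPanelGreedy(mats, target = target))
    expect_equal(as.character(got), oracle(mats, character(0), target))
  }
})

test_that("qPCR calls use strict thresholds and treat missing as negative", {
  r <- qpcrCall(c(25.9, 26.0, NA), c(10.0, 9.9, NA), c(10.4, 10.5, NA))
  expect_equal(r$mutation_positive, c(TRUE, FALSE, FALSE))
  # row 1: dCtA 10.0 fails (strict) but dCtB 10.4 < 10.5 passes
  expect_equal(r$methylation_positive, c(TRUE, TRUE, FALSE))
})
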