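## Cohort-scale synthetic data generators: stand-ins for the public tumor
## methylation/expression compendia, mutation incidence cohorts, blood-count
## calibration data and gene-event tables the clinical layers consume.
## They emulate the statistical structure those inputs are assumed to have
## (documented per generator), not any real cohort.

#' Simulate a methylation/expression cohort with planted promoter CpGs
#'
#' Emulates a tumor compendium of paired promoter CpG methylation and gene
#' expression: for each gene, a block of densely spaced promoter CpGs of
#' which a subset is negatively correlated with expression (silencing
#' signal), the rest uncorrelated noise; plus control CpGs outside the
#' promoter and sparsely spaced CpGs that fail the neighbor criterion.
#' Methylation is `0.5 + 0.1 * (rho * z + sqrt(1 - rho^2) * eps)` clipped
#' to `[0, 1]`, where `z` is the standardized expression, so the planted
#' Pearson correlation is `rho` up to clipping.
#'
#' @param nSamples number of samples (default 300).
#' @param nGenes number of genes (default 4).
#' @param nPlanted planted expression-correlated CpGs per gene (default 20).
#' @param nNull uncorrelated promoter CpGs per gene (default 10).
#' @param plantedCor planted correlation (default -0.6).
#' @param cpgSpacing spacing of promoter CpGs in bp (default 10).
#' @param seed integer RNG seed.
#' @return list with `meth` (CpG x sample matrix), `expr` (gene x sample),
#'   `cpgAnnotation` (cpg_id, contig, pos, gene), `tssTable` (gene, contig,
#'   tss, strand), `plantedCpgs` (character ids).
#' @export
simulateExpressionMethylation <- function(nSamples = 300L, nGenes = 4L,
                                          nPlanted = 20L, nNull = 10L,
                                          plantedCor = -0.6,
                                          cpgSpacing = 10L, seed = 1L) {
  if (nSamples < 3L) stop("need at least 3 samples")
  withSeed(seed, {
    genes <- sprintf("gene%02d", seq_len(nGenes))
    samples <- sprintf("s%03d", seq_len(nSamples))
    expr <- matrix(rnorm(nGenes * nSamples), nGenes,
                   dimnames = list(genes, samples))
    ann <- NULL; rows <- list(); planted <- character(0L)
    for (g in seq_len(nGenes)) {
      tss <- 100000L * g
      ## dense CpG block downstream of the TSS, inside the promoter window
      nProm <- nPlanted + nNull
      pos <- tss + 50L + cpgSpacing * (seq_len(nProm) - 1L)
      isPlanted <- seq_len(nProm) <= nPlanted
      ## CpGs outside the promoter (same density) and sparse isolated CpGs
      outPos <- tss + 5000L + cpgSpacing * (0:9)
      sparsePos <- tss - 900L + 400L * (0:1)
      allPos <- c(pos, outPos, sparsePos)
      grp <- c(ifelse(isPlanted, "planted", "null"),
               rep("outside", length(outPos)), rep("sparse", length(sparsePos)))
      ids <- sprintf("%s_cpg%03d", genes[g], seq_along(allPos))
      z <- expr[g, ]
      m <- t(vapply(seq_along(allPos), function(i) {
        rho <- if (grp[i] %in% c("planted", "sparse")) plantedCor else 0
        eps <- rnorm(nSamples)
        pmin(pmax(0.5 + 0.1 * (rho * z + sqrt(1 - rho^2) * eps), 0), 1)
      }, numeric(nSamples)))
      rownames(m) <- ids
      rows[[g]] <- m
      planted <- c(planted, ids[grp == "planted"])
      ann <- rbind(ann, data.frame(cpg_id = ids, contig = "cohort",
                                   pos = allPos, gene = genes[g],
                                   stringsAsFactors = FALSE))
    }
    meth <- do.call(rbind, rows)
    colnames(meth) <- samples
    tss <- data.frame(gene = genes, contig = "cohort",
                      tss = 100000L * seq_len(nGenes), strand = "+",
                      stringsAsFactors = FALSE)
    list(meth = meth, expr = expr, cpgAnnotation = ann, tssTable = tss,
         plantedCpgs = planted)
  })
}

#' Simulate patient-by-exon mutation incidence cohorts
#'
#' Emulates the mutation incidence matrices that panel design draws on:
#' each exon has a cohort-shared mutation prevalence drawn from a decaying
#' profile (a few recurrently mutated exons, a long tail), and patients
#' mutate exons independently.
#'
#' @param nPatients named integer vector, patients per cohort.
#' @param nExons number of candidate exons (default 40).
#' @param topRate prevalence of the most recurrent exon (default 0.35).
#' @param decay geometric decay of prevalence across exons (default 0.85).
#' @param seed integer RNG seed.
#' @return named list of binary patient x exon matrices (shared colnames).
#' @export
simulateMutationIncidence <- function(nPatients = c(cohortA = 120L,
                                                    cohortB = 100L),
                                      nExons = 40L, topRate = 0.35,
                                      decay = 0.85, seed = 1L) {
  if (any(nPatients < 1L) || nExons < 1L) stop("degenerate cohort sizes")
  withSeed(seed, {
    rate <- topRate * decay^(seq_len(nExons) - 1L)
    exons <- sprintf("exon%02d", seq_len(nExons))
    lapply(nPatients, function(n) {
      m <- matrix(rbinom(n * nExons, 1L, rep(rate, each = n)), nrow = n)
      dimnames(m) <- list(NULL, exons)
      m
    })
  })
}

#' Simulate an immune cell-type cfDNA mixture at methylation markers
#'
#' Emulates cell type-specific methylation markers: each marker is
#' unmethylated in exactly one cell type and methylated in all others, so
#' the proportion of fully unmethylated fragments at a marker estimates
#' that cell type's DNA fraction. Fragments draw their source cell type
#' from the mixture and their observed CpG states through the conversion
#' error model (a methylated CpG reads methylated with probability
#' `specificity`; an unmethylated CpG reads unmethylated with probability
#' `sensitivity`).
#'
#' @param fractions named numeric mixture fractions summing to 1 (default:
#'   a blood-like 7-type mixture).
#' @param markersPerType integer vector recycled over cell types (default
#'   gives 17 markers over 7 types).
#' @param fragsPerMarker fragments per marker (default 2000).
#' @param nCpgs CpG sites per marker (default 5).
#' @param sensitivity,specificity conversion error model (defaults 0.9989,
#'   0.9743).
#' @param pool a [UMIPool-class] (default: bundled pool).
#' @param seed integer RNG seed.
#' @return list with `frags` ([MMFragments-class], methylation stream),
#'   `markers` (`GRanges` with `name`, `cellType`, `cpgPos` columns) and
#'   `truth` (the mixture fractions).
#' @export
simulateImmuneMixture <- function(fractions = c(neutrophil = 0.55,
                                                monocyte = 0.08,
                                                eosinophil = 0.03,
                                                b_cell = 0.06,
                                                cd4_t = 0.13, cd8_t = 0.09,
                                                nk = 0.06),
                                  markersPerType = c(3L, 3L, 2L, 2L, 3L,
                                                     2L, 2L),
                                  fragsPerMarker = 2000L, nCpgs = 5L,
                                  sensitivity = 0.9989,
                                  specificity = 0.9743,
                                  pool = NULL, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mixture fractions must sum to 1")
  if (is.null(pool)) pool <- defaultUMIPool()
  withSeed(seed, {
    types <- names(fractions)
    mpt <- rep_len(markersPerType, length(types))
    markerType <- rep(types, mpt)
    nM <- length(markerType)
    width <- (nCpgs + 1L) * 20L
    startM <- 1000L + (seq_len(nM) - 1L) * (width + 200L)
    cpgPos <- lapply(seq_len(nM), function(i)
      as.integer(startM[i] + 20L * seq_len(nCpgs)))
    markers <- GRanges("immune", IRanges(startM, width = width),
                       name = sprintf("mk%02d_%s", seq_len(nM), markerType),
                       cellType = markerType)
    markers$cpgPos <- IntegerList(cpgPos)
    frags <- vector("list", nM)
    for (i in seq_len(nM)) {
      src <- sample(types, fragsPerMarker, replace = TRUE, prob = fractions)
      unmeth <- src == markerType[i]
      truthState <- matrix(rep(!unmeth, nCpgs), ncol = nCpgs)
      pMeth <- ifelse(truthState, specificity, 1 - sensitivity)
      obs <- matrix(runif(length(pMeth)) < pMeth, ncol = nCpgs)
      u1 <- sample(poolUMIs(pool), fragsPerMarker, replace = TRUE)
      u2 <- sample(poolUMIs(pool), fragsPerMarker, replace = TRUE)
      frags[[i]] <- MMFragments(
        contig = "immune", start = rep(startM[i], fragsPerMarker),
        end = rep(startM[i] + width - 1L, fragsPerMarker),
        stream = "METH",
        umi1 = collapseSequence(u1, "C2T"),
        umi2 = collapseSequence(u2, "G2A"),
        flag1 = 67L, flag2 = 131L,
        methPos = IntegerList(rep(list(cpgPos[[i]]), fragsPerMarker)),
        methState = LogicalList(lapply(seq_len(fragsPerMarker),
                                       function(j) obs[j, ])))
    }
    frags <- do.call(c, frags)
    list(frags = frags, markers = markers, truth = fractions)
  })
}

#' Simulate per-gene event tables with an HRD-enriched biallelic signal
#'
#' Emulates a cohort of patients labelled homologous recombination
#' deficient (HRD) or proficient (HRP), with per-gene loss of
#' heterozygosity, promoter methylation, deleterious mutation counts and
#' homozygous deletions. Biallelic inactivation of at least one gene is
#' planted at a higher rate in the HRD group.
#'
#' @param nHRD,nHRP patients per group (defaults 16 and 11).
#' @param genes gene names (default: 16 homologous recombination repair
#'   genes).
#' @param pBiallelicHRD,pBiallelicHRP probability that a patient carries a
#'   biallelic loss in at least one gene (defaults 0.75 and 0.09).
#' @param pLohBackground background per-gene LOH rate (default 0.4).
#' @param seed integer RNG seed.
#' @return list with `events` (data.frame: patient, gene, loh,
#'   promoter_methylated, deleterious_mutations, homozygous_deletion) and
#'   `labels` (data.frame: patient, hrd).
#' @export
simulateGeneEvents <- function(nHRD = 16L, nHRP = 11L,
                               genes = c("ATM", "BARD1", "BRCA1", "BRCA2",
                                         "BRIP1", "CDK12", "CHEK1", "CHEK2",
                                         "FANCA", "FANCL", "HDAC2", "PALB2",
                                         "RAD51B", "RAD51C", "RAD51D",
                                         "RAD54L"),
                               pBiallelicHRD = 0.75, pBiallelicHRP = 0.09,
                               pLohBackground = 0.4, seed = 1L) {
  if (nHRD < 1L || nHRP < 1L) stop("degenerate group sizes")
  withSeed(seed, {
    patients <- sprintf("p%02d", seq_len(nHRD + nHRP))
    hrd <- rep(c(TRUE, FALSE), c(nHRD, nHRP))
    ev <- expand.grid(patient = patients, gene = genes,
                      stringsAsFactors = FALSE)
    n <- nrow(ev)
    ev$loh <- runif(n) < pLohBackground
    ev$promoter_methylated <- FALSE
    ev$deleterious_mutations <- 0L
    ev$homozygous_deletion <- FALSE
    carrier <- runif(length(patients)) < ifelse(hrd, pBiallelicHRD,
                                                pBiallelicHRP)
    for (i in which(carrier)) {
      g <- sample(genes, 1L)
      row <- which(ev$patient == patients[i] & ev$gene == g)
      mech <- sample(c("loh_meth", "loh_mut", "two_mut", "homdel"), 1L,
                     prob = c(0.6, 0.2, 0.1, 0.1))
      if (mech == "loh_meth") {
        ev$loh[row] <- TRUE; ev$promoter_methylated[row] <- TRUE
      } else if (mech == "loh_mut") {
        ev$loh[row] <- TRUE; ev$deleterious_mutations[row] <- 1L
      } else if (mech == "two_mut") {
        ev$deleterious_mutations[row] <- 2L
      } else ev$homozygous_deletion[row] <- TRUE
    }
    list(events = ev, labels = data.frame(patient = patients, hrd = hrd,
                                          stringsAsFactors = FALSE))
  })
}

#' Simulate a binned genome coverage track with GC bias and planted CNVs
#'
#' Read counts per non-overlapping bin are Poisson around
#' `meanCoverage * (copies / 2) * bias(gc)` where `bias` is a linear GC
#' effect normalized to 1 at the mean GC.
#'
#' @param contigLength genome length in bp (default 10 Mb).
#' @param binSize bin size in bp (default 10 kb).
#' @param meanCoverage diploid mean coverage (default 30).
#' @param gcRange range of per-bin GC fractions (default 0.35-0.55).
#' @param gcBiasAmp linear GC bias amplitude; 0 disables (default 0).
#' @param cnv data.frame(start, end, copies) of planted copy-number
#'   segments (1-based closed, absolute copy number; default none).
#' @param readLength read length used to convert read counts to coverage
#'   (default 100).
#' @param contig contig name (default "sim1").
#' @param seed integer RNG seed.
#' @return data.frame(contig, start, end, coverage, gc) with 1-based
#'   closed bin spans; a short trailing bin is dropped.
#' @export
simulateCoverageTrack <- function(contigLength = 10e6, binSize = 10000L,
                                  meanCoverage = 30, gcRange = c(0.35, 0.55),
                                  gcBiasAmp = 0, cnv = NULL,
                                  readLength = 100L, contig = "sim1",
                                  seed = 1L) {
  withSeed(seed, {
    nBins <- floor(contigLength / binSize)
    start <- (seq_len(nBins) - 1L) * binSize + 1L
    end <- start + binSize - 1L
    gc <- runif(nBins, gcRange[1L], gcRange[2L])
    copies <- rep(2, nBins)
    if (!is.null(cnv) && nrow(cnv)) for (i in seq_len(nrow(cnv))) {
      hit <- start >= cnv$start[i] & end <= cnv$end[i]
      copies[hit] <- cnv$copies[i]
    }
    bias <- 1 + gcBiasAmp * (gc - mean(gcRange))
    lambda <- meanCoverage * (copies / 2) * bias * binSize / readLength
    coverage <- rpois(nBins, pmax(lambda, 0)) * readLength / binSize
    data.frame(contig = contig, start = start, end = end,
               coverage = coverage, gc = gc, truthCopies = copies,
               stringsAsFactors = FALSE)
  })
}

#' Simulate marker-region cfDNA fragments with a planted ctDNA fraction
#'
#' Emulates hypermethylated tumor markers in a cfDNA background: a
#' fraction of fragments is tumor-derived (every marker CpG methylated),
#' the rest background with a low independent per-CpG methylation level.
#' Observed states pass through the conversion error model.
#'
#' @param nFragments total fragments across markers (default 4000).
#' @param ctdnaFrac planted tumor-derived fraction (default 0.00125).
#' @param nMarkers marker regions (default 8).
#' @param nCpgs CpGs per marker (default 6).
#' @param backgroundBeta background per-CpG methylation (default 0.01).
#' @param sensitivity,specificity conversion error model (defaults 1, 1:
#'   chemistry-free counting; set to assay values for realism).
#' @param seed integer RNG seed.
#' @return list with `frags` ([MMFragments-class]), `markers` (`GRanges`
#'   with `cpgPos`) and `truth` (planted fraction and per-fragment label).
#' @export
simulateCtdnaFragments <- function(nFragments = 4000L, ctdnaFrac = 0.00125,
                                   nMarkers = 8L, nCpgs = 6L,
                                   backgroundBeta = 0.01,
                                   sensitivity = 1, specificity = 1,
                                   seed = 1L) {
  withSeed(seed, {
    width <- (nCpgs + 1L) * 20L
    startM <- 1000L + (seq_len(nMarkers) - 1L) * (width + 200L)
    cpgPos <- lapply(seq_len(nMarkers), function(i)
      as.integer(startM[i] + 20L * seq_len(nCpgs)))
    markers <- GRanges("ctdna", IRanges(startM, width = width),
                       name = sprintf("mm%02d", seq_len(nMarkers)))
    markers$cpgPos <- IntegerList(cpgPos)
    mk <- sample.int(nMarkers, nFragments, replace = TRUE)
    isTumor <- runif(nFragments) < ctdnaFrac
    truthState <- matrix(runif(nFragments * nCpgs) < backgroundBeta,
                         nFragments, nCpgs)
    truthState[isTumor, ] <- TRUE
    pMeth <- ifelse(truthState, specificity, 1 - sensitivity)
    obs <- matrix(runif(length(pMeth)) < pMeth, nFragments, nCpgs)
    frags <- MMFragments(
      contig = "ctdna", start = startM[mk], end = startM[mk] + width - 1L,
      stream = "METH", umi1 = strrep("T", 8L), umi2 = strrep("A", 8L),
      flag1 = 67L, flag2 = 131L,
      methPos = IntegerList(cpgPos[mk]),
      methState = LogicalList(lapply(seq_len(nFragments),
                                     function(j) obs[j, ])))
    list(frags = frags, markers = markers,
         truth = list(fraction = ctdnaFrac, isTumor = isTumor))
  })
}

#' Simulate duplex fragment pairs with allele-specific methylation
#'
#' Generates matched genetic/methylation fragment pairs from molecules
#' heterozygous at a target SNP: molecules carrying the reference allele
#' are methylated at the surrounding CpGs with `betaRef`, alternate-allele
#' molecules with `betaAlt`. Genetic fragments carry exact pool UMIs and
#' the allele base; methylation fragments carry the fully collapsed UMIs
#' and drawn CpG states, so the duplex pairing join is exercised end to
#' end.
#'
#' @param nPerAllele molecules per allele (default 100).
#' @param betaRef,betaAlt CpG methylation level on the reference /
#'   alternate haplotype (defaults 0.9 and 0.1).
#' @param nCpgs CpGs within the window around the SNP (default 8).
#' @param fragmentLength fragment length (default 120).
#' @param pool a [UMIPool-class] (default: bundled pool).
#' @param seed integer RNG seed.
#' @return list with `genet`, `meth` ([MMFragments-class]), `snp`
#'   (list(contig, pos, ref, alt)) and `reference` (`DNAStringSet`).
#' @export
simulateAsmDuplex <- function(nPerAllele = 100L, betaRef = 0.9,
                              betaAlt = 0.1, nCpgs = 8L,
                              fragmentLength = 120L, pool = NULL,
                              seed = 1L) {
  if (is.null(pool)) pool <- defaultUMIPool()
  withSeed(seed, {
    fl <- fragmentLength
    n <- 2L * nPerAllele
    allele <- rep(c("REF", "ALT"), each = nPerAllele)
    ## reference: A background with CpGs flanking a central A/G SNP
    snpPos <- 500L
    cpgPos <- as.integer(snpPos + c(-(seq_len(ceiling(nCpgs / 2)) * 12L),
                                    seq_len(floor(nCpgs / 2)) * 12L))
    cpgPos <- sort(cpgPos)[seq_len(nCpgs)]
    refChars <- rep("A", 1000L)
    refChars[snpPos] <- "A"
    refChars[cpgPos] <- "C"; refChars[cpgPos + 1L] <- "G"
    reference <- DNAStringSet(setNames(paste(refChars, collapse = ""),
                                       "asm1"))
    start <- as.integer(snpPos - floor(fl / 2) -
                          sample.int(10L, n, replace = TRUE) + 5L)
    end <- start + fl - 1L
    u1 <- sample(poolUMIs(pool), n, replace = TRUE)
    u2 <- sample(poolUMIs(pool), n, replace = TRUE)
    beta <- ifelse(allele == "REF", betaRef, betaAlt)
    bases <- vapply(seq_len(n), function(i) {
      b <- refChars[start[i]:end[i]]
      b[snpPos - start[i] + 1L] <- if (allele[i] == "REF") "A" else "G"
      paste(b, collapse = "")
    }, character(1L))
    covered <- lapply(seq_len(n), function(i)
      cpgPos[cpgPos >= start[i] & cpgPos <= end[i]])
    states <- lapply(seq_len(n), function(i)
      runif(length(covered[[i]])) < beta[i])
    genet <- MMFragments("asm1", start, end, "GENET", u1, u2, 99L, 147L,
                         molId = seq_len(n), bases = bases)
    meth <- MMFragments("asm1", start, end, "METH",
                        collapseSequence(u1, "C2T"),
                        collapseSequence(u2, "G2A"), 67L, 131L,
                        molId = seq_len(n),
                        methPos = IntegerList(covered),
                        methState = LogicalList(states))
    list(genet = sort(genet), meth = sort(meth),
         snp = list(contig = "asm1", pos = snpPos, ref = "A", alt = "G"),
         reference = reference)
  })
}

#' Simulate a full synthetic cohort bundle
#'
#' Convenience wrapper producing every cohort-scale table the clinical
#' layers consume; see the individual generators for the emulated
#' structure.
#'
#' @param seed integer RNG seed (sub-generators use derived seeds).
#' @param ... passed through to nothing; reserved.
#' @return list with `expressionMethylation`, `incidence`, `immune`,
#'   `geneEvents`, `coverage` components.
#' @export
simulateCohort <- function(seed = 1L, ...) {
  list(expressionMethylation = simulateExpressionMethylation(seed = seed),
       incidence = simulateMutationIncidence(seed = seed + 1L),
       immune = simulateImmuneMixture(seed = seed + 2L),
       geneEvents = simulateGeneEvents(seed = seed + 3L),
       coverage = simulateCoverageTrack(contigLength = 2e6, seed = seed + 4L))
}
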