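#' SimConfig: conditions for the in-silico duplex library simulator
#'
#' Describes a simulated co-detection library: reference contigs (optionally
#' spike-in analogs with fixed methylation levels), per-CpG methylation
#' truth, planted variants, conversion chemistry parameters, protective
#' copy-strand cycles, strand survival and PCR duplication.
#'
#' The generative model per duplex molecule: a fragment of fixed length is
#' drawn uniformly from the contigs; a UMI pair is attached from the pool;
#' the Watson and Crick original strands each receive `2^copyCycles - 1`
#' protected copy strands (the documented exponential-doubling model of the
#' pre-amplification step). During conversion, an unmethylated cytosine on
#' an original strand converts with probability `conversionSensitivity` and
#' a methylated CpG cytosine survives with probability
#' `conversionSpecificity`; a protected-copy cytosine survives with
#' probability `analogResistance`. UMI cytosines are unmodified by design
#' and convert like genomic unmethylated cytosines on original strands.
#' Each strand survives conversion with probability `strandSurvival`; each
#' surviving strand yields one read pair plus a PCR duplicate with
#' probability `pcrDuplicateRate`.
#'
#' @slot contigLengths named integer contig lengths.
#' @slot contigGC named numeric GC content per contig.
#' @slot methLevel named numeric per contig: a fixed CpG methylation level
#'   (0 for an unmethylated lambda-like analog, 1 for a fully CpG-methylated
#'   pUC19-like analog, intermediate for dilution series), or `NA` to draw
#'   per-CpG truth betas from a bimodal landscape.
#' @slot variants data.frame with columns `contig`, `pos` (1-based), `alt`,
#'   `af` (allele fraction); the reference base is taken from the simulated
#'   reference.
#' @slot conversionSensitivity,conversionSpecificity,analogResistance,strandSurvival,pcrDuplicateRate
#'   probabilities in `[0, 1]`.
#' @slot copyCycles integer protective pre-amplification cycles (1 for
#'   genomic DNA, 3 for cell-free DNA).
#' @slot nMolecules number of duplex molecules.
#' @slot fragmentLength fragment length in bp (reads fully span fragments).
#' @slot umiLength UMI length (default 8).
#' @slot pool a [UMIPool-class].
#' @slot seed integer RNG seed; all randomness flows from it.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(contigLengths = "integer", contigGC = "numeric",
                 methLevel = "numeric", variants = "data.frame",
                 conversionSensitivity = "numeric",
                 conversionSpecificity = "numeric",
                 analogResistance = "numeric", copyCycles = "integer",
                 strandSurvival = "numeric", pcrDuplicateRate = "numeric",
                 nMolecules = "integer", fragmentLength = "integer",
                 umiLength = "integer", pool = "UMIPool", seed = "integer"))

setValidity("SimConfig", function(object) {
  pr <- c(sensitivity = object@conversionSensitivity,
          specificity = object@conversionSpecificity,
          resistance = object@analogResistance,
          survival = object@strandSurvival,
          duplicates = object@pcrDuplicateRate)
  if (any(pr < 0 | pr > 1))
    return(sprintf("probability out of [0,1]: %s",
                   paste(names(pr)[pr < 0 | pr > 1], collapse = ", ")))
  if (object@copyCycles < 0L) return("copyCycles must be >= 0")
  if (object@nMolecules < 1L) return("nMolecules must be >= 1")
  if (!length(object@contigLengths) || is.null(names(object@contigLengths)))
    return("contigLengths must be a named vector")
  if (object@fragmentLength > min(object@contigLengths))
    return("fragmentLength exceeds the shortest contig")
  if (nrow(object@variants) &&
      any(pmin(object@variants$af, 1 - object@variants$af) < 0))
    return("variant allele fractions must lie in [0,1]")
  if (length(object@pool@umis) < 2L) return("empty UMI pool")
  TRUE
})

#' Construct a SimConfig
#'
#' Defaults are the study conditions of the assay: conversion sensitivity
#' 0.9989 and specificity 0.9743 (the spike-in figures of merit of the
#' method), analog resistance 0.9985 (matching the ~0.15% C-to-T
#' substitution rate of the propynyl analog), one copy cycle (genomic DNA),
#' and a bimodal CpG methylation landscape with genome-wide mean ~0.5.
#'
#' @param contigLengths named integer/numeric contig lengths.
#' @param nMolecules number of duplex molecules.
#' @param contigGC GC content, recycled over contigs (default 0.42).
#' @param methLevel named numeric per-contig fixed methylation level;
#'   contigs not named here use the bimodal landscape.
#' @param variants data.frame(contig, pos, alt, af) of planted variants.
#' @param conversionSensitivity,conversionSpecificity,analogResistance,strandSurvival,pcrDuplicateRate
#'   chemistry probabilities; see [SimConfig-class].
#' @param copyCycles protective pre-amplification cycles (default 1).
#' @param fragmentLength fragment length (default 80).
#' @param umiLength UMI length (default 8).
#' @param pool UMI pool (default: the bundled synthetic 32-member pool).
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class].
#' @export
SimConfig <- function(contigLengths, nMolecules,
                      contigGC = 0.42, methLevel = NULL,
                      variants = NULL,
                      conversionSensitivity = 0.9989,
                      conversionSpecificity = 0.9743,
                      analogResistance = 0.9985,
                      copyCycles = 1L, strandSurvival = 0.8,
                      pcrDuplicateRate = 0.1,
                      fragmentLength = 80L, umiLength = 8L,
                      pool = NULL, seed = 1L) {
  cl <- setNames(as.integer(contigLengths), names(contigLengths))
  gc <- setNames(rep_len(contigGC, length(cl)), names(cl))
  ml <- setNames(rep(NA_real_, length(cl)), names(cl))
  if (!is.null(methLevel)) {
    bad <- setdiff(names(methLevel), names(cl))
    if (length(bad)) stop("methLevel names not in contigs: ",
                          paste(bad, collapse = ", "))
    ml[names(methLevel)] <- methLevel
  }
  if (is.null(variants))
    variants <- data.frame(contig = character(0L), pos = integer(0L),
                           alt = character(0L), af = numeric(0L))
  if (is.null(pool)) pool <- defaultUMIPool()
  new("SimConfig", contigLengths = cl, contigGC = gc, methLevel = ml,
      variants = variants,
      conversionSensitivity = conversionSensitivity,
      conversionSpecificity = conversionSpecificity,
      analogResistance = analogResistance,
      copyCycles = as.integer(copyCycles),
      strandSurvival = strandSurvival,
      pcrDuplicateRate = pcrDuplicateRate,
      nMolecules = as.integer(nMolecules),
      fragmentLength = as.integer(fragmentLength),
      umiLength = as.integer(umiLength), pool = pool,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d molecules over %d contig(s) (%s bp), ",
                     "%d copy cycle(s)\n  sens=%.4f spec=%.4f res=%.4f ",
                     "survival=%.2f dup=%.2f seed=%d\n"),
              object@nMolecules, length(object@contigLengths),
              format(sum(object@contigLengths), big.mark = ","),
              object@copyCycles, object@conversionSensitivity,
              object@conversionSpecificity, object@analogResistance,
              object@strandSurvival, object@pcrDuplicateRate, object@seed))
})

#' The bundled synthetic 32-member UMI pool
#'
#' A generated collision-free pool (the real adapter set is proprietary and
#' unpublished); shipped at `inst/extdata/umi_pool_synthetic.txt`.
#'
#' @return a [UMIPool-class].
#' @export
defaultUMIPool <- function() {
  loadUMIPool(system.file("extdata", "umi_pool_synthetic.txt",
                          package = "mmseqtools", mustWork = TRUE))
}

## stochastic collapse of pool UMIs: each convertible base (C for C2T, G
## for G2A) flips with probability pConv, independently per strand
.stochCollapse <- function(umis, pConv, mode) {
  if (!length(umis)) return(character(0L))
  m <- .charMatrix(umis)
  from <- if (mode == "C2T") "C" else "G"
  to <- if (mode == "C2T") "T" else "A"
  hit <- m == from & matrix(runif(length(m)) < pConv, nrow(m))
  m[hit] <- to
  .pasteRows(m)
}

#' Number of protected copy strands per original strand
#'
#' Exponential-doubling model of the protective pre-amplification:
#' `2^cycles - 1` copies per original strand.
#'
#' @param cycles number of copy cycles.
#' @return integer count of protected strands per original strand.
#' @export
nProtectedStrands <- function(cycles) as.integer(2^cycles - 1L)

#' Simulate a co-detection duplex library
#'
#' Generates reference contigs, duplex molecules with per-CpG methylation
#' truth and planted variants, UMI attachment, protective copy strands,
#' conversion, strand survival and PCR duplication, and emits truth-labelled
#' fragments (plus FASTQ-ready read pairs when `emitReads = TRUE`).
#'
#' @param config a [SimConfig-class].
#' @param emitReads also materialize mate sequences (needed for
#'   demultiplexing and FASTQ output; skipping them makes large
#'   methylation-focused simulations much cheaper).
#' @return a list with elements:
#' \describe{
#'   \item{reads}{read-pair `DataFrame` ([readPairSet()]; `NULL` when
#'     `emitReads = FALSE`).}
#'   \item{truth}{`DataFrame`, one row per emitted read pair: `molId`,
#'     `duplexStrand`, `stream`, `poolUmi1`, `poolUmi2`, `isDuplicate`.}
#'   \item{fragments}{[MMFragments-class], one per emitted read pair, with
#'     observed UMIs, truth stream/flags, base calls (genetic stream) and
#'     observed cytosine states (methylation stream).}
#'   \item{reference}{`DNAStringSet` of the simulated contigs.}
#'   \item{cpgTruth}{`GRanges` of CpG dyads (position of the plus-strand C)
#'     with the configured `truthBeta`.}
#' }
#' @export
simulateLibrary <- function(config, emitReads = TRUE) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, .simulateLibrary(config, emitReads))
}

.simulateLibrary <- function(cfg, emitReads) {
  fl <- cfg@fragmentLength
  contigs <- names(cfg@contigLengths)

  ## --- reference ---------------------------------------------------------
  refChars <- lapply(contigs, function(ct) {
    gc <- cfg@contigGC[[ct]]
    sample(c("A", "C", "G", "T"), cfg@contigLengths[[ct]], replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  names(refChars) <- contigs
  offsets <- setNames(cumsum(c(0L, head(cfg@contigLengths, -1L))), contigs)
  globalRef <- unlist(refChars, use.names = FALSE)
  reference <- DNAStringSet(vapply(refChars, paste, character(1L),
                                   collapse = ""))

  ## --- CpG dyads and truth betas -----------------------------------------
  cpg <- do.call(rbind, lapply(contigs, function(ct) {
    rc <- refChars[[ct]]
    p <- which(rc[-length(rc)] == "C" & rc[-1L] == "G")
    if (!length(p)) return(NULL)
    lvl <- cfg@methLevel[[ct]]
    beta <- if (!is.na(lvl)) rep(lvl, length(p)) else .bimodalBetas(length(p))
    data.frame(contig = ct, pos = p, beta = beta, stringsAsFactors = FALSE)
  }))
  if (is.null(cpg))
    cpg <- data.frame(contig = character(0L), pos = integer(0L),
                      beta = numeric(0L))
  cpg$gpos <- offsets[cpg$contig] + cpg$pos
  cpgTruth <- GRanges(cpg$contig, IRanges(cpg$pos, width = 1L),
                      truthBeta = cpg$beta)

  ## --- molecules ----------------------------------------------------------
  nMol <- cfg@nMolecules
  molContig <- sample(contigs, nMol, replace = TRUE,
                      prob = cfg@contigLengths / sum(cfg@contigLengths))
  molStart <- as.integer(floor(runif(nMol) *
                      (cfg@contigLengths[molContig] - fl + 1L)) + 1L)
  molG <- offsets[molContig] + molStart  # global coords

  ## variant carriage per molecule
  vtab <- cfg@variants
  carriage <- vector("list", nrow(vtab))
  if (nrow(vtab)) {
    vtab$ref <- globalRef[offsets[vtab$contig] + vtab$pos]
    for (v in seq_len(nrow(vtab))) {
      cov <- which(molContig == vtab$contig[v] &
                   molStart <= vtab$pos[v] &
                   vtab$pos[v] <= molStart + fl - 1L)
      carriage[[v]] <- cov[runif(length(cov)) < vtab$af[v]]
    }
  }

  ## molecule-level CpG dyad states (dyads whose C falls in [start-1, end])
  molRanges <- IRanges(molG - 1L, molG + fl - 1L)
  ov <- findOverlaps(molRanges, IRanges(cpg$gpos, width = 1L))
  stM <- queryHits(ov); stS <- subjectHits(ov)
  stState <- runif(length(stM)) < cpg$beta[stS]
  stateKey <- paste0(stM, "_", cpg$gpos[stS])

  ## --- strand expansion ---------------------------------------------------
  nProt <- nProtectedStrands(cfg@copyCycles)
  perMol <- 2L * (1L + nProt)
  strMol <- rep(seq_len(nMol), each = perMol)
  strOrigin <- rep(rep(c("WATSON", "CRICK"), each = 1L + nProt), nMol)
  strStream <- rep(rep(c("METH", rep("GENET", nProt)), 2L), nMol)
  keep <- runif(length(strMol)) < cfg@strandSurvival
  strMol <- strMol[keep]; strOrigin <- strOrigin[keep]
  strStream <- strStream[keep]
  nStr <- length(strMol)
  if (!nStr) stop("no strands survived; increase nMolecules or survival")

  ## --- UMI observation per strand ----------------------------------------
  u1i <- sample.int(length(cfg@pool@umis), nMol, replace = TRUE)
  u2i <- sample.int(length(cfg@pool@umis), nMol, replace = TRUE)
  poolU <- cfg@pool@umis
  pu1 <- poolU[u1i[strMol]]; pu2 <- poolU[u2i[strMol]]
  isW <- strOrigin == "WATSON"; isMeth <- strStream == "METH"
  ## mate-1 reads the sequenced strand itself (C-to-T events visible);
  ## mate-2 reads its PCR complement (the same events appear as G-to-A)
  mate1src <- ifelse(isMeth, ifelse(isW, pu1, pu2),
                     ifelse(isW, pu2, pu1))
  mate2src <- ifelse(isMeth, ifelse(isW, pu2, pu1),
                     ifelse(isW, pu1, pu2))
  pConv <- ifelse(isMeth, cfg@conversionSensitivity,
                  1 - cfg@analogResistance)
  obsU1 <- character(nStr); obsU2 <- character(nStr)
  obsU1[isMeth] <- .stochCollapse(mate1src[isMeth],
                                  cfg@conversionSensitivity, "C2T")
  obsU2[isMeth] <- .stochCollapse(mate2src[isMeth],
                                  cfg@conversionSensitivity, "G2A")
  obsU1[!isMeth] <- .stochCollapse(mate1src[!isMeth],
                                   1 - cfg@analogResistance, "C2T")
  obsU2[!isMeth] <- .stochCollapse(mate2src[!isMeth],
                                   1 - cfg@analogResistance, "G2A")

  ## --- methylation-stream cytosine observations ---------------------------
  methIdx <- which(isMeth)
  methPosL <- methStateL <- NULL
  plusSub <- NULL   # per meth strand: plus-oriented substitutions (for reads)
  if (length(methIdx)) {
    ## per-molecule plus-strand C and G positions (global coords)
    isC <- globalRef == "C"; isG <- globalRef == "G"
    cPos <- which(isC); gPos <- which(isG)
    ovC <- findOverlaps(IRanges(molG, width = fl), IRanges(cPos, width = 1L))
    ovG <- findOverlaps(IRanges(molG, width = fl), IRanges(gPos, width = 1L))
    cByMol <- splitAsList(cPos[subjectHits(ovC)],
                          factor(queryHits(ovC), levels = seq_len(nMol)))
    gByMol <- splitAsList(gPos[subjectHits(ovG)],
                          factor(queryHits(ovG), levels = seq_len(nMol)))
    mMol <- strMol[methIdx]; mW <- isW[methIdx]
    posL <- vector("list", length(methIdx))
    posL[mW] <- as.list(cByMol[mMol[mW]])
    posL[!mW] <- as.list(gByMol[mMol[!mW]])
    npos <- lengths(posL)
    posV <- unlist(posL, use.names = FALSE)
    sIdx <- rep(seq_along(methIdx), npos)
    wV <- rep(mW, npos)
    ## context and dyad key: Watson C at p is CpG iff ref[p+1] == G;
    ## Crick C (plus G at p) is CpG iff ref[p-1] == C, dyad keyed at p-1
    isCpG <- ifelse(wV,
                    c(globalRef, "N")[posV + 1L] == "G",
                    c("N", globalRef)[posV] == "C")
    dyad <- ifelse(wV, posV, posV - 1L)
    key <- paste0(mMol[sIdx], "_", dyad)
    dyState <- rep(FALSE, length(posV))
    hit <- match(key[isCpG], stateKey)
    hitIdx <- ifelse(is.na(hit), 1L, hit)
    dyState[isCpG] <- !is.na(hit) & stState[hitIdx]
    ## observed state: methylated dyads survive conversion w.p. specificity;
    ## everything else converts w.p. sensitivity
    pMeth <- ifelse(dyState, cfg@conversionSpecificity,
                    1 - cfg@conversionSensitivity)
    obsMeth <- runif(length(posV)) < pMeth
    f <- factor(sIdx, levels = seq_along(methIdx))
    localPos <- posV - offsets[molContig[mMol[sIdx]]]
    methPosL <- splitAsList(as.integer(localPos), f)
    methStateL <- splitAsList(obsMeth, f)
    if (emitReads)
      plusSub <- list(sIdx = sIdx, pos = posV, w = wV, obs = obsMeth)
  }

  ## --- genetic-stream base calls (plus orientation) ------------------------
  genIdx <- which(!isMeth)
  genBases <- NULL
  if (length(genIdx)) {
    gm <- matrix(globalRef[outer(molG[strMol[genIdx]], 0:(fl - 1L), "+")],
                 nrow = length(genIdx))
    if (nrow(vtab)) for (v in seq_len(nrow(vtab))) {
      hit <- which(strMol[genIdx] %in% carriage[[v]])
      if (length(hit))
        gm[cbind(hit, vtab$pos[v] - molStart[strMol[genIdx[hit]]] + 1L)] <-
          vtab$alt[v]
    }
    ## copy of a Watson original is Crick-sense: its conversion errors show
    ## as G-to-A in plus orientation; copy of Crick shows C-to-T
    wRows <- isW[genIdx]
    err <- matrix(runif(length(gm)) < 1 - cfg@analogResistance, nrow(gm))
    hitGA <- gm == "G" & err & wRows
    hitCT <- gm == "C" & err & !wRows
    gm[hitGA] <- "A"; gm[hitCT] <- "T"
    genBases <- .pasteRows(gm)
  }

  ## --- read sequences ------------------------------------------------------
  reads <- NULL
  mate1seq <- mate2seq <- NULL
  if (emitReads) {
    plusObs <- character(nStr)
    if (length(genIdx)) plusObs[genIdx] <- genBases
    if (length(methIdx)) {
      mm <- matrix(globalRef[outer(molG[strMol[methIdx]], 0:(fl - 1L), "+")],
                   nrow = length(methIdx))
      if (!is.null(plusSub)) {
        col <- plusSub$pos - molG[strMol[methIdx[plusSub$sIdx]]] + 1L
        conv <- !plusSub$obs
        ## converted Watson C reads T; converted Crick C reads A in plus
        mm[cbind(plusSub$sIdx[conv & plusSub$w], col[conv & plusSub$w])] <- "T"
        mm[cbind(plusSub$sIdx[conv & !plusSub$w],
                 col[conv & !plusSub$w])] <- "A"
      }
      plusObs[methIdx] <- .pasteRows(mm)
    }
    rcObs <- as.character(reverseComplement(DNAStringSet(plusObs)))
    ## Watson-sense sequenced strands: METH Watson originals and copies of
    ## Crick originals; everything else is Crick-sense
    plusSense <- (isMeth & isW) | (!isMeth & !isW)
    strandSeq <- ifelse(plusSense, plusObs, rcObs)
    strandSeqRC <- ifelse(plusSense, rcObs, plusObs)
    mate1seq <- paste0(obsU1, strandSeq)
    mate2seq <- paste0(obsU2, strandSeqRC)
  }

  ## --- PCR duplication and assembly ---------------------------------------
  nDup <- rbinom(nStr, 1L, cfg@pcrDuplicateRate)
  emit <- rep(seq_len(nStr), 1L + nDup)
  isDup <- sequence(1L + nDup) > 1L
  flag1 <- ifelse(isMeth, ifelse(isW, 67L, 115L), ifelse(isW, 99L, 83L))
  flag2 <- ifelse(isMeth, ifelse(isW, 131L, 179L), ifelse(isW, 147L, 163L))

  frags <- MMFragments(contig = molContig[strMol[emit]],
                       start = molStart[strMol[emit]],
                       end = molStart[strMol[emit]] + fl - 1L,
                       stream = strStream[emit],
                       umi1 = obsU1[emit], umi2 = obsU2[emit],
                       flag1 = flag1[emit], flag2 = flag2[emit],
                       molId = strMol[emit])
  if (length(genIdx)) {
    bases <- rep(NA_character_, nStr)
    bases[genIdx] <- genBases
    mcols(frags)$bases <- bases[emit]
  }
  if (length(methIdx)) {
    allPos <- splitAsList(integer(0L), factor(integer(0L),
                                              levels = seq_len(nStr)))
    allPos[methIdx] <- methPosL
    allState <- splitAsList(logical(0L), factor(integer(0L),
                                                levels = seq_len(nStr)))
    allState[methIdx] <- methStateL
    mcols(frags)$methPos <- allPos[emit]
    mcols(frags)$methState <- as(allState[emit], "LogicalList")
  }

  truth <- DataFrame(readId = paste0("rp", seq_along(emit)),
                     molId = strMol[emit], duplexStrand = strOrigin[emit],
                     stream = strStream[emit],
                     poolUmi1 = pu1[emit], poolUmi2 = pu2[emit],
                     isDuplicate = isDup)
  if (emitReads)
    reads <- readPairSet(mate1seq[emit], mate2seq[emit],
                         id = truth$readId, umiLength = cfg@umiLength)

  list(reads = reads, truth = truth, fragments = frags,
       reference = reference, cpgTruth = cpgTruth,
       variants = vtab, nStrands = nStr)
}

## bimodal CpG methylation landscape: 50/50 mixture of a hypomethylated
## Beta(0.5, 8) and a hypermethylated Beta(8, 0.5) mode (genome-wide mean
## ~0.5, matching whole-genome methylomes)
.bimodalBetas <- function(n) {
  hyper <- runif(n) < 0.5
  b <- rbeta(n, 0.5, 8)
  b[hyper] <- rbeta(sum(hyper), 8, 0.5)
  b
}
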