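## fast path key: contig / duplex strand class / exact coords
.coordKey <- function(frags) {
  mc <- mcols(frags)
  paste(as.character(seqnames(frags)),
        strandClass(mc$flag1, mc$flag2, mc$stream),
        start(frags), end(frags), sep = "|")
}

.checkSorted <- function(frags) {
  if (!length(frags)) return(invisible(TRUE))
  ct <- as.character(seqnames(frags))
  r <- rle(ct)
  if (anyDuplicated(r$values))
    stop("fragments must be sorted by contig/start")
  bad <- vapply(split(start(frags), factor(ct, levels = r$values)),
                is.unsorted, logical(1L))
  if (any(bad))
    stop("fragments must be sorted by contig/start")
  invisible(TRUE)
}

#' Cluster fragments into duplicate groups
#'
#' Fragments belong to the same cluster when they share contig and duplex
#' strand class, their start and end coordinates each differ from the
#' cluster representative's by at most `coordTolerance`, and (when
#' `umiAware`) each mate's UMI is within `maxUmiMismatch` Hamming distance
#' of the representative's. The representative is the first member in
#' sort order, making the clustering deterministic and order-invariant for
#' sorted input.
#'
#' @param frags sorted [MMFragments-class].
#' @param coordTolerance coordinate tolerance in bp (default 0).
#' @param umiAware compare UMIs (default FALSE).
#' @param maxUmiMismatch per-mate UMI mismatch allowance (default 1).
#' @return integer vector of cluster ids (1-based, in order of first
#'   appearance).
#' @export
clusterFragments <- function(frags, coordTolerance = 0L, umiAware = FALSE,
                             maxUmiMismatch = 1L) {
  .checkSorted(frags)
  n <- length(frags)
  if (!n) return(integer(0L))
  if (coordTolerance == 0L && !umiAware) {
    key <- .coordKey(frags)
    return(as.integer(match(key, unique(key))))
  }
  mc <- mcols(frags)
  grpKey <- paste(as.character(seqnames(frags)),
                  strandClass(mc$flag1, mc$flag2, mc$stream), sep = "|")
  st <- start(frags); en <- end(frags)
  u1 <- mc$umi1; u2 <- mc$umi2
  ids <- integer(n)
  nextId <- 0L
  for (grp in split(seq_len(n), factor(grpKey, levels = unique(grpKey)))) {
    open <- list()  # each: list(idx, start, end, umi1, umi2, id)
    lo <- 1L
    for (i in grp) {
      ## retire clusters whose representative starts > tol before i
      while (lo <= length(open) &&
             open[[lo]]$start < st[i] - coordTolerance) lo <- lo + 1L
      assigned <- FALSE
      j <- lo
      while (j <= length(open)) {
        cl <- open[[j]]
        if (abs(st[i] - cl$start) <= coordTolerance &&
            abs(en[i] - cl$end) <= coordTolerance &&
            (!umiAware ||
             (umiHamming(u1[i], cl$umi1) <= maxUmiMismatch &&
              umiHamming(u2[i], cl$umi2) <= maxUmiMismatch))) {
          ids[i] <- cl$id
          assigned <- TRUE
          break
        }
        j <- j + 1L
      }
      if (!assigned) {
        nextId <- nextId + 1L
        ids[i] <- nextId
        open[[length(open) + 1L]] <- list(start = st[i], end = en[i],
                                          umi1 = u1[i], umi2 = u2[i],
                                          id = nextId)
      }
    }
  }
  as.integer(match(ids, unique(ids)))
}

#' Remove duplicate fragments
#'
#' Two presets mirror the pipeline's two distinct duplicate definitions:
#' methylation-stream deduplication uses exact coordinates without UMIs
#' (MarkDuplicates-equivalent; the defaults), while duplicate-rate QC for
#' the genetic stream uses `coordTolerance = 5`, `umiAware = TRUE`,
#' `maxUmiMismatch = 1` ("same genomic coordinates within five base pairs
#' and UMI sequences with no more than 1 mismatch").
#'
#' @inheritParams clusterFragments
#' @return list with `unique` (one representative per cluster, first in
#'   sort order), `duplicateRate` (`1 - unique/total`) and `clusters`
#'   (cluster id per input fragment).
#' @export
deduplicateFragments <- function(frags, coordTolerance = 0L,
                                 umiAware = FALSE, maxUmiMismatch = 1L) {
  ids <- clusterFragments(frags, coordTolerance, umiAware, maxUmiMismatch)
  rep_ <- which(!duplicated(ids))
  list(unique = frags[rep_],
       duplicateRate = if (length(frags))
         1 - length(rep_) / length(frags) else NA_real_,
       clusters = ids)
}

.refCharList <- function(reference) {
  lapply(setNames(as.character(reference), names(reference)),
         function(s) strsplit(s, "", fixed = TRUE)[[1L]])
}

#' Call per-cytosine methylation from methylation-stream fragments
#'
#' Aggregates the observed cytosine states carried by deduplicated
#' methylation fragments into per-site methylated/unmethylated counts and
#' beta values, in CpG, CHG and CHH context. Plus- and minus-strand calls
#' at a CpG dyad are merged into one site keyed by the plus-strand C (the
#' standard CX-report convention); CHG/CHH sites stay strand-resolved at
#' their own position.
#'
#' @param frags [MMFragments-class] (methylation stream, with `methPos` /
#'   `methState`).
#' @param reference `DNAStringSet` of the contigs.
#' @return `GRanges` with metadata columns `nMeth`, `nUnmeth`, `beta`,
#'   `context` (`"CpG"`, `"CHG"`, `"CHH"`).
#' @export
callMethylation <- function(frags, reference) {
  mc <- mcols(frags)
  frags <- frags[mc$stream == "METH"]
  mc <- mcols(frags)
  if (is.null(mc$methPos)) {
    if (is.null(mc$bases))
      stop("fragments carry no methylation states or base calls")
    frags <- deriveMethStates(frags, reference)
    mc <- mcols(frags)
  }
  miss <- setdiff(unique(as.character(seqnames(frags))), names(reference))
  if (length(miss))
    stop(sprintf("contig(s) not in reference: %s",
                 paste(miss, collapse = ", ")))
  refc <- .refCharList(reference)
  pos <- unlist(mc$methPos, use.names = FALSE)
  state <- unlist(mc$methState, use.names = FALSE)
  contig <- rep(as.character(seqnames(frags)), lengths(mc$methPos))
  if (!length(pos))
    return(GRanges(nMeth = integer(0L), nUnmeth = integer(0L),
                   beta = numeric(0L), context = character(0L)))
  at <- function(ct, p) {  # reference base with out-of-range -> "N"
    out <- rep("N", length(p))
    for (c_ in unique(ct)) {
      sel <- ct == c_
      ok <- sel & p >= 1L & p <= length(refc[[c_]])
      out[ok] <- refc[[c_]][p[ok]]
    }
    out
  }
  base0 <- at(contig, pos)
  if (any(!base0 %in% c("C", "G")))
    stop("reference mismatch: methylation state at a non-C/G reference base")
  plus <- base0 == "C"
  nxt1 <- at(contig, ifelse(plus, pos + 1L, pos - 1L))
  nxt2 <- at(contig, ifelse(plus, pos + 2L, pos - 2L))
  partner <- ifelse(plus, "G", "C")
  context <- ifelse(nxt1 == partner, "CpG",
                    ifelse(nxt2 == partner, "CHG", "CHH"))
  site <- ifelse(context == "CpG" & !plus, pos - 1L, pos)
  key <- paste(contig, site, context, sep = "|")
  uk <- unique(key)
  idx <- match(key, uk)
  nMeth <- as.integer(rowsum(as.integer(state), idx)[, 1L])
  nUnmeth <- as.integer(rowsum(as.integer(!state), idx)[, 1L])
  parts <- strsplit(uk, "|", fixed = TRUE)
  out <- GRanges(vapply(parts, `[`, character(1L), 1L),
                 IRanges(as.integer(vapply(parts, `[`, character(1L), 2L)),
                         width = 1L),
                 nMeth = nMeth, nUnmeth = nUnmeth,
                 beta = nMeth / (nMeth + nUnmeth),
                 context = vapply(parts, `[`, character(1L), 3L))
  sort(out)
}

#' Derive per-cytosine methylation states from base calls
#'
#' The converted-read path of methylation calling: a Watson-original
#' fragment reports the plus-strand cytosines (read C = methylated,
#' read T = converted/unmethylated); a Crick-original fragment reports the
#' plus-strand guanines (read G = methylated, read A = converted). Other
#' base calls at those positions (variants, masked bases) are dropped.
#'
#' @param frags methylation-stream [MMFragments-class] with `bases`.
#' @param reference `DNAStringSet`.
#' @return the fragments with `methPos`/`methState` columns filled in.
#' @export
deriveMethStates <- function(frags, reference) {
  mc <- mcols(frags)
  refc <- .refCharList(reference)
  w <- width(frags)
  obs <- unlist(strsplit(mc$bases, "", fixed = TRUE), use.names = FALSE)
  pos <- rep(start(frags), w) + sequence(w) - 1L
  contig <- rep(as.character(seqnames(frags)), w)
  fi <- rep(seq_along(frags), w)
  isW <- rep(strandClass(mc$flag1, mc$flag2, mc$stream) == "WATSON", w)
  refb <- rep("N", length(pos))
  for (c_ in unique(contig)) {
    if (!c_ %in% names(refc))
      stop(sprintf("contig '%s' not in reference", c_))
    sel <- contig == c_
    refb[sel] <- refc[[c_]][pos[sel]]
  }
  keep <- (isW & refb == "C" & obs %in% c("C", "T")) |
    (!isW & refb == "G" & obs %in% c("G", "A"))
  f <- factor(fi[keep], levels = seq_along(frags))
  mcols(frags)$methPos <- splitAsList(pos[keep], f)
  mcols(frags)$methState <- splitAsList(obs[keep] == refb[keep], f)
  frags
}

#' C-to-T / G-to-A substitution rate in the genetic stream
#'
#' Fraction of covered reference C positions read as T plus covered
#' reference G positions read as A, over all covered reference C/G
#' positions — the residual-deamination QC metric of the protected copy
#' strands.
#'
#' @param frags [MMFragments-class] genetic-stream fragments with `bases`.
#' @param reference `DNAStringSet`.
#' @param region optional `GRanges` restricting the assessed positions
#'   (e.g. an exome BED).
#' @return rate in `[0, 1]` (`NA` when no C/G position is covered).
#' @export
ctgaSubstitutionRate <- function(frags, reference, region = NULL) {
  mc <- mcols(frags)
  frags <- frags[mc$stream == "GENET" & !is.na(mc$bases)]
  if (!length(frags)) return(NA_real_)
  refc <- .refCharList(reference)
  w <- width(frags)
  obs <- unlist(strsplit(mcols(frags)$bases, "", fixed = TRUE),
                use.names = FALSE)
  pos <- rep(start(frags), w) + sequence(w) - 1L
  contig <- rep(as.character(seqnames(frags)), w)
  if (!is.null(region)) {
    keep <- overlapsAny(GRanges(contig, IRanges(pos, width = 1L)), region)
    obs <- obs[keep]; pos <- pos[keep]; contig <- contig[keep]
  }
  refb <- rep("N", length(pos))
  for (c_ in unique(contig)) {
    sel <- contig == c_
    refb[sel] <- refc[[c_]][pos[sel]]
  }
  isC <- refb == "C"; isG <- refb == "G"
  denom <- sum(isC) + sum(isG)
  if (!denom) return(NA_real_)
  (sum(isC & obs == "T") + sum(isG & obs == "A")) / denom
}

#' Spike-in conversion QC
#'
#' Sensitivity is the proportion of converted (read unmethylated)
#' cytosines on the fully unmethylated lambda-like analog (all contexts);
#' specificity is the proportion of unconverted (read methylated) CpG
#' cytosines on the fully CpG-methylated pUC19-like analog. Optionally
#' also reports the C-to-T/G-to-A substitution rate of the genetic stream
#' over a QC region.
#'
#' @param calls `GRanges` from [callMethylation()].
#' @param lambdaContig,puc19Contig spike-in contig names.
#' @param genetFrags optional genetic-stream [MMFragments-class].
#' @param reference required when `genetFrags` is given.
#' @param qcRegion optional `GRanges` for the substitution-rate QC.
#' @return list(`sensitivity`, `specificity`, `ctga_substitution_rate`);
#'   components are `NA` (flagged undefined) when no covered cytosine
#'   supports them.
#' @export
conversionQC <- function(calls, lambdaContig = "lambda",
                         puc19Contig = "puc19", genetFrags = NULL,
                         reference = NULL, qcRegion = NULL) {
  lam <- calls[as.character(seqnames(calls)) == lambdaContig]
  puc <- calls[as.character(seqnames(calls)) == puc19Contig &
                 calls$context == "CpG"]
  tot <- function(x) sum(x$nMeth) + sum(x$nUnmeth)
  sens <- if (tot(lam)) sum(lam$nUnmeth) / tot(lam) else NA_real_
  spec <- if (tot(puc)) sum(puc$nMeth) / tot(puc) else NA_real_
  ctga <- if (!is.null(genetFrags))
    ctgaSubstitutionRate(genetFrags, reference, qcRegion) else NA_real_
  list(sensitivity = sens, specificity = spec,
       ctga_substitution_rate = ctga)
}

#' Recovery of a spike-in methylation dilution series
#'
#' Aggregates CpG calls per dilution contig into a count-weighted mean
#' beta and correlates the estimates with the configured levels.
#'
#' @param calls `GRanges` from [callMethylation()].
#' @param dilutionTruth named numeric: contig -> configured methylation
#'   level (proportions).
#' @return list with `perLevel` (data.frame: contig, truth, meanBeta,
#'   nSites, nObservations) and `pearsonR` (`NA`, flagged, when the truth
#'   levels are degenerate).
#' @export
dilutionRecovery <- function(calls, dilutionTruth) {
  if (length(dilutionTruth) < 2L)
    stop("need at least two dilution levels")
  per <- do.call(rbind, lapply(names(dilutionTruth), function(ct) {
    x <- calls[as.character(seqnames(calls)) == ct & calls$context == "CpG"]
    tot <- sum(x$nMeth) + sum(x$nUnmeth)
    data.frame(contig = ct, truth = dilutionTruth[[ct]],
               meanBeta = if (tot) sum(x$nMeth) / tot else NA_real_,
               nSites = length(x), nObservations = tot,
               stringsAsFactors = FALSE)
  }))
  r <- if (stats::sd(per$truth) > 0 && sum(!is.na(per$meanBeta)) >= 2L &&
           stats::sd(per$meanBeta, na.rm = TRUE) > 0)
    cor(per$truth, per$meanBeta, use = "complete.obs") else NA_real_
  list(perLevel = per, pearsonR = r)
}
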