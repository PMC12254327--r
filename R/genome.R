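#' Collapse duplicate genetic-stream fragments into consensus fragments
#'
#' Clusters fragments sharing coordinates within 5 bp and UMI pairs within
#' 1 mismatch per mate (the duplicate definition of the genetic stream),
#' then takes a per-position majority base across cluster members;
#' positions where the majority base falls below `minAgreement` of the
#' covering members are masked to N. The consensus fragment takes the
#' representative's span and UMIs and carries the cluster size as `depth`.
#'
#' @param frags sorted genetic-stream [MMFragments-class] with `bases`.
#' @param coordTolerance coordinate tolerance (default 5).
#' @param maxUmiMismatch per-mate UMI mismatch allowance (default 1).
#' @param minAgreement minimum within-cluster agreement to keep the
#'   majority base (default 0.70).
#' @return [MMFragments-class] of consensus fragments with a `depth`
#'   metadata column.
#' @export
clusterConsensus <- function(frags, coordTolerance = 5L,
                             maxUmiMismatch = 1L, minAgreement = 0.70) {
  ids <- clusterFragments(frags, coordTolerance, umiAware = TRUE,
                          maxUmiMismatch = maxUmiMismatch)
  if (!length(frags)) return(frags)
  repIdx <- which(!duplicated(ids))
  size <- as.integer(table(ids)[as.character(ids[repIdx])])
  multi <- which(size > 1L)
  bases <- mcols(frags)$bases
  consensus <- bases[repIdx]
  st <- start(frags)
  for (k in multi) {
    mem <- which(ids == ids[repIdx[k]])
    rs <- st[repIdx[k]]
    w <- width(frags)[repIdx[k]]
    chars <- matrix("N", length(mem), w)
    for (j in seq_along(mem)) {
      b <- strsplit(bases[mem[j]], "", fixed = TRUE)[[1L]]
      off <- st[mem[j]] - rs  # may be negative within tolerance
      src <- seq_along(b) + off
      keep <- src >= 1L & src <= w
      chars[j, src[keep]] <- b[seq_along(b)][keep]
    }
    cons <- vapply(seq_len(w), function(p) {
      col <- chars[, p]
      col <- col[col != "N"]
      if (!length(col)) return("N")
      tab <- sort(table(col), decreasing = TRUE)
      if (tab[1L] / length(col) < minAgreement) "N" else names(tab)[1L]
    }, character(1L))
    consensus[k] <- paste(cons, collapse = "")
  }
  out <- frags[repIdx]
  mcols(out)$bases <- consensus
  mcols(out)$depth <- size
  out
}

#' Per-position base pileup from fragments
#'
#' @param frags [MMFragments-class] with `bases`.
#' @param reference `DNAStringSet`.
#' @return data.frame(contig, pos, ref, A, C, G, T, depth); `depth` counts
#'   A/C/G/T calls only (N calls are excluded).
#' @export
pileupFromFragments <- function(frags, reference) {
  frags <- frags[!is.na(mcols(frags)$bases)]
  if (!length(frags))
    return(data.frame(contig = character(0L), pos = integer(0L),
                      ref = character(0L), A = integer(0L), C = integer(0L),
                      G = integer(0L), T = integer(0L), depth = integer(0L)))
  refc <- .refCharList(reference)
  w <- width(frags)
  obs <- unlist(strsplit(mcols(frags)$bases, "", fixed = TRUE),
                use.names = FALSE)
  pos <- rep(start(frags), w) + sequence(w) - 1L
  contig <- rep(as.character(seqnames(frags)), w)
  keep <- obs %in% c("A", "C", "G", "T")
  obs <- obs[keep]; pos <- pos[keep]; contig <- contig[keep]
  key <- paste(contig, pos, sep = "|")
  uk <- unique(key)
  idx <- match(key, uk)
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    as.integer(rowsum(as.integer(obs == b), idx)[, 1L]),
    integer(length(uk)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL,
                                               c("A", "C", "G", "T")))
  parts <- strsplit(uk, "|", fixed = TRUE)
  uct <- vapply(parts, `[`, character(1L), 1L)
  upos <- as.integer(vapply(parts, `[`, character(1L), 2L))
  refb <- rep("N", length(uk))
  for (c_ in unique(uct)) {
    sel <- uct == c_
    if (!c_ %in% names(refc))
      stop(sprintf("contig '%s' not in reference", c_))
    refb[sel] <- refc[[c_]][upos[sel]]
  }
  out <- data.frame(contig = uct, pos = upos, ref = refb,
                    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
                    T = counts[, "T"], stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' Call germline SNPs from a pileup with the standard co-detection filters
#'
#' A deliberately simple substitution caller: every non-reference base at
#' a position is emitted when it passes all three filters — minimum
#' coverage, minimum supporting reads, minimum variant allele fraction.
#' No genotype model is applied.
#'
#' @param pileup data.frame from [pileupFromFragments()].
#' @param minCoverage minimum position depth (default 10).
#' @param minAltReads minimum supporting reads (default 2).
#' @param minVAF minimum variant allele fraction (default 0.15).
#' @return data.frame(contig, pos, ref, alt, depth, alt_count, vaf).
#' @export
callGermlineSNPs <- function(pileup, minCoverage = 10L, minAltReads = 2L,
                             minVAF = 0.15) {
  out <- NULL
  for (b in c("A", "C", "G", "T")) {
    sel <- pileup$ref != b & pileup$depth >= minCoverage &
      pileup[[b]] >= minAltReads &
      pileup[[b]] / pileup$depth >= minVAF
    if (any(sel))
      out <- rbind(out, data.frame(
        contig = pileup$contig[sel], pos = pileup$pos[sel],
        ref = pileup$ref[sel], alt = b, depth = pileup$depth[sel],
        alt_count = pileup[[b]][sel],
        vaf = pileup[[b]][sel] / pileup$depth[sel],
        stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(contig = character(0L), pos = integer(0L),
                      ref = character(0L), alt = character(0L),
                      depth = integer(0L), alt_count = integer(0L),
                      vaf = numeric(0L))
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}

#' Filter somatic variant candidates with the standard exclusion rules
#'
#' Keeps a variant iff it has at least `minAltReads` supporting reads, a
#' VAF of at least `minVAF`, is not a C-to-T or G-to-A substitution
#' (deamination artifacts of the protected strands; retained in DNA-seq
#' comparison mode), is not present in the paired white blood cell sample
#' (clonal hematopoiesis), and is not annotated synonymous/intron/UTR.
#' A pure predicate: the output is a subset of the input and independent
#' of row order.
#'
#' @param variants data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `alt_count`, `vaf`, `annotation` (one of `"synonymous"`, `"intron"`,
#'   `"utr"`, `"other"`); an optional logical `in_wbc` column is used when
#'   `wbcVariants` is `NULL`.
#' @param wbcVariants optional data.frame of white-blood-cell variants
#'   (matched on contig/pos/ref/alt).
#' @param minAltReads minimum supporting reads (default 5).
#' @param minVAF minimum VAF (default 0.001, i.e. 0.1%).
#' @param retainCtga keep C-to-T/G-to-A substitutions (DNA-seq comparison
#'   mode; default FALSE).
#' @return the kept subset of `variants`.
#' @export
filterSomatic <- function(variants, wbcVariants = NULL, minAltReads = 5L,
                          minVAF = 0.001, retainCtga = FALSE) {
  if (!nrow(variants)) return(variants)
  inWbc <- if (!is.null(wbcVariants)) {
    if (nrow(wbcVariants))
      paste(variants$contig, variants$pos, variants$ref, variants$alt) %in%
        paste(wbcVariants$contig, wbcVariants$pos, wbcVariants$ref,
              wbcVariants$alt)
    else rep(FALSE, nrow(variants))
  } else if (!is.null(variants$in_wbc)) variants$in_wbc
  else rep(FALSE, nrow(variants))
  isCtga <- (variants$ref == "C" & variants$alt == "T") |
    (variants$ref == "G" & variants$alt == "A")
  ann <- if (!is.null(variants$annotation)) variants$annotation
         else rep("other", nrow(variants))
  keep <- variants$alt_count >= minAltReads & variants$vaf >= minVAF &
    (retainCtga | !isCtga) & !inWbc & ann == "other"
  variants[keep, , drop = FALSE]
}

#' Bin a coverage track into copy-ratio bins with GC correction
#'
#' Bins with mean coverage below `minCoverage` are dropped; the copy ratio
#' of each kept bin is its coverage over the median coverage of all kept
#' bins; a LOWESS fit of copy ratio against GC fraction is divided out
#' (when GC varies), and the copy number is twice the corrected ratio
#' (diploid baseline).
#'
#' @param track data.frame(contig, start, end, coverage, gc) of
#'   non-overlapping bins (1-based closed spans).
#' @param binSize expected bin size (default 10 kb); a short trailing bin
#'   per contig is dropped.
#' @param minCoverage minimum mean coverage to keep a bin (default 1).
#' @param lowessF LOWESS smoother span (default 0.3).
#' @return data.frame(contig, start, end, coverage, gc, copy_ratio,
#'   gc_corrected_ratio, copy_number).
#' @export
cnvBins <- function(track, binSize = 10000L, minCoverage = 1,
                    lowessF = 0.3) {
  full <- track$end - track$start + 1L == binSize
  track <- track[full & track$coverage >= minCoverage, , drop = FALSE]
  if (!nrow(track))
    stop("all bins filtered out")
  track$copy_ratio <- track$coverage / median(track$coverage)
  if (length(unique(track$gc)) < 2L || stats::sd(track$gc) == 0) {
    fitted <- rep(median(track$copy_ratio), nrow(track))
  } else {
    lw <- lowess(track$gc, track$copy_ratio, f = lowessF)
    fitted <- approx(lw$x, lw$y, xout = track$gc, rule = 2L)$y
  }
  fitted[fitted <= 0] <- NA_real_
  track$gc_corrected_ratio <- track$copy_ratio / fitted
  track$copy_number <- 2 * track$gc_corrected_ratio
  track
}

#' Segment copy-number bins into candidate CNV calls
#'
#' Maximal runs of at least `minConsecutive` bins with copy number above
#' `gainThreshold` (gain) or below `lossThreshold` (loss).
#'
#' @param bins data.frame from [cnvBins()], ordered per contig.
#' @param gainThreshold copy number above which a bin is a gain candidate
#'   (default 3.5).
#' @param lossThreshold copy number below which a bin is a loss candidate
#'   (default 0.5).
#' @param minConsecutive minimum run length in bins (default 3).
#' @return data.frame(contig, start, end, type, n_bins, mean_copy_number).
#' @export
cnvSegments <- function(bins, gainThreshold = 3.5, lossThreshold = 0.5,
                        minConsecutive = 3L) {
  out <- NULL
  for (ct in unique(bins$contig)) {
    b <- bins[bins$contig == ct, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    state <- ifelse(b$copy_number > gainThreshold, "gain",
                    ifelse(b$copy_number < lossThreshold, "loss",
                           "neutral"))
    ## consecutive in genomic terms: a gap between bins breaks the run
    gap <- c(FALSE, b$start[-1L] != b$end[-nrow(b)] + 1L)
    runId <- cumsum(c(TRUE, state[-1L] != state[-length(state)]) | gap)
    for (r in unique(runId)) {
      sel <- runId == r
      if (state[which(sel)[1L]] == "neutral" || sum(sel) < minConsecutive)
        next
      out <- rbind(out, data.frame(
        contig = ct, start = min(b$start[sel]), end = max(b$end[sel]),
        type = state[which(sel)[1L]], n_bins = sum(sel),
        mean_copy_number = mean(b$copy_number[sel]),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(contig = character(0L), start = integer(0L),
                      end = integer(0L), type = character(0L),
                      n_bins = integer(0L), mean_copy_number = numeric(0L))
  out
}
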