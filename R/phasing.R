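## canonical (sorted) pool-UMI pair per fragment, or NA when the fragment
## cannot be mapped back to the pool under its stream's expected match modes
.canonicalUmiPair <- function(frags, pool) {
  mc <- mcols(frags)
  m1 <- matchUMI(mc$umi1, pool)
  m2 <- matchUMI(mc$umi2, pool)
  conv <- c("C2T", "G2A")
  ok <- ifelse(mc$stream == "GENET",
               m1$mode == "EXACT" & m2$mode == "EXACT",
               m1$mode %in% conv & m2$mode %in% conv)
  a <- pmin(m1$match, m2$match)
  b <- pmax(m1$match, m2$match)
  out <- paste(a, b, sep = "-")
  out[!ok] <- NA_character_
  out
}

#' Pair genetic- and methylation-stream fragments from the same duplex
#'
#' Two fragments are considered to originate from the same double-stranded
#' molecule when they have (1) identical mapping coordinates, (2) paired
#' original and converted UMIs (the methylation fragment's UMIs are the
#' conversion collapse of the genetic fragment's pool UMIs), and
#' (3) consistent strand origin: Watson (genetic flags 99/147 with
#' methylation flags 67/131) or Crick (83/163 with 115/179). Matching is
#' greedy one-to-one in sort order on the join key, so each fragment is
#' used at most once and ambiguous multi-candidate joins resolve
#' deterministically.
#'
#' @param genetFrags,methFrags deduplicated [MMFragments-class] per stream.
#' @param pool a [UMIPool-class].
#' @return list with `pairs` (`DataFrame`: `genetIdx`, `methIdx`,
#'   `strand`) and `pairingRate` (paired fraction of the methylation
#'   fragments).
#' @export
pairDuplex <- function(genetFrags, methFrags, pool) {
  gmc <- mcols(genetFrags); mmc <- mcols(methFrags)
  gStrand <- strandClass(gmc$flag1, gmc$flag2, gmc$stream)
  mStrand <- strandClass(mmc$flag1, mmc$flag2, mmc$stream)
  gUmi <- .canonicalUmiPair(genetFrags, pool)
  mUmi <- .canonicalUmiPair(methFrags, pool)
  gKey <- paste(as.character(seqnames(genetFrags)), start(genetFrags),
                end(genetFrags), gStrand, gUmi, sep = "|")
  mKey <- paste(as.character(seqnames(methFrags)), start(methFrags),
                end(methFrags), mStrand, mUmi, sep = "|")
  gKey[is.na(gStrand) | is.na(gUmi)] <- NA_character_
  mKey[is.na(mStrand) | is.na(mUmi)] <- NA_character_
  ## k-th occurrence of a key on one side joins the k-th on the other
  gOcc <- stats::ave(seq_along(gKey), gKey, FUN = seq_along)
  mOcc <- stats::ave(seq_along(mKey), mKey, FUN = seq_along)
  gFull <- paste0(gKey, "#", gOcc); gFull[is.na(gKey)] <- NA
  mFull <- paste0(mKey, "#", mOcc); mFull[is.na(mKey)] <- NA
  hit <- match(mFull, gFull)
  methIdx <- which(!is.na(hit) & !is.na(mFull))
  genetIdx <- hit[methIdx]
  pairs <- DataFrame(genetIdx = genetIdx, methIdx = methIdx,
                     strand = mStrand[methIdx])
  list(pairs = pairs,
       pairingRate = if (length(methFrags))
         nrow(pairs) / length(methFrags) else NA_real_)
}

#' Allele carried by genetic fragments at a SNP
#'
#' @param frags [MMFragments-class] with `bases`.
#' @param snp list(contig, pos, ref, alt).
#' @return character vector `"REF"`, `"ALT"` or `"NONE"` (not covering,
#'   masked, or third allele).
#' @export
alleleAtSNP <- function(frags, snp) {
  out <- rep("NONE", length(frags))
  cover <- as.character(seqnames(frags)) == snp$contig &
    start(frags) <= snp$pos & end(frags) >= snp$pos &
    !is.na(mcols(frags)$bases)
  b <- substr(mcols(frags)$bases[cover], snp$pos - start(frags)[cover] + 1L,
              snp$pos - start(frags)[cover] + 1L)
  out[cover][b == snp$ref] <- "REF"
  out[cover][b == snp$alt] <- "ALT"
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p by the minimum-likelihood method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p value (`NA` for an all-zero table).
#' @examples
#' fisherExact(matrix(c(12, 4, 1, 10), 2, byrow = TRUE))
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative entries in contingency table")
  if (any(tab != round(tab))) stop("counts must be integers")
  if (sum(tab) == 0) return(NA_real_)
  fisher.test(tab)$p.value
}

#' Test allele-specific methylation over duplex pairs
#'
#' Allocates each duplex pair to the reference or alternate allele by the
#' genetic fragment's base at the SNP, accumulates methylated and
#' unmethylated CpG observations within `window` bp of the SNP from the
#' methylation fragments, and compares the alleles with a two-sided
#' Fisher exact test on the 2x2 count table.
#'
#' @param genetFrags,methFrags the paired streams.
#' @param pairs `DataFrame` from [pairDuplex()].
#' @param snp list(contig, pos, ref, alt).
#' @param window half-width of the CpG window around the SNP in bp
#'   (default 200).
#' @param reference optional `DNAStringSet`; when given, only
#'   CpG-context positions are counted.
#' @return list with `table` (2x2: REF/ALT x meth/unmeth), `p`
#'   (`NA`, flagged, when any margin is zero), `nRef`, `nAlt` (pairs per
#'   allele) and `pairingInfo`.
#' @export
asmTest <- function(genetFrags, methFrags, pairs, snp, window = 200L,
                    reference = NULL) {
  allele <- alleleAtSNP(genetFrags[pairs$genetIdx], snp)
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(c("REF", "ALT"),
                                   c("methylated", "unmethylated")))
  mf <- methFrags[pairs$methIdx]
  mp <- mcols(mf)$methPos
  ms <- mcols(mf)$methState
  pos <- unlist(mp, use.names = FALSE)
  state <- unlist(ms, use.names = FALSE)
  al <- rep(allele, lengths(mp))
  ct <- rep(as.character(seqnames(mf)), lengths(mp))
  keep <- al != "NONE" & ct == snp$contig & abs(pos - snp$pos) <= window
  if (!is.null(reference)) {
    refc <- .refCharList(reference)[[snp$contig]]
    base0 <- ifelse(pos >= 1L & pos <= length(refc), refc[pmax(pos, 1L)],
                    "N")
    nxt <- ifelse(base0 == "C",
                  ifelse(pos + 1L <= length(refc), refc[pmin(pos + 1L,
                                                  length(refc))], "N"),
                  ifelse(pos - 1L >= 1L, refc[pmax(pos - 1L, 1L)], "N"))
    isCpG <- (base0 == "C" & nxt == "G") | (base0 == "G" & nxt == "C")
    keep <- keep & isCpG
  }
  pos <- pos[keep]; state <- state[keep]; al <- al[keep]
  for (a in c("REF", "ALT")) {
    counts[a, "methylated"] <- sum(al == a & state)
    counts[a, "unmethylated"] <- sum(al == a & !state)
  }
  marginZero <- any(rowSums(counts) == 0L) || any(colSums(counts) == 0L)
  p <- if (marginZero) NA_real_ else fisherExact(counts)
  list(table = counts, p = p, nRef = sum(allele == "REF"),
       nAlt = sum(allele == "ALT"))
}
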