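#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet reverseComplement
#' @importFrom stats setNames lowess approx fisher.test lm predict
#'   coef rbinom runif rbeta rpois rnorm dnorm
NULL

## Legal duplex flag pairs. The genetic stream (protected copy strands)
## reports 99/147 (Watson molecule) or 83/163 (Crick molecule); the
## methylation stream (converted original strands) reports 67/131 (Watson)
## or 115/179 (Crick).
.FLAG_PAIRS <- list(
  GENET = list(WATSON = c(99L, 147L), CRICK = c(83L, 163L)),
  METH  = list(WATSON = c(67L, 131L), CRICK = c(115L, 179L))
)

.STREAMS <- c("GENET", "METH")

#' UMIPool: a fixed pool of 8-base UMIs with conversion-collapse indices
#'
#' The duplex adapters carry UMIs from a fixed pool (default size 32).
#' Because enzymatic conversion turns unmodified cytosines into uracils
#' (read as thymines), a UMI read from a converted original strand appears
#' with all its Cs replaced by Ts (or, on the opposite mate, all Gs by As).
#' The pool therefore must be collision-free under both collapses:
#' no exact or collapsed form of any member may equal any form of another,
#' otherwise stream assignment is ambiguous.
#'
#' @slot umis character vector of pool UMIs (all the same length, default 8).
#' @slot c2tIndex named character; names are C-to-T collapsed forms, values
#'   the source UMIs.
#' @slot g2aIndex named character; names are G-to-A collapsed forms, values
#'   the source UMIs.
#' @exportClass UMIPool
setClass("UMIPool",
  representation(umis = "character", c2tIndex = "character",
                 g2aIndex = "character"))

setValidity("UMIPool", function(object) {
  u <- object@umis
  if (length(u) < 2L)
    return("pool must contain at least 2 UMIs")
  len <- unique(nchar(u))
  if (length(len) != 1L)
    return("all UMIs must have the same length")
  if (!all(grepl("^[ACGT]+$", u)))
    return("UMIs must be over the alphabet {A,C,G,T}")
  if (anyDuplicated(u))
    return(sprintf("duplicated UMI: %s", u[duplicated(u)][1L]))
  ## brute-force pairwise comparison across all exact/C2T/G2A forms:
  ## a form shared by two different pool members is a collision
  forms <- c(u, collapseSequence(u, "C2T"), collapseSequence(u, "G2A"))
  src <- rep(u, 3L)
  nSrc <- vapply(split(src, forms), function(x) length(unique(x)),
                 integer(1L))
  if (any(nSrc > 1L)) {
    clash <- unique(src[forms %in% names(nSrc)[nSrc > 1L]])
    return(sprintf("UMI collision under conversion collapse between: %s",
                   paste(clash[seq_len(min(2L, length(clash)))],
                         collapse = " and ")))
  }
  noC <- !grepl("C", u)
  if (any(noC))
    return(sprintf("UMI without any C (collapsed form equals exact form): %s",
                   u[noC][1L]))
  noG <- !grepl("G", u)
  if (any(noG))
    return(sprintf("UMI without any G (collapsed form equals exact form): %s",
                   u[noG][1L]))
  TRUE
})

setMethod("show", "UMIPool", function(object) {
  cat(sprintf("UMIPool with %d UMIs of length %d\n",
              length(object@umis), nchar(object@umis[1L])))
  n <- min(4L, length(object@umis))
  cat("  ", paste(object@umis[seq_len(n)], collapse = " "),
      if (length(object@umis) > n) "..." else "", "\n")
})

#' @describeIn UMIPool number of UMIs in the pool
#' @param x a `UMIPool`
#' @export
setMethod("length", "UMIPool", function(x) length(x@umis))

#' Construct a validated UMIPool
#'
#' @param umis character vector of UMI sequences (same length, default 8 nt,
#'   each containing at least one C and one G).
#' @return a validated [UMIPool-class] with collapse indices built.
#' @examples
#' UMIPool(c("ACCGTCAG", "GGATCCTA"))
#' @export
UMIPool <- function(umis) {
  umis <- toupper(as.character(umis))
  obj <- new("UMIPool", umis = umis,
             c2tIndex = stats::setNames(umis, collapseSequence(umis, "C2T")),
             g2aIndex = stats::setNames(umis, collapseSequence(umis, "G2A")))
  obj
}

#' poolUMIs: the UMI sequences of a pool
#' @param pool a [UMIPool-class]
#' @return character vector of UMIs
#' @export
poolUMIs <- function(pool) pool@umis

#' MMFragments: aligned duplex fragments with stream, UMI and methylation data
#'
#' A [GenomicRanges::GRanges] subclass holding one record per sequenced
#' fragment (read pair) after alignment (or directly from the simulator).
#' Required metadata columns:
#' \describe{
#'   \item{stream}{`"GENET"` or `"METH"`.}
#'   \item{umi1, umi2}{observed mate-1 / mate-2 UMIs (8 nt).}
#'   \item{flag1, flag2}{SAM-style flags; must form one of the four legal
#'     duplex pairs (99/147, 83/163 genetic; 67/131, 115/179 methylation).}
#' }
#' Optional columns: `molId` (simulation truth molecule id), `bases`
#' (plus-strand base calls, genetic stream), `methPos` (IntegerList of
#' genomic positions of strand-informative cytosines, methylation stream),
#' `methState` (LogicalList, `TRUE` = read as methylated, i.e. unconverted).
#'
#' @exportClass MMFragments
setClass("MMFragments", contains = "GRanges")

setValidity("MMFragments", function(object) {
  mc <- mcols(object)
  need <- c("stream", "umi1", "umi2", "flag1", "flag2")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(sprintf("missing metadata column(s): %s",
                   paste(miss, collapse = ", ")))
  if (length(object) == 0L)
    return(TRUE)
  if (any(width(object) < 1L))
    return("fragments must have positive width (start < end)")
  if (!all(mc$stream %in% .STREAMS))
    return("stream must be 'GENET' or 'METH'")
  legal <- do.call(rbind, lapply(names(.FLAG_PAIRS), function(s)
    do.call(rbind, lapply(.FLAG_PAIRS[[s]], function(fp)
      data.frame(stream = s, f1 = fp[1L], f2 = fp[2L])))))
  key <- paste(mc$stream, mc$flag1, mc$flag2)
  ok <- key %in% paste(legal$stream, legal$f1, legal$f2)
  if (!all(ok))
    return(sprintf("illegal stream/flag combination: %s", key[!ok][1L]))
  if ("methState" %in% colnames(mc) && "methPos" %in% colnames(mc)) {
    if (!identical(lengths(mc$methPos), lengths(mc$methState)))
      return("methPos and methState must have matching element lengths")
  }
  TRUE
})

#' Construct MMFragments
#'
#' @param contig character vector of contig names.
#' @param start,end integer, 1-based closed fragment span (the container's
#'   native convention; converters from 0-based formats sit at I/O
#'   boundaries).
#' @param stream `"GENET"` or `"METH"` per fragment.
#' @param umi1,umi2 observed mate UMIs.
#' @param flag1,flag2 SAM-style flag pair.
#' @param molId optional truth molecule id.
#' @param bases optional plus-strand base calls (genetic stream).
#' @param methPos,methState optional IntegerList / LogicalList of
#'   strand-informative cytosine positions and observed methylation states.
#' @return an [MMFragments-class] object.
#' @export
MMFragments <- function(contig, start, end, stream, umi1, umi2, flag1, flag2,
                        molId = NULL, bases = NULL, methPos = NULL,
                        methState = NULL) {
  gr <- GRanges(contig, IRanges(start = as.integer(start),
                                end = as.integer(end)))
  mcols(gr)$stream <- as.character(stream)
  mcols(gr)$umi1 <- as.character(umi1)
  mcols(gr)$umi2 <- as.character(umi2)
  mcols(gr)$flag1 <- as.integer(flag1)
  mcols(gr)$flag2 <- as.integer(flag2)
  if (!is.null(molId)) mcols(gr)$molId <- as.integer(molId)
  if (!is.null(bases)) mcols(gr)$bases <- as.character(bases)
  if (!is.null(methPos)) {
    mcols(gr)$methPos <- as(methPos, "IntegerList")
    mcols(gr)$methState <- as(methState, "LogicalList")
  }
  new("MMFragments", gr)
}

setMethod("show", "MMFragments", function(object) {
  cat(sprintf("MMFragments with %d fragments (%d GENET, %d METH)\n",
              length(object), sum(mcols(object)$stream == "GENET"),
              sum(mcols(object)$stream == "METH")))
  if (length(object))
    methods::callNextMethod()
})

#' Duplex strand class from a flag pair
#'
#' Maps the SAM-style flag pair of a fragment to its duplex strand of
#' origin: Watson molecules report genetic flags 99/147 and methylation
#' flags 67/131; Crick molecules report 83/163 and 115/179.
#'
#' @param flag1,flag2 integer flag pairs.
#' @param stream `"GENET"` or `"METH"` (vector).
#' @return character vector `"WATSON"`/`"CRICK"` (`NA` for illegal pairs).
#' @export
strandClass <- function(flag1, flag2, stream) {
  out <- rep(NA_character_, length(flag1))
  for (s in .STREAMS) for (cl in c("WATSON", "CRICK")) {
    fp <- .FLAG_PAIRS[[s]][[cl]]
    out[stream == s & flag1 == fp[1L] & flag2 == fp[2L]] <- cl
  }
  out
}

.streamFlags <- function(stream, strand) {
  .FLAG_PAIRS[[stream]][[strand]]
}
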