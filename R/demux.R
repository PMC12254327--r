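#' Classify read pairs into the genetic and methylation streams
#'
#' Each mate's 8-base UMI is looked up against the pool: exact match first,
#' then the C-to-T collapse index, then the G-to-A collapse index (a UMI
#' containing N never matches). A pair is assigned to the genetic stream
#' (MM-genet) when both mates match exactly (the UMI cytosines survived,
#' so the strand is a protected copy), to the methylation stream (MM-meth)
#' when both mates match a converted form (either collapse per mate, since
#' mate orientation relative to the original strand is symmetric), and is
#' left unassigned otherwise — including discordant mates, the conservative
#' rule that keeps stream contamination out of variant calling.
#'
#' @param umi1,umi2 observed mate UMIs (character vectors), or a read-pair
#'   `DataFrame` from [readPairSet()] as the first argument.
#' @param pool a [UMIPool-class].
#' @return `DataFrame` with columns `stream` (`"GENET"`, `"METH"`,
#'   `"UNASSIGNED"`), `mode1`, `mode2` (per-mate match modes) and
#'   `matchedUmi1`, `matchedUmi2` (source pool UMIs or `NA`).
#' @export
classifyReadPair <- function(umi1, umi2 = NULL, pool) {
  if (is.null(umi2)) {
    pairs <- umi1
    umi1 <- pairs$umi1; umi2 <- pairs$umi2
  }
  m1 <- matchUMI(umi1, pool)
  m2 <- matchUMI(umi2, pool)
  conv <- c("C2T", "G2A")
  stream <- rep("UNASSIGNED", length(umi1))
  stream[m1$mode == "EXACT" & m2$mode == "EXACT"] <- "GENET"
  stream[m1$mode %in% conv & m2$mode %in% conv] <- "METH"
  DataFrame(stream = stream, mode1 = m1$mode, mode2 = m2$mode,
            matchedUmi1 = m1$match, matchedUmi2 = m2$match)
}

#' Demultiplex an in-memory read-pair table
#'
#' @param pairs read-pair `DataFrame` from [readPairSet()] /
#'   [readFastqPair()].
#' @param pool a [UMIPool-class].
#' @return list with `genet`, `meth`, `unassigned` (read-pair subsets, UMI
#'   prefixes preserved) and `stats` (see [demuxStats()]).
#' @export
demuxReads <- function(pairs, pool) {
  cls <- classifyReadPair(pairs, pool = pool)
  out <- list(genet = pairs[cls$stream == "GENET", , drop = FALSE],
              meth = pairs[cls$stream == "METH", , drop = FALSE],
              unassigned = pairs[cls$stream == "UNASSIGNED", , drop = FALSE],
              classification = cls,
              stats = demuxStats(cls))
  out
}

#' Demultiplexing statistics
#'
#' @param cls classification `DataFrame` from [classifyReadPair()].
#' @return list: `n_total`, `n_genet`, `n_meth`, `n_unassigned`,
#'   `perfect_match_fraction` (pairs with both mates matching a pool UMI
#'   exactly, over all pairs; `NA` when empty).
#' @export
demuxStats <- function(cls) {
  n <- nrow(cls)
  list(n_total = n,
       n_genet = sum(cls$stream == "GENET"),
       n_meth = sum(cls$stream == "METH"),
       n_unassigned = sum(cls$stream == "UNASSIGNED"),
       perfect_match_fraction =
         if (n) sum(cls$mode1 == "EXACT" & cls$mode2 == "EXACT") / n
         else NA_real_)
}

#' Demultiplex FASTQ mate files into per-stream FASTQ pairs
#'
#' Routes every input pair to exactly one of the genetic stream, the
#' methylation stream, or the unassigned bucket; counts are conserved.
#'
#' @param r1,r2 input mate FASTQ paths.
#' @param pool a [UMIPool-class] (or a pool file path).
#' @param outPrefix output prefix; writes `<prefix>.genet.R1.fastq` etc.,
#'   plus `<prefix>.demux_stats.json`.
#' @param writeUnassigned also write the unassigned pairs (default TRUE).
#' @return invisibly, the stats list.
#' @export
demuxStream <- function(r1, r2, pool, outPrefix,
                        writeUnassigned = TRUE) {
  if (is.character(pool)) pool <- loadUMIPool(pool)
  pairs <- readFastqPair(r1, r2)
  res <- demuxReads(pairs, pool)
  writeFastqPair(res$genet, paste0(outPrefix, ".genet.R1.fastq"),
                 paste0(outPrefix, ".genet.R2.fastq"))
  writeFastqPair(res$meth, paste0(outPrefix, ".meth.R1.fastq"),
                 paste0(outPrefix, ".meth.R2.fastq"))
  if (writeUnassigned)
    writeFastqPair(res$unassigned, paste0(outPrefix, ".unassigned.R1.fastq"),
                   paste0(outPrefix, ".unassigned.R2.fastq"))
  jsonlite::write_json(res$stats, paste0(outPrefix, ".demux_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res$stats)
}
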