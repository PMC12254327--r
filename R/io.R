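#' Build a read-pair table
#'
#' Read pairs are held in a `DataFrame` with columns `id`, `seq1`, `qual1`,
#' `seq2`, `qual2`, `umi1`, `umi2`; the UMIs are the first `umiLength`
#' bases of each mate (kept as an explicit column, always a prefix of the
#' mate sequence).
#'
#' @param seq1,seq2 mate sequences (length >= `umiLength`).
#' @param qual1,qual2 quality strings (same lengths as the sequences).
#' @param id read ids (default `rp1`, `rp2`, ...).
#' @param umiLength UMI prefix length (default 8).
#' @return `DataFrame` of read pairs.
#' @export
readPairSet <- function(seq1, seq2, qual1 = NULL, qual2 = NULL, id = NULL,
                        umiLength = 8L) {
  n <- length(seq1)
  if (length(seq2) != n) stop("desynchronized mates: unequal pair counts")
  if (!n)
    return(DataFrame(id = character(0L), seq1 = character(0L),
                     qual1 = character(0L), seq2 = character(0L),
                     qual2 = character(0L), umi1 = character(0L),
                     umi2 = character(0L)))
  if (any(nchar(seq1) < umiLength | nchar(seq2) < umiLength))
    stop(sprintf("reads shorter than the %d-base UMI prefix", umiLength))
  if (is.null(qual1)) qual1 <- strrep("I", nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep("I", nchar(seq2))
  if (is.null(id)) id <- paste0("rp", seq_len(n))
  DataFrame(id = as.character(id),
            seq1 = as.character(seq1), qual1 = as.character(qual1),
            seq2 = as.character(seq2), qual2 = as.character(qual2),
            umi1 = substr(seq1, 1L, umiLength),
            umi2 = substr(seq2, 1L, umiLength))
}

#' Read a FASTQ mate pair into a read-pair table
#'
#' @param r1,r2 paths to the mate FASTQ files (plain or gzipped).
#' @param umiLength UMI prefix length (default 8).
#' @return `DataFrame` as produced by [readPairSet()].
#' @export
readFastqPair <- function(r1, r2, umiLength = 8L) {
  s1 <- readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(s1) != length(s2))
    stop("desynchronized mates: unequal record counts")
  id1 <- sub("[/ ].*$", "", names(s1))
  id2 <- sub("[/ ].*$", "", names(s2))
  if (length(id1) && !identical(id1, id2))
    stop("desynchronized mates: read ids differ")
  readPairSet(as.character(s1), as.character(s2),
              as.character(mcols(s1)$qualities),
              as.character(mcols(s2)$qualities),
              id = id1, umiLength = umiLength)
}

#' Write a read-pair table as a FASTQ mate pair
#'
#' @param pairs `DataFrame` from [readPairSet()].
#' @param r1,r2 output FASTQ paths (`.gz` suffix compresses).
#' @return invisibly, `c(r1, r2)`.
#' @export
writeFastqPair <- function(pairs, r1, r2) {
  .writeOne <- function(seq, qual, id, path) {
    x <- DNAStringSet(seq)
    names(x) <- id
    writeXStringSet(x, path, format = "fastq", qualities = BStringSet(qual),
                    compress = grepl("\\.gz$", path))
  }
  .writeOne(pairs$seq1, pairs$qual1, pairs$id, r1)
  .writeOne(pairs$seq2, pairs$qual2, pairs$id, r2)
  invisible(c(r1, r2))
}

#' Basic quality filter for read pairs
#'
#' Drops a pair when either mate has more than `maxLowQualFrac` of its
#' bases below `minQ`, or more than `maxN` N calls. A deliberately simple
#' filter (no trimming).
#'
#' @param pairs read-pair `DataFrame`.
#' @param minQ Phred threshold (default 20).
#' @param maxLowQualFrac maximum tolerated fraction of low-quality bases
#'   (default 0.30).
#' @param maxN maximum tolerated N calls per mate (default 10).
#' @param qualOffset ASCII offset of the quality encoding (default 33).
#' @return filtered read-pair `DataFrame`.
#' @export
filterReadPairs <- function(pairs, minQ = 20L, maxLowQualFrac = 0.30,
                            maxN = 10L, qualOffset = 33L) {
  .bad <- function(seq, qual) {
    q <- lapply(qual, function(x) utf8ToInt(x) - qualOffset)
    lowFrac <- vapply(q, function(x) mean(x < minQ), numeric(1L))
    nN <- vapply(gregexpr("N", seq, fixed = TRUE), function(m)
      sum(m > 0L), numeric(1L))
    lowFrac > maxLowQualFrac | nN > maxN
  }
  if (!nrow(pairs)) return(pairs)
  drop <- .bad(pairs$seq1, pairs$qual1) | .bad(pairs$seq2, pairs$qual2)
  pairs[!drop, , drop = FALSE]
}

#' Downsample read pairs uniformly without replacement
#'
#' @param pairs read-pair `DataFrame` (or any subsettable table).
#' @param n number of pairs to keep (`n <=` available pairs).
#' @param seed integer seed for reproducible selection.
#' @return the downsampled table, in original order.
#' @export
downsamplePairs <- function(pairs, n, seed = NULL) {
  total <- nrow(pairs)
  if (n > total)
    stop(sprintf("cannot downsample to %d from %d pairs", n, total))
  keep <- withSeed(seed, sort(sample.int(total, n)))
  pairs[keep, , drop = FALSE]
}

#' Read regions from a BED file
#'
#' BED's 0-based half-open convention is converted exactly once into the
#' 1-based closed convention of `GRanges`.
#'
#' @param path BED file (3+ columns).
#' @param kind region kind label stored in the `kind` metadata column
#'   (default `"METHYL_MARKER"`).
#' @return `GRanges` with `name` and `kind` metadata columns.
#' @export
readRegionsBED <- function(path, kind = "METHYL_MARKER") {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop(sprintf("malformed BED '%s': %s", path,
                                conditionMessage(e))))
  gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                name = if (!is.null(gr$name)) gr$name
                       else paste0("region", seq_along(gr)))
  gr$kind <- kind
  gr
}

#' Write regions to a BED file
#' @param regions `GRanges` with an optional `name` column.
#' @param path output BED path.
#' @export
writeRegionsBED <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions),
                   name = if (!is.null(regions$name)) regions$name
                          else paste0("region", seq_along(regions)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write aligned fragments as SAM
#'
#' Emits two proper-pair records per fragment. The UMI pair travels in the
#' read name as a `...:UMI1-UMI2` suffix (aligner-agnostic; no dialect
#' tags). Positions follow SAM's 1-based convention directly.
#'
#' @param frags an [MMFragments-class].
#' @param path output SAM path.
#' @param reference named vector of contig lengths, or a `DNAStringSet`.
#' @return invisibly, `path`.
#' @export
writeFragmentsSAM <- function(frags, path, reference) {
  lens <- if (is(reference, "DNAStringSet"))
    stats::setNames(Biostrings::width(reference), names(reference))
  else reference
  mc <- mcols(frags)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens))),
             con)
  if (length(frags)) {
    o <- order(as.character(seqnames(frags)), start(frags), end(frags))
    frags <- frags[o]; mc <- mcols(frags)
    qname <- sprintf("frag%06d:%s:%s-%s", seq_along(frags), mc$stream,
                     mc$umi1, mc$umi2)
    w <- width(frags)
    seqs <- if (!is.null(mc$bases)) mc$bases else rep(NA_character_,
                                                      length(frags))
    if (anyNA(seqs) && !is.null(mc$methPos) && is(reference, "DNAStringSet"))
      seqs[is.na(seqs)] <- .methObservedBases(frags[is.na(seqs)], reference)
    seqs[is.na(seqs)] <- strrep("N", w[is.na(seqs)])
    line <- function(flag, pos, mpos, tlen)
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
              qname, flag, as.character(seqnames(frags)), pos, w, mpos,
              tlen, seqs, strrep("I", w))
    writeLines(c(line(mc$flag1, start(frags), start(frags), w),
                 line(mc$flag2, start(frags), start(frags), -w)), con)
  }
  invisible(path)
}

#' Read aligned fragments from SAM/BAM
#'
#' SAM input is converted to BAM internally (Rsamtools). Mates are paired
#' by read name; the UMI pair is recovered from the `...:UMI1-UMI2`
#' read-name suffix.
#'
#' @param path SAM or BAM file.
#' @return an [MMFragments-class] (without methylation states; `bases`
#'   taken from the flag-1 mate record).
#' @export
readFragmentsSAM <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "qwidth", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  if (!length(x$qname))
    return(MMFragments(character(0L), integer(0L), integer(0L),
                       character(0L), character(0L), character(0L),
                       integer(0L), integer(0L)))
  df <- data.frame(qname = x$qname, flag = x$flag,
                   contig = as.character(x$rname), pos = x$pos,
                   width = x$qwidth, seq = as.character(x$seq),
                   stringsAsFactors = FALSE)
  sp <- split(df, df$qname)
  rec <- lapply(sp, function(d) {
    d <- d[order(d$flag), , drop = FALSE]
    if (nrow(d) != 2L)
      stop(sprintf("read '%s' does not form a proper pair", d$qname[1L]))
    parts <- strsplit(d$qname[1L], ":", fixed = TRUE)[[1L]]
    umis <- strsplit(parts[length(parts)], "-", fixed = TRUE)[[1L]]
    data.frame(contig = d$contig[1L], start = min(d$pos),
               end = min(d$pos) + d$width[1L] - 1L,
               stream = parts[length(parts) - 1L],
               umi1 = umis[1L], umi2 = umis[2L],
               flag1 = min(d$flag), flag2 = max(d$flag),
               bases = d$seq[1L], stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  ## flag order within a pair: flag1 is the record carrying the smaller flag
  ## of the legal pair for METH Crick (115 < 179) and all other classes
  frags <- MMFragments(rec$contig, rec$start, rec$end, rec$stream,
                       rec$umi1, rec$umi2, rec$flag1, rec$flag2,
                       bases = rec$bases)
  sort(frags)
}

## observed plus-strand bases of methylation fragments: the reference
## sequence with converted (unmethylated-read) cytosines substituted -
## C-to-T at Watson-strand positions, G-to-A at Crick-strand positions
.methObservedBases <- function(frags, reference) {
  refc <- .refCharList(reference)
  mc <- mcols(frags)
  vapply(seq_along(frags), function(i) {
    ct <- as.character(seqnames(frags))[i]
    chars <- refc[[ct]][start(frags)[i]:end(frags)[i]]
    p <- mc$methPos[[i]] - start(frags)[i] + 1L
    conv <- !mc$methState[[i]]
    isC <- chars[p] == "C"
    chars[p[conv & isC]] <- "T"
    chars[p[conv & !isC]] <- "A"
    paste(chars, collapse = "")
  }, character(1L))
}

#' Write per-cytosine methylation calls as a bedGraph-style TSV
#'
#' Columns: contig, start (0-based), end, beta, n_methylated,
#' n_unmethylated, context.
#'
#' @param calls `GRanges` from [callMethylation()].
#' @param path output TSV path.
#' @export
writeCpGCallsTSV <- function(calls, path) {
  df <- data.frame(contig = as.character(seqnames(calls)),
                   start = start(calls) - 1L, end = end(calls),
                   beta = calls$beta, n_meth = calls$nMeth,
                   n_unmeth = calls$nUnmeth, context = calls$context)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cytosine methylation calls written by [writeCpGCallsTSV()]
#' @param path TSV path.
#' @return `GRanges` with `nMeth`, `nUnmeth`, `beta`, `context` columns.
#' @export
readCpGCallsTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  GRanges(df$contig, IRanges(df$start + 1L, df$end),
          nMeth = df$n_meth, nUnmeth = df$n_unmeth, beta = df$beta,
          context = df$context)
}

#' Read a delimited cohort table
#'
#' Thin wrapper over `read.delim` with a line-numbered parse error.
#'
#' @param path TSV/CSV path.
#' @param sep field separator (default tab).
#' @return `data.frame`.
#' @export
readCohortTable <- function(path, sep = "\t") {
  tryCatch(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                             check.names = FALSE),
           error = function(e)
             stop(sprintf("malformed table '%s': %s", path,
                          conditionMessage(e))))
}
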