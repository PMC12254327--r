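#' Collapse a DNA sequence under conversion
#'
#' Enzymatic conversion deaminates unmodified cytosines to uracil, read as
#' thymine; on the opposite mate the same events appear as G-to-A. This
#' applies the corresponding deterministic character map (the fully
#' converted limit).
#'
#' @param seq character vector of DNA sequences over \{A,C,G,T,N\}.
#' @param mode `"C2T"` (every C becomes T) or `"G2A"` (every G becomes A).
#' @return character vector of collapsed sequences, lengths preserved.
#' @examples
#' collapseSequence("ACCGTCAG", "C2T")  # "ATTGTTAG"
#' collapseSequence("ACCGTCAG", "G2A")  # "ACCATCAA"
#' @export
collapseSequence <- function(seq, mode = c("C2T", "G2A")) {
  mode <- match.arg(mode)
  if (mode == "C2T") chartr("C", "T", seq) else chartr("G", "A", seq)
}

#' Load a UMI pool from a text file
#'
#' @param path text file with one UMI per line.
#' @param umiLength expected UMI length (default 8).
#' @param poolSize expected pool size, or `NA` to accept any size >= 2
#'   (default 32, the configured adapter pool size).
#' @return a validated [UMIPool-class].
#' @export
loadUMIPool <- function(path, umiLength = 8L, poolSize = 32L) {
  u <- toupper(trimws(readLines(path)))
  u <- u[nzchar(u)]
  bad <- which(nchar(u) != umiLength)
  if (length(bad))
    stop(sprintf("UMI pool format error at line %d: '%s' is not %d bases",
                 bad[1L], u[bad[1L]], umiLength))
  if (!is.na(poolSize) && length(u) != poolSize)
    stop(sprintf("expected %d UMIs, found %d", poolSize, length(u)))
  UMIPool(u)
}

#' Write a UMI pool to a text file
#' @param pool a [UMIPool-class]
#' @param path output file, one UMI per line
#' @export
writeUMIPool <- function(pool, path) {
  writeLines(poolUMIs(pool), path)
  invisible(path)
}

#' Generate a collision-free UMI pool
#'
#' Rejection-samples fixed-length UMIs (each containing at least one C and
#' one G) until the requested pool size is reached with no exact or
#' collapse-form collisions. Used to ship a synthetic stand-in pool, since
#' commercial adapter UMI sets are not published.
#'
#' @param n pool size (default 32).
#' @param umiLength UMI length (default 8).
#' @param seed integer RNG seed.
#' @return a validated [UMIPool-class].
#' @export
generateUMIPool <- function(n = 32L, umiLength = 8L, seed = 1L) {
  stopifnot(n >= 2L, umiLength >= 4L)
  withSeed(seed, {
    umis <- character(0L)
    forms <- character(0L)
    guard <- 0L
    while (length(umis) < n) {
      guard <- guard + 1L
      if (guard > 100000L) stop("failed to generate a collision-free pool")
      cand <- paste(sample(c("A", "C", "G", "T"), umiLength, replace = TRUE),
                    collapse = "")
      if (!grepl("C", cand) || !grepl("G", cand)) next
      cf <- c(cand, collapseSequence(cand, "C2T"),
              collapseSequence(cand, "G2A"))
      if (any(cf %in% forms) || anyDuplicated(cf)) next
      umis <- c(umis, cand)
      forms <- c(forms, cf)
    }
    UMIPool(umis)
  })
}

#' Per-mate UMI lookup against a pool
#'
#' Lookup order is exact match first, then the C-to-T collapse index, then
#' the G-to-A collapse index. A UMI containing N never matches.
#'
#' @param umi character vector of observed UMIs.
#' @param pool a [UMIPool-class].
#' @return `DataFrame` with columns `mode` (`"EXACT"`, `"C2T"`, `"G2A"` or
#'   `"NONE"`) and `match` (the source pool UMI, or `NA`).
#' @export
matchUMI <- function(umi, pool) {
  mode <- rep("NONE", length(umi))
  match_ <- rep(NA_character_, length(umi))
  hasN <- grepl("N", umi, fixed = TRUE)
  i <- match(umi, pool@umis)
  hit <- !is.na(i) & !hasN
  mode[hit] <- "EXACT"; match_[hit] <- pool@umis[i[hit]]
  todo <- mode == "NONE" & !hasN
  i <- match(umi[todo], names(pool@c2tIndex))
  hit <- !is.na(i)
  mode[todo][hit] <- "C2T"
  match_[todo][hit] <- unname(pool@c2tIndex[i[hit]])
  todo <- mode == "NONE" & !hasN
  i <- match(umi[todo], names(pool@g2aIndex))
  hit <- !is.na(i)
  mode[todo][hit] <- "G2A"
  match_[todo][hit] <- unname(pool@g2aIndex[i[hit]])
  DataFrame(mode = mode, match = match_)
}

#' Hamming distance between equal-length UMI pairs (vectorized)
#'
#' An N mismatches everything, including another N (conservative).
#'
#' @param a,b character vectors of equal-length sequences.
#' @return integer vector of mismatch counts.
#' @export
umiHamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer(0L))
  if (any(nchar(a) != nchar(b))) stop("sequences must have equal length")
  am <- .charMatrix(a)
  bm <- .charMatrix(b)
  as.integer(rowSums(am != bm | am == "N" | bm == "N"))
}

## character matrix (rows = sequences) from equal-length strings
.charMatrix <- function(x) {
  n <- unique(nchar(x))
  stopifnot(length(n) == 1L)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}

## rows of a character matrix pasted back into strings
.pasteRows <- function(m) {
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so library code never perturbs
#' the caller's random stream.
#'
#' @param seed integer seed (or `NULL` to use the current stream).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
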