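## marker CpG positions per contig, from the markers' cpgPos column when
## present, otherwise from reference CpG context within the marker spans
.markerCpGs <- function(markers, reference = NULL) {
  if (!is.null(mcols(markers)$cpgPos)) {
    split(unlist(mcols(markers)$cpgPos, use.names = FALSE),
          rep(as.character(seqnames(markers)),
              lengths(mcols(markers)$cpgPos)))
  } else if (!is.null(reference)) {
    refc <- .refCharList(reference)
    out <- list()
    for (ct in unique(as.character(seqnames(markers)))) {
      rc <- refc[[ct]]
      if (is.null(rc)) stop(sprintf("contig '%s' not in reference", ct))
      cpg <- which(rc[-length(rc)] == "C" & rc[-1L] == "G")
      m <- markers[as.character(seqnames(markers)) == ct]
      keep <- overlapsAny(IRanges(cpg, width = 1L), ranges(m))
      out[[ct]] <- cpg[keep]
    }
    out
  } else stop("markers need a cpgPos column or a reference")
}

#' Methylation-derived ctDNA fragment fraction
#'
#' Over the methylation markers, fragments reporting at least `minCpgs`
#' marker CpG sites are eligible; an eligible fragment whose covered
#' marker CpGs are all methylated is counted as tumor-derived (the markers
#' are hypermethylated in tumor), and the ctDNA fraction is their
#' proportion.
#'
#' @param methFrags methylation-stream [MMFragments-class].
#' @param markers `GRanges` of methylation marker regions (with a `cpgPos`
#'   IntegerList column, or supply `reference`).
#' @param minCpgs minimum covered marker CpGs for eligibility (default 5).
#' @param reference optional `DNAStringSet` to derive marker CpGs.
#' @return list(`n_eligible`, `n_ctdna`, `fraction`); `fraction` is `NA`
#'   (flagged undefined) when nothing is eligible.
#' @export
ctdnaFraction <- function(methFrags, markers, minCpgs = 5L,
                          reference = NULL) {
  cpgByContig <- .markerCpGs(markers, reference)
  mc <- mcols(methFrags)
  frags <- methFrags[mc$stream == "METH" & lengths(mc$methPos) > 0L]
  mc <- mcols(frags)
  pos <- unlist(mc$methPos, use.names = FALSE)
  state <- unlist(mc$methState, use.names = FALSE)
  fi <- rep(seq_along(frags), lengths(mc$methPos))
  ct <- rep(as.character(seqnames(frags)), lengths(mc$methPos))
  inMarker <- rep(FALSE, length(pos))
  for (c_ in names(cpgByContig))
    inMarker[ct == c_] <- pos[ct == c_] %in% cpgByContig[[c_]]
  pos <- pos[inMarker]; state <- state[inMarker]; fi <- fi[inMarker]
  if (!length(fi))
    return(list(n_eligible = 0L, n_ctdna = 0L, fraction = NA_real_))
  f <- factor(fi)
  nCov <- as.integer(tapply(pos, f, length))
  allMeth <- as.logical(tapply(state, f, all))
  eligible <- nCov >= minCpgs
  nEligible <- sum(eligible)
  nCtdna <- sum(eligible & allMeth)
  list(n_eligible = nEligible, n_ctdna = nCtdna,
       fraction = if (nEligible) nCtdna / nEligible else NA_real_)
}

#' ctDNA positivity call
#'
#' Positive iff any somatic mutation was kept, or the methylation-derived
#' ctDNA fraction exceeds `fractionThreshold` with at least `minCtdna`
#' ctDNA fragments and at least `minTotal` eligible cfDNA fragments.
#'
#' @param result list from [ctdnaFraction()] (fields `n_eligible`,
#'   `n_ctdna`, `fraction`), optionally with `n_somatic`.
#' @param nSomatic number of kept somatic mutations (overrides
#'   `result$n_somatic`; default 0).
#' @param fractionThreshold strict lower bound on the fraction
#'   (default 0.001, i.e. 0.1%).
#' @param minCtdna minimum ctDNA fragments (default 3).
#' @param minTotal minimum eligible fragments (default 3000).
#' @return `"POSITIVE"` or `"NEGATIVE"`.
#' @export
callCtdnaStatus <- function(result, nSomatic = NULL,
                            fractionThreshold = 0.001, minCtdna = 3L,
                            minTotal = 3000L) {
  if (is.null(nSomatic)) nSomatic <- result$n_somatic
  if (is.null(nSomatic)) nSomatic <- 0L
  frac <- result$fraction
  methPos <- !is.na(frac) && frac > fractionThreshold &&
    result$n_ctdna >= minCtdna && result$n_eligible >= minTotal
  if (nSomatic >= 1L || methPos) "POSITIVE" else "NEGATIVE"
}

#' Raw immune cell-type fractions from marker fragments
#'
#' Each marker is specific to one cell type (unmethylated in that type,
#' methylated elsewhere). Fragments reporting every CpG of a marker are
#' its covering fragments; the marker's signal is the proportion of
#' covering fragments with at least the requisite number of unmethylated
#' CpGs (default: all of them), and a cell type's raw fraction is the
#' mean over its markers. Markers with no covering fragments are excluded
#' from the mean with a message.
#'
#' @param frags methylation-stream [MMFragments-class].
#' @param markers `GRanges` with `name`, `cellType` and `cpgPos` columns.
#' @param requisite optional named integer per marker name: minimum
#'   unmethylated CpGs (default: all CpGs of the marker).
#' @return named numeric raw fractions per cell type.
#' @export
immuneFractions <- function(frags, markers, requisite = NULL) {
  mc <- mcols(frags)
  frags <- frags[mc$stream == "METH" & lengths(mc$methPos) > 0L]
  mc <- mcols(frags)
  pos <- unlist(mc$methPos, use.names = FALSE)
  state <- unlist(mc$methState, use.names = FALSE)
  fi <- rep(seq_along(frags), lengths(mc$methPos))
  ct <- rep(as.character(seqnames(frags)), lengths(mc$methPos))
  fragContig <- as.character(seqnames(frags))
  perMarker <- numeric(length(markers))
  covered <- logical(length(markers))
  for (i in seq_along(markers)) {
    mcp <- mcols(markers)$cpgPos[[i]]
    mct <- as.character(seqnames(markers))[i]
    sel <- ct == mct & pos %in% mcp
    if (!any(sel)) { covered[i] <- FALSE; next }
    f <- factor(fi[sel])
    nCov <- tapply(pos[sel], f, function(p) length(unique(p)))
    full <- nCov == length(mcp)
    if (!any(full)) { covered[i] <- FALSE; next }
    nUnmeth <- tapply(!state[sel], f, sum)
    req <- if (!is.null(requisite) &&
               mcols(markers)$name[i] %in% names(requisite))
      requisite[[mcols(markers)$name[i]]] else length(mcp)
    covered[i] <- TRUE
    perMarker[i] <- mean(nUnmeth[full] >= req)
  }
  if (any(!covered))
    message(sprintf("%d marker(s) with no covering fragments excluded",
                    sum(!covered)))
  types <- unique(mcols(markers)$cellType)
  vapply(setNames(types, types), function(t) {
    sel <- mcols(markers)$cellType == t & covered
    if (!any(sel)) return(NA_real_)
    mean(perMarker[sel])
  }, numeric(1L))
}

#' Calibrate raw immune fractions against blood-count training data
#'
#' Fits one ordinary least-squares line per cell type from training pairs
#' of (raw marker-derived fraction, complete-blood-count proportion),
#' applies it to the raw fractions, clips negatives to zero, and
#' renormalizes so the fractions sum to exactly 1.
#'
#' @param raw named numeric raw fractions (from [immuneFractions()]).
#' @param training data.frame(cell_type, raw, cbc), at least 2 training
#'   points per cell type with nonzero variance.
#' @return list with `raw`, `calibrated` (sums to 1) and `models`
#'   (per-type coefficient pairs).
#' @export
calibrateFractions <- function(raw, training) {
  models <- list()
  cal <- raw
  for (t in names(raw)) {
    tr <- training[training$cell_type == t, , drop = FALSE]
    if (nrow(tr) < 2L)
      stop(sprintf("need >= 2 training points for '%s'", t))
    if (stats::sd(tr$raw) == 0)
      stop(sprintf("degenerate training (zero variance) for '%s'", t))
    fit <- lm(cbc ~ raw, data = tr)
    models[[t]] <- coef(fit)
    cal[t] <- unname(coef(fit)[1L] + coef(fit)[2L] * raw[t])
  }
  cal[cal < 0] <- 0
  if (sum(cal, na.rm = TRUE) == 0) stop("all calibrated fractions zero")
  cal <- cal / sum(cal, na.rm = TRUE)
  list(raw = raw, calibrated = cal, models = models)
}

#' Neutrophil-to-lymphocyte ratio from immune fractions
#'
#' @param fractions named numeric cell-type fractions.
#' @param neutrophil name of the neutrophil component.
#' @param lymphocytes names of the lymphoid components summed in the
#'   denominator.
#' @return the ratio (`NA` when the lymphocyte fraction is zero).
#' @export
computeNLR <- function(fractions, neutrophil = "neutrophil",
                       lymphocytes = c("b_cell", "cd4_t", "cd8_t", "nk")) {
  lym <- sum(fractions[intersect(lymphocytes, names(fractions))])
  if (!length(lym) || lym == 0) return(NA_real_)
  unname(fractions[neutrophil] / lym)
}

#' Rescale flow-cytometry subsets to complete-blood-count group totals
#'
#' Each group of flow-cytometry subsets (the lymphoid subsets; the
#' neutrophil/eosinophil/monocyte group) is proportionally rescaled so its
#' sum matches the blood-count total for that group.
#'
#' @param fcm named numeric subset proportions.
#' @param groups named list of character vectors partitioning (a subset
#'   of) `names(fcm)`.
#' @param cbcTotals named numeric, one total per group.
#' @return adjusted named proportions for the grouped subsets.
#' @export
normalizeFCM <- function(fcm, groups, cbcTotals) {
  out <- fcm
  for (g in names(groups)) {
    members <- groups[[g]]
    s <- sum(fcm[members])
    if (s == 0) stop(sprintf("group '%s' has zero total", g))
    out[members] <- fcm[members] * cbcTotals[[g]] / s
  }
  out
}

#' Select expression-correlated promoter CpGs and merge them into clusters
#'
#' A CpG is a candidate when (1) its Pearson correlation with its gene's
#' expression is below `corThreshold`, (2) it lies in the promoter
#' (`promoterUp` bp upstream to `promoterDown` bp downstream of the TSS,
#' strand-aware), and (3) more than `minNeighbors` other CpG sites lie
#' within `neighborWindow` bp. Candidates whose `mergeFlank` bp flanks
#' overlap merge into one cluster (interval = union of the flanks);
#' isolated candidates get an `isolatedFlank` bp flank.
#'
#' @param meth CpG x sample methylation matrix (rownames = cpg ids).
#' @param expr gene x sample expression matrix (rownames = genes).
#' @param cpgAnnotation data.frame(cpg_id, contig, pos, gene).
#' @param tssTable data.frame(gene, contig, tss, strand).
#' @param corThreshold correlation threshold (default -0.15, strict `<`).
#' @param promoterUp,promoterDown promoter extent around the TSS
#'   (defaults 1000 and 750 bp).
#' @param neighborWindow neighbor window half-width (default 75 bp).
#' @param minNeighbors required neighbor count, strict `>` (default 5).
#' @param mergeFlank merge flank half-width (default 100 bp).
#' @param isolatedFlank isolated-cluster flank half-width (default 75 bp).
#' @return list with `candidates` (data.frame: cpg_id, gene, contig, pos,
#'   r) and `clusters` (data.frame: gene, contig, start, end, n_cpgs,
#'   with a `members` list column of CpG positions).
#' @export
selectCorrelatedCpGs <- function(meth, expr, cpgAnnotation, tssTable,
                                 corThreshold = -0.15, promoterUp = 1000L,
                                 promoterDown = 750L, neighborWindow = 75L,
                                 minNeighbors = 5L, mergeFlank = 100L,
                                 isolatedFlank = 75L) {
  shared <- intersect(colnames(meth), colnames(expr))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  meth <- meth[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]
  ann <- cpgAnnotation
  ann <- ann[ann$cpg_id %in% rownames(meth) & ann$gene %in% rownames(expr), ,
             drop = FALSE]
  r <- vapply(seq_len(nrow(ann)), function(i)
    suppressWarnings(cor(meth[ann$cpg_id[i], ], expr[ann$gene[i], ])),
    numeric(1L))
  tssIdx <- match(ann$gene, tssTable$gene)
  tss <- tssTable$tss[tssIdx]
  minus <- tssTable$strand[tssIdx] == "-"
  pLo <- ifelse(minus, tss - promoterDown, tss - promoterUp)
  pHi <- ifelse(minus, tss + promoterUp, tss + promoterDown)
  inProm <- ann$contig == tssTable$contig[tssIdx] &
    ann$pos >= pLo & ann$pos <= pHi
  nNeigh <- vapply(seq_len(nrow(ann)), function(i)
    sum(ann$contig == ann$contig[i] &
          abs(ann$pos - ann$pos[i]) <= neighborWindow) - 1L,
    integer(1L))
  cand <- !is.na(r) & r < corThreshold & inProm & nNeigh > minNeighbors
  candidates <- data.frame(cpg_id = ann$cpg_id[cand], gene = ann$gene[cand],
                           contig = ann$contig[cand], pos = ann$pos[cand],
                           r = r[cand], stringsAsFactors = FALSE)
  clusters <- NULL
  members <- list()
  for (g in unique(candidates$gene)) {
    cc <- candidates[candidates$gene == g, , drop = FALSE]
    cc <- cc[order(cc$contig, cc$pos), , drop = FALSE]
    for (ct in unique(cc$contig)) {
      p <- cc$pos[cc$contig == ct]
      fl <- IRanges(p - mergeFlank, p + mergeFlank)
      red <- reduce(fl, min.gapwidth = 0L)  # merge on overlap only
      ov <- findOverlaps(IRanges(p, width = 1L), red)
      for (k in seq_along(red)) {
        mem <- sort(p[queryHits(ov)[subjectHits(ov) == k]])
        span <- if (length(mem) == 1L)
          c(mem - isolatedFlank, mem + isolatedFlank)
        else range(c(mem - mergeFlank, mem + mergeFlank))
        clusters <- rbind(clusters, data.frame(
          gene = g, contig = ct, start = span[1L], end = span[2L],
          n_cpgs = length(mem), stringsAsFactors = FALSE))
        members[[length(members) + 1L]] <- mem
      }
    }
  }
  if (is.null(clusters))
    clusters <- data.frame(gene = character(0L), contig = character(0L),
                           start = integer(0L), end = integer(0L),
                           n_cpgs = integer(0L))
  clusters$members <- members
  list(candidates = candidates, clusters = clusters)
}

#' Promoter hypermethylation status of a gene
#'
#' `TRUE` iff the mean beta over the cluster's member CpG sites exceeds
#' the threshold (strict `>`); `NA` (flagged) when no member is covered.
#'
#' @param calls `GRanges` from [callMethylation()] (CpG context used).
#' @param cluster one row of the `clusters` table from
#'   [selectCorrelatedCpGs()], or any list with `contig` and `members`.
#' @param threshold beta threshold (default 0.07).
#' @return logical (or `NA`).
#' @export
geneMethylationStatus <- function(calls, cluster, threshold = 0.07) {
  members <- if (is.list(cluster$members)) cluster$members[[1L]]
             else cluster$members
  sel <- as.character(seqnames(calls)) == as.character(cluster$contig) &
    start(calls) %in% members & calls$context == "CpG"
  if (!any(sel)) return(NA)
  mean(calls$beta[sel]) > threshold
}

#' Expected B-allele frequency and normalized depth under (M, N)
#'
#' With tumor purity `p` and tumor ploidy `psi`, a gene with major/minor
#' allele copy numbers (M, N) has expected BAF
#' `(M p + (1 - p)) / ((M + N) p + 2 (1 - p))` and expected normalized
#' depth `((M + N) p + 2 (1 - p)) / (psi p + 2 (1 - p))`.
#'
#' @param M,N integer allele copy numbers (`M >= N >= 0`).
#' @param purity tumor purity in (0, 1].
#' @param ploidy tumor ploidy.
#' @return list(`baf`, `depth`); `baf` is `NA` when the locus has zero
#'   total copies in a pure tumor.
#' @export
lohExpected <- function(M, N, purity, ploidy) {
  tot <- (M + N) * purity + 2 * (1 - purity)
  baf <- ifelse(tot > 0, (M * purity + (1 - purity)) / tot, NA_real_)
  depth <- tot / (ploidy * purity + 2 * (1 - purity))
  list(baf = baf, depth = depth)
}

#' Fit major/minor allele copy numbers and call LOH
#'
#' Maximum-posterior grid search over integer `(M, N)` with
#' `M >= N >= 0`, `M <= maxCopies` and a uniform prior: Gaussian
#' likelihood on the observed normalized depth and B-allele frequency
#' around their expectations under tumor purity and ploidy
#' ([lohExpected()]). LOH is called when `N = 0` and `M >= 1`.
#'
#' @param normDepth observed normalized depth(s) for the gene.
#' @param baf observed B-allele frequenc(ies); `NA` entries contribute
#'   only through depth.
#' @param purity tumor purity in (0, 1].
#' @param ploidy tumor ploidy (default 2).
#' @param maxCopies grid bound on M (default 8).
#' @param sdBaf,sdDepth Gaussian observation standard deviations
#'   (defaults 0.05 and 0.1).
#' @return list(`M`, `N`, `loh`, `logLik`).
#' @export
fitLOH <- function(normDepth, baf, purity, ploidy = 2, maxCopies = 8L,
                   sdBaf = 0.05, sdDepth = 0.1) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  grid <- expand.grid(N = 0:maxCopies, M = 0:maxCopies)
  grid <- grid[grid$M >= grid$N, , drop = FALSE]
  grid <- grid[order(grid$M + grid$N, grid$M), , drop = FALSE]
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    e <- lohExpected(grid$M[i], grid$N[i], purity, ploidy)
    s <- sum(dnorm(normDepth, e$depth, sdDepth, log = TRUE))
    ok <- !is.na(baf) & !is.na(e$baf)
    if (any(ok)) s <- s + sum(dnorm(baf[ok], e$baf, sdBaf, log = TRUE))
    s
  }, numeric(1L))
  best <- which.max(ll)
  list(M = grid$M[best], N = grid$N[best],
       loh = grid$N[best] == 0L && grid$M[best] >= 1L,
       logLik = ll[best])
}

#' Classify biallelic loss of gene function
#'
#' `TRUE` iff any of the four rules holds: homozygous deletion; LOH with
#' promoter methylation; LOH with at least one deleterious mutation; two
#' or more deleterious mutations.
#'
#' @param events data.frame with columns `loh`, `promoter_methylated`,
#'   `deleterious_mutations`, `homozygous_deletion` (one row per
#'   gene/patient event).
#' @return logical vector.
#' @export
classifyBiallelic <- function(events) {
  events$homozygous_deletion |
    (events$loh & events$promoter_methylated) |
    (events$loh & events$deleterious_mutations >= 1L) |
    events$deleterious_mutations >= 2L
}

#' Association between biallelic loss and HRD status
#'
#' Two-sided Fisher exact test on the (biallelic, not) x (HRD, HRP)
#' patient table.
#'
#' @param biallelic logical per patient (biallelic loss in >= 1 gene).
#' @param hrd logical per patient (HRD vs HRP).
#' @return list(`table`, `p`).
#' @export
hrdAssociation <- function(biallelic, hrd) {
  if (!any(hrd) || all(hrd)) stop("need both HRD and HRP patients")
  tab <- matrix(c(sum(biallelic & hrd), sum(biallelic & !hrd),
                  sum(!biallelic & hrd), sum(!biallelic & !hrd)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("biallelic", "not_biallelic"),
                                c("HRD", "HRP")))
  list(table = tab, p = fisherExact(tab))
}

#' Greedy panel design over mutation incidence cohorts
#'
#' Starting from the base exon set, repeatedly adds the exon that
#' maximizes the minimum-across-cohorts proportion of patients with at
#' least one detectable mutation (ties broken by column order), until
#' that proportion strictly exceeds `target` in every cohort or no exon
#' adds coverage (then the best achievable panel is returned with a
#' warning).
#'
#' @param incidence binary patient x exon matrix, or a named list of such
#'   matrices (one per cohort, shared exon columns).
#' @param baseExons character vector of exons always included
#'   (default none).
#' @param target coverage target, strict `>` (default 0.85).
#' @return character vector of exons (base first, then additions in
#'   selection order) with a `coverage` attribute (per-cohort final
#'   coverage).
#' @export
designPanelGreedy <- function(incidence, baseExons = character(0L),
                              target = 0.85) {
  if (is.matrix(incidence)) incidence <- list(cohort = incidence)
  exons <- colnames(incidence[[1L]])
  cov <- function(sel) vapply(incidence, function(m)
    if (length(sel)) mean(rowSums(m[, sel, drop = FALSE]) > 0L) else 0,
    numeric(1L))
  selected <- intersect(exons, baseExons)
  current <- cov(selected)
  repeat {
    if (min(current) > target) break
    candidates <- setdiff(exons, selected)
    if (!length(candidates)) {
      warning(sprintf("coverage target %.2f unreachable; best %.4f",
                      target, min(current)))
      break
    }
    gains <- vapply(candidates, function(e) min(cov(c(selected, e))),
                    numeric(1L))
    best <- candidates[which.max(gains)]
    if (max(gains) <= min(current)) {
      warning(sprintf("coverage target %.2f unreachable; best %.4f",
                      target, min(current)))
      break
    }
    selected <- c(selected, best)
    current <- cov(selected)
  }
  structure(selected, coverage = cov(selected))
}

#' qPCR positivity calls for the co-detection assay
#'
#' The mutation is positive iff its cycle threshold is strictly below
#' `ctThreshold`; hypermethylation is positive iff either marker's
#' delta-Ct is strictly below its threshold. Missing values (failed
#' amplification) are negative.
#'
#' @param ctMutation mutation assay Ct value(s).
#' @param deltaCtA,deltaCtB methylation marker delta-Ct values.
#' @param ctThreshold mutation Ct threshold (default 26).
#' @param dctAThreshold,dctBThreshold marker thresholds (defaults 10 and
#'   10.5).
#' @return data.frame(mutation_positive, methylation_positive).
#' @export
qpcrCall <- function(ctMutation, deltaCtA, deltaCtB, ctThreshold = 26,
                     dctAThreshold = 10, dctBThreshold = 10.5) {
  mut <- !is.na(ctMutation) & ctMutation < ctThreshold
  meth <- (!is.na(deltaCtA) & deltaCtA < dctAThreshold) |
    (!is.na(deltaCtB) & deltaCtB < dctBThreshold)
  data.frame(mutation_positive = mut, methylation_positive = meth)
}
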