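---
title: "Co-detecting mutations and methylation from one duplex library: models and methods"
author: "mmseqtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-detecting mutations and methylation from one duplex library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmseqtools)
```

## The assay this package models

Bisulfite or enzymatic conversion reads out DNA methylation by deaminating
unmodified cytosines to uracil (sequenced as thymine), but in doing so it
destroys the very C:G base identities a mutation caller needs. The
co-detection strategy implemented here sidesteps the usual
split-the-sample workaround: before conversion, a *protective copy strand*
is synthesized along each original strand using a deamination-resistant
cytosine analog (5-propynyl-dCTP). After conversion, the library contains
two read populations from every double-stranded molecule:

* **original strands** — methylation-informative: unmethylated cytosines
  read as T, methylated CpGs read as C (the MM-meth stream);
* **protected copies** — sequence-informative: all cytosines intact, so
  genuine variants are preserved (the MM-genet stream).

The two populations are separated *computationally*, by the conversion
state of the 8-base UMIs ligated to both duplex ends. UMIs come from a
fixed pool (32 sequences by default): a read pair whose UMIs match a pool
sequence exactly is a protected copy; a pair whose UMIs match the C-to-T
(or, on the opposite mate, G-to-A) collapse of a pool sequence is a
converted original strand. For this to be unambiguous the pool must be
**collision-free**: no exact or collapsed form of one member may equal any
form of another. `UMIPool()` validates this by brute-force comparison of
all forms; since the vendor's actual 32 sequences are not published, the
package ships a generated collision-free stand-in
(`inst/extdata/umi_pool_synthetic.txt`, `generateUMIPool()`).

Because both streams carry the *same* UMI pair (one exact, one collapsed)
and map to the same coordinates, fragments from the two streams can be
re-joined into duplex pairs, phasing methylation and genotype on the same
molecule — the basis of allele-specific methylation analysis.

## Stream assignment

`classifyReadPair()` looks each mate's UMI up in order: exact match,
C-to-T index, G-to-A index; an N never matches. The pair-level rule is
deliberately conservative:

* both mates exact → MM-genet;
* both mates converted-matched (either collapse per mate) → MM-meth;
* anything else, including discordant mates → unassigned.

The underlying per-read description leaves discordant pairs open; we
require mate agreement because a single misassigned protected copy in the
methylation stream (or vice versa) corrupts both downstream callers,
whereas discarding a discordant pair costs only coverage. Discordant
pairs are counted in `DemuxStats`. Each mate accepts either collapse
because which mate shows C-to-T versus G-to-A depends on which strand the
sequencer happened to read first, which is not controlled.

No mismatch tolerance is applied at classification (assignment is by
*perfect* match, as the assay defines it); the 1-mismatch UMI allowance
exists only in duplicate marking, a distinct use with a distinct purpose.

## The simulator: what it emulates, and what it does not

`simulateLibrary()` generates the full causal chain so that every
downstream stage can be scored against planted truth:

1. random reference contigs at a configurable GC content, with optional
   spike-in analogs held at fixed methylation levels (an unmethylated
   lambda-like contig, a fully or partially CpG-methylated pUC19-like
   contig for dilution series);
2. duplex molecules of fixed fragment length, uniform over the genome;
   per-CpG truth betas, drawn per molecule as one Bernoulli state shared
   by both strands of the dyad;
3. planted variants carried per molecule at their allele fraction;
4. UMI attachment from the pool; `2^c − 1` protected copies per original
   strand for `c` copy cycles (1 for genomic DNA, 3 for cell-free DNA).
   The exponential-doubling count is *our* model of the pre-amplification
   step — all the chemistry guarantees is that extra cycles compensate
   template loss — and is isolated in `nProtectedStrands()`;
5. conversion: an unmethylated C converts with probability
   `conversionSensitivity` (default 0.9989), a methylated CpG survives
   with probability `conversionSpecificity` (default 0.9743), a
   protected-copy C survives with probability `analogResistance` (default
   0.9985, consistent with the ~0.15% residual substitution rate of the
   propynyl analog). UMI cytosines are unmodified by design and convert
   like genomic unmethylated cytosines;
6. strand survival (default 0.8) modeling template loss during
   conversion, then PCR duplication (default rate 0.1).

Default truth betas follow a bimodal landscape — a 50/50 mixture of
Beta(0.5, 8) and Beta(8, 0.5) — giving the hypo/hypermethylated valley
structure and ~50% genome-wide mean methylation characteristic of
whole-genome methylomes.

Deliberately **not** modeled: sequencing errors other than conversion
events, indels, fragment-size distributions of real cfDNA, partial
read/fragment overlap (fragments are fully spanned by both mates), and
variant effects on the methylation stream (variants are expressed only in
genetic-stream base calls; a variant that creates or destroys a cytosine
is a second-order effect the simulator ignores). Passing tests therefore
demonstrate the *logic* of each stage under the assay's own statistical
model, not robustness to alignment artifacts or error modes absent from
that model.

## Methylation calling and conversion QC

Duplicates in the methylation stream are removed on exact coordinates
(the MarkDuplicates convention); the genetic stream's duplicate
definition is looser — coordinates within 5 bp and UMI pairs within 1
mismatch per mate — reflecting its consensus-building purpose. Both run
through one clustering routine (`clusterFragments()`), whose key always
includes the duplex strand class derived from the flag pair: without it,
the Watson- and Crick-original strands of one molecule (identical
coordinates, different UMIs) would be collapsed as "duplicates", halving
dyad coverage. The cluster representative is the first member in sort
order — determinism over quality heuristics; quality-aware selection is a
consensus concern and lives in `clusterConsensus()`.

`callMethylation()` aggregates observed cytosine states into per-site
counts and betas in CpG/CHG/CHH context. Plus- and minus-strand CpG
calls are merged per dyad, keyed at the plus-strand C (the CX-report
convention; the alternative — strand-resolved reporting — is equivalent
information, and merging is what the downstream marker logic expects).
Fragments may carry explicit per-cytosine states (the simulator's native
records) or plain base calls, from which `deriveMethStates()`
reconstructs states against the reference.

Conversion QC follows the spike-in definitions: **sensitivity** is the
converted proportion of cytosines on the unmethylated lambda analog (all
contexts), **specificity** the unconverted proportion of CpG cytosines on
the methylated pUC19 analog, and the residual C-to-T/G-to-A substitution
rate of the genetic stream is measured over a user-supplied QC region
(typically an exome BED; the region is deliberately an input rather than
a built-in definition). With zero covered spike-in cytosines the metrics are returned as
`NA`, flagged rather than silently zero.

## Variants and copy number

`clusterConsensus()` collapses genetic-stream duplicate clusters to
per-position majority bases, masking positions below 70% agreement to N.
The 70%/N rule is this package's own concretization of consensus
building; it subsumes base-quality recalibration at the depths this
pipeline targets.
Germline SNPs come from a plain pileup with exactly the documented filters
(depth ≥ 10, ≥ 2 supporting reads, VAF ≥ 0.15) — no genotype model, by
scope. Somatic filtering is a pure predicate implementing the documented
exclusions: support ≥ 5 reads, VAF ≥ 0.1%, no C>T/G>A (deamination
artifacts; retained in the DNA-seq comparison mode), no white-blood-cell
sharing (clonal hematopoiesis), coding-impact annotation only. Annotation
is consumed as an input column rather than computed from a gene model, to
avoid shipping an annotation database.

Copy number uses 10 kb bins, drops bins under 1× coverage, divides by the
genome-wide median, and removes the GC trend with a LOWESS fit (when GC
is degenerate the median stands in for the fit, so uniform-GC inputs pass
through exactly). Copy number is **2 × corrected ratio**: the candidate
thresholds of 3.5 and 0.5 read naturally on a diploid copy-number scale
(rather than the ratio scale), and both stay configurable for anyone
preferring the other reading. Segmentation is threshold run-length with
≥ 3 consecutive bins — the simplest rule that yields segment-level
calls.

## Duplex phasing and allele-specific methylation

`pairDuplex()` joins deduplicated fragments across streams on (identical
coordinates, canonical pool-UMI pair, consistent strand class), where the
strand classes are fixed flag pairs: Watson molecules show genetic flags
99/147 with methylation flags 67/131, Crick molecules 83/163 with
115/179; supplementary/secondary alignments are out of scope and dropped
upstream. Matching is greedy one-to-one in sort order, so rare ambiguous
keys (same span *and* same UMI pair) resolve deterministically.

`asmTest()` allocates each pair to an allele by the genetic base at the
SNP, accumulates methylated/unmethylated CpG observations within ±200 bp
of the SNP (a default chosen to span the typical probe footprint;
configurable), and applies a two-sided Fisher exact test by the
minimum-likelihood method (`stats::fisher.test`, cross-checked in the
test suite against a brute-force hypergeometric enumeration for all
tables with n ≤ 30). A zero margin yields a flagged `NA`, not a p value.

## Clinical decision layers

* **ctDNA fraction** (`ctdnaFraction()`): over hypermethylated marker
  regions, fragments reporting ≥ 5 marker CpGs are eligible; an eligible
  fragment with *all* covered marker CpGs methylated counts as
  tumor-derived. Positivity (`callCtdnaStatus()`) is exactly the documented
  boolean: any kept somatic mutation, or fraction > 0.1% with ≥ 3 ctDNA
  fragments and ≥ 3000 eligible fragments. All boundaries are strict as
  documented.
* **Immune cfDNA deconvolution** (`immuneFractions()`,
  `calibrateFractions()`): each marker is unmethylated in exactly one
  cell type; a fragment must report every marker CpG to count, and the
  "requisite" unmethylated-CpG count defaults to *all* of them —
  symmetric with the fully-methylated ctDNA rule — with a per-marker
  override for marker sets that tolerate partial methylation. Calibration is one OLS line per cell type against
  blood-count training pairs, negatives clipped, then renormalized to sum
  exactly to 1. `computeNLR()` derives the neutrophil-to-lymphocyte
  ratio; by scope it is reported, never used for ctDNA calling.
* **Promoter CpG selection** (`selectCorrelatedCpGs()`): Pearson r <
  −0.15 against the gene's expression, position inside the promoter
  (1000 bp upstream to 750 bp downstream of the TSS — implemented
  strand-aware, the reading we consider biologically coherent), and more
  than five
  other CpGs within 75 bp. Candidates merge when their 100 bp flanks
  overlap; isolated candidates get a 75 bp flank. Hypermethylation is
  mean cluster beta > 0.07, strict.
* **LOH** (`fitLOH()`): a grid search over integer major/minor copy
  numbers (M ≥ N ≥ 0, M ≤ 8, uniform prior) maximizing a Gaussian
  likelihood around the expectations
  `BAF = (Mp + (1−p)) / ((M+N)p + 2(1−p))` and
  `depth = ((M+N)p + 2(1−p)) / (ψp + 2(1−p))` for purity p and ploidy ψ.
  Independent Gaussian errors with configurable SDs (0.05 on BAF, 0.1 on
  depth) are the simplest identifiable observation model for this
  maximum-posterior formulation. Ties resolve to the
  lowest total copy number, then lowest M. LOH is N = 0 with M ≥ 1;
  biallelic loss (`classifyBiallelic()`) is any of: homozygous deletion,
  LOH + promoter methylation, LOH + deleterious mutation, two deleterious
  mutations.
* **Panel design** (`designPanelGreedy()`): greedy marginal gain on the
  proportion of patients with ≥ 1 detectable mutation, until the
  proportion strictly exceeds 85% in *every* cohort. With multiple
  cohorts the objective is the minimum cohort coverage: maximizing the
  minimum guarantees every cohort progresses, which single-cohort
  marginal gain does not. Ties break by column order; an unreachable target
  returns the best achievable panel with a warning.
* **qPCR calls** (`qpcrCall()`): mutation positive iff Ct < 26;
  hypermethylation positive iff marker-A ΔCt < 10 or marker-B ΔCt < 10.5;
  missing values are negative.

## Numerical and testing choices

Fragments live in `MMFragments`, a `GRanges` subclass, so coordinates are
1-based closed inside the package — the container's single native
convention — with converters applied exactly once at I/O boundaries
(BED's 0-based half-open, SAM's 1-based). UMIs travel in SAM read names
as a `:UMI1-UMI2` suffix, aligner-agnostic.

All generator randomness flows from one seed per configuration, and
library code restores the caller's RNG state. Problem sizes in the test
suite are desk-scale choices: ~50,000 read pairs for demultiplexing
checks, 200 kb of genome at ~24× molecule-level coverage for methylation
recovery (dyad states are drawn once per molecule, so molecule coverage —
not strand coverage — is the effective binomial depth), a 10 Mb genome
for copy-number detection, 100 duplex pairs per allele for
allele-specific methylation, and 2000 fragments per marker over 20 seeds
for deconvolution.

## Known limitations

The simulator's omissions above bound what green tests mean for real
data. Beyond those: the pipeline consumes aligned fragments and does not
perform (conversion-aware) alignment; indels and structural variants are
out of scope; tumor purity, ploidy and HRD scores are inputs, not
estimates; the shipped UMI pool is a synthetic stand-in, so real
libraries demultiplexed against it would be nonsense — supply the
vendor's pool file. The residual substitution-rate QC depends on the
supplied QC region and measures the fragment-level rate over both C and
G positions, which is half the single-strand rate when errors are
strand-specific.
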