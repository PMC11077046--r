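---
title: "Per-nucleotide transcriptomic pileups with mate bridging: models and methods"
author: "txpileup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-nucleotide transcriptomic pileups with mate bridging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txpileup)
```

## The problem

Beyond counting reads per gene, an RNA-seq alignment carries four
per-nucleotide "read-outs": coverage, read starts, read ends, and the
identity of the base calls (including deletions) relative to a reference.
Chemistries used in epitranscriptomics turn RNA modifications into
signatures in exactly these read-outs: carbodiimide adducts on
pseudouridine and antibody crosslinks at m6A block reverse transcription
and pile cDNA starts up one nucleotide downstream of the modified base;
borohydride reduction of ac4C makes the reverse transcriptase read a C as
a T; modification-sensitive RNases convert modification status into
coordinated read ends and starts. Quantifying any of these needs a table
with one row per transcript nucleotide — in transcript coordinates,
because the transcript is the functional unit — built from reads that
were aligned in genomic space.

txpileup implements that conversion and summarization, with one
deliberately distinctive choice: in paired-end data the two mates of a
fragment are *bridged*, so the whole insert from the start of read 1 to
the end of read 2 counts toward coverage, including the unsequenced
stretch between the mates. A 150-nt fragment sequenced as two 40-nt mates
still certifies that no truncation or cleavage occurred anywhere inside
its 70-nt interior; tools that count only sequenced bases discard that
information.

## Data model

**TranscriptModel** holds one BED record: chromosome, strand, ordered
disjoint exon blocks, and an optional CDS span. BED input is 0-based
half-open; everything the package exposes is 1-based inclusive (the SAM
convention), and transcript coordinate 1 is the transcript 5' end, so
minus-strand genes count down the genome. BED6 records are promoted to
single-block BED12 with no CDS. Overlapping exon blocks within a record
are rejected rather than silently merged, and CDS endpoints must fall on
exonic positions — both are treated as annotation errors worth failing
loudly on. Duplicate names across records are allowed; each record is an
independent model and tables carry the BED name verbatim.

**TxFragments** stores, per gene, the bridged fragment spans
(`txStart`, `txEnd`) and a sparse set of base calls: one `(position,
base)` entry for every sequenced or deleted position. The inter-mate gap
has no entries by construction — that single representation choice *is*
the bridging semantics: spans feed coverage, calls feed base counts, and
the two never conflate.

**The per-base table** has one row per transcript nucleotide with both
coordinate systems (`chrom`, `gencoor`, `strand`, `gene`, `txcoor`), the
reference base `refSeq` when a genome is supplied, and the read-outs
`cov`, `start_5p`, `end_3p`, `A`, `C`, `G`, `T`, `N`, `del`. Two
structural identities hold by construction and are re-verified by
`validateTxTable()`:

* `cov(1) = start_5p(1)` and
  `cov(i) = cov(i-1) + start_5p(i) - end_3p(i-1)` for `i > 1`;
* `sum(start_5p) = sum(end_3p) =` number of fragments, and
  `A+C+G+T+N+del <= cov` everywhere.

`refSeq` is reported whenever a genome is given, in every summarization
mode: the reference base column depends only on the availability of the
reference, not on which counts were requested.

## Read-to-transcript conversion

A segment is accepted for a model only if every aligned (M) and deleted
(D) CIGAR block lies inside the exon union **and** every N gap coincides
exactly with an annotated intron. Exact junction concordance (rather than
mere containment) was chosen because a read whose splice does not match
the model's intron chain did not come from that transcript; near-miss
junctions are alignment artifacts we prefer to drop. Soft-clipped bases
and insertions have no reference position and contribute nothing;
deletions occupy their reference positions as `-` calls. On minus-strand
models base calls are complemented so that everything downstream works in
transcript orientation.

Mates are merged by taking the union span and the union of calls; where
mates overlap and agree the call is kept once, where they disagree it
becomes `N`. Arbitrating which mate is right would require quality
modeling the package deliberately avoids; `N` keeps the denominator
honest without double-counting. The fragment strand is the alignment
strand of read 1 (FR library layout); `strandMode` can require it to
match the model (`same`, the default), be opposite, or be ignored. Merged
spans longer than `maxFragment` (default 1000 nt; 300 is a typical choice
for short-fragment protocols) are discarded as likely chimeric pairs.
Pairs with exactly one usable mate are discarded rather than demoted to
single-end — demotion would give those fragments different coverage
semantics than the rest of the library — and the discard report counts
them (`halfPair`) along with `strand`, `structure`, `span` and
`offAnnotation` rejections, classified by the furthest pipeline stage the
pair reached against any candidate model. A pair compatible with several
overlapping isoforms yields one fragment per isoform.

## Metrics

All ratio metrics leave `NA` where their denominator is zero — a position
without data is missing, not zero — and missing values always *fail*
site-calling predicates.

* `startRatio(i) = start_5p(i) / cov(i)`.
* `startRatio_1bpDS(i) = startRatio(i+1)`, within the same gene; the last
  position of each gene is `NA`. The shifted ratio uses the coverage at
  `i+1` in its denominator because it is literally the start ratio one
  base downstream — the statistic that peaks *at* a
  reverse-transcription-blocking modification. The treated-minus-control
  difference `SRD_1bpDS` is produced by `addDiff()` on row-aligned
  tables.
* `misincRate(i)` is the fraction of unambiguous calls (`A,C,G,T`)
  differing from `refSeq(i)`. `N` and deletions are excluded from both
  numerator and denominator; an `includeDeletions` flag adds deletions to
  both (keeping the ratio in `[0, 1]`) for cleavage-style chemistries.
  Positions whose reference base is not `A/C/G/T` are `NA`.
* `MR_CtoT` (generally `MR_<from>to<to>`) restricts to reference-`from`
  positions and counts `to` calls over unambiguous calls; `MRD_CtoT` is
  again an `addDiff()` column.
* Motif annotation scans each transcript sequence with a 15-letter IUPAC
  motif (DNA alphabet, `U` normalized to `T`); position `p` is marked
  when the motif, anchored with its `centerOffset`-th letter (default the
  central one) on `p`, matches. Scanning never crosses gene boundaries.

## Statistical tests

`rowTtests()` is a vectorized two-sample t-test per transcript position
across replicate tables, pooled variance by default (Welch by flag).
Degenerate rows follow explicit conventions: zero within-group variance
with a nonzero difference gives a `±Inf` statistic with p = 0; a zero
difference always gives statistic 0, p = 1; any missing replicate value
makes the row's result missing. Raw p-values are reported because the
downstream use case thresholds raw p; Benjamini–Hochberg adjustment is
available through `p.adjust` on the result column if wanted.

`rowBinomialLRT()` compares a per-position proportion (successes over
trials, e.g. starts over coverage, or converted calls over total calls)
between two groups: counts are summed within each group and a
one-degree-of-freedom likelihood ratio of per-group binomial proportions
against the pooled proportion is referred to the chi-square distribution.
The `0·log 0 = 0` convention keeps boundary proportions finite. A
negative-binomial count-model test is the heavier classical alternative
here; the binomial LRT was chosen as a self-contained test on the
proportion scale the metrics already live on, and its exactness is
checked against a direct log-likelihood oracle in the test suite.

## Metagene, flanks, logo data, peaks

Flank extraction takes, for every `TRUE` position of a logical column,
the values of a chosen column in a window of half-width `w`; windows are
padded with `NA` where they leave the transcript. The metagene matrix
bins each coding gene's 5'UTR, CDS and 3'UTR into fixed bin counts using
equal-width position intervals computed from that gene's own region
boundaries (position `k` of a region of length `L` falls in bin
`floor((k-1)·b/L) + 1`); a region shorter than its bin count leaves its
trailing bins `NA`. The position frequency matrix counts reference bases
at each window offset over a set of sites — the data behind a sequence
logo.

The peak caller is intentionally simple plumbing: a centered,
edge-truncated moving average (`smoothW`), strict local maxima at or
above `minCov`, and greedy merging of candidates closer than `minGap`
keeping the highest (ties to the leftmost, making results deterministic).
It exists to demonstrate the bridging effect — fragment-shaped coverage
is unimodal over the captured site in paired mode but bimodal in
single-end mode whenever the insert is longer than twice the read length,
so bridged processing centers peaks on the site far more often — not to
compete with dedicated peak callers, and its absolute peak counts should
not be compared across tools.

## The simulator

The generator emulates the study conditions the rest of the package is
tested under: a uniform-random multi-chromosome genome; non-overlapping
genes on both strands with 1–3 exons (configurable), intron widths of
50–200 nt, and a CDS with non-empty UTRs whenever the transcript reaches
90 nt; and a paired-end library of normal-length fragments (default mean
150, sd 20, clipped to 100–300 nt) with uniform starts over the positions
where the whole fragment fits, sequenced as the terminal 40 nt of each
end. Modification effects are injected per fragment: `rt_stop` moves the
fragment 5' end to one nucleotide downstream of the site with the given
probability (a fragment ending exactly at the site cannot be truncated
and is left intact); `misinc` substitutes the configured base at the site
in the fragment's sequence; `cleavage` splits a spanning fragment into
two at the site. An optional immunoprecipitation model keeps fragments
spanning a designated site and retains others only at a background rate —
the enrichment shape of antibody-based m6A protocols. Per-base sequencing
errors are applied last, independently per mate, so overlapping mates can
genuinely disagree. Alignments are written directly as coordinate-sorted
SAM (correct spliced CIGARs, flags, mate fields) rather than through an
external aligner; this keeps the conversion step testable in isolation
and the whole pipeline free of alignment ambiguity.

What the simulator does *not* model — coverage and GC bias, PCR
duplicates, quality scores, misalignment — bounds what passing tests
show: they certify the bookkeeping, the coordinate algebra, and the
recovery of injected effect sizes under clean sampling noise, not
robustness to real-library artifacts.

All randomness is derived from a single integer seed (distinct fixed
offsets for the genome, annotation and library stages), output is
byte-identical across runs, and the caller's RNG state is restored.

## Numerical and interface choices

* Tables serialize as TSV with fixed canonical column names and `"."`
  for an absent reference base; round-trips are lossless and shuffled
  column order is normalized on read. Unknown columns on read are an
  error (typo protection), with an `extraCols` escape hatch.
* `unifyTxTables()` restricts all tables to their common genes in the
  first table's order and treats a per-gene length mismatch as an
  annotation error.
* Gene subsampling uses an explicit seed and restores the caller's RNG
  state.
* The command-line front end (`inst/scripts/txpileup.R`) is a thin layer
  over the exported functions; `-r` is interpreted as the maximum merged
  fragment span and `-m` as the minimum number of assigned fragments for
  a gene to be reported, logging goes to standard error only, and the
  data output is byte-reproducible.

## Problem sizes used in the checks

The test suite verifies the pileup against a brute-force per-position
oracle on a 10-gene × 1000-fragment paired library (exact integer
equality on every column), exercises the coordinate round-trip
exhaustively on 50 random multi-exon models on both strands, recovers an
injected RT-stop contrast of 0.8 vs 0.02 and a C→T conversion contrast of
0.30 vs 0 from 2000-fragment libraries at a marked site, checks the null
calibration of both row-wise tests on 5000 simulated positions, and
contrasts paired against single-end peak centering on 200 genes with one
methylated DRACH site each. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-supplied seed and writes the
measured quantities as JSON.

## Known limitations

Processing is single-threaded; the per-gene decomposition (each gene's
fragments and table rows are independent) is what a parallel scheduler
would exploit, but none is built in. Reads are not deduplicated and no
UMI handling exists. Base qualities are ignored apart from an optional
minimum mapping quality. Long-read data can be processed as single-end
spliced alignments, but no platform-specific error model is applied.
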