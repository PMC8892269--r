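---
title: "Detecting translation-dependent silencing signatures: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting translation-dependent silencing signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsilence)
library(dplyr)
```

## The biological question

When a transposable element such as the *Ty1/Copia* retroelement EVADÉ
invades a plant genome de novo, post-transcriptional gene silencing (PTGS)
must be triggered without any pre-existing small-RNA identity for the
intruder. In the system this package models, the element expresses two mRNA
isoforms: a spliced, short subgenomic mRNA (the translated GAG message,
generated by splicing-coupled premature cleavage and polyadenylation) and
an unspliced full-length genomic mRNA. Translation of the short isoform is
accompanied by an unusually intense and discrete ribosome stalling event;
the mRNA breaks there, leaving 3' fragments with 5'-hydroxyl (5'OH) ends
that escape the 5'-phosphate-dependent exonucleolytic quality control and
can serve as templates for RNA-DEPENDENT RNA POLYMERASE 6 (RDR6), whose
dsRNA products are diced into 21/22-nt siRNAs. The analytical signature of
this "translation-dependent silencing" is a three-way coincidence, in one
coordinate system, of

1. the maximal codon-level ribosome occupancy (the stall),
2. the 5' starting point of the siRNA coverage pattern, and
3. the modal 5'OH breakage position recovered from RACE clones.

`tdsilence` implements each measurement, the statistics used to rank the
stall transcriptome-wide, the supporting quantifications (polysome
association, qPCR relative expression and element copy number), and
sequence-intrinsic scans (codon adaptation, GC/GC3, G-quadruplex, ORF
content) used to test candidate causes of stalling. A seeded synthetic-data
generator reproduces the statistical structure of all the input data so the
whole pipeline is testable end to end.

## Models and statistics

### P-site offsets and codon occupancy

Ribosome footprints (25–32 nt) are assigned a P-site at `5' end + offset(L)`
where the length-dependent offset is calibrated on start-codon metagenes:
for each length `L`, `offset(L)` is the candidate distance
`d in [6, L - 6]` maximizing the weighted number of reads whose 5' end lies
exactly `d` nt upstream of an annotated start codon, with ties broken to
the smallest `d`. Only lengths with at least `min_support` (default 100)
such reads are calibrated; reads of uncalibrated lengths are dropped rather
than guessed. All three frames pool into the codon the P-site falls in
(`floor((psite - cds_start)/3) + 1`), and counts accumulate fractional
multimapper weights (weight `1/n` for a read reported at `n` loci).

The candidate window and the support threshold are this package's
decisions; they are configurable and the defaults are stated here rather
than inherited from any upstream tool.

### The stalling score

For a transcript with per-codon P-site counts `c_1..c_n` (stop codon
excluded from everything, and the stop-containing di-codon excluded from
the pair search), the stalling score of codon `i` is

    score_i = c_i / mean(c)

the observed count over the expectation under uniform occupancy. By
construction the mean score over included codons is 1. Two further
summaries are reported: the maximal score with its codon, and the
*pair fraction* — the largest share of the transcript's occupancy carried
by two adjacent codons, `max_i (c_i + c_{i+1}) / sum(c)`. Transcripts are
ranked transcriptome-wide by their maximal score; the percentile of a
transcript is the percentage of qualified transcripts with a *strictly*
larger maximal score, so the most intensely stalled transcript scores 0.

Qualification filters: only the most translated isoform per gene enters the
ranking, and only if at least 70% of its sense codons carry a nonzero
P-site count. The 70% is interpreted at codon (not nucleotide) resolution,
with `>=` at the boundary; both choices are configurable.

### Codon dwell time and usage

Per qualified transcript the occupancy is normalized by its mean and
log-transformed as `ln(c_i/mean + eps)` with `eps = 0.5/mean` — a
half-read pseudo-count, chosen because the literature phrase
"log-normalized" fixes no formula; the dwell time of a codon is the mean of
this quantity over every instance of that codon. Codon usage is the
sense-codon frequency spectrum of the qualified CDSs (stop codons are
absent from both maps).

### siRNA profiles and onset detection

Small-RNA coverage is stratified by size class (21/22/24/other nt, the
DCL4/DCL2/DCL3 classes) and strand, in reads per million; each read adds
`weight * 1e6/library_total` to every position it covers. The 5' onset of
the siRNA pattern is found by fitting a single change-point, two-level
piecewise-constant model by least squares over all candidate breakpoints of
the pooled 21+22-nt track, and is reported only when the model reduces the
sum of squared errors of the flat fit by more than 25% (configurable).

The field has no operational definition of a pattern's "5' starting point",
so the change-point rule is this package's definition. One numerical choice
deserves emphasis: by default the change-point is fitted to the track of
read 5'-boundary positions (each read counted once, at its leftmost covered
coordinate) rather than to covered-position coverage. Covered-position
coverage rises over a ~21-nt ramp at the true boundary, which biases a
two-level least-squares breakpoint about half a read length 3' of the true
onset; the boundary track has a sharp step at the true start and removes
that bias. `stat = "coverage"` restores the literal coverage-based fit.

### 5'OH breakage ends

RACE clone inserts are mapped by their first `anchor_k = 25` bases,
allowing one mismatch, after optional adapter stripping and trailing-N
trimming; a clone maps only if its anchor occurs exactly once in the
reference (no full aligner is needed at Sanger scale, and ambiguity is
treated as failure rather than guessed). The modal breakage position is the
2-nt window (the breakage signature is a two-nucleotide doublet) capturing
the most mapped 5' ends, reported with its clone count and fraction, plus
the single most frequent end. Nucleotide-to-codon conversion is
`ceiling(nt/3)`. Both the reference-relative and ORF-relative coordinates
are reported, because a breakage nucleotide at the first position of codon
`k` belongs to codon `k` while the following nucleotide pair may already
touch codon `k + 1`; the package reports both systems and does not
hard-code a reconciliation.

### Abundance and qPCR

The polysome association score is `log2((polysome + q)/(total + q))` on
RPKM (the abundance unit is a package decision; only "abundance" is fixed
by the problem). Quartile partitioning of features by siRNA level places
boundaries at the empirical 25/50/75 percentiles; tied keys share a
quartile, and the degenerate all-tied case assigns quartile 1 everywhere
with a warning. Relative expression is `2^(Ct_ref - Ct_target)` with
replicate Cts and multiple reference genes averaged arithmetically — the
delta-Ct exponentiation reading of a "Ct ratio", the only one consistent
with fold-change semantics. Element copy number from genomic-DNA qPCR is

    copies(s) = 2 * 2^(dCt(s) - dCt(calibrator)),   dCt = Ct_ref - Ct_element

anchored on the two genomic element copies and single-copy reference gene
of a wild-type calibrator. Amplification efficiency is fixed at perfect
doubling (configurable); the estimate is invariant to per-sample
instrument offsets by construction.

### Sequence scans

The codon adaptation index uses family-relative weights
`w = f/max(f over synonymous family)` and the geometric mean over codons,
excluding Met, Trp and stops; zero-frequency reference codons receive half
the smallest positive family frequency so the geometric mean stays
defined. GC and GC3 are centred sliding-window means at codon resolution,
truncated at the ends. G-quadruplex propensity uses run-length scoring
(each base of a G run of length `r` scores `+min(r, 4)`, C runs the
negative) averaged in 25-nt windows with a 1.2 hotspot threshold — a
transparent published-style scheme chosen because no specific scorer is
fixed by the problem; window and threshold are arguments. The ORF-content
statistic is the longest ATG-to-stop frame over both strands divided by
element length.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions; its defaults are the conditions
under which the package's tests and the acceptance script run.

* **Locus geometry**: a 40-nt leader, a 300-codon ORF (plus stop), a
  120-nt trailer to the premature poly(A) site; an exon1–intron–exon2
  layout with a 150-nt intron 3' of the stall so that siRNAs span the
  exon–exon junction; 400 nt of tail transcribed only in the full-length
  isoform. The stall pair sits at codons 148–149 (fixed to proline CCA and
  glycine GGT), the breakage/siRNA breakpoint at ORF nt 447 — the first
  nucleotide of codon 149, near the middle of the ORF.
* **Footprints**: lengths 25–32 nt with a mode at 28, true offsets 10–13 nt,
  frame-0 periodicity 0.9, translation weights 0.95/0.05 for the
  short/full-length isoform. Dwell is uniform except a 5-fold initiation
  boost — the start-codon peak universal in ribosome-profiling metagenes,
  and the feature that makes offsets identifiable from a start-codon
  metagene at all (under perfectly uniform occupancy the argmax ties across
  `d, d - 3, d - 6, ...`) — and the stall multiplier. The default
  multiplier of 80 per stall codon reproduces the observed design point of
  roughly 35% of elongating ribosomes sitting on the two stall codons of a
  300-codon ORF; note that a multiplier `m` yields an expected pair
  fraction `2m/(N - 2 + 2m)` for `N` sense codons, so with a stall beyond
  codon 148 no multiplier of 20 can push the pair fraction past ~0.21.
* **siRNAs**: sizes 21/22/24 at 0.5/0.3/0.2, both strands equally, reads
  placed (by their leftmost coordinate) uniformly 3' of the breakpoint so
  that no duplex extends 5' of the breakage point, plus a 2% uniform
  background over the locus.
* **RACE clones**: 36 clones, 5/6 of which start exactly at the breakpoint
  (the 30-of-36 design point), 80–200 nt long; the rest start uniformly
  elsewhere.
* **Counts and Ct tables**: negative-binomial counts (dispersion 0.05)
  around configured abundances and log2 polysome enrichments; Ct values
  with Gaussian well noise (sd 0.2), four technical wells and four
  biological samples per genotype — a design chosen, before any testing,
  from a simple power analysis so that a 40-copy line is recoverable
  within 15% at that noise level.

The generator deliberately omits sequencing errors, quality scores, PCR
duplicates, rRNA contamination, nucleotide-composition biases of library
chemistry, and alignment ambiguity beyond a fractional multimapper weight.
Passing tests therefore demonstrate that the estimators are correct on data
satisfying the stated statistical model, not that they are robust to every
artefact of real libraries; adapter trimming and alignment are consumed as
already-done inputs by design.

## Numerical and coordinate conventions

In-memory coordinates are 1-based inclusive throughout — the R/Bioconductor
convention shared by `IRanges`/`GRanges`/`Biostrings`, which all interval
arithmetic here leans on — and user-facing reports are likewise 1-based
(positions print the way they are quoted in the literature, e.g.
"nucleotides 447–448"). On disk, bedGraph and the documented 6-column
tabular alignment format keep their native 0-based conventions and are
converted at the boundary. The tabular format
(`read_id, ref, start0, length, strand, n_hits`) exists so that alignment
fixtures stay plain text.

Deterministic tie-breaks everywhere: smallest candidate offset, leftmost
modal window, leftmost change-point, smallest codon index at equal scores,
stable input order at equal quartile keys. Degenerate inputs are defined
rather than undefined: zero-occupancy transcripts are flagged unqualified
(not scored), a flat siRNA track yields "no onset", an all-tied quartile
key warns, and an empty qualified set is an error. Every simulator is a
pure function of its configuration; a seed plus the config reproduces
byte-identical output, and the end-to-end run log records the seed, the
full configuration and checksums of every artifact written.

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic data
at sizes chosen as this package's reference workloads: 50,000 footprints on
the two-isoform locus, a 200-gene background transcriptome (150–200 codons
per gene) for percentile ranking, 20,000 siRNAs per onset replicate with
50 seeded replicates, 36 RACE clones per tally with 200 seeded replicates,
and 16-well qPCR designs. At these sizes the whole suite completes in
about a minute on a single core.

## Known limitations

* The SAM reader covers the subset the pipeline needs (primary/secondary
  flags, M/N/D CIGARs, leading/trailing soft clips); indels and chimeric
  alignments are out of scope, as is BAM.
* Differential expression is a normalized log-ratio with a pseudocount,
  not a shrinkage estimator; it stands in for genotype comparisons at
  single-locus scale only.
* The change-point model assumes one onset; loci with multiple siRNA
  blocks would need a multi-segment extension.
* Dwell times are means of log-normalized occupancies, not a full
  codon-level regression; they are intended for ranking, not for absolute
  dwell estimation.
* The percentile ranking is only as representative as the qualified set;
  with shallow libraries the 70% coverage filter removes long ORFs first,
  which should be kept in mind when comparing percentiles across depths.
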