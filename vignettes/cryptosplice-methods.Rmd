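---
title: "Discovering non-productive splicing and its NMD signature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering non-productive splicing and its NMD signature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptosplice)
```

## The problem

Budding yeast has few introns, but the introns it has are spliced with
imperfect fidelity: the spliceosome sometimes selects a donor (5'-SS) or
acceptor (3'-SS) a handful of nucleotides away from the annotated site.
Most such products shift the reading frame or splice in a stop-codon-bearing
stretch of intron, creating a premature termination codon (PTC). PTC
transcripts are degraded by nonsense-mediated decay (NMD), so they are
nearly invisible in wild-type cells and accumulate when NMD is inactivated
(*upf1Δ*, *upf2Δ*, *upf3Δ*). `cryptosplice` implements the computational
side of this study design: it discovers splice junctions from gapped
RNA-seq alignments, decides which junctions are alternative (unannotated)
within intron-containing genes (ICGs), reconstructs and translates each
splice product to call PTCs, quantifies unspliced pre-mRNA signal, and
tests for enrichment of these non-productive species in NMD mutants
relative to wild type.

Because the real study is a genome-scale experiment, the package also
contains a first-class simulator: a toy genome of ICGs with planted
alternative splice sites and an explicit NMD decay model, which supplies
ground truth for every stage of the pipeline and drives all tests.

## The two-step mapping policy

Reads are 75-nt single-end. The toy aligner reproduces a two-step policy:

1. **Ungapped step.** Every read is scanned exhaustively against both
   strands of every chromosome; the score is the mismatch count, at most 4.
   All locations tying the best score are returned.
2. **Gapped step.** Only reads with *no* ungapped placement at all are
   retried with a single gap (the intron): every split of the read into a
   prefix and suffix of at least 12 nt each, with a gap of 10–20,000 nt,
   again keeping all best-score placements at up to 3 mismatches.

A read is kept only if its best score is achieved at **at most two**
genomic locations; gaps shorter than 10 nt are never produced. Kept
two-location reads are counted at both locations and flagged
(`n_best = 2`), and junction tables carry their support in separate
`ambig_*` columns so downstream users can audit them. Alignments
containing indels are outside the model and the SAM reader rejects them.

Numerical choices worth stating:

* The 12-nt minimum anchor is a design choice of this package (the policy
  itself states no anchor); it prevents spurious 1–2-nt anchors at toy
  scale. It also means a junction-spanning read with a shorter overhang is
  *unfindable by construction* — the simulator's truth tables are the
  reference for such reads.
* Step precedence is strict: a read with a poor (4-mismatch) ungapped
  placement is never retried gapped, even if a perfect gapped placement
  exists. This follows from the policy's step order.
* `N` bases never match anything, including other `N`s.
* When the junction boundary base repeats (the first intron base equals
  the first base of the downstream exon), the same read has two
  score-tied gapped placements shifted by one; both are reported, and the
  two-location filter treats them as distinct locations. This
  micro-ambiguity is why exact truth-count recovery is validated through
  the truth-alignment (SAM) interface rather than through the aligner.

The aligner is exhaustive and intended for toy genomes (tens of
kilobases). For real data the pipeline ingests external spliced
alignments in SAM via `read_alignments()`, which preserves the policy's
filter semantics (gap bounds from the `N` CIGAR operator, mismatches from
`NM`, location counts from `NH`).

## Junctions, events and splice products

`extract_junctions()` collapses gapped alignments into one event per
distinct `(chrom, intron_start, intron_end)` with per-sample counts.
`classify_events()` assigns a junction to a gene when its interval lies
entirely inside the gene's span — the library is unstranded, so the
junction inherits the gene's strand — and labels it `annotated` (exact
match to an annotated intron), `alternative` (inside an ICG but not
annotated), or `outside_icg` (everything else, excluded from event
statistics). Junctions contained in two genes are reported once per gene
and flagged rather than silently resolved. The minimum read support for
an event defaults to 1: any sequencing-supported junction counts.

`build_splice_product()` rebuilds the mRNA that one junction implies: the
single annotated intron the event overlaps is replaced by the event's
excision, all other introns are spliced canonically, and exonic sequence
inside the excision is removed. Events overlapping zero or two annotated
introns are refused (compound events are handled one junction at a time,
which matches the RNA-seq observable: one junction per read).
`call_ptc()` then translates from the *annotated* CDS start — the product
is anchored on the canonical transcript — and:

* flags a **PTC** when the first in-frame stop (TAA/TAG/TGA, standard
  nuclear code) lies strictly upstream of the canonical stop's position
  mapped onto the product;
* flags a **frameshift** exactly when the excised length changes by a
  non-multiple of 3;
* flags `start_lost` (excluded from PTC statistics) when the event
  removes the start codon, and `nonstop` when no stop remains;
* marks every PTC product an **NMD candidate** by default. The faux-3'-UTR
  model (long 3' UTRs trigger NMD, very short ones may escape) is
  available as an optional `utr3_threshold`; it is off by default because
  the underlying analysis applies no systematic threshold.

`protein_consequence()` reports the affected amino-acid stretch by the
codon span covering the nucleotide-level difference between the canonical
and product CDS (for example `VCT -> QTSVDST at 2-4`, or `Δ10 aa 12-21`
for an in-frame deletion). Working at the nucleotide level matters: a
protein-level greedy diff can swallow a residue that the two mRNAs encode
with different codons at the splice boundary.

## Counting and statistics

* **Unspliced signal** per ICG sums reads whose aligned blocks overlap an
  intron by ≥ 1 nt — fully intronic reads and exon–intron boundary reads
  alike. Gapped reads whose gap equals an annotated intron are spliced
  transcripts and never count. Note that reads spanning an *alternative*
  junction can still retain intronic sequence in their blocks and then
  contribute to the unspliced signal; this slightly dilutes the measured
  unspliced enrichment below the event-level value, and the same boundary
  effect is discussed in the original analysis.
* **Depth normalisation** scales each sample by
  `reference_total / sample_total` (reference = first sample); raw counts
  are kept alongside.
* **Enrichment** vs wild type is reported per unit and in aggregate, with
  an upper-tail Poisson p-value: the wild-type count (depth-scaled) is the
  Poisson mean and the mutant count the observation,
  `P(X >= k)`. The upper tail is the enrichment-direction reading of
  "probability of observing the mutant count"; the point-probability
  reading is rejected as non-monotonic. Wild-type zeros receive a
  pseudocount of 0.5 by default so folds and p-values stay defined (the
  source analysis is silent on this; disable with `pseudocount = 0`).
  Event-level aggregates use unique-event counts; read-supported counts
  are available through `junction_counts_long(unique_events = FALSE)`.
  P-values are raw; Benjamini–Hochberg correction is available
  (`adjust_bh()`) but not applied by default.
* **RPKM** is `count / ((len/1000) * (total/1e6))`;
  `abundance_stratification()` bins gene RPKM with a catch-all final bin
  (default 2,300 RPKM) and reports group medians for genes with and
  without detected alternative events.
* **Consensus logos**: `build_pfm()` tallies per-position base
  frequencies over unique events (not read support — the logos summarise
  splice sites, not depth), with an optional pseudocount;
  `info_content()` is the standard `2 + Σ f log2 f` bits per position.
  The small-sample correction is off by default, with a flag to enable.
  Default windows are 6 nt of donor (covers the GUAUGU consensus) and the
  last 8 intronic nt for the acceptor (polypyrimidine context plus the
  terminal YAG); both are configurable, as the exact logo extents in the
  source figure are not numerically specified.

## The simulator and its decay model

`sim_config()` / `build_toy_genome()` construct one synthetic chromosome
of two-exon ICGs on both strands. Each gene has a clean ORF (ATG, random
sense codons, TAA) split across the exon boundary, a canonical intron
with GTATGT donor, TACTAAC branchpoint, a pyrimidine-rich tract and a YAG
acceptor, and the configured alternative sites planted as degenerate
motifs (donor pool GTTTGT/GTACGT/GCATGT/GTAAGT/GTATGA, acceptor pool
AAG/CAG/GAG/TAG — the kind of near-consensus variants seen at real
alternative sites). A registry records each planted event's coordinates
and its expected PTC/frameshift status, computed by directly splicing the
planted strings and translating them with Biostrings — an independent
code path from the genomic-coordinate reconstruction in the PTC module,
which is what makes the registry usable as an oracle.

Each gene has isoforms: canonical, one per alternative event, and
unspliced pre-mRNA. NMD decay is a single **retention factor**
`r ∈ (0, 1]`: in the NMD-competent genotype every NMD-target isoform's
pre-decay proportion is multiplied by `r` and the gene's proportions are
renormalised; NMD-deficient genotypes keep pre-decay proportions. Targets
are the PTC-generating isoforms plus (by default, configurable) the
unspliced isoform. No kinetics are modelled — the measured quantities are
steady-state ratios, for which a retention factor is sufficient. Under
this model the expected mutant/wild-type ratio of a target's read count
is `Z/r` in closed form, where `Z = 1 − (1 − r)·p_target` is the
renormaliser; `calibrate_retention()` inverts the exact closed form (via
`expected_event_reads()`) to place the aggregate NMD-target enrichment at
a chosen value such as the 1.7 scale of the study.

Reads are sampled gene ∝ a per-gene log-normal abundance draw (meanlog
log 50, sdlog 1 — a typical right-skewed expression distribution), then
isoform ∝ post-decay proportions, then start position uniform along the
isoform (no positional bias; the simplest defensible model), sequenced
from either strand with probability ½ (the protocol is unstranded), with
i.i.d. substitution errors (default 0.001/base, an Illumina-like rate).
Default pre-decay proportions are canonical 0.7, alternative 0.1 (shared
across a gene's events), unspliced 0.2, and `r = 0.5` — with all-target
events these give exactly the 1.7-fold study scale, since
`Z/r = (1 − 0.3·0.5)/0.5 = 1.7`. Exons are kept at least as long as the
read (default 120–400 nt) so a read crosses at most one junction; introns
default to 80–400 nt, the range of typical yeast introns. What the
simulator does *not* emulate: positional/GC coverage bias, quality-score
structure, paired ends, PCR duplicates, multi-intron genes, and genuinely
novel genes — so passing tests demonstrate the correctness of the
pipeline's logic under the stated model, not robustness to every artefact
of real libraries.

## Problem sizes and verification

The package's own acceptance checks (in `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) run at sizes chosen to give stable statistics
on a single CPU:

* Poisson tail vs direct pmf summation over λ ∈ [0.1, 50], k ≤ 200, at
  1e-12.
* The two-step aligner vs a Biostrings-based enumeration of every
  (position, split, gap) placement: 20 random 10-kb genomes × 200 reads
  mixing exact, mutated, junction-spanning, sub-threshold-gap,
  multi-mapping and random reads; results must be identical, filters
  included.
* PTC/frameshift calls vs the registry's translation oracle on 500
  planted events (250 genes × 2), plus the universal frame-arithmetic
  identity.
* Parameter recovery: 50 ICGs, 4 genotypes × 200,000 reads, retention
  calibrated so the closed-form target enrichment is 1.7; the measured
  read-supported fold (mutants pooled) must contain 1.7 in its 95% CI.
  The CI uses the log-scale normal approximation
  `SE = sqrt(1/Σmut + 1/Σwt)`, slightly conservative for multinomial
  sampling.
* Exact truth recovery at `error_rate = 0` through the SAM interface:
  every planted junction recovered with exact per-sample counts, zero
  spurious junctions.
* Logo relaxation: mean information content of alternative-site PFMs
  strictly below canonical-site PFMs when degenerate motifs are planted.

At 200,000 reads per genotype the unique-event enrichment saturates near
1 (every planted event is detected in every sample); the discriminating
measured quantity at this depth is the read-supported target enrichment,
and `scripts/acceptance.R` reports both. One known limitation follows
from the containment rule for gene assignment: junctions that straddle a
gene boundary are flagged rather than assigned, and events in terminal
exons are interpreted with the same single-overlapped-intron rule as
internal ones — a stated interpretation, since the source analysis does
not specify its terminal-exon handling.
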