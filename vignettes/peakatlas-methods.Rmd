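---
title: "peakatlas: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakatlas: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakatlas)
```

`peakatlas` treats the peak list — a table of half-open, 0-based genomic
intervals — as the universal currency: every module consumes peak lists and
emits peak lists (or plot-ready tables keyed by them). This vignette
explains the statistical models behind each module, the parameters that
matter and why their defaults are what they are, the synthetic data the
test suite runs on, and the numerical and design choices made where more
than one reasonable convention exists.

## Coordinates and formats

All internal coordinates are 0-based half-open (the BED convention). SAM
positions (1-based) are shifted on input; fixedStep wiggle output is
shifted back on output. Overlap always means positive-width intersection:
abutting intervals (`[0,10)` and `[10,20)`) do not overlap. Readers exist
for BED3+/BED6, SAM text, refGene-style transcript tables, FASTA (with
`.fai` emission for generated genomes), fixedStep wiggle and bedGraph
score tracks, JASPAR PFM matrices and GMT gene-set collections; all
round-trip through their paired writers.

## The interval engine

Interval comparison uses one augmented balanced binary search tree per
chromosome: nodes are keyed by interval start and store the maximum end
coordinate of their subtree, which lets a query skip any subtree whose
maximum end precedes the query start. The query is the *all-overlaps*
variant — it walks every branch that can still contain an overlap instead
of stopping at the first hit. `compare_intervals()` builds its three modes
(overlap / unique / merge) on this engine and guarantees that overlap and
unique partition the first set exactly; merge coalesces transitively
overlapping intervals into disjoint spanning blocks and is idempotent.

The Jaccard index between two peak files is computed on the connected
components of the merged pair: J = (components containing peaks from both
files) / (all components). This is the only reading of
"overlapping / union" that is symmetric, bounded by 1, and insensitive to
which file is named first; it is also the convention the tests pin down
with a hand-computed three-interval case (J = 1/2).

## Gene-part annotation

A peak collects candidate labels against every transcript and receives one
*primary* category by the fixed priority

promoter > exon > first intron > intron > downstream > distal > other.

* **promoter** — a `promoter_window` (default 4000 bp) window centered on
  the TSS, clipped so it never extends past the transcript's downstream
  extremity (a 1 kb gene does not acquire a 2 kb "promoter" running out of
  its far end).
* **first intron** — the 5′-most intron in transcription order, reported
  separately for its regulatory relevance.
* **downstream** — `downstream_window` (default 2000 bp) past the TES. The
  width is our choice; only the category's existence is canonical.
* **distal** — no gene-part overlap and ≥ `distal_min` (default 2000 bp)
  from every transcript.
* **other** — near a gene (< `distal_min`) but in no part. With the
  default windows this category has empty territory (the promoter and
  downstream windows tile the 2 kb flanks); it exists so that the
  categories always partition the peak set, and becomes populated when
  `distal_min` exceeds the flanking windows.

The same priority applied per base labels the whole genome, yielding the
*expected* fraction of each category for comparison with observed peak
fractions, and the category territories used by the randomization null.
The per-base labeling and the per-peak classification are constructed to
agree exactly: a peak's category equals the highest-priority label among
the bases it covers, except that covering any near-gene ("other") base
pulls an otherwise-distal peak under the distance cutoff. This equivalence
is what makes the randomization's conservation law testable bit-exactly.

Multi-transcript genes are classified per transcript and collapse to gene
symbols in the link table; a peak may link to several genes but has one
primary category. Whole-peak overlap drives part labels; peak midpoint
drives distance measures.

## The randomization null

`overlap_significance()` holds the second peak set fixed and redraws the
first `n_rand` times (default 100). Each replicate conserves, exactly: the
number of peaks, the per-chromosome multiset of peak lengths, and every
peak's gene-part category. Placement is uniform over all positions on the
peak's chromosome where a peak of its length classifies into its own
category. Sampling proposes uniformly over placements touching the
category's territory and rejects those whose re-classification differs
(e.g. a placement that also grazes a higher-priority promoter base); the
original position is always valid, so acceptance has positive probability
by construction. We chose this over placing peaks wholly inside territory
segments because gene parts are often shorter than peaks — a 500 bp peak
overlapping a 300 bp exon cannot fit inside it, yet its randomized twin
must still classify as exonic for the conservation law to hold. For peaks
whose territory is degenerate even for the proposal, a midpoint-inside-
territory fallback is used with a warning.

The p-value uses add-one smoothing, p = (1 + #(rand ≥ obs)) / (1 + n_rand),
so it is never 0 and is conservative under ties; the z-score is flagged
undefined when the randomized counts are constant. Calibration is checked
by drawing the first set from the generator's own null: over 200 replicates
at `n_rand = 99`, the fraction of p ≤ 0.05 must sit inside the binomial
99% band around 0.05, and z must be near standard normal (|mean| < 0.2,
sd within [0.8, 1.25]).

## Peak calling

The caller is a thresholded extended-read coverage design: reads extend to
`fragment_length` (default 200 bp) in their strand direction (minus reads
leftward from their 3′ end), candidate bases have coverage ≥ `t` (default
15), candidate runs separated by < `max_gap` (default 200 bp) merge,
regions shorter than `min_len` (default 100 bp) drop, and the control
filter keeps regions whose library-size-normalized ChIP/control ratio
reaches `fold` (default 2), with a one-read pseudocount on the control so
empty control windows cannot divide by zero. Summits are the leftmost
coverage maximum (deterministic tie-break). Raising `t`, `fold` or
`min_len` never increases the peak count, and every stricter-setting peak
is contained in a looser-setting peak. These defaults are our own
reconstruction of a standard design family; they are deliberately
conservative for point-source factors at the fixture's coverage
(background mean 4, spikes near 40).

## Motif scanning and backgrounds

PWM columns are scored by the ratio of each base's pseudocounted count to
the column maximum: w[b,i] = ln((n[b,i]+pc)/(n[b*,i]+pc)), pc = 0.5. The
consensus word therefore scores exactly 0 and every window's *relative
affinity* exp(score) lies in (0, 1]; a window is a hit when it reaches τ
(default 0.5), on the forward strand and the reverse complement. Windows
containing N are rejected rather than penalized. The affinity-threshold
semantics (exp(score) ≥ τ rather than a fraction of the dynamic range) is
one of two defensible readings; it has the convenient property that τ = 1
returns exactly consensus occurrences.

Four background generators produce one length-matched control per peak:

* **random** — uniform placement over the genome;
* **adjacent** — flanks immediately left/right of each peak, alternating
  sides to avoid directional bias, shifted inward at chromosome ends;
* **CGI** — placement stratified so the background set reproduces the
  peaks' CpG-island overlap fraction: the target number of backgrounds is
  drawn overlapping an island and the rest strictly outside. We chose
  stratified placement over resampling whole batches until the fraction
  matches, because batch resampling has a vanishing success probability
  whenever the genomic island fraction differs from the peaks' fraction —
  stratification achieves the required fraction exactly, every time;
* **1MM** — a synthetic sequence per peak from that peak's own first-order
  Markov chain, started at the source's first base, falling back to
  mononucleotide frequencies for unseen contexts. Pooled dinucleotide
  frequencies of the backgrounds track the sources within 0.02.

## Pathway association

Counting is gene-level (a gene with five promoter peaks contributes once).
The association p-value is the hypergeometric upper tail via `phyper`;
tests verify it against exhaustive subset enumeration for every design
with N ≤ 12. The default universe is the intersection of the gene-model
symbols with the collection; genes outside the universe never enter N, K,
n or k. Benjamini–Hochberg correction is applied across the tested family
(sets with at least `min_set` members), switchable off.

## Conservation and read density

Per-peak mean conservation uses a *strict* threshold (mean > threshold,
default 0.5, natural for phastCons scores in [0, 1]); uncovered bases
default to 0 (`missing_policy = "zero"`, appropriate for near-complete
phastCons tracks) or can be excluded (`"skip"`). Profiles center a 2000 bp
window on the summit (midpoint when no summit is available), with 10 nt
bins → 200 bins; windows running off a chromosome end are flagged
truncated and excluded from the group mean rather than zero-padded, which
would bias edge bins downward. Random-region profiles reuse the same
lengths and machinery.

Density matrices center 4000 bp on the TSS/TES/summit with 10 nt bins →
400 columns; minus-strand rows are flipped so column 1 is always 5′-most.
The bin statistic is mean per-base coverage, which obeys an exact
conservation law (Σ bins × bin_bp = extended-read base overlap with the
window) that the tests assert. RPKM multiplies by 1e9 / (bin_bp ×
total_reads) — invariant under read duplication, linear in depth.

Clustering offers a built-in online SOM (rectangular grid, Gaussian
neighborhood, radius max(grid)/2 and learning rate 0.5 → 0.01 decaying
linearly over 100 epochs, seeded weight initialization), Lloyd k-means and
average-linkage hierarchical clustering; all are deterministic given the
seed, and per-cluster region lists export as BED/gene lists.

## The synthetic fixtures

`make_fixture()` writes a complete input bundle from a single seed:
a 350 kb two-chromosome genome (i.i.d. bases, GC-rich planted CpG
islands), 20 non-overlapping multi-exon genes, 30 truth peaks of 500 bp,
ChIP reads at 0.02 reads/bp background with spikes giving 10× local
enrichment (the control shares the background generator), a bedGraph
conservation track at 0.8 over truth peaks versus 0.1 elsewhere, a strong
10-bp motif embedded in 80% of truth peaks, CpG islands over 30% of them,
three mark tracks covering 70/30/50% of them plus decoys, and a gene-set
collection whose planted set is the genes nearest the truth peaks. Every
file is a deterministic function of the seed (byte-identical across runs),
and `truth.json` records all memberships for oracle checks — including the
enhancer-style workflow distal → mark1⁺ → mark2⁻ → cofactor⁺, which the
tests verify against brute-force set algebra at every stage.

What the fixtures do *not* emulate: mappability holes, duplicated reads,
copy-number and chromatin-accessibility bias in the background, motif
degeneracy gradients, and realistic gene density. Passing tests therefore
establish algorithmic correctness and calibration under a clean generative
model, not performance on real libraries; caller thresholds in particular
should be re-tuned on real depth.

## Problem sizes and determinism

The default test run uses the 350 kb fixture throughout; the acceptance
suite runs 10⁴ interval-tree query instances against linear scans, 10³
random set pairs for partition/merge laws, 200 null replicates at 99
randomizations for calibration, 20 seeded fixtures for caller
recall/precision, and 10 seeds each for conservation contrast and planted
k-means recovery — sizes chosen so the whole suite completes in about a
minute of compute while keeping binomial test bands meaningful. Every
stochastic API takes an explicit seed, records it in its result, and
restores the caller's RNG state on exit.
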