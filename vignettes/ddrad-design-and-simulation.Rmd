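---
title: "Designing and validating ddRAD experiments with ddradkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating ddRAD experiments with ddradkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradkit)
library(dplyr)
```

## The problem

Double-digest RAD sequencing (ddRAD-seq) reduces a genome to a reproducible
subset of restriction fragments: DNA is cut with two enzymes, fragments
falling in a chosen size window are retained, and only fragments flanked by
one cut site of each enzyme (*AB fragments*) receive both sequencing
adapters and amplify. The number of sequenced tags is therefore controlled
by two dials — the enzyme pair and the size-selection window — and both can
be evaluated entirely in silico before any bench work.

ddradkit implements that computational layer end to end:

1. **in silico digestion** of genomes with degenerate (IUPAC) recognition
   sites and fragment-class accounting;
2. **enzyme-pair screening** across genomes, with a linear model of tag
   yield against genome size;
3. **library design**: variable-length inline barcodes, shortened P1/P2
   adapters, combinatorial (barcode × pool index) sample sheets;
4. **read simulation** with the protocol's exact read anatomy, dispersed
   per-fragment depth, substitution errors and adapter read-through;
5. **demultiplexing and QC** with restriction-remnant validation,
   sliding-window quality filtering and pool-balance statistics;
6. **tag clustering** into per-sample tags, a cross-sample catalog of loci
   and a Phylip-exportable SNP matrix.

Everything is testable without downloads: the synthetic-genome generator
and the read simulator produce inputs with known ground truth, and each
downstream stage can be checked against that truth exactly.

## Digestion model

Recognition motifs are IUPAC patterns; `expand_iupac()` enumerates their
concrete expansions and matching is exact over those expansions. A window
containing any non-ACGT base (assembly gaps, ambiguity codes) never
matches — a deliberately conservative rule that avoids inventing sites
inside gaps. Minus-strand sites are scanned only for enzymes whose
expansion set is not closed under reverse complement; for palindromic-set
enzymes (every bundled one) the forward scan already finds everything.

Cut offsets are not something a digest report usually states, so the
bundled table carries the standard biochemical offsets (AvaII G^GWCC,
MspI C^CGG, EcoRI G^AATTC, PstI CTGCA^G, SbfI CC^TGCAGG, MluCI ^AATT,
NlaIII CATG^); user enzymes load from the same TSV format.

Conventions, stated once:

* coordinates are 0-based, intervals half-open (BED-compatible);
* fragment boundaries are **top-strand** cut coordinates; sticky-end
  overhangs are ignored for fragment length (error ≤ 4 bp per end);
* coincident cut coordinates from the two enzymes are deduplicated with an
  alphabetical label tie-break, which also makes
  `double_digest(g, A, B)` and `double_digest(g, B, A)` return identical
  intervals;
* size windows are inclusive on both ends ("between 400–700 bp" reads most
  plainly as inclusive);
* reported fragment counts default to the AB class only, since only AB
  fragments amplify; AA/BB/TERMINAL counts are retained and reportable,
  because published total-fragment tables do not always say which
  convention they use.

```{r digest-example}
frags <- double_digest(c(chr1 = "TTTGGACCTTTTCCGGTTT"), "AvaII", "MspI")
frags
```

## Screening pairs and modelling tag yield

`screen_pairs()` tabulates total and in-window AB counts per genome × pair.
`fit_genome_size_model()` then fits an unweighted ordinary least-squares
line of count on genome size in Mb — screens of real plant genomes show
close-to-linear growth of tag number with genome size, so the line lets a
project predict tag yield for an unscreened species from its C-value. No
transform is applied: the published relationship is shown on raw counts.
`summary_metrics()` computes the standard descriptive table of a sequenced
run; percentages round half-away-from-zero to two decimals, the usual
table convention.

```{r metrics}
summary_metrics(66547, 140, 383e6, 14146516, expected_tag_count = 60925)
```

One documented discrepancy: with 60,925 expected and 66,547 observed tags
the plain ratio is 91.55 %, yet 86.54 % has been quoted for the same rice
inputs. ddradkit implements the plain ratio (the maize column, 97.99 %,
is consistent with it) and does not chase the inconsistent figure.
Similarly, some published per-species depth values cannot be reproduced as
clean reads / tags under any evident convention; only internally
consistent quantities are reproduced here.

`compare_observed_expected()` correlates per-chromosome expected and
observed counts (Pearson), the standard consistency check between an in
silico digest and a sequenced run.

## Barcode and adapter design

Variable-length inline barcodes (4–8 bp) stagger the restriction remnant
across sequencing cycles, improving base diversity near the cut site. The
generator enforces, and `validate_barcode_set()` audits:

* **prefix-freeness** — with variable lengths the remnant, not a fixed
  position, delimits the barcode, so no barcode may be a prefix of
  another;
* **pairwise Levenshtein distance ≥ 2** — one-error detection; the
  distance is configurable, 2 is the default because the demultiplexer's
  default tolerance is 1 mismatch;
* **no site reconstitution** — a barcode must not end in bases that
  recreate the P1 enzyme's recognition site when followed by the read-side
  remnant (for AvaII, remnant GWCC: no terminal G);
* **length balance** — each length class within ±1 of an equal share.

Sets come in multiples of 20; pool indexes provide further multiplexing,
and `build_sample_sheet()` assigns samples round-robin so 40 samples over
20 barcodes and 2 pools use each barcode exactly twice, once per pool.
The published oligo batch itself is not bundled: the toolkit reproduces
the *design system* (the constraints above, as a generator), not one
vendor order. The exact staggered length distribution of any particular
published set is unknown; balance across the full 4–8 bp range is the
documented assumption.

P1 adapters follow the shortened-oligo length contract
`|P1| = 20 + |barcode|` (25 bp at the usual 5-bp barcode): a fixed stub
plus barcode plus the sticky-end overhang complementary to enzyme A's cut.
Only the length contract and the overhangs are normative; the stub content
is an Illumina-compatible placeholder. Blunt cutters are rejected — the
ligation chemistry requires sticky ends.

## Read simulation

For each sample, each in-window AB fragment receives *k* read pairs with
*k* ~ NegBin(mean `mean_depth`, dispersion `depth_dispersion`);
`depth_dispersion = Inf` is the deterministic limit (exactly `mean_depth`
pairs), used when conservation-style tests need exact counts. The negative
binomial was chosen because pool imbalance, not Poisson noise, is what the
CV analysis needs to exercise; no published depth model exists to copy.

Read anatomy: read1 = inline barcode + enzyme-A remnant (as present in the
genome, e.g. GACC/GTCC for AvaII) + insert; read2 starts with the enzyme-B
remnant (CGG for MspI) and reads the opposite strand from the other end.
Each enzyme end is extended to its outermost cut before reads are taken,
which models the sticky-end fill-in of library preparation and makes both
remnants emerge from genomic sequence rather than being pasted on. Read1
always starts at the P1 (enzyme-A) end; fragments occur in both A-left and
A-right genomic orientations, which is where the strand variety in the
library comes from. When read-through is enabled and the insert is shorter
than the read, the read continues into the reverse complement of the
opposite adapter — the classic short-insert contamination signature that a
3' adapter search must detect.

Errors are i.i.d. substitutions only (no indels): sufficient to exercise
demultiplexing tolerance and clustering mismatches, which are the
consumers being tested. PCR duplicates are not distinguished from
biological depth (the protocol has no UMI). Qualities are a constant Q37
with an optional 3' taper; published quality claims are coarse (">Q20
average, >Q30 at site bases"), so nothing finer is modelled. Per-sample
planted variants (`variants =`) give downstream SNP recovery an exact
truth set.

What the simulator does **not** emulate: platform-specific error profiles,
indels, optical duplicates, index hopping, GC-coverage bias, and
degraded-DNA site loss. Passing round-trip tests therefore demonstrate
pipeline correctness (lossless accounting, exact anatomy handling), not
robustness to every real-data pathology.

## Demultiplexing and QC

Candidate barcodes are compared over their own lengths at the read start,
longest first; an exact barcode-plus-remnant hit is unambiguous by
prefix-freeness and wins immediately. Otherwise the unique candidate
within `tol` mismatches whose downstream remnant also matches within `tol`
is taken; ties go to the unassigned bucket. The remnant anchor is what
makes variable-length matching well-posed under mismatches. Default
`tol = 1`, consistent with distance-2 sets. Pool-index matching is exact
(indexes are sequencer-demultiplexed in practice).

Quality filtering discards a read when any 15-base sliding window has mean
Phred < 10 (both parameters configurable). The pool-balance CV uses the
sample (n−1) standard deviation over the mean — "standard deviation /
mean" does not specify which estimator, so the choice is documented and
the function accepts any counts vector. The adapter search is an
overlap-mode 3' scan (≥ `min_overlap` bases, ≤ 10 % mismatches);
`min_overlap = 10` is a documented default since definitions of an
"adapter read" vary between any-overlap and full-match.

## Tag clustering

`build_stacks()` / `build_catalog()` / `match_and_genotype()` are an
explicit **simplification** of the ustacks/cstacks/sstacks stage of the
Stacks pipeline, built so the whole path stays self-contained and
oracle-testable:

* Hamming (not gapped) distance on fixed-length 140-bp tags;
* identical reads form exact stacks; stacks with depth ≥ `m` (default 10)
  seed tags, deeper seeds first; primaries within `M` (default 3)
  mismatches of an existing seed fuse into it, then shallow stacks join
  their nearest seed (ties to the deeper, then lexicographic);
* a 3-sigma depth cutoff (primary depth > mean + 3 sd of primary depths)
  flags repetitive stacks and excludes them — a stand-in for Stacks'
  removal/deleveraging heuristics, documented as such and not claimed
  equivalent;
* catalog building is greedy single-linkage at ≤ `n` (default 5)
  mismatches in deterministic (sample, consensus) order; consensuses are
  depth-weighted column majorities with lexicographic tie-breaks, so
  outputs are byte-stable;
* columns with more than two observed bases are retained and coded with
  IUPAC ambiguity in the Phylip export.

Read conservation holds at every stage: tag depths + dropped-short +
unmerged-below-m + repetitive-excluded = input reads, and the test suite
asserts it. `filter_fixed_among()` implements a fixed-within /
variable-among group filter with explicit parameters (the screening
thresholds used in published analyses are unstated, so none are guessed).

## Numerical and degenerate-input choices

* Reported percentages/densities: round half away from zero, 2 decimals;
  correlations and CVs: 4 decimals.
* `predict_tag_count()` floors predictions at 0.
* A perfectly flat screen response reports R² = 0 (computed directly, not
  via `summary.lm`, which is numerically unreliable on zero-variance
  responses).
* Empty windows simulate to empty FASTQ with a warning; contigs without
  sites yield a single TERMINAL fragment; zero-length fragments are
  impossible by construction (coincident cuts deduplicate).
* All randomness is seeded and locally scoped: generator, simulator and
  barcode search restore the caller's RNG state.

## Problem sizes used in the tests

The default suite runs entirely on synthetic data: digestion oracles on
1,000 random sequences up to 10 kb; a 1-Mb single-contig genome, 3 samples
at depth 20 for the end-to-end round trip; a 0.4-Mb genome, 40 barcoded
samples at dispersed depth for the pool-balance simulation; 100 seeds for
the barcode-constraint property. Reproducing published 23-genome screen
tables requires the original genome assemblies and is therefore not part
of the default suite — the oracle-equivalence tests cover the same code
path on synthetic sequence instead.

## Known limitations

* Star activity, methylation sensitivity, nicking and type IIB enzymes are
  out of scope; digestion is complete (no partial digests).
* Fragment lengths ignore overhang geometry (≤ 4 bp per end).
* The clustering stage approximates Stacks; on real data with indel
  polymorphism or paralogy its loci will differ from a Stacks run.
* Oligo thermodynamics (Tm, hairpins) are not checked in barcode/adapter
  design.
* Phylogenetic inference is downstream of the Phylip hand-off and out of
  scope.
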