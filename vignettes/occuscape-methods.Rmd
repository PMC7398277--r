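---
title: "Methods: co-occupancy, chromatin-state and motif analysis in occuscape"
author: "occuscape maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy, chromatin-state and motif analysis in occuscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter and their defaults, what the synthetic
regulome does and does not emulate, and the numerical choices made where the
design was genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and the interval engine

All coordinates are 0-based half-open `[start, end)` (BED convention), so
end-abutting intervals share no base and never intersect. Sorting is by
(chromosome lexicographic, start, end, name) under a locale-independent
ordering. Peak anchors are the narrowPeak summit when recorded (column 10,
offset from `start`, −1 when unknown), else `floor((start + end) / 2)`; all
summit-centric analyses use this anchor.

Merging peaks from many experiments into candidate loci offers three size
rules. `none` is the classic union merge requiring ≥ 1 bp of shared sequence.
`filter:W` union-merges and then discards merged loci wider than `W` bp — on
real compendia roughly the widest ~1% at `W = 2000`, and the default for
occupancy and HOT analyses, where a bounded locus width keeps "factors per
locus" interpretable. `cap:W` instead closes the growing locus when an
incoming peak would push it past `W` and opens the next locus exactly where
the previous one ends; every covered base therefore belongs to exactly one
locus, and a single input wider than `W` is chopped at `W` boundaries. Both
rules are exposed because "bounded at 2 kb" can legitimately mean either
discarding or splitting; provenance records which rule produced a matrix.
`window_partition()` tiles merged intervals with fixed windows (default
2 kb) anchored at each merged interval's start — windows are anchored to
merged regions rather than the whole genome so that window content is
invariant to everything outside the merged peaks; the final partial window is
kept so coverage is exact.

## Occupancy matrices and co-binding

A factor occupies a locus iff one of its peak anchors lies inside it
(summit-in-locus, not any-overlap): a peak straddling a boundary contributes
to exactly one locus and row sums are unambiguous. Loci with fewer than
`min_factors` (default 2) distinct factors are dropped. PCA of the binary
matrix is mean-centered and unscaled (`prcomp`); variance fractions are taken
against the total variance of all columns, so they are comparable across
component counts. Factor–factor distances weight squared loading differences
by each component's variance fraction.

Pairwise co-binding uses closed summit windows `[s − 50, s + 50]`: two peaks
co-bind when their summits are within 100 bp. `M[a, b]` is the fraction of
a's peaks co-binding some peak of b — deliberately asymmetric, since a small
factor set nested inside a large one co-binds at a high rate in one direction
only. Directed edges require `M[a, b] >= 0.75` (the conventional 75%
threshold for calling two factors co-binding partners). Count correlations
are Spearman by default (rank-based, robust to the heavy-tailed count
distributions of ChIP signal); Pearson is available behind a flag.

## Chromatin states and matched nulls

Each peak is assigned a single state via its center, making per-state
fractions a partition that sums to one. Enrichment compares observed state
fractions with those of matched null intervals: for every source interval we
draw placements of identical length whose GC is within 0.02 and soft-masked
repeat fraction within 0.05 of the source, rejecting overlaps with any input
interval. Candidates are screened in vectorised batches against cumulative
GC/repeat arrays (O(1) per candidate); if the budget is exhausted the
tolerances double once, with a 25-fold deeper search, before a resource error
reporting the achieved fold. Enrichment is `log2((obs + ε) / (null + ε))`
with ε = 1e-6 — a pseudo-fraction chosen to keep empty states finite without
visibly perturbing fractions at realistic peak counts. Significance is a
one-sided Fisher test (upper hypergeometric tail) per state, BH-adjusted
across states, called at adjusted *P* < 0.001. Clustering of enrichment
profiles (and of co-occupancy profiles) is hierarchical with Ward linkage on
Euclidean distances — `ward.D2`, the variant that operates on distances, not
squared distances.

CpG promoter classes scan 500-bp subwindows of the ±1-kb promoter window:
`high` requires some subwindow with GC ≥ 0.55 *and* CpG observed/expected ≥
0.6 (o/e = #CpG × L / (#C × #G)); `low` means no subwindow reaches o/e ≥ 0.4;
`intermediate` otherwise. These are the conventional strong/weak CpG-island
cutoffs.

The promoter/enhancer prediction curves are an evaluation protocol, not a
modelling contribution: per feature-count grid point, sample 1,000 loci and
that many features uniformly, train a random forest, record out-of-bag
accuracy, and report median/min/max over 100 repetitions. Any tree ensemble
with an honest error estimate would serve; `randomForest`'s OOB estimate is
used.

## PWM scanning with exact p-values

Site scores are log2-odds in bits against a 0-order background (estimated
from the scanned sequences unless supplied). Zero motif probabilities are
floored at 1e-4 *without renormalising the column*, so nonzero entries keep
their exact odds (a unit-probability column scores exactly log2(1/bg)); zero
background frequencies get pseudo-frequency 1e-4. For p-values, per-column
scores are rounded onto an integer lattice (bin width 0.01 bits, recorded in
the scan output) and the full null distribution of the lattice score is built
by column-wise convolution; site scores are computed on the same lattice, so
the reported p-value is exactly the null tail mass at the observed score —
no interpolation, and the test suite checks equality against exhaustive
enumeration of all 4^L words for short motifs. Both strands are scanned; a
minus-strand hit at position *i* is the forward match of the
reverse-complemented matrix at *i*.

## Motif similarity and concordance

Similarity aligns two PWMs at every ungapped offset with at least
`min_overlap = 4` aligned columns, in both target orientations, scoring each
alignment by the sum of per-column Pearson correlations of the probability
4-vectors divided by the shorter motif's length. The normalisation is the one
genuinely open design point: a plain mean over aligned columns lets a chance
4-column alignment score 1.0 exactly as a full-length match does, which
destroys the contrast between true matches and column-shuffled nulls
(single-dominant-base columns recur, so shuffles recreate short perfect
alignments easily). Dividing the sum by min(L_q, L_t) keeps self-similarity
at exactly 1 while a k-column fluke scores k/min(L) < 1. Unaligned overhangs
are ignored, not penalised. Significance is empirical: the target's columns
are shuffled (default 1,000 times; 5,000 in concordance classification),
each shuffle realigned to its own best offset and orientation, with +1
smoothing; E-values multiply the empirical p by the database cardinality.

Concordance classification compares the motif derived from a factor's peaks
against an annotated library: the best match is the *most similar* motif
(highest score; E-value breaks ties), and the call is `novel` if that match's
E-value is ≥ 0.05, `concordant` if its annotation is the assayed factor,
`discordant` otherwise. The shuffle null is evaluated only for the top few
candidates by score — nulls across targets are comparable, so the decision is
unaffected while the cost drops by the database size. Manual overrides
(motif id → forced call) are applied last and flagged, mirroring curated
corrections of automatic calls. Offsets are signed distances between motif
center (`position + floor(L/2)`) and peak center; offset distributions are
compared with a two-sample KS test whose p-value follows R's convention —
exact for small untied samples, Kolmogorov asymptotic otherwise — which is
what permutation of the pooled sample converges to.

## HOT regions

A locus is HOT when *strictly more* factors occupy it than the threshold; the
fractional form resolves as `ceiling(fraction × n_assayed)` against the
factors actually in the matrix, never a hard-coded compendium size.
Subsampling curves draw k factors without replacement (default grid
12–162 by 10, clipped to the factor count, which is always included so
identification recovery ends at exactly 1), identify HOT loci bound by more
than a third of the subsample, and report the fraction of identified loci
containing ≥ 1 / ≥ 2 / ≥ 3 planted motifs of subsampled factors, each motif
counted at most once per locus.

The anchor profile is a declared PWM-percentile analog of sequence-model
scoring of HOT sites, not a reproduction of any trained model. Every factor's
PWM is scanned over the HOT loci *plus* a GC/repeat-matched background panel
(default 10× the HOT set); each factor's best per-locus scores are
percentile-ranked across all scanned loci, and per HOT locus we count
occupying factors at ≥ the 95th percentile (strong) or in the [25th, 95th)
band (weak). Ranking against a background panel matters: within the HOT set
alone, the top 5% band is a fixed 5% of loci per factor and the planted
strong/degenerate structure cannot be read out. Counting is restricted to
locus occupants by default — motif strength is interpreted for factors with
binding evidence there. Percentiles make the profile invariant to monotone
transforms of raw scores.

## The synthetic regulome

The generator plants exactly the structure the analyses measure, at a
reference scale of 4 chromosomes × 1.5 Mb, 120 factors and ~5,000 regulatory
elements — sized so the full pipeline runs in minutes on one CPU.

- **Factors.** 60 anchors (sequence-specific, each with a PWM whose total
  information content hits the 13-bit target within numerical tolerance;
  consensus words have balanced base composition — low-complexity,
  homopolymer-like consensus words are chance-matched by column shuffles of
  themselves and make poor anchor motifs — and pairwise Hamming distance
  ≥ 4), 30 tethered factors bound to distinct anchors, and 30 chromatin
  regulators without motifs. Anchors carry a state-class preference
  (promoter / enhancer / both); a small solitary subset binds only simple
  one-to-two-factor elements and stays out of HOT loci, providing pure
  promoter-only and enhancer-only factors.
- **Genome.** I.i.d. background at GC 0.41 with contiguous soft-masked blocks
  (default 12% of the genome) placed outside elements, so planted motifs are
  never masked.
- **Elements.** Promoter and enhancer territories are disjoint per
  chromosome, separated by > 3 kb, so enhancer peaks are never TSS-proximal;
  this is the one deliberately unrealistic layout choice, needed because
  ~5,000 elements in 6 Mb leave no room for genome-wide 3-kb buffers. A third
  of elements are occupied; occupied elements draw a CAP count with mean 7
  (capped at 25, well under the HOT threshold), leaving two-thirds of
  elements empty. Anchor summits sit on a ≥ 12-bp grid so plants never
  overwrite each other; each anchor peak has its motif word (consensus, or
  one substitution with probability 0.3, random strand) centered at the
  summit. Tether summits sit N(30, 8) bp from the anchor's motif center, and
  tethers receive extra solo background peaks so that exactly the configured
  fraction (default 0.9) of their peaks co-occur with the anchor.
- **HOT loci.** 50 loci of 1.4 kb; each receives 1–5 strong anchors (true
  plants) and 25–50 further anchors with degenerate plants — consensus with
  2–3 substitutions, deliberately below the p ≤ 1e-4 scan threshold — plus
  most chromatin regulators and co-occurring tethers, for 60–110 occupants
  against a detection threshold of 41. HOT state classes are drawn from
  (0.42, 0.50, 0.08) over promoter / strong-enhancer / other.
- **Expression and counts.** Each promoter element carries a gene at its
  center with lognormal TPM (meanlog 1.5, sdlog 1) plus a saturating
  occupancy term and a +1.5 meanlog increment per co-bound anchor–tether
  pair at ordinary promoters — the planted effect behind expression-by-
  co-occupancy contrasts. Silent TSSs (meanlog −3) populate element-free
  space to exercise the ≥ 1 TPM filter. Counts are negative binomial (mean
  50 at occupied peak-center loci, 5 elsewhere, size 5). Constrained elements
  cover a fraction of each locus growing with its CAP count, planting the
  conservation-by-occupancy trend.
- **Determinism.** One base seed; each stage derives its own seed by a fixed
  offset, so adding a stage never perturbs earlier ones, and the emitted
  artifact set is byte-identical across runs. The global RNG state is saved
  and restored around every seeded operation.

What the generator does **not** emulate: read-level noise (no FASTQ/BAM),
realistic human nucleotide composition or repeat families, peak-width and
signal-strength heterogeneity, overlapping or nested regulatory elements,
and TSS-proximal enhancers. Passing tests therefore demonstrate that the
implementations recover planted structure under clean conditions with
realistic scale and effect sizes — not that they are robust to every artifact
of real ChIP-seq data.

## Degenerate inputs and edge conventions

Empty peak collections make TSS fractions and state fractions an error (an
undefined fraction, never silently 0); empty overlap-matrix rows are NA and
flagged. All-zero Fisher margins give p = 1. Annotation ties are broken by
the first state in segment order and flagged. All-tied rank-sum comparisons
report p = 1 (no evidence of a group effect). Scanner positions overlapping
an N are skipped; sequences shorter than the motif are counted and skipped.
Strong/weak percentile cut points, scan thresholds, bin widths and all size
rules are recorded in outputs or provenance fields so a result can be traced
to its settings.

## Test-suite problem sizes

Unit tests run a reduced simulation (2 × 400 kb, 44 factors, ~360 elements,
8 HOT loci); the acceptance tests and `scripts/acceptance.R` run the
reference scale (4 × 1.5 Mb, 120 factors, ~5,050 elements, 50 HOT loci) with
100-iteration subsampling and prediction protocols, 1e5-permutation KS
checks, and exhaustive-enumeration scanner checks for motif lengths ≤ 6.
Byte-level determinism of the full pipeline is verified at the reduced scale
— determinism is scale-free.
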