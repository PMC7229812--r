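---
title: "Methods: detecting nanopore sequencing failures at inverted-duplicate junctions"
author: "nanoJunction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting nanopore sequencing failures at inverted-duplicate junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoJunction)
```

## The phenomenon and the analysis model

When a nanopore read crosses the junction of an inverted duplication — two
nearly identical DNA segments in opposite orientations, as produced for
example by ODIRA-type amplification (a triplication whose middle copy is
inverted, hence two such junctions per event) — base calling degrades in a
stereotyped way. Up to the junction the read is of normal quality. After it,
per-base phred scores collapse for a stretch slightly *shorter* than the
sequence that preceded the junction, bases are miscalled and missed, the raw
pore current shows a sustained elevation ("uplift"), and the number of
sensor samples recorded per translocated nucleotide drops — consistent with
the newly freed complementary strand re-annealing behind the pore and
accelerating translocation. This package detects the phenotype on base-called
reads, locates the causal junctions on the reference via split alignments,
and quantifies the signal-level signatures.

The analysis operates on four inputs: FASTQ reads (Phred+33), split
alignments (SAM/BAM with supplementary records and SA tags), optionally raw
signal traces with a signal-to-base index, and a reference naming shared by
all of them. All coordinates are 0-based half-open; read coordinates are in
as-sequenced orientation (reverse-strand alignments have their clipping
arithmetic flipped), so split boundaries are comparable along the read as it
passed the pore.

## Low-phred region detection

Let $m$ and $s$ be the median and standard deviation of the sample-wide
phred distribution (`computePhredStats()`). The detection threshold is
$t = m - k\,s$ with $k = 5$ by default (`sd_multiplier`). Detection has
three stages (`detectLowPhredRegions()`):

1. **Seeds.** Maximal runs of at least `min_length = 10` consecutive bases
   with phred $< t$. Operating on raw per-base values (the default,
   `seed_mode = "run"`) guarantees that a collapse shorter than 10 bases can
   never seed a region; the windowed alternative
   (`seed_mode = "window"`, a centered 10-base rolling median) is smoother
   at edges but lets a 9-base collapse spread over ten below-threshold
   windowed positions, which we consider a violation of the 10-nucleotide
   minimum. Strict inequality is used throughout, so a value exactly at the
   threshold does not trigger detection.
2. **Expansion.** Each seed is extended outward one base at a time on each
   side; a side halts when the median of the `window = 10` bases
   immediately adjacent to it is **at or above** the global median $m$ (or
   the read edge is reached; at edges the adjacent window truncates).
   Halting at $\ge m$ rather than $> m$ matters: flanking sequence of
   typical quality has windows whose median equals $m$ exactly much of the
   time, and a strict comparison would never halt there.
3. **Merging and bounding.** Overlapping or abutting expanded regions are
   merged; a region whose end reaches the read end never recovered and is
   flagged unbounded.

For each *bounded* region, `measureLengthPairs()` records the pre-junction
length (read start to region start) and the region length. Unbounded
regions, and regions starting at the very first base, carry no usable
length information and are excluded with an explicit reason.

**Statistics estimator.** The default pools the per-base phred values of
every read in the sample and takes their median and population standard
deviation (denominator $n$). This estimator is only sensible when aberrant
bases are a small fraction of the pool: because the low-phred mode sits
~25 phred units below the normal mode, a contaminated pool inflates $s$
quickly, and beyond roughly 2.5% aberrant bases the $5s$ band crosses below
the low-phred level itself, blinding detection. In a whole-genome sample
with one CNV locus, junction-spanning reads are rare and the pooled
estimator works; for targeted or junction-enriched cohorts use
`method = "read_median"` (median and SD of per-read medians), which is
nearly immune to the aberrant fraction but produces a much tighter band —
appropriate only when per-read medians are stable. The pipeline estimates
statistics from the full input sample; supplying reference statistics from
a matched control sample is supported by passing any `PhredStats` object.

**Monotonicity caveat.** Raising `sd_multiplier` (lowering the threshold)
shrinks the set of below-threshold bases pointwise, but on noisy data a
single long run can fragment into several shorter runs that each still pass
`min_length`, so the *count* of regions is only guaranteed monotone for
clean block-structured quality profiles; the suite tests it there.

## Junction calling from split alignments

A read crossing an inverted-duplicate junction maps as a primary plus a
supplementary segment on the same chromosome in opposite orientations.
For every read-adjacent pair of segments with that signature,
`extractBoundaryPairs()` emits the two reference coordinates flanking the
split: the earlier segment's read-adjacent end (`ref_end` on `+`,
`ref_start` on `-`) and the later segment's (`ref_start` on `+`, `ref_end`
on `-`). Same-strand splits (tandem duplications) and cross-chromosome
splits never qualify.

`resolvePairsGreedy()` resolves the pairs into junction calls: pairs are
binned per chromosome at `tolerance = 200` bp resolution (nanopore
split-mapping jitter scale); the bin supported by most distinct reads seeds
a cluster (ties broken by leftmost coordinate, then chromosome name); every
remaining pair with both coordinates within the tolerance of the seed's
medians is absorbed; the call position is the median of all member
coordinates; repeat until no pairs remain. Sorting the input canonically
first makes the procedure deterministic and permutation-invariant.

Because the underlying event is a duplication, true junctions sit in
locally enriched read depth. `depthEnrichment()` computes the mean depth in
a `flank = 2000` bp window on each side of the call (truncated at contig
edges) over the chromosome-wide median depth, and flags calls at
`depth_ratio >= 1.5` — chosen so that a heterozygous-level duplication
passes. The coverage track includes both primary and supplementary
segments: the duplicated copy of a spanning molecule is represented by the
supplementary alignment, and discarding it halves the depth signal exactly
where it is being measured, while the chromosome median that normalizes the
ratio is dominated by ordinary primary alignments. All calls are retained
with their flag and support; filtering is a report-time choice, and
support-1 calls are visible as such.

## Raw-signal analysis

`detectUplift()` summarizes a trace with a centered rolling median of
`window = 250` samples, then thresholds it at
$\mathrm{baseline} + 5 \times \mathrm{MAD}$, where baseline and MAD
(unscaled median absolute deviation) are taken over the rolling-median
series itself. The rolling-median series is the statistic being
thresholded, and its MAD is robust to the uplift: in a junction read a
third of the *samples* can be uplifted, which inflates a raw-sample MAD
enough to push the threshold above the uplifted level, whereas the
rolling-median series still has its spread set by the quiet majority.
Maximal above-threshold runs closer than one window are merged. Intervals
are invariant to shifting or uniformly rescaling the current, since
baseline and spread transform along.

Translocation rate is estimated inversely as samples per expected
nucleotide (`segmentRate()`): the number of sensor samples spanned by a
read region (difference of the signal-to-base index at its bounds) divided
by the number of reference bases the molecule must have traversed while
producing it (`expectedBasesForRegion()`). Inside an aligned segment that
count is the CIGAR-walked reference span of the sub-segment — deletions
count, because the molecule traversed them even though base calling dropped
them; a deletion sitting exactly at a region edge is not counted. Across an
unaligned gap between two segments, the span implied by the flanking
read-adjacent reference coordinates (absolute difference) is used,
pro-rated if the region covers only part of the gap; where segments
slightly overlap on the read, the earlier segment takes precedence so no
base is counted twice. `compareRegionRates()` pools samples and expected
bases per read over its low-phred regions and their complement and
summarizes the direction across reads with a one-sided sign test
(`binom.test`).

## Rank correlation

`spearmanCorrelation()` ranks both axes with average ranks for ties and
takes the Pearson correlation of the ranks. For $n \ge 10$ the two-sided
p-value uses the $t$ approximation with $n - 2$ degrees of freedom; for
$n < 10$ it enumerates all $n!$ permutations exactly. The estimate is
symmetric in its arguments and invariant under strictly monotone transforms
of either axis.

## What the simulator emulates — and what it does not

`simulationConfig()` fixes the generative conditions; everything downstream
is deterministic given the seed. `makeGenome()` draws a uniform random
reference (200 kb default) and plants a centered ODIRA-style triplication
of a 5 kb segment (`S·revcomp(S)·S`), giving two inverted-duplicate
junctions; tandem (`S·S`) and CNV-free alleles serve as controls.

`simulateReads()` draws 5% of reads (default
`background_read_fraction = 0.95`) as junction-spanning molecules from the
CNV allele: a pre-junction region of 500–3800 bases called cleanly at phred
$\mathcal{N}(30, 3)$; then a low region whose *molecule* length equals the
pre-junction length but whose called length is
$\mathrm{round}(0.9 \times \text{pre})$ plus small between-read noise
(`degrade_ratio = 0.9`, SD 0.015) — the deficit realized as deletions, 30%
of retained bases substituted, phred $\mathcal{N}(5, 2)$; then a clean tail
of 200–1000 bases (5% of spanning reads instead end inside the low region
and become unbounded). Matching primary/supplementary SAM records with
exact CIGARs (deletions interleaved per the retained-base mask) and mutual
SA tags are emitted directly — no aligner is involved — with split
boundaries jittered by trimming or extending the primary alignment by
$\mathcal{N}(0, 8)$ bases (clamped at ±30) to emulate mapping jitter.
Background reads come from the reference with normal quality throughout.
The defaults place the low-phred mode well below the pooled
$5\sigma$ detection band *provided* spanning reads stay a small minority,
which is exactly the regime the background fraction encodes.

`simulateSignal()` generates samples per *molecule* base — missed bases
still contribute samples, since the strand traversed the pore — with
$\mathcal{N}(10, 1)$ samples/base at $\mathcal{N}(90, 8)$ pA outside the
failure region and $\mathcal{N}(6, 1)$ samples/base at
$\mathcal{N}(125, 8)$ pA inside it; the signal-to-base index maps each
called base to the first sample of its molecule base, and currents are
rounded to 0.01 pA so traces round-trip exactly through the TSV dialect.

The simulator does **not** emulate: k-mer-dependent pore currents or any
sequence-dependent signal structure, homopolymer-specific errors, quality
drift along reads, chimeras, multi-junction reads, heterozygosity, or an
actual aligner's soft-clipping behavior around noisy junctions. Passing
tests on simulated data therefore demonstrates that the detection and
estimation machinery recovers planted parameters under the stated error
model — not that thresholds are tuned for any particular flow cell or base
caller. On real data the squiggle ingestion also abstracts over
base-caller-specific signal-to-base mappings (move tables vs. event
tables): any monotone index satisfying the `SignalTraceSet` contract works,
and a proportional fallback is the user's responsibility to flag.

## Numerical and degenerate-input choices

* Even-width medians are the mean of the two central order statistics;
  rolling medians truncate at sequence edges (centered form) or shrink only
  at the end (trailing form used for phred profiles). Both are implemented
  in C++ with a sliding sorted buffer.
* Reads shorter than the seed window and traces shorter than the uplift
  window are skipped with a warning, yielding empty results rather than
  errors; an empty FASTQ yields an empty read set, but empty input to
  `computePhredStats()` is a hard error.
* Zero chromosome median depth, non-monotone base indices, regions without
  flanking alignments, zero-length rate regions and zero-variance
  correlation axes are hard errors with named subjects.
* Greedy clustering ties are broken by support, then leftmost coordinate,
  then chromosome name; inputs are canonically sorted first, so results are
  independent of input order.
* Problem sizes used by the automated checks: detection equivalence on 100
  reads of 0.8–1.4 kb against an exhaustive brute-force enumeration; the
  length-correlation analysis on a 10,000-read sample containing 500
  spanning reads; junction recovery at ~40× coverage of the 200 kb genome
  (1,600 reads); signal analysis on a 200-trace cohort; Spearman
  equivalence on 1,000 random small instances. These sizes make the whole
  suite a desk-scale computation while keeping every estimate's sampling
  error far inside the asserted tolerances.

## Known limitations

* The pooled-statistics detection band degrades with the aberrant-base
  fraction (see above); junction-enriched cohorts need the per-read-median
  estimator or external reference statistics.
* Junction calling requires the aligner to have emitted supplementary
  alignments on the opposite strand; reads whose post-junction segment is
  entirely soft-clipped contribute no boundary pair (in the simulator,
  unbounded reads model this).
* Depth enrichment assumes a roughly uniform background; heavily biased
  coverage (amplicons, extreme GC) will distort the chromosome median.
* `expectedBasesForRegion()` trusts the alignment: reference spans implied
  across unaligned gaps are linear interpolations and inherit any mapping
  error of the flanking segments.
* rDNA-like high-copy loci produce many legitimate opposite-strand splits;
  calls there deserve manual review rather than automated filtering.
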