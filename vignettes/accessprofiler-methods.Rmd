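---
title: "Methods: models, parameters and design choices in accessprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in accessprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accessprofiler)
```

# The signal model

ATAC-seq reads out chromatin accessibility through Tn5 transposase
insertion: the enzyme cuts and tags accessible DNA, and every sequenced
fragment therefore marks **two** insertion events, one at each fragment
end. All analyses in this package start from that event-level signal.

For a fragment $(c, s, e)$ in 0-based half-open coordinates the two
insertion sites are $s$ and $e-1$. This is the package default
(`shift_mode = "none"`). The conventional +4/−5 correction for the 9-bp Tn5
dimer footprint is available (`shift_mode = "tn5_offset"`, sites $s+4$ and
$e-6$, clamped to the chromosome); it shifts every downstream coordinate by
at most 5 bp and does not change any qualitative result, so the uncorrected
ends are the default and the corrected ones an explicit opt-in.

Coordinates are 0-based half-open throughout the package, the BED
convention; GFF3 input/output is converted at the boundary. One convention
everywhere avoids the classic off-by-one errors between track, peak and
annotation code.

## Derived tracks and QC scores

* **Density track** — sliding histogram with `bin_size` = 150 bp and
  `slide` = 20 bp; each window is drawn as a bar over its central 20 bp
  whose height is the total insertion count in the full 150-bp window.
  Windows are anchored at multiples of `slide` from coordinate 0 (not from
  the first insertion), so tracks from different samples are comparable
  bin-for-bin.
* **SPOT score** — fraction of insertion *events* (not read pairs) that
  fall inside the union of the sample's own merged peaks. Whether the
  original statistic counted reads or events is not documented for the data
  this package is modeled on; events are used because they are the unit
  every other function operates on, and the choice only rescales the score
  monotonically. The score is 0 with no peaks and exactly 1 when peaks tile
  the genome.
* **Organellar fractions** — plastid and mitochondrial contigs are carried
  as ordinary chromosomes with the reserved names `chrPt` and `chrMt`;
  fractions are simple read-count ratios over
  {nuclear, plastid, mitochondrial}. Organellar insertions are excluded
  from the nuclear background rate (below) but included in totals such as
  the SPOT denominator, mirroring how aligned-read statistics are usually
  reported.

# Peak-set comparison

`merge_peaks()` merges peaks whose gap is **strictly less than** 10 bp
(transitively; a merged peak takes the maximum member score). The strict
inequality is deliberate: a 10-bp gap is kept.

The two-sample comparison uses a minimum-overlap rule: peak $q$ overlaps
set $S$ when the bases of $q$ covered by the **union** of $S$ amount to at
least `min_fraction` (default 10 %) of $q$'s **own** length. Two design
points deserve justification:

* *Query-relative, per direction.* "Overlap in at least 10 % of their
  sequences" could be read query-relative, subject-relative, or reciprocal.
  The query-relative reading is the only one that lets the two directions
  of a two-sample comparison be computed independently — which is how
  shared/unique counts are reported per set — so that is what
  `partition_peak_sets()` does, for each set against the other. The shared
  counts of the two directions need not agree: one broad peak can absorb
  several narrow ones on the other side, and both counts are reported.
* *Union coverage.* A query split across two subject peaks is biologically
  one overlap, so covered bases are unioned before the fraction is taken.

The fraction is compared as a ratio (`covered / length >= min_fraction`)
rather than as `covered >= min_fraction * length`: `0.1 * 100` is slightly
above 10 in binary floating point, and the ratio form keeps the exact
10 %-boundary case on the inclusive side where it belongs.

`downsample_fragments()` draws a uniform subset of read pairs without
replacement under an explicit seed. Down-sampling operates on fragments,
not insertions, because insertions come in pairs and subsampling events
independently would break that pairing.

# Genomic categories

`build_category_index()` partitions every base into five categories: exon,
intron, up2k (within 2 kb upstream of a TSS, strand-aware), down2k (within
2 kb downstream of a TTS), and intergenic. Where several genes claim a base
the fixed precedence **exon > intron > up2k > down2k > intergenic**
applies: transcribed state is directly observed while flanks are inferred,
so transcription wins. UTR bases count as exon (transcribed sequence). The
index is a true partition — per-category base totals sum to the genome
length, and the test suite asserts this on random annotations.

Peaks are classified by the category of their midpoint base
$\lfloor (start + end)/2 \rfloor$. A peak spanning a boundary therefore
lands in exactly one category and distributions sum to 100 %; any rule for
boundary-spanning peaks is somewhat arbitrary, and the midpoint is the
simplest one that preserves normalization.

`closest_gene()` minimizes interval-to-interval distance (0 for overlap),
with exact ties broken toward the lexicographically smaller gene id so the
mapping is deterministic. Gene-body distance was chosen over TSS distance
as the plainer reading of "closest gene"; for the mutually-exclusive class
construction (`exclusive_gene_classes()`) the choice only matters for peaks
near long genes, and the construction — drop every gene claimed by both
peak classes — is independent of the metric.

# Accessibility versus expression

Genes are stratified into 11 groups: group 0 holds FPKM = 0 genes; genes
with FPKM > 0 are rank-split into ten deciles whose sizes differ by at most
one (group 10 = highest). Ties are broken by gene id, making the partition
deterministic under permutation of input rows.

The aggregate profile reports, for each upstream offset
$u \in \{1, \dots, 1000\}$, the mean insertion count at the strand-aware
base $u$ bp 5′ of the TSS (offset $u = 1$ is the base immediately upstream;
plus strand $TSS - u$, minus strand $TSS + u$). Bases off the chromosome
are excluded from the mean at that offset. Each mean is divided by the
genome-wide per-base rate

$$\hat\lambda = \frac{\text{total nuclear insertions}}{\text{nuclear genome length}}$$

to give *fold accessibility over background*; organellar contigs enter
neither numerator nor denominator. Note that $\hat\lambda$ includes
promoter-hotspot insertions, so on a genome where hotspots hold a
substantial share of all insertions the background-level fold sits slightly
below 1 — visible in the dense synthetic genome, negligible on a real
genome where promoters are a tiny length fraction.

The per-gene promoter statistic is the total insertion count in a 150-bp
window centered 225 bp upstream of the TSS: upstream offsets 151–300
inclusive, i.e. genomic $[t-300, t-150)$ for a plus-strand TSS at $t$. The
"centered at 225" phrasing admits two half-open placements; offsets
151–300 make the window symmetric about the 225/226 boundary and keep its
width exactly 150. Genes whose window overlaps a neighboring gene are not
excluded (no such filter is applied by default; a minimum-flank filter
would be a caller-side subset of `gene_ids`).

`expression_correlation()` computes Pearson's r between raw window counts
and raw FPKM by default. Raw-vs-raw is the plain reading of "correlation
between total accessibility and expression"; a `log = TRUE` option applies
$\log_{10}(x+1)$ to both sides for users who prefer a variance-stabilized
version. Correlation on ranks (Spearman) can be had by passing ranks.

**LOESS**: degree-1 local regression with tricube weights, span 0.3,
evaluated at the input offsets. The span is chosen so each local fit uses
~300 of the 1,000 offsets — wide enough to suppress per-base Poisson noise,
narrow enough to resolve a ~150-bp hotspot; degree 1 reproduces straight
lines exactly (asserted to 1e-6 in the tests).

**Heatmaps** use $\log_{10}(count + 1)$ — the pseudocount makes the empty
window map to 0 — with one row per gene ordered by descending FPKM and
columns running 5′→3′: 150/20 sliding windows over the 1 kb upstream of the
TSS, a gene body scaled to `body_bins` equal-width windows (default 20),
and 1 kb downstream of the TTS. Scaling the body (rather than cropping a
fixed width) keeps genes of different lengths comparable column-for-column.

# Enrichment statistics

A gene is *tissue-enriched* when FPKM in the target tissue is at least
tenfold the other tissue's and positive; `(5, 0)` is enriched, `(0, 0)` is
not. The inclusive `>=` is used because "at least tenfold" is inclusive;
the distinction affects only exact-boundary ties.

`class_enrichment_test()` builds the 2×2 class × enrichment table and
applies Pearson's chi-square with 1 df and **no continuity correction**
(exposed as an option), matching the large-sample setting in which such
tables arise here; on integer tables the statistic equals the closed form
$n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ exactly, and the tests assert
this. Degenerate margins (an all-enriched or no-enriched column, or an
empty class) raise an error naming the margin rather than returning NaN.

# The synthetic-data generator

The generator produces data with exactly the statistical structure the
analyses assume, plus the ground truth needed to test recovery:

* **Annotation** — `n_genes` non-overlapping gene models packed onto the
  nuclear chromosomes with all gaps (including chromosome ends) at least
  `flank_min`; uniform strands; 1–3 exons per gene. Infeasible packings
  fail loudly, naming the chromosome and the capacity shortfall.
* **Expression** — zero-inflated log-normal FPKM per tissue, with a
  configurable subset of genes forced to ≥ 10-fold tissue enrichment by
  construction (truth labels attached).
* **Fragments** — insertion *anchor* ends arrive as an inhomogeneous
  Poisson process: rate $\lambda_0/2$ per bp background, raised to
  $(\lambda_0/2)(1 + I_q)$ inside each gene's promoter hotspot, a 150-bp
  window centered 225 bp upstream of the TSS whose intensity $I_q$ is
  looked up from the gene's expression quantile (defaults $I_q = q$,
  $q = 0, \dots, 10$, non-decreasing as required). Each anchor is completed
  into a fragment by a partner end 50–300 bp away on a random side, so
  every fragment contributes exactly two ends and the expected insertion
  total on a hotspot-free genome is $\lambda_0 L$. Defining intensity as
  *extra* fold over background (rate multiplier $1 + I$) makes $I = 0$ mean
  "background", so non-expressed genes have no hotspot rather than a
  zero-coverage hole. Partner ends smear the hotspot symmetrically, which
  broadens the aggregate profile but does not move its mode — the profile
  argmax recovers the 225-bp center within ±20 bp in the tests and the
  acceptance run. Organellar fragments are added with expected share
  `organelle_fraction` of all fragments (default 0.08, matching the
  plastid + mitochondrial percentages typical of clean nuclei
  preparations).
* **Peak pairs** — set A is packed disjointly; each same-sized B peak is
  independently designated shared (probability `shared_peak_fraction`,
  default 0.83) and placed as a jittered copy of a distinct A peak whose
  overlap clears the 10 % rule by construction on both sides, or placed
  disjoint from everything. The partition therefore recovers the designed
  labels exactly, and the recovered shared count is binomial around
  $n \cdot p$.

One master seed drives everything through fixed per-generator substreams
(annotation, expression, fragments, peaks, down-sampling), so regenerating
one output never perturbs another, and every generator restores the
caller's RNG state.

**What the generator does not emulate:** sequence content (no FASTQ, no
aligner, no Tn5 sequence bias), mappability, duplicate reads, nucleosome
phasing, distal enhancer hotspots, and realistic gene density. The default
study — 500 genes on 1 Mb — is roughly 60× denser than the wheat genome, so
genomic-category distributions on synthetic data are dominated by the 2-kb
flank categories and contain essentially no intergenic space; passing tests
demonstrate the correctness of the interval logic and the recovery of the
generative parameters, not field-realistic category proportions. Likewise
the demo's SPOT score is a property of arbitrary simulated peaks, not a
quality statement.

# Problem sizes and determinism

The default validation study uses a 1 Mb nuclear genome, 500 genes,
background 0.02 insertions/bp (≈ 29k insertions), and 1,000 peaks per set —
large enough for stable moment checks (3-SD binomial/Poisson bands, ±20-bp
mode recovery, Spearman ρ > 0.9 across deciles) while a full test run stays
under a minute. Oracle-equivalence tests run the sparse implementations
against dense brute-force re-implementations on 100+ random small
instances per operation and require exact agreement.

All stochastic checks run under fixed seeds. Statistical tolerances are
stated in the units of the check (3 binomial SD for proportions, ±20 bp for
the profile mode) and were fixed from the generative model, not tuned.

# Known limitations

* The insertion track is held as per-chromosome sparse position/count
  vectors; this is comfortable up to tens of millions of insertions but
  has no on-disk backing for genome-scale data — for a 15-Gb genome users
  should process per chromosome.
* `closest_gene()` computes all nearest candidates per peak; on very large
  peak sets with dense annotations the tie-resolution step is the slow
  path.
* The chi-square test is asymptotic; for classes with expected counts < 5
  users should prefer `fisher.test()` on `result$table`.
* `heatmap_matrix()` scales gene bodies; there is no fixed-width cropping
  mode.
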