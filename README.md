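# accessprofiler

Downstream analysis of plant ATAC-seq data in R, starting from aligned
paired-end fragments. The package targets the standard post-alignment,
post-peak-calling questions of an open-chromatin study: how clean is the
signal, how do two peak sets relate, where do peaks sit relative to genes,
and how does promoter accessibility track gene expression.

Each sequenced ATAC fragment marks two Tn5 insertion events, one at each end.
From a fragment table the package builds:

- **Insertion tracks** — per-base Tn5 insertion counts
  (`extract_insertions()`), browser-ready sliding-window density tracks
  (150 bp windows, 20 bp slide; `density_track()`), and bedGraph output.
- **QC statistics** — the SPOT score (Signal Portion Of Tags,
  `spot_score()`: the fraction of insertion events inside peaks) and
  plastid/mitochondrial read fractions (`organelle_fraction()`).
- **Peak-set operations** — merging of peaks separated by < 10 bp
  (`merge_peaks()`), the ≥ 10 %-of-own-length overlap criterion
  (`overlaps_by_fraction()`), two-sample shared/unique partitioning
  (`partition_peak_sets()`), and seeded fragment down-sampling
  (`downsample_fragments()`).
- **Genomic annotation** — every base of the genome assigned to one of five
  categories (exon, intron, ≤ 2 kb upstream, ≤ 2 kb downstream, intergenic;
  `build_category_index()`), peak classification by midpoint, closest-gene
  mapping, and mutually exclusive peak-associated gene classes.
- **Accessibility–expression analysis** — genes stratified into 11
  expression quantiles (group 0 = FPKM 0, deciles 1–10;
  `stratify_quantiles()`); aggregate per-base insertion profiles over the
  1 kb upstream of TSSs, normalized to fold accessibility over the
  genome-wide background rate `lambda = N_insertions / L_genome`
  (`upstream_profile()`, `fold_over_background()`); LOESS-smoothed curves;
  per-gene counts in a 150-bp window centered 225 bp upstream of the TSS
  (`window_accessibility()`); Pearson correlation of window counts with
  FPKM (`expression_correlation()`); expression-ordered heatmap matrices.
- **Enrichment statistics** — tissue-enriched gene classification
  (FPKM_target ≥ 10 × FPKM_other, `fold_enrichment_class()`) and a 2×2
  Pearson chi-square test (1 df, no continuity correction) comparing
  enriched-gene proportions between gene classes
  (`class_enrichment_test()`).
- **A synthetic-data generator** with known ground truth
  (`sim_config()`, `generate_annotation()`, `generate_expression()`,
  `simulate_fragments()`, `simulate_peak_pair()`): uniform background
  insertions, promoter hotspots centered 225 bp upstream of TSSs whose
  intensity rises with expression quantile, organellar contamination, and
  peak pairs with a designed shared fraction — so the whole pipeline can be
  exercised and validated without external data.

`run_pipeline()` chains all stages from a config list or YAML file;
`run_demo()` does the same on freshly simulated data. A thin command-line
wrapper is installed at `inst/scripts/accessprofiler`.

## Worked example

```r
library(accessprofiler)
res <- run_demo(seed = 1, verbose = FALSE)  # 1 Mb genome, 500 genes
print(res)
```

```
pipeline_result
  total_insertions       29154
  spot_score             0.182788
  organelle_fraction     0.0805378
  n_peaks                1000
  ...
  n_shared_B             828
  n_only_B               172
  correlation_r          0.294166
  correlation_p          1.94197e-11
```

Reading the output: 29,154 insertion events (two per fragment) were
extracted; 8.05 % of fragments landed on the organellar contigs, recovering
the simulated 8 % contamination; the ≥ 10 %-overlap partition classified 828
of 1,000 set-B peaks as shared, recovering the designed 0.83 shared
fraction; and promoter-window accessibility correlates positively with FPKM
(r = 0.29, p ≈ 2e-11), driven by the simulated expression-coupled promoter
hotspots. The per-quantile fold-accessibility profiles in `res$profiles`
peak ~225 bp upstream of the TSS and order monotonically with expression
quantile (`plot_quantile_profiles(res$profiles)` draws them).

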