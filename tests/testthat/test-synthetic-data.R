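test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(hotspot_intensity_per_quantile = 1:5), "11 entries")
  expect_error(sim_config(hotspot_intensity_per_quantile = c(5, 0:9)), "non-decreasing")
  expect_error(sim_config(organelle_fraction = 1), "organelle_fraction")
  expect_error(sim_config(shared_peak_fraction = 1.2), "shared_peak_fraction")
  expect_error(sim_config(gene_length_range = c(100, 50)), "gene_length_range")
  expect_error(sim_config(organelle_sizes = c(weird = 100)), "chrPt")
})

test_that("generate_annotation handles the empty case and preserves sizes", {
  cfg <- sim_config(n_genes = 0)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 0L)
  expect_equal(ann$chrom_sizes, c(cfg$chrom_sizes, cfg$organelle_sizes))
})

test_that("annotation generation is deterministic (byte-identical GFF3)", {
  cfg <- sim_config(n_genes = 40, seed = 7)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_gff3(generate_annotation(cfg), f1)
  write_gff3(generate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene packing respects the minimum flank everywhere", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 1e6), n_genes = 50,
                    gene_length_range = c(1000, 3000), flank_min = 2000, seed = 3)
  ann <- generate_annotation(cfg)
  g <- ann$genes[order(ann$genes$start), ]
  expect_equal(nrow(g), 50L)
  gaps <- g$start[-1] - g$end[-nrow(g)]
  expect_true(all(gaps >= 2000))
  expect_gte(g$start[1], 2000)
  expect_lte(g$end[nrow(g)], 1e6 - 2000)
  # non-overlap, exon containment, >= 1 exon per gene
  expect_true(all(gaps > 0))
  expect_true(all(ann$genes$gene_id %in% ann$exons$gene_id))
  gi <- match(ann$exons$gene_id, ann$genes$gene_id)
  expect_true(all(ann$exons$start >= ann$genes$start[gi] &
                  ann$exons$end <= ann$genes$end[gi]))
})

test_that("infeasible packing errors name the violated capacity", {
  cfg <- sim_config(chrom_sizes = c(chrTiny = 10000), n_genes = 20,
                    gene_length_range = c(1000, 1000), flank_min = 500)
  expect_error(generate_annotation(cfg), "infeasible packing on 'chrTiny'")
})

test_that("expression generation hits its boundary cases and truth labels hold", {
  cfg <- sim_config(n_genes = 100, seed = 11)
  ann <- generate_annotation(cfg)
  expect_error(generate_expression(ann, cfg, n_tissues = 0), "n_tissues")

  all_zero <- generate_expression(ann, cfg, zero_prob = 1, enriched_fraction = 0)
  expect_true(all(all_zero$root == 0) && all(all_zero$leaf == 0))

  none_zero <- generate_expression(ann, cfg, zero_prob = 0, enriched_fraction = 0)
  expect_equal(sum(none_zero$root > 0), 100L)

  ex <- generate_expression(ann, cfg, n_tissues = 2, zero_prob = 0.2,
                            enriched_fraction = 0.2, enriched_fold = 10)
  truth <- attr(ex, "truth")
  enr <- truth[!is.na(truth$enriched_tissue), ]
  expect_equal(nrow(enr), 20L)
  for (i in seq_len(nrow(enr))) {
    row <- ex[ex$gene_id == enr$gene_id[i], ]
    t <- enr$enriched_tissue[i]
    o <- setdiff(c("root", "leaf"), t)
    expect_gt(row[[t]], 0)
    expect_gte(row[[t]], 10 * row[[o]])
  }
  # determinism
  ex2 <- generate_expression(ann, cfg, n_tissues = 2, zero_prob = 0.2,
                             enriched_fraction = 0.2, enriched_fold = 10)
  expect_identical(ex, ex2)
})

test_that("fragment simulation matches its Poisson and binomial moments", {
  # no signal at all -> empty fragment set
  cfg0 <- sim_config(n_genes = 10, background_rate = 0,
                     hotspot_intensity_per_quantile = rep(0, 11),
                     organelle_fraction = 0, seed = 5)
  ann0 <- generate_annotation(cfg0)
  ex0 <- generate_expression(ann0, cfg0)
  sim0 <- simulate_fragments(ann0, ex0, cfg0)
  expect_equal(nrow(sim0$fragments), 0L)

  # hotspot-free genome: total insertions ~ background_rate x genome length
  cfg <- sim_config(chrom_sizes = c(chr1 = 1e6), n_genes = 10,
                    background_rate = 0.01,
                    hotspot_intensity_per_quantile = rep(0, 11),
                    organelle_fraction = 0, seed = 42)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg)
  sim <- simulate_fragments(ann, ex, cfg)
  total <- 2L * nrow(sim$fragments)
  expect_lt(abs(total - 1e4), 3 * sqrt(1e4))
  track <- extract_insertions(sim$fragments, ann$chrom_sizes)
  expect_equal(track$total_insertions, total)

  # organellar contamination moment check
  cfgo <- sim_config(chrom_sizes = c(chr1 = 2e6), n_genes = 10,
                     background_rate = 0.05,
                     hotspot_intensity_per_quantile = rep(0, 11),
                     organelle_fraction = 0.05, seed = 9)
  anno <- generate_annotation(cfgo)
  simo <- simulate_fragments(anno, generate_expression(anno, cfgo), cfgo)
  n_tot <- nrow(simo$fragments)
  n_org <- sum(is_org <- simo$fragments$chrom %in% c("chrPt", "chrMt"))
  expect_lt(abs(n_org - 0.05 * n_tot), 3 * sqrt(n_tot * 0.05 * 0.95))
  expect_equal(n_org, simo$truth$n_organelle_fragments)
})

test_that("hotspots follow the TSS geometry and are truncated at bounds", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 50000), n_genes = 10,
                    gene_length_range = c(500, 800), flank_min = 300, seed = 2)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann, cfg, zero_prob = 0)
  sim <- simulate_fragments(ann, ex, cfg)
  hs <- sim$truth$hotspots
  tss <- tss_positions(ann)
  for (i in seq_len(nrow(hs))) {
    g <- ann$genes[ann$genes$gene_id == hs$gene_id[i], ]
    t <- tss[[g$gene_id]]
    if (!hs$truncated[i]) {
      if (g$strand == "+") {
        expect_equal(hs$start[i], t - 300L)
        expect_equal(hs$end[i], t - 150L)
      } else {
        expect_equal(hs$start[i], t + 151L)
        expect_equal(hs$end[i], t + 301L)
      }
    }
    expect_gte(hs$start[i], 0)
    expect_lte(hs$end[i], 50000)
  }
  # a gene whose upstream flank leaves the chromosome gets a truncated hotspot
  ann2 <- genome_annotation(c(chr1 = 10000),
                            data.frame(gene_id = "g1", chrom = "chr1",
                                       start = 100L, end = 600L, strand = "+"),
                            data.frame(gene_id = "g1", chrom = "chr1",
                                       start = 100L, end = 600L))
  ex2 <- data.frame(gene_id = "g1", root = 5)
  sim2 <- simulate_fragments(ann2, ex2, sim_config(seed = 1))
  expect_true(sim2$truth$hotspots$truncated[1])
  expect_equal(sim2$truth$hotspots$start[1], 0L)
})

test_that("all simulated intervals lie within chromosome bounds", {
  for (seed in 1:5) {
    cfg <- sim_config(chrom_sizes = c(chrA = 3e5, chrB = 2e5), n_genes = 60,
                      background_rate = 0.01, seed = seed)
    ann <- generate_annotation(cfg)
    ex <- generate_expression(ann, cfg)
    sim <- simulate_fragments(ann, ex, cfg)
    sizes <- ann$chrom_sizes
    f <- sim$fragments
    expect_true(all(f$start >= 0 & f$start < f$end & f$end <= sizes[f$chrom]))
    pair <- simulate_peak_pair(ann, cfg, n_peaks = 100)
    for (p in list(pair$A, pair$B))
      expect_true(all(p$start >= 0 & p$start < p$end & p$end <= sizes[p$chrom]))
  }
})

test_that("peak pairs honor the designed shared fraction at the boundaries", {
  cfg1 <- sim_config(shared_peak_fraction = 1, seed = 13)
  ann <- generate_annotation(sim_config(n_genes = 0))
  pair1 <- simulate_peak_pair(ann, cfg1, n_peaks = 150)
  expect_true(all(overlaps_by_fraction(pair1$B, pair1$A, 0.10)))
  expect_true(all(pair1$truth$labels_B == "shared"))

  cfg0 <- sim_config(shared_peak_fraction = 0, seed = 13)
  pair0 <- simulate_peak_pair(ann, cfg0, n_peaks = 150)
  part <- partition_peak_sets(pair0$A, pair0$B)
  expect_equal(part$counts[["shared_A"]], 0L)
  expect_equal(part$counts[["shared_B"]], 0L)

  # labels partition each peak set
  expect_setequal(names(pair1$truth$labels_A), pair1$A$name)
  expect_setequal(names(pair1$truth$labels_B), pair1$B$name)
})

test_that("generator substreams are independent", {
  cfg <- sim_config(n_genes = 30, seed = 99)
  ann <- generate_annotation(cfg)
  ex1 <- generate_expression(ann, cfg)
  invisible(generate_annotation(cfg))  # regenerating one output ...
  ex2 <- generate_expression(ann, cfg) # ... must not perturb another
  expect_identical(ex1, ex2)
})
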