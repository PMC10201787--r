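# minimal annotation with single-exon genes at given TSS geometry
make_ann <- function(strand = "+", tss = 10000L, chrom_len = 40000L, n = 1L) {
  start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    t <- tss + (i - 1L) * 3000L
    if (strand == "+") { start[i] <- t; end[i] <- t + 500L }
    else { start[i] <- t - 499L; end[i] <- t + 1L }
  }
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
                      start = start, end = end, strand = strand,
                      stringsAsFactors = FALSE)
  genome_annotation(c(chr1 = chrom_len), genes,
                    genes[, c("gene_id", "chrom", "start", "end")])
}

test_that("quantile stratification is a balanced deterministic partition", {
  ex <- data.frame(gene_id = sprintf("g%02d", 1:20), root = as.numeric(1:20))
  s <- stratify_quantiles(ex, "root")
  expect_equal(unname(vapply(s$groups, length, integer(1))), c(0L, rep(2L, 10)))
  expect_setequal(s$groups[["10"]], c("g19", "g20"))
  expect_setequal(s$groups[["1"]], c("g01", "g02"))

  allz <- data.frame(gene_id = c("a", "b"), root = c(0, 0))
  expect_warning(s0 <- stratify_quantiles(allz, "root"), "no expressed")
  expect_equal(length(s0$groups[["0"]]), 2L)

  ex95 <- data.frame(gene_id = sprintf("g%03d", 1:95), root = runif(95) + 0.1)
  s95 <- stratify_quantiles(ex95, "root")
  sizes <- vapply(s95$groups[as.character(1:10)], length, integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_equal(sum(sizes), 95L)

  # groups partition the gene set; ties broken by id, reproducibly
  tied <- data.frame(gene_id = c("b", "a", "c", "d"), root = c(1, 1, 1, 1))
  s1 <- stratify_quantiles(tied, "root")
  s2 <- stratify_quantiles(tied[c(2, 1, 4, 3), ], "root")
  expect_equal(s1$quantile[sort(names(s1$quantile))],
               s2$quantile[sort(names(s2$quantile))])
})

test_that("upstream profiles place insertions at the strand-aware offset", {
  ann <- make_ann("+", tss = 10000L)
  z <- upstream_profile(insertion_track(list(), c(chr1 = 40000L)), ann, "g01")
  expect_true(all(z$mean_count == 0))

  tr <- insertion_track(list(chr1 = 10000L - 225L), c(chr1 = 40000L))
  p <- upstream_profile(tr, ann, "g01")
  expect_equal(p$mean_count[p$offset == 225], 1)
  expect_equal(sum(p$mean_count), 1)

  annm <- make_ann("-", tss = 10000L)
  trm <- insertion_track(list(chr1 = 10000L + 300L), c(chr1 = 40000L))
  pm <- upstream_profile(trm, annm, "g01")
  expect_equal(pm$mean_count[pm$offset == 300], 1)
  expect_equal(sum(pm$mean_count), 1)

  expect_error(upstream_profile(tr, ann, character(0)), "empty")
})

test_that("off-chromosome bases are excluded from the profile mean", {
  # TSS at 500: offsets > 500 fall off the chromosome for the plus strand
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 500L, end = 900L,
                      strand = "+", stringsAsFactors = FALSE)
  ann <- genome_annotation(c(chr1 = 40000L), genes,
                           genes[, c("gene_id", "chrom", "start", "end")])
  p <- upstream_profile(insertion_track(list(chr1 = 0L), c(chr1 = 40000L)), ann, "g1")
  expect_equal(p$n_genes[p$offset <= 500], rep(1, 500))
  expect_equal(p$n_genes[p$offset > 500], rep(0, 500))
  expect_equal(p$mean_count[p$offset == 500], 1)  # base 0 is offset 500
})

test_that("profiles match a per-gene brute-force scan", {
  set.seed(61)
  ann <- make_ann(sample(c("+", "-"), 1), tss = 5000L, chrom_len = 20000L, n = 4)
  f <- random_fragments(80, chrom_len = 20000L)
  tr <- extract_insertions(f, c(chr1 = 20000L))
  dense <- oracle_insertion_counts(f, 20000L)
  p <- upstream_profile(tr, ann, ann$genes$gene_id, span = 600)
  want <- oracle_upstream_profile(dense, tss_positions(ann),
                                  ann$genes$strand, 600, 20000L)
  expect_equal(p$mean_count, unname(want))
})

test_that("fold over background divides by the nuclear genome-wide rate", {
  tr <- insertion_track(list(chr1 = rep(0:999, 1)), c(chr1 = 1000L))  # 1/bp
  prof <- data.frame(offset = 1:10, mean_count = rep(1, 10), n_genes = 1)
  expect_equal(fold_over_background(prof, tr)$fold, rep(1, 10))

  # 1000 insertions over 1 Mb -> background 0.001; 0.005 -> fold 5
  tr2 <- insertion_track(list(chr1 = data.frame(pos = 0:999, count = 1L)),
                         c(chr1 = 1e6))
  prof2 <- data.frame(offset = 1, mean_count = 0.005, n_genes = 10)
  expect_equal(fold_over_background(prof2, tr2)$fold, 5.0)

  # organellar insertions do not enter the background
  tr3 <- insertion_track(list(chr1 = data.frame(pos = 0:999, count = 1L),
                              chrPt = data.frame(pos = 0:99, count = 50L)),
                         c(chr1 = 1e6, chrPt = 10000L))
  expect_equal(fold_over_background(prof2, tr3)$fold, 5.0)

  expect_error(fold_over_background(prof, insertion_track(list(), c(chr1 = 10L))),
               "zero insertions")
})

test_that("loess smoothing is exact on lines and finds a noisy peak", {
  off <- 1:100
  expect_equal(loess_smooth(off, rep(3, 100)), rep(3, 100), tolerance = 1e-8)
  lin <- 0.5 * off + 2
  expect_lt(max(abs(loess_smooth(off, lin) - lin)), 1e-6)

  set.seed(8)
  off2 <- 1:1000
  bump <- 3 * exp(-((off2 - 225)^2) / (2 * 75^2)) + rnorm(1000, 0, 0.3)
  sm <- loess_smooth(off2, bump, span = 0.3)
  expect_lte(abs(off2[which.max(sm)] - 225), 20)

  expect_error(loess_smooth(1:5, 1:5), "at least 10")
  expect_error(loess_smooth(1:100, rnorm(100), span = 0.01), "span")
})

test_that("window accessibility covers upstream offsets 151-300 by default", {
  ann <- make_ann("+", tss = 1000L, chrom_len = 5000L)
  # boundary inclusion: offsets 151 and 300 in, 150 and 301 out
  pos <- c(1000L - 151L, 1000L - 300L, 1000L - 150L, 1000L - 301L)
  tr <- insertion_track(list(chr1 = pos), c(chr1 = 5000L))
  expect_equal(unname(window_accessibility(tr, ann, "g01")), 2)
  # genomic interval is [700, 850) for a plus-strand TSS at 1000
  tr2 <- insertion_track(list(chr1 = c(700L, 849L, 850L, 699L)), c(chr1 = 5000L))
  expect_equal(unname(window_accessibility(tr2, ann, "g01")), 2)
  expect_equal(unname(window_accessibility(insertion_track(list(), c(chr1 = 5000L)),
                                           ann, "g01")), 0)
  # minus strand mirrors rightward
  annm <- make_ann("-", tss = 1000L, chrom_len = 5000L)
  trm <- insertion_track(list(chr1 = c(1151L, 1300L, 1301L, 1150L)), c(chr1 = 5000L))
  expect_equal(unname(window_accessibility(trm, annm, "g01")), 2)
  # off-chromosome bases contribute zero rather than erroring
  ann_edge <- make_ann("+", tss = 100L, chrom_len = 5000L)
  expect_equal(unname(window_accessibility(tr, ann_edge, "g01")), 0)
})

test_that("a full-span window equals the profile total for a single gene", {
  set.seed(19)
  ann <- make_ann("+", tss = 10000L)
  f <- random_fragments(60, chrom_len = 40000L)
  tr <- extract_insertions(f, c(chr1 = 40000L))
  w <- window_accessibility(tr, ann, "g01", center_offset = 500, width = 1000)
  p <- upstream_profile(tr, ann, "g01", span = 1000)
  expect_equal(unname(w), sum(p$mean_count))
})

test_that("expression correlation behaves at its exact extremes", {
  w <- stats::setNames(c(1, 2, 3, 4, 5), letters[1:5])
  expect_equal(expression_correlation(w, w * 10)$r, 1.0)
  expect_equal(expression_correlation(w, -w + 10)$r, -1.0)
  expect_error(expression_correlation(w, stats::setNames(rep(2, 5), letters[1:5])),
               "constant")
  expect_error(expression_correlation(w[1:2], w[1:2] * 2), "3 paired")
  # table interface + log option
  ex <- data.frame(gene_id = letters[1:5], root = c(10, 20, 30, 40, 50))
  expect_equal(expression_correlation(w, ex, tissue = "root")$r, 1.0)
  expect_equal(expression_correlation(w, ex, tissue = "root", log = TRUE)$r,
               expression_correlation(log10(w + 1),
                                      stats::setNames(log10(ex$root + 1),
                                                      ex$gene_id))$r)
})

test_that("heatmap rows are expression-ordered and values are log10(count+1)", {
  ann <- make_ann("+", tss = 10000L, chrom_len = 40000L, n = 3)
  ex <- data.frame(gene_id = c("g01", "g02", "g03"), root = c(1, 100, 10))
  tr0 <- insertion_track(list(), c(chr1 = 40000L))
  m0 <- heatmap_matrix(tr0, ann, ex, "root")
  expect_true(all(m0 == 0))
  expect_equal(rownames(m0), c("g02", "g03", "g01"))  # descending FPKM

  # 99 insertions in g01's first upstream window [tss-1000, tss-850)
  tr <- insertion_track(list(chr1 = data.frame(pos = 9000:9098, count = 1L)),
                        c(chr1 = 40000L))
  m <- heatmap_matrix(tr, ann, ex, "root")
  expect_equal(unname(m["g01", 1]), 2.0)  # log10(99 + 1)
  expect_equal(sum(attr(m, "region") == "body"), 20)
})
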