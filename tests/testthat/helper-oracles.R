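# Brute-force oracles and small random-instance generators. Each oracle is a
# direct per-base / all-pairs restatement of the definition, independent of
# the package's sparse/interval-tree code paths.

# dense per-base insertion counts from fragments (shift none)
oracle_insertion_counts <- function(fragments, chrom_len, chrom = "chr1") {
  counts <- integer(chrom_len)
  f <- fragments[fragments$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    counts[f$start[i] + 1L] <- counts[f$start[i] + 1L] + 1L
    counts[f$end[i]] <- counts[f$end[i]] + 1L  # end-1 in 0-based = index end
  }
  counts
}

# window sums over a dense count vector for windows starting at multiples of
# slide (0-based starts)
oracle_density <- function(dense, bin, slide) {
  starts <- seq.int(0L, length(dense) - 1L, by = slide)
  vapply(starts, function(s) {
    idx <- seq.int(s + 1L, min(s + bin, length(dense)))
    sum(dense[idx])
  }, numeric(1))
}

# transitive merge by repeated pairwise scan
oracle_merge <- function(peaks, max_gap) {
  df <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(df)) {
      if (df$chrom[i] == df$chrom[i + 1L] &&
          df$start[i + 1L] - df$end[i] < max_gap) {
        df$end[i] <- max(df$end[i], df$end[i + 1L])
        df$score[i] <- max(df$score[i], df$score[i + 1L])
        df <- df[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  rownames(df) <- NULL
  df
}

# per-base union coverage of each query by the subject set
oracle_covered <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    bases <- seq.int(query$start[i], query$end[i] - 1L)
    s <- subject[subject$chrom == query$chrom[i], , drop = FALSE]
    covered <- rep(FALSE, length(bases))
    for (j in seq_len(nrow(s)))
      covered <- covered | (bases >= s$start[j] & bases < s$end[j])
    sum(covered)
  }, numeric(1))
}

oracle_overlaps <- function(query, subject, min_fraction) {
  cov <- oracle_covered(query, subject)
  cov / (query$end - query$start) >= min_fraction
}

# per-base category under the fixed precedence, scanning every gene
oracle_category_at <- function(annotation, chrom, pos, flank = 2000L) {
  g <- annotation$genes[annotation$genes$chrom == chrom, , drop = FALSE]
  e <- annotation$exons[annotation$exons$chrom == chrom, , drop = FALSE]
  in_exon <- any(pos >= e$start & pos < e$end)
  in_gene <- any(pos >= g$start & pos < g$end)
  if (in_exon) return("exon")
  if (in_gene) return("intron")
  up <- any(ifelse(g$strand == "+",
                   pos >= g$start - flank & pos < g$start,
                   pos >= g$end & pos < g$end + flank))
  if (up) return("up2k")
  down <- any(ifelse(g$strand == "+",
                     pos >= g$end & pos < g$end + flank,
                     pos >= g$start - flank & pos < g$start))
  if (down) return("down2k")
  "intergenic"
}

# per-gene per-offset upstream counts from a dense vector
oracle_upstream_profile <- function(dense, tss, strand, span, chrom_len) {
  sapply(seq_len(span), function(u) {
    vals <- mapply(function(t, st) {
      p <- if (st == "+") t - u else t + u
      if (p < 0 || p >= chrom_len) NA_real_ else dense[p + 1L]
    }, tss, strand)
    mean(vals, na.rm = TRUE)
  })
}

# --- random instance generators (small scale) -------------------------------

random_fragments <- function(n, chrom_len = 1000L, chrom = "chr1") {
  start <- sample.int(chrom_len - 60L, n, replace = TRUE) - 1L
  len <- sample(5:50, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + len, chrom_len),
             stringsAsFactors = FALSE)
}

random_peak_df <- function(n, chrom_len = 1000L, chroms = "chr1") {
  repeat {
    chrom <- sample(chroms, n, replace = TRUE)
    start <- sample.int(chrom_len - 60L, n, replace = TRUE) - 1L
    df <- data.frame(chrom = chrom, start = start,
                     end = start + sample(5:50, n, replace = TRUE),
                     score = round(stats::runif(n, 0, 100), 1),
                     stringsAsFactors = FALSE)
    if (!anyDuplicated(df[c("chrom", "start", "end")])) return(df)
  }
}

random_annotation <- function(n_genes, chrom_len = 20000L, min_gap = 100L,
                              gene_len = c(200L, 800L)) {
  cfg <- sim_config(chrom_sizes = c(chr1 = chrom_len), organelle_sizes = numeric(0),
                    n_genes = n_genes, gene_length_range = gene_len,
                    flank_min = min_gap, seed = sample.int(1e6, 1))
  generate_annotation(cfg)
}
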