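#' Simulation configuration
#'
#' Parameters of the synthetic ATAC data generator. The generative model:
#' Tn5 insertion ends arrive as an inhomogeneous Poisson process with a
#' uniform nuclear background of `background_rate` insertions per bp; inside
#' each gene's promoter hotspot — a `hotspot_width`-bp window centered
#' `hotspot_center_offset` bp upstream of the TSS, strand-aware — the rate is
#' raised to `background_rate * (1 + intensity)`, where the intensity is
#' looked up from `hotspot_intensity_per_quantile` by the gene's expression
#' quantile (group 0 = non-expressed, 10 = highest). Intensity 0 therefore
#' leaves a hotspot at background level. A configurable fraction of fragments
#' is assigned to the organellar contigs `chrPt`/`chrMt` to emulate
#' plastid/mitochondrial contamination.
#'
#' @param chrom_sizes Named vector of nuclear chromosome lengths in bp.
#' @param organelle_sizes Named vector of organellar contig lengths; names
#'   must be `chrPt` / `chrMt`.
#' @param n_genes Number of genes to place.
#' @param gene_length_range Length-2 integer vector, uniform gene-length range
#'   in bp.
#' @param flank_min Minimum intergenic spacing in bp (also kept at chromosome
#'   ends).
#' @param background_rate Expected background insertions per bp.
#' @param hotspot_center_offset Hotspot center, bp upstream of the TSS
#'   (default 225).
#' @param hotspot_width Hotspot width in bp (default 150).
#' @param hotspot_intensity_per_quantile Non-decreasing numeric vector of 11
#'   extra-fold-over-background multipliers for quantile groups 0..10.
#' @param organelle_fraction Expected fraction of fragments on organellar
#'   contigs, in `[0, 1)`.
#' @param shared_peak_fraction Designed fraction of set-B peaks overlapping
#'   set A in [simulate_peak_pair()], in `[0, 1]`.
#' @param seed Integer master seed; each generator draws from a documented
#'   substream derived from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 1e6),
                       organelle_sizes = c(chrPt = 135000, chrMt = 450000),
                       n_genes = 500L,
                       gene_length_range = c(600L, 1200L),
                       flank_min = 500L,
                       background_rate = 0.02,
                       hotspot_center_offset = 225L,
                       hotspot_width = 150L,
                       hotspot_intensity_per_quantile = 0:10,
                       organelle_fraction = 0.08,
                       shared_peak_fraction = 0.83,
                       seed = 1L) {
  cfg <- list(chrom_sizes = chrom_sizes, organelle_sizes = organelle_sizes,
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              flank_min = as.integer(flank_min),
              background_rate = background_rate,
              hotspot_center_offset = as.integer(hotspot_center_offset),
              hotspot_width = as.integer(hotspot_width),
              hotspot_intensity_per_quantile = as.numeric(hotspot_intensity_per_quantile),
              organelle_fraction = organelle_fraction,
              shared_peak_fraction = shared_peak_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$chrom_sizes)) || any(cfg$chrom_sizes <= 0))
    stop("chrom_sizes must be named and positive", call. = FALSE)
  if (length(cfg$organelle_sizes) &&
      !all(names(cfg$organelle_sizes) %in% ORGANELLE_CHROMS))
    stop("organelle contigs must be named chrPt / chrMt", call. = FALSE)
  if (cfg$n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  if (length(cfg$gene_length_range) != 2L || any(cfg$gene_length_range <= 0) ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2])
    stop("gene_length_range must be a positive increasing pair", call. = FALSE)
  if (cfg$flank_min < 0) stop("flank_min must be >= 0", call. = FALSE)
  if (cfg$background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  if (cfg$hotspot_width <= 0 || cfg$hotspot_center_offset <= 0)
    stop("hotspot geometry must be positive", call. = FALSE)
  ints <- cfg$hotspot_intensity_per_quantile
  if (length(ints) != 11L)
    stop("hotspot_intensity_per_quantile must have exactly 11 entries", call. = FALSE)
  if (any(ints < 0) || is.unsorted(ints))
    stop("hotspot_intensity_per_quantile must be non-negative and non-decreasing",
         call. = FALSE)
  if (cfg$organelle_fraction < 0 || cfg$organelle_fraction >= 1)
    stop("organelle_fraction must be in [0, 1)", call. = FALSE)
  if (cfg$shared_peak_fraction < 0 || cfg$shared_peak_fraction > 1)
    stop("shared_peak_fraction must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

all_chrom_sizes <- function(cfg) c(cfg$chrom_sizes, cfg$organelle_sizes)

# Proportional allocation of n items across chromosomes (largest remainder).
allocate_counts <- function(n, sizes) {
  if (n == 0L) return(stats::setNames(integer(length(sizes)), names(sizes)))
  raw <- n * sizes / sum(sizes)
  base <- floor(raw)
  rem <- n - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1L
  stats::setNames(as.integer(base), names(sizes))
}

# Random integer composition: k non-negative parts summing to total.
random_composition <- function(total, k) {
  if (k == 1L) return(total)
  as.integer(stats::rmultinom(1, total, rep(1, k)))
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping gene models on the nuclear chromosomes
#' (allocated proportionally to length) with all intergenic gaps — including
#' the chromosome ends — at least `flank_min` bp. Strands are sampled
#' uniformly; each gene gets 1-3 exons separated by introns of at least 50 bp
#' where the gene is long enough. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()] (includes the organellar contigs, which
#'   carry no genes).
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  sizes <- config$chrom_sizes
  n_per <- allocate_counts(config$n_genes, sizes)
  with_seed(sub_seed(config$seed, "annotation"), {
    genes <- list(); exons <- list()
    gene_no <- 0L
    for (chrom in names(sizes)) {
      n <- n_per[[chrom]]
      if (n == 0L) next
      len <- as.integer(sizes[[chrom]])
      glen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                     n, replace = TRUE)
      need <- sum(glen) + (n + 1L) * config$flank_min
      if (need > len)
        stop(sprintf(paste0("infeasible packing on '%s': %d genes plus %d-bp",
                            " flanks need %d bp but the chromosome has %d"),
                     chrom, n, config$flank_min, need, len), call. = FALSE)
      gaps <- config$flank_min + random_composition(len - need, n + 1L)
      starts <- as.integer(cumsum(gaps[seq_len(n)]) + c(0L, cumsum(glen[-n])))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      ids <- sprintf("gene_%05d", gene_no + seq_len(n))
      gene_no <- gene_no + n
      genes[[chrom]] <- data.frame(gene_id = ids, chrom = chrom,
                                   start = starts, end = starts + glen,
                                   strand = strand, stringsAsFactors = FALSE)
      exons[[chrom]] <- make_exons(genes[[chrom]])
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0))
    exons <- if (length(exons)) do.call(rbind, exons) else
      data.frame(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0))
    rownames(genes) <- rownames(exons) <- NULL
    genome_annotation(all_chrom_sizes(config), genes, exons)
  })
}

# 1-3 exons per gene; alternating exon/intron segments, each >= 50 bp.
make_exons <- function(genes) {
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    len <- genes$end[i] - genes$start[i]
    k <- sample(1:3, 1)
    while (k > 1L && len < 50L * (2L * k - 1L)) k <- k - 1L
    nseg <- 2L * k - 1L
    seg <- 50L + random_composition(len - 50L * nseg, nseg)
    bounds <- genes$start[i] + cumsum(c(0L, seg))
    ei <- seq(1L, nseg, by = 2L)  # odd segments are exons
    out[[i]] <- data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                           start = bounds[ei], end = bounds[ei + 1L],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic expression table
#'
#' Per-tissue FPKM from a zero-inflated log-normal. A configurable subset of
#' genes is made tissue-enriched by construction: for each selected gene one
#' tissue is forced to at least `enriched_fold` times the maximum FPKM of the
#' other tissues (and positive). Truth labels are attached as
#' `attr(, "truth")`. The first two tissues are named `root` and `leaf`.
#'
#' @param annotation A non-empty [genome_annotation()].
#' @param config A [sim_config()] (supplies the seed).
#' @param n_tissues Number of tissue columns (>= 1).
#' @param zero_prob Zero-inflation probability per gene and tissue.
#' @param meanlog,sdlog Log-normal parameters of positive FPKM.
#' @param enriched_fraction Fraction of genes made tissue-enriched.
#' @param enriched_fold Fold threshold used for the construction (default 10).
#' @return data.frame with `gene_id` plus one FPKM column per tissue and a
#'   `truth` attribute (`gene_id`, `enriched_tissue`).
#' @export
generate_expression <- function(annotation, config, n_tissues = 2L,
                                zero_prob = 0.2, meanlog = 1.5, sdlog = 1.5,
                                enriched_fraction = 0.1, enriched_fold = 10) {
  if (n_tissues < 1L) stop("n_tissues must be >= 1", call. = FALSE)
  if (nrow(annotation$genes) == 0L) stop("annotation has no genes", call. = FALSE)
  if (zero_prob < 0 || zero_prob > 1) stop("zero_prob must be in [0, 1]", call. = FALSE)
  ids <- annotation$genes$gene_id
  n <- length(ids)
  tissues <- c("root", "leaf", sprintf("tissue_%d", seq_len(max(0L, n_tissues - 2L)) + 2L))
  tissues <- tissues[seq_len(n_tissues)]
  with_seed(sub_seed(config$seed, "expression"), {
    fpkm <- matrix(0, nrow = n, ncol = n_tissues, dimnames = list(ids, tissues))
    for (j in seq_len(n_tissues)) {
      zero <- stats::runif(n) < zero_prob
      fpkm[!zero, j] <- stats::rlnorm(sum(!zero), meanlog, sdlog)
    }
    enriched_tissue <- rep(NA_character_, n)
    n_enr <- round(enriched_fraction * n)
    if (n_enr > 0 && n_tissues >= 2L) {
      pick <- sample.int(n, n_enr)
      target <- sample.int(n_tissues, n_enr, replace = TRUE)
      for (k in seq_len(n_enr)) {
        i <- pick[k]; j <- target[k]
        other_max <- max(fpkm[i, -j])
        floor_val <- if (other_max > 0) enriched_fold * other_max
                     else stats::rlnorm(1, meanlog, sdlog)
        fpkm[i, j] <- max(fpkm[i, j], floor_val)
        enriched_tissue[i] <- tissues[j]
      }
    }
    out <- data.frame(gene_id = ids, fpkm, stringsAsFactors = FALSE,
                      row.names = NULL, check.names = FALSE)
    attr(out, "truth") <- data.frame(gene_id = ids,
                                     enriched_tissue = enriched_tissue,
                                     stringsAsFactors = FALSE)
    out
  })
}

# Strand-aware hotspot interval (0-based half-open) for one gene; may need
# truncation at chromosome bounds.
hotspot_interval <- function(tss, strand, center, width) {
  u_min <- center - width %/% 2L + 1L
  u_max <- center + width %/% 2L
  if (strand == "+") c(tss - u_max, tss - u_min + 1L)
  else c(tss + u_min, tss + u_max + 1L)
}

#' Simulate ATAC fragments with promoter hotspots
#'
#' Draws Tn5 insertion anchor ends from the inhomogeneous Poisson model of
#' [sim_config()] (uniform background, elevated promoter hotspots whose
#' intensity follows the gene's expression quantile in `tissue`), then
#' completes each anchor into a fragment by placing the partner end
#' 50-300 bp away on a random side (clamped to the chromosome). Each fragment
#' contributes exactly two insertion ends, and the expected total insertion
#' count on a hotspot-free genome is `background_rate` x genome length.
#' Organellar contamination fragments are added so their expected share of
#' all fragments is `organelle_fraction`. Deterministic given `config$seed`.
#'
#' @param annotation A [genome_annotation()] from [generate_annotation()].
#' @param expression Expression table from [generate_expression()].
#' @param config A [sim_config()].
#' @param tissue Tissue used for quantile stratification (default: first
#'   tissue column).
#' @return List with `fragments` (data.frame `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`) and `truth` (hotspot table with realized intervals,
#'   truncation flags, intensities and quantiles; organelle counts).
#' @export
simulate_fragments <- function(annotation, expression, config, tissue = NULL) {
  validate_sim_config(config)
  if (is.null(tissue)) tissue <- setdiff(names(expression), "gene_id")[1]
  strat <- stratify_quantiles(expression, tissue)
  g <- annotation$genes
  q <- strat$quantile[g$gene_id]
  intensity <- config$hotspot_intensity_per_quantile[q + 1L]
  tss <- tss_positions(annotation)[g$gene_id]

  hotspots <- NULL
  if (nrow(g)) {
    hs <- t(mapply(hotspot_interval, tss, g$strand,
                   MoreArgs = list(center = config$hotspot_center_offset,
                                   width = config$hotspot_width)))
    len <- as.numeric(annotation$chrom_sizes[g$chrom])
    start <- pmax(hs[, 1], 0)
    end <- pmin(hs[, 2], len)
    hotspots <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                           start = as.integer(start), end = as.integer(end),
                           truncated = start != hs[, 1] | end != hs[, 2],
                           intensity = intensity, quantile = unname(q),
                           stringsAsFactors = FALSE)
  }

  nuclear_sizes <- annotation$chrom_sizes[!annotation$organelle]
  organelle_sizes <- annotation$chrom_sizes[annotation$organelle]
  with_seed(sub_seed(config$seed, "fragments"), {
    half_rate <- config$background_rate / 2
    anchors <- lapply(names(nuclear_sizes), function(chrom) {
      len <- as.numeric(nuclear_sizes[[chrom]])
      n_bg <- stats::rpois(1, half_rate * len)
      pos <- if (n_bg > 0) sample.int(len, n_bg, replace = TRUE) - 1L else integer(0)
      hc <- hotspots[hotspots$chrom == chrom & hotspots$intensity > 0 &
                     hotspots$end > hotspots$start, , drop = FALSE]
      if (!is.null(hc) && nrow(hc)) {
        for (i in seq_len(nrow(hc))) {
          w <- hc$end[i] - hc$start[i]
          n_h <- stats::rpois(1, half_rate * hc$intensity[i] * w)
          if (n_h > 0)
            pos <- c(pos, hc$start[i] + sample.int(w, n_h, replace = TRUE) - 1L)
        }
      }
      pos
    })
    names(anchors) <- names(nuclear_sizes)

    frag_chrom <- rep(names(anchors), lengths(anchors))
    a <- unlist(anchors, use.names = FALSE)
    n_nuc <- length(a)
    if (n_nuc > 0) {
      side <- sample(c(-1L, 1L), n_nuc, replace = TRUE)
      d <- sample(50:300, n_nuc, replace = TRUE)
      b <- a + side * d
      lens <- as.integer(nuclear_sizes[frag_chrom])
      b <- pmin(pmax(b, 0L), lens - 1L)
      fs <- pmin(a, b); fe <- pmax(a, b) + 1L
    } else fs <- fe <- integer(0)

    f <- config$organelle_fraction
    n_org <- if (f > 0 && n_nuc > 0 && length(organelle_sizes))
      stats::rpois(1, n_nuc * f / (1 - f)) else 0L
    if (n_org > 0) {
      osz <- organelle_sizes
      ochrom <- sample(names(osz), n_org, replace = TRUE, prob = osz / sum(osz))
      olen <- sample(50:300, n_org, replace = TRUE)
      omax <- as.integer(osz[ochrom]) - olen
      ostart <- as.integer(floor(stats::runif(n_org) * pmax(omax, 1L)))
      frag_chrom <- c(frag_chrom, ochrom)
      fs <- c(fs, ostart); fe <- c(fe, ostart + olen)
    }

    ord <- order(frag_chrom, fs, fe)
    fragments <- data.frame(chrom = frag_chrom[ord], start = fs[ord], end = fe[ord],
                            name = sprintf("frag_%d", seq_along(ord)),
                            score = rep(0L, length(ord)),
                            strand = rep("+", length(ord)),
                            stringsAsFactors = FALSE)
    truth <- list(hotspots = hotspots, tissue = tissue,
                  n_nuclear_fragments = n_nuc, n_organelle_fragments = n_org,
                  organelle_fraction_realized =
                    if (n_nuc + n_org > 0) n_org / (n_nuc + n_org) else 0)
    list(fragments = fragments, truth = truth)
  })
}

#' Simulate a pair of peak sets with a designed shared fraction
#'
#' Generates a disjoint peak set A on the nuclear chromosomes, then a set B of
#' the same size in which each peak is independently designated shared with
#' probability `config$shared_peak_fraction`. Shared B peaks are jittered
#' copies of distinct A peaks, constructed so both directions clear a 10%
#' reciprocal-length overlap by a wide margin; unique B peaks are placed
#' disjoint from A and from each other. Deterministic given `config$seed`.
#'
#' @param annotation A [genome_annotation()] (supplies chromosome sizes).
#' @param config A [sim_config()].
#' @param n_peaks Number of peaks per set (default 1000).
#' @param peak_width_range Uniform peak-width range in bp (default 100-300).
#' @return List with `A`, `B` ([peak_set()]s) and `truth` (per-peak
#'   shared/unique labels for both sets, by peak name).
#' @export
simulate_peak_pair <- function(annotation, config, n_peaks = 1000L,
                               peak_width_range = c(100L, 300L)) {
  validate_sim_config(config)
  sizes <- annotation$chrom_sizes[!annotation$organelle]
  n_per <- allocate_counts(as.integer(n_peaks), sizes)
  gap_min <- 2L * peak_width_range[2]
  with_seed(sub_seed(config$seed, "peaks"), {
    a_list <- list(); b_list <- list()
    a_lab <- character(0); b_lab <- character(0)
    a_no <- 0L; b_no <- 0L
    for (chrom in names(sizes)) {
      n <- n_per[[chrom]]
      if (n == 0L) next
      len <- as.integer(sizes[[chrom]])
      wa <- sample(seq(peak_width_range[1], peak_width_range[2]), n, replace = TRUE)
      need <- sum(wa) + (n + 1L) * gap_min
      if (need > len)
        stop(sprintf("infeasible peak packing on '%s': need %d bp, have %d",
                     chrom, need, len), call. = FALSE)
      gaps <- gap_min + random_composition(len - need, n + 1L)
      as_ <- as.integer(cumsum(gaps[seq_len(n)]) + c(0L, cumsum(wa[-n])))
      ae_ <- as_ + wa

      shared <- stats::runif(n) < config$shared_peak_fraction
      n_sh <- sum(shared)
      # shared B: jitter distinct A peaks; overlap >= wa/4 on both sides
      tgt <- sample.int(n, n_sh)
      wb_sh <- as.integer(round(stats::runif(n_sh, 0.5, 1.5) * wa[tgt]))
      bs_sh <- as_[tgt] + as.integer(round(stats::runif(n_sh, -0.25, 0.25) * wa[tgt]))
      bs_sh <- pmax(bs_sh, 0L)
      be_sh <- pmin(bs_sh + wb_sh, len)

      # unique B: disjoint from A and from each other, in the inter-A gaps
      n_un <- n - n_sh
      bs_un <- be_un <- integer(0)
      if (n_un > 0) {
        occupied <- IRanges::reduce(IRanges::IRanges(c(as_, bs_sh) + 1L,
                                                     c(ae_, be_sh)))
        margin <- 10L
        for (k in seq_len(n_un)) {
          wb <- sample(seq(peak_width_range[1], peak_width_range[2]), 1)
          free <- IRanges::setdiff(IRanges::IRanges(1L, len), occupied)
          free <- free[IRanges::width(free) >= wb + 2L * margin]
          if (length(free) == 0L)
            stop(sprintf("no room for a unique B peak on '%s'", chrom), call. = FALSE)
          slot <- sample.int(length(free), 1,
                             prob = IRanges::width(free) - wb - 2L * margin + 1L)
          lo <- IRanges::start(free)[slot] - 1L + margin
          hi <- IRanges::end(free)[slot] - wb - margin
          s <- lo + sample.int(hi - lo + 1L, 1) - 1L
          bs_un <- c(bs_un, s); be_un <- c(be_un, s + wb)
          occupied <- IRanges::reduce(c(occupied, IRanges::IRanges(s + 1L, s + wb)))
        }
      }

      a_ids <- sprintf("A_%05d", a_no + seq_len(n)); a_no <- a_no + n
      nb <- n_sh + n_un
      b_ids <- sprintf("B_%05d", b_no + seq_len(nb)); b_no <- b_no + nb
      a_list[[chrom]] <- data.frame(chrom = chrom, start = as_, end = ae_,
                                    name = a_ids, stringsAsFactors = FALSE)
      b_list[[chrom]] <- data.frame(chrom = chrom,
                                    start = c(bs_sh, bs_un),
                                    end = c(be_sh, be_un),
                                    name = b_ids, stringsAsFactors = FALSE)
      lab_a <- rep("unique", n); lab_a[tgt] <- "shared"
      a_lab <- c(a_lab, stats::setNames(lab_a, a_ids))
      b_lab <- c(b_lab, stats::setNames(c(rep("shared", n_sh), rep("unique", n_un)),
                                        b_ids))
    }
    a_df <- do.call(rbind, a_list); b_df <- do.call(rbind, b_list)
    A <- peak_set(a_df$chrom, a_df$start, a_df$end, name = a_df$name,
                  score = rep(1, nrow(a_df)))
    B <- peak_set(b_df$chrom, b_df$start, b_df$end, name = b_df$name,
                  score = rep(1, nrow(b_df)))
    list(A = A, B = B,
         truth = list(labels_A = a_lab, labels_B = b_lab,
                      shared_fraction = config$shared_peak_fraction))
  })
}
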