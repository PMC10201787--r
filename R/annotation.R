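#' Genome annotation container
#'
#' Chromosome sizes plus gene models (one transcript per gene): transcript
#' interval, strand and exon intervals, all 0-based half-open. TSS and TTS are
#' derived strand-aware (TSS = first transcribed base, TTS = last).
#'
#' @param chrom_sizes Named vector of chromosome lengths in bp (may include
#'   the organellar contigs `chrPt` / `chrMt`).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`;
#'   every gene must own at least one exon and exons must lie inside their
#'   gene.
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes, genes, exons) {
  if (is.null(names(chrom_sizes))) stop("'chrom_sizes' must be named", call. = FALSE)
  genes <- as.data.frame(genes); exons <- as.data.frame(exons)
  if (nrow(genes)) {
    check_intervals(genes$chrom, genes$start, genes$end, chrom_sizes, "gene")
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids", call. = FALSE)
    if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'", call. = FALSE)
    check_intervals(exons$chrom, exons$start, exons$end, chrom_sizes, "exon")
    if (!all(genes$gene_id %in% exons$gene_id))
      stop("every gene needs at least one exon", call. = FALSE)
    gi <- match(exons$gene_id, genes$gene_id)
    if (anyNA(gi) || any(exons$start < genes$start[gi]) || any(exons$end > genes$end[gi]))
      stop("exons must lie within their gene", call. = FALSE)
  }
  organelle <- is_organelle_chrom(names(chrom_sizes))
  names(organelle) <- names(chrom_sizes)
  structure(list(chrom_sizes = chrom_sizes, organelle = organelle,
                 genes = genes, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s) (%s bp), %d gene(s)\n",
              length(x$chrom_sizes),
              format(sum(as.numeric(x$chrom_sizes)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Strand-aware TSS / TTS positions
#'
#' @param annotation A [genome_annotation()].
#' @return Named integer vector (0-based base position per gene): the first
#'   (`tss_positions`) or last (`tts_positions`) transcribed base.
#' @export
tss_positions <- function(annotation) {
  g <- annotation$genes
  stats::setNames(ifelse(g$strand == "+", g$start, g$end - 1L), g$gene_id)
}

#' @rdname tss_positions
#' @export
tts_positions <- function(annotation) {
  g <- annotation$genes
  stats::setNames(ifelse(g$strand == "+", g$end - 1L, g$start), g$gene_id)
}

CATEGORY_LEVELS <- c("exon", "intron", "up2k", "down2k", "intergenic")

#' Build the five-category genomic index
#'
#' Partitions every base of the genome into one of five categories: `exon`,
#' `intron`, `up2k` (within `flank` bp upstream of a TSS, strand-aware),
#' `down2k` (within `flank` bp downstream of a TTS), or `intergenic`. Where
#' several genes claim a base the fixed precedence
#' exon > intron > up2k > down2k > intergenic applies; UTR bases count as
#' exon (transcribed sequence).
#'
#' @param annotation A [genome_annotation()].
#' @param flank Flank width in bp (default 2000).
#' @return Object of class `category_index`: per-chromosome disjoint sorted
#'   intervals covering the chromosome, each labeled with a category.
#' @export
build_category_index <- function(annotation, flank = 2000L) {
  flank <- as.integer(flank)
  if (flank < 0) stop("flank must be non-negative", call. = FALSE)
  g <- annotation$genes
  per_chrom <- lapply(names(annotation$chrom_sizes), function(chrom) {
    len <- as.integer(annotation$chrom_sizes[[chrom]])
    gc <- g[g$chrom == chrom, , drop = FALSE]
    full <- IRanges::IRanges(1L, len)
    if (nrow(gc) == 0L) {
      return(data.frame(start = 0L, end = len, category = "intergenic",
                        stringsAsFactors = FALSE))
    }
    ec <- annotation$exons[annotation$exons$chrom == chrom, , drop = FALSE]
    ir <- function(s, e) {  # 0-based half-open -> IRanges, clipped to chrom
      keep <- e > s
      IRanges::restrict(IRanges::IRanges(s[keep] + 1L, e[keep]), start = 1L, end = len)
    }
    exon_u <- IRanges::reduce(ir(ec$start, ec$end))
    gene_u <- IRanges::reduce(ir(gc$start, gc$end))
    intron_u <- IRanges::setdiff(gene_u, exon_u)
    up_u <- IRanges::reduce(ir(ifelse(gc$strand == "+", gc$start - flank, gc$end),
                               ifelse(gc$strand == "+", gc$start, gc$end + flank)))
    down_u <- IRanges::reduce(ir(ifelse(gc$strand == "+", gc$end, gc$start - flank),
                                 ifelse(gc$strand == "+", gc$end + flank, gc$start)))
    up_u <- IRanges::setdiff(up_u, gene_u)
    down_u <- IRanges::setdiff(IRanges::setdiff(down_u, gene_u), up_u)
    inter_u <- IRanges::setdiff(IRanges::setdiff(full, gene_u),
                                IRanges::union(up_u, down_u))
    piece <- function(x, cat) {
      if (length(x) == 0L) return(NULL)
      data.frame(start = IRanges::start(x) - 1L, end = IRanges::end(x),
                 category = cat, stringsAsFactors = FALSE)
    }
    out <- rbind(piece(exon_u, "exon"), piece(intron_u, "intron"),
                 piece(up_u, "up2k"), piece(down_u, "down2k"),
                 piece(inter_u, "intergenic"))
    out[order(out$start), , drop = FALSE]
  })
  names(per_chrom) <- names(annotation$chrom_sizes)
  structure(list(intervals = per_chrom, chrom_sizes = annotation$chrom_sizes,
                 flank = flank),
            class = "category_index")
}

#' Category of arbitrary genomic positions
#'
#' @param index A [build_category_index()] result.
#' @param chrom Chromosome name.
#' @param positions 0-based positions within the chromosome.
#' @return Character vector of categories.
#' @export
category_at <- function(index, chrom, positions) {
  iv <- index$intervals[[chrom]]
  if (is.null(iv)) stop(sprintf("unknown chromosome: %s", chrom), call. = FALSE)
  if (any(positions < 0 | positions >= index$chrom_sizes[[chrom]]))
    stop("position outside chromosome", call. = FALSE)
  iv$category[findInterval(positions, iv$start)]
}

#' Per-category base totals of a category index
#'
#' @param index A [build_category_index()] result.
#' @return Named numeric vector of total bp per category; sums to the genome
#'   length (the index is a partition).
#' @export
category_base_totals <- function(index) {
  tot <- stats::setNames(numeric(length(CATEGORY_LEVELS)), CATEGORY_LEVELS)
  for (iv in index$intervals) {
    w <- tapply(as.numeric(iv$end - iv$start), factor(iv$category, CATEGORY_LEVELS),
                sum, default = 0)
    tot <- tot + w
  }
  tot
}

#' Classify peaks into genomic categories
#'
#' Each peak is assigned the category of its midpoint base
#' `floor((start + end) / 2)`, so every peak lands in exactly one category and
#' distributions sum to 100%.
#'
#' @param peaks Peak data.frame.
#' @param index A [build_category_index()] result.
#' @return Character vector of categories, one per peak (sorted peak order).
#' @export
classify_peak <- function(peaks, index) {
  peaks <- as_peak_set(peaks)
  if (nrow(peaks) == 0L) return(character(0))
  mid <- (peaks$start + peaks$end) %/% 2L
  out <- character(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    i <- peaks$chrom == chrom
    out[i] <- category_at(index, chrom, mid[i])
  }
  out
}

#' Genomic category distribution of a peak set
#'
#' @param peaks Non-empty peak data.frame.
#' @param index A [build_category_index()] result.
#' @return Named numeric vector of proportions over the five categories
#'   (exon, intron, up2k, down2k, intergenic), summing to 1.
#' @export
category_distribution <- function(peaks, index) {
  peaks <- as_peak_set(peaks)
  if (nrow(peaks) == 0L) stop("empty peak set", call. = FALSE)
  cats <- factor(classify_peak(peaks, index), levels = CATEGORY_LEVELS)
  p <- as.numeric(table(cats)) / nrow(peaks)
  stats::setNames(p, CATEGORY_LEVELS)
}

#' Closest gene for each peak
#'
#' Interval-to-interval distance (0 for overlap); equidistant genes are
#' resolved to the lexicographically smallest gene id so the mapping is
#' deterministic.
#'
#' @param peaks Peak data.frame.
#' @param annotation A [genome_annotation()] with at least one gene.
#' @return data.frame with the (sorted) peak columns plus `gene_id` and
#'   `distance` (bp; NA if the peak's chromosome has no gene).
#' @export
closest_gene <- function(peaks, annotation) {
  peaks <- as_peak_set(peaks)
  g <- annotation$genes
  if (nrow(g) == 0L) stop("annotation contains no genes", call. = FALSE)
  peaks$gene_id <- NA_character_
  peaks$distance <- NA_real_
  if (nrow(peaks) == 0L) return(peaks)
  pgr <- df_to_granges(peaks)
  ggr <- df_to_granges(g)
  hits <- GenomicRanges::distanceToNearest(pgr, ggr, select = "all",
                                           ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    d <- S4Vectors::mcols(hits)$distance
    # select="all" returns every nearest gene per peak; break ties by id
    ord <- order(qh, g$gene_id[sh])
    first <- !duplicated(qh[ord])
    peaks$gene_id[qh[ord][first]] <- g$gene_id[sh[ord][first]]
    peaks$distance[qh[ord][first]] <- d[ord][first]
  }
  peaks
}

#' Mutually exclusive peak-associated gene classes
#'
#' Maps each peak of two peak classes (e.g. detected-in-one-tissue-only versus
#' detected-in-both) to its closest gene, then removes genes claimed by both
#' classes: the result keeps only genes whose associated peaks all fall in a
#' single class.
#'
#' @param only_A_peaks,shared_peaks Peak data.frames for the two classes.
#' @param annotation A [genome_annotation()].
#' @return List of class `gene_class_assignment` with character vectors
#'   `A_only`, `Shared_only` (disjoint) and `mixed` (genes dropped for
#'   appearing in both), plus the two per-peak closest-gene tables.
#' @export
exclusive_gene_classes <- function(only_A_peaks, shared_peaks, annotation) {
  map_a <- if (nrow(as_peak_set(only_A_peaks)) > 0)
    closest_gene(only_A_peaks, annotation) else NULL
  map_s <- if (nrow(as_peak_set(shared_peaks)) > 0)
    closest_gene(shared_peaks, annotation) else NULL
  genes_a <- unique(stats::na.omit(map_a$gene_id))
  genes_s <- unique(stats::na.omit(map_s$gene_id))
  structure(list(
    A_only = sort(setdiff(genes_a, genes_s)),
    Shared_only = sort(setdiff(genes_s, genes_a)),
    mixed = sort(intersect(genes_a, genes_s)),
    peaks_A = map_a, peaks_shared = map_s
  ), class = "gene_class_assignment")
}

#' @export
print.gene_class_assignment <- function(x, ...) {
  cat(sprintf("gene classes: %d A-only, %d shared-only, %d mixed (excluded)\n",
              length(x$A_only), length(x$Shared_only), length(x$mixed)))
  invisible(x)
}
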