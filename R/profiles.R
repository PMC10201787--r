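#' Stratify genes into expression quantiles
#'
#' Splits genes into 11 ordered groups: group 0 holds genes with FPKM = 0;
#' genes with FPKM > 0 are rank-split into ten deciles (group 10 = most
#' highly expressed) whose sizes differ by at most one. Ties are broken by
#' gene id so the partition is deterministic.
#'
#' @param expression data.frame with column `gene_id` and one numeric FPKM
#'   column per tissue.
#' @param tissue Name of the tissue column to stratify on.
#' @return Object of class `quantile_stratification`: list with `groups`
#'   (list of 11 character vectors of gene ids, names `"0"`..`"10"`),
#'   `quantile` (named integer per gene) and `tissue`.
#' @export
stratify_quantiles <- function(expression, tissue) {
  if (!tissue %in% names(expression))
    stop(sprintf("no tissue column '%s' in expression table", tissue), call. = FALSE)
  if (nrow(expression) == 0L) stop("empty expression table", call. = FALSE)
  fpkm <- expression[[tissue]]
  if (any(fpkm < 0, na.rm = TRUE)) stop("negative FPKM", call. = FALSE)
  ids <- as.character(expression$gene_id)
  if (anyDuplicated(ids)) stop("duplicate gene ids", call. = FALSE)
  q <- integer(length(ids))
  expressed <- which(fpkm > 0)
  if (length(expressed) == 0L) {
    warning("no expressed genes; deciles 1-10 are empty")
  } else {
    ord <- expressed[order(fpkm[expressed], ids[expressed])]  # ascending
    n <- length(ord)
    # balanced rank split: group sizes differ by <= 1, highest ranks -> 10
    q[ord] <- pmin(10L, (seq_len(n) - 1L) %/% (n / 10) + 1L)
  }
  names(q) <- ids
  groups <- split(ids, factor(q, levels = 0:10))
  structure(list(groups = groups, quantile = q, tissue = tissue),
            class = "quantile_stratification")
}

#' @export
print.quantile_stratification <- function(x, ...) {
  sizes <- vapply(x$groups, length, integer(1))
  cat(sprintf("quantile_stratification ('%s'): %d genes (%d non-expressed)\n",
              x$tissue, sum(sizes), sizes[["0"]]))
  invisible(x)
}

# Genomic 0-based positions of the strand-aware upstream offsets u (vector)
# for one gene: plus strand TSS t -> t - u; minus strand -> t + u.
upstream_positions <- function(tss, strand, offsets) {
  if (strand == "+") tss - offsets else tss + offsets
}

#' Aggregate upstream accessibility profile
#'
#' For each upstream offset `u` in `1..span` (u = 1 is the base immediately
#' 5' of the TSS, strand-aware), the mean per-base Tn5 insertion count over a
#' gene group. Bases falling off the chromosome are excluded from the mean at
#' that offset.
#'
#' @param track An [insertion_track()].
#' @param annotation A [genome_annotation()].
#' @param gene_ids Non-empty character vector of gene ids to aggregate.
#' @param span Upstream span in bp (default 1000).
#' @return data.frame of class `aggregate_profile` with columns `offset`,
#'   `mean_count`, `n_genes` (genes contributing at that offset).
#' @export
upstream_profile <- function(track, annotation, gene_ids, span = 1000L) {
  span <- as.integer(span)
  g <- annotation$genes
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("empty gene group", call. = FALSE)
  if (!all(gene_ids %in% g$gene_id)) stop("unknown gene id(s)", call. = FALSE)
  g <- g[match(gene_ids, g$gene_id), , drop = FALSE]
  tss <- tss_positions(annotation)[gene_ids]
  offsets <- seq_len(span)
  total <- numeric(span)
  n_ok <- numeric(span)
  for (i in seq_len(nrow(g))) {
    pos <- upstream_positions(tss[[i]], g$strand[i], offsets)
    ok <- pos >= 0L & pos < track$chrom_sizes[[g$chrom[i]]]
    if (any(ok))
      total[ok] <- total[ok] + track_counts_at(track, g$chrom[i], pos[ok])
    n_ok <- n_ok + ok
  }
  out <- data.frame(offset = offsets,
                    mean_count = ifelse(n_ok > 0, total / n_ok, 0),
                    n_genes = n_ok)
  class(out) <- c("aggregate_profile", "data.frame")
  out
}

#' Normalize a profile to fold accessibility over genomic background
#'
#' Divides each per-base mean by the genome-wide per-base insertion rate
#' (total nuclear insertions / nuclear genome length), giving fold
#' accessibility above the genomic average; 1.0 means background level.
#'
#' @param profile An [upstream_profile()] result.
#' @param track The [insertion_track()] supplying the background rate; must
#'   contain insertions.
#' @return The profile with an added `fold` column.
#' @export
fold_over_background <- function(profile, track) {
  if (track$total_insertions <= 0) stop("track has zero insertions", call. = FALSE)
  bg <- background_rate_of(track)
  profile$fold <- profile$mean_count / bg
  profile
}

#' LOESS smoothing of a profile series
#'
#' Locally weighted degree-1 regression (tricube weights) evaluated at each
#' input offset; used to draw a smooth curve through per-base fold values.
#'
#' @param offset,value Numeric vectors (at least 10 points).
#' @param span LOESS span as a fraction of points per local fit (default 0.3).
#' @return Numeric vector of smoothed values at the input offsets.
#' @export
loess_smooth <- function(offset, value, span = 0.3) {
  if (length(offset) != length(value)) stop("length mismatch", call. = FALSE)
  if (length(offset) < 10L) stop("need at least 10 points", call. = FALSE)
  if (span * length(offset) < 4)
    stop("span too small for local linear fits", call. = FALSE)
  fit <- stats::loess(value ~ offset, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(offset = offset)))
}

#' Promoter-window accessibility per gene
#'
#' Total insertion count in a `width`-bp window centered `center_offset` bp
#' upstream of each gene's TSS — with the defaults, upstream offsets 151-300
#' inclusive (for a plus-strand TSS at base t this is the genomic interval
#' `[t-300, t-150)`). Strand-aware; bases off the chromosome contribute 0.
#'
#' @param track An [insertion_track()].
#' @param annotation A [genome_annotation()].
#' @param gene_ids Gene ids (default: all genes).
#' @param center_offset Window center, bp upstream of the TSS (default 225).
#' @param width Window width in bp (default 150).
#' @return Named numeric vector of window counts per gene.
#' @export
window_accessibility <- function(track, annotation, gene_ids = NULL,
                                 center_offset = 225L, width = 150L) {
  g <- annotation$genes
  if (is.null(gene_ids)) gene_ids <- g$gene_id
  gene_ids <- as.character(gene_ids)
  if (!all(gene_ids %in% g$gene_id)) stop("unknown gene id(s)", call. = FALSE)
  g <- g[match(gene_ids, g$gene_id), , drop = FALSE]
  tss <- tss_positions(annotation)[gene_ids]
  u_min <- as.integer(center_offset - width %/% 2 + 1L)
  u_max <- as.integer(center_offset + width %/% 2)
  out <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  for (chrom in unique(g$chrom)) {
    i <- which(g$chrom == chrom)
    len <- track$chrom_sizes[[chrom]]
    plus <- g$strand[i] == "+"
    # half-open genomic windows containing upstream offsets u_min..u_max
    ws <- ifelse(plus, tss[i] - u_max, tss[i] + u_min)
    we <- ifelse(plus, tss[i] - u_min + 1L, tss[i] + u_max + 1L)
    ws <- pmax(ws, 0L); we <- pmin(we, len)
    ok <- we > ws
    if (any(ok))
      out[i[ok]] <- track_window_sums(track, chrom, ws[ok], we[ok])
  }
  out
}

#' Correlate window accessibility with expression
#'
#' Pearson correlation between per-gene promoter-window insertion counts and
#' FPKM, over genes present in both inputs. A log-log option
#' (`log10(x + 1)` on both sides) is available.
#'
#' @param windows Named numeric vector of per-gene window counts.
#' @param expression data.frame with `gene_id` and a tissue FPKM column, or a
#'   named numeric vector of FPKM.
#' @param tissue Tissue column name (ignored for a vector input).
#' @param log Apply `log10(x + 1)` to both variables first (default FALSE).
#' @return List with `r` (Pearson correlation), `p` (two-sided p-value) and
#'   `n` (paired genes).
#' @export
expression_correlation <- function(windows, expression, tissue = NULL, log = FALSE) {
  if (is.data.frame(expression)) {
    if (is.null(tissue)) stop("'tissue' required for a table input", call. = FALSE)
    fpkm <- stats::setNames(expression[[tissue]], as.character(expression$gene_id))
  } else fpkm <- expression
  common <- intersect(names(windows), names(fpkm))
  if (length(common) < 3L) stop("need at least 3 paired genes", call. = FALSE)
  x <- windows[common]; y <- fpkm[common]
  if (log) { x <- log10(x + 1); y <- log10(y + 1) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Accessibility heatmap matrix
#'
#' One row per gene, ordered from highest to lowest expression; columns are
#' sliding `bin`/`slide` windows over the `flank` bp upstream of the TSS, a
#' scaled gene body (`body_bins` equal-width windows), and the `flank` bp
#' downstream of the TTS, oriented 5'→3' left to right. Values are
#' `log10(count + 1)`.
#'
#' @param track An [insertion_track()].
#' @param annotation A [genome_annotation()].
#' @param expression Expression table (data.frame with `gene_id` + tissue).
#' @param tissue Tissue column for row ordering.
#' @param flank Flank width in bp (default 1000).
#' @param body_bins Number of scaled gene-body windows (default 20).
#' @param bin,slide Window size and step for the flanks (defaults 150 / 20).
#' @return Numeric matrix (genes × windows) with gene-id rownames and an
#'   attribute `region` marking each column as upstream / body / downstream.
#' @export
heatmap_matrix <- function(track, annotation, expression, tissue,
                           flank = 1000L, body_bins = 20L,
                           bin = 150L, slide = 20L) {
  g <- annotation$genes
  if (nrow(g) == 0L) stop("annotation contains no genes", call. = FALSE)
  fpkm <- stats::setNames(expression[[tissue]], as.character(expression$gene_id))
  g <- g[order(-fpkm[g$gene_id], g$gene_id), , drop = FALSE]
  tss <- tss_positions(annotation)
  tts <- tts_positions(annotation)
  n_flank <- max(0L, (as.integer(flank) - as.integer(bin)) %/% as.integer(slide) + 1L)
  region <- c(rep("upstream", n_flank), rep("body", body_bins),
              rep("downstream", n_flank))
  mat <- matrix(0, nrow = nrow(g), ncol = length(region),
                dimnames = list(g$gene_id, NULL))
  for (i in seq_len(nrow(g))) {
    chrom <- g$chrom[i]; len <- track$chrom_sizes[[chrom]]
    t5 <- tss[[g$gene_id[i]]]; t3 <- tts[[g$gene_id[i]]]
    plus <- g$strand[i] == "+"
    sum_win <- function(ws, we) {
      ws <- pmax(ws, 0); we <- pmin(we, len)
      out <- numeric(length(ws))
      ok <- we > ws
      if (any(ok)) out[ok] <- track_window_sums(track, chrom, ws[ok], we[ok])
      out
    }
    k <- seq_len(n_flank) - 1L
    if (plus) {
      up <- sum_win(t5 - flank + k * slide, t5 - flank + k * slide + bin)
      down <- sum_win(t3 + 1L + k * slide, t3 + 1L + k * slide + bin)
    } else {  # 5'->3' runs right-to-left on the genome
      up <- sum_win(t5 + flank - k * slide - bin + 1L, t5 + flank - k * slide + 1L)
      down <- sum_win(t3 - k * slide - bin, t3 - k * slide)
    }
    # scaled body: body_bins equal-width windows across the gene, 5'->3'
    bs <- round(seq(g$start[i], g$end[i], length.out = body_bins + 1L))
    body <- sum_win(bs[-length(bs)], bs[-1L])
    if (!plus) body <- rev(body)
    mat[i, ] <- c(up, body, down)
  }
  mat <- log10(mat + 1)
  attr(mat, "region") <- region
  mat
}

#' Plot quantile fold-accessibility profiles
#'
#' Base-graphics rendering of per-quantile fold-over-background upstream
#' profiles with LOESS curves, upstream distance increasing leftwards as in
#' standard TSS aggregate plots.
#'
#' @param profiles Named list of profiles (as from [fold_over_background()]),
#'   one per quantile group.
#' @param span LOESS span passed to [loess_smooth()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the list of smoothed series.
#' @export
plot_quantile_profiles <- function(profiles, span = 0.3, ...) {
  stopifnot(length(profiles) > 0)
  cols <- grDevices::hcl.colors(length(profiles), "Zissou 1")
  ylim <- range(unlist(lapply(profiles, function(p) p$fold)), 0)
  graphics::plot(NA, xlim = c(max(profiles[[1]]$offset), 1), ylim = ylim,
                 xlab = "distance upstream of TSS (bp)",
                 ylab = "fold accessibility over background", ...)
  smooth <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    graphics::points(p$offset, p$fold, col = grDevices::adjustcolor(cols[i], 0.25),
                     pch = 16, cex = 0.3)
    smooth[[i]] <- loess_smooth(p$offset, p$fold, span = span)
    graphics::lines(p$offset, smooth[[i]], col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = names(profiles), col = cols, lwd = 2,
                   cex = 0.6, bty = "n")
  invisible(stats::setNames(smooth, names(profiles)))
}
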