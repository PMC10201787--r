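#' Extract per-base Tn5 insertion counts from aligned fragments
#'
#' Each sequenced ATAC fragment marks two Tn5 insertion events, one at each
#' end. For a fragment `(chrom, start, end)` in 0-based half-open coordinates
#' the two insertion sites are `start` and `end - 1` (`shift_mode = "none"`),
#' or `start + 4` and `end - 6` under the conventional Tn5 +4/-5 dyad offset
#' (`shift_mode = "tn5_offset"`, clamped to chromosome bounds).
#'
#' @param fragments data.frame of aligned fragments with columns `chrom`,
#'   `start`, `end` (0-based half-open, one row per read pair).
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param shift_mode `"none"` (default) or `"tn5_offset"`.
#' @return An [insertion_track()] with `total_insertions` equal to twice the
#'   number of fragments.
#' @export
extract_insertions <- function(fragments, chrom_sizes, shift_mode = c("none", "tn5_offset")) {
  shift_mode <- match.arg(shift_mode)
  check_intervals(fragments$chrom, fragments$start, fragments$end,
                  chrom_sizes = chrom_sizes, what = "fragment")
  if (nrow(fragments) == 0L)
    return(insertion_track(list(), chrom_sizes))
  if (shift_mode == "none") {
    left <- fragments$start
    right <- fragments$end - 1L
  } else {
    left <- fragments$start + 4L
    right <- fragments$end - 6L
  }
  chrom <- rep(fragments$chrom, 2L)
  pos <- c(left, right)
  # clamp (tn5_offset can push sites past either end of short fragments)
  pos <- pmax(pos, 0L)
  pos <- pmin(pos, as.integer(chrom_sizes[chrom]) - 1L)
  positions <- split(pos, chrom)
  insertion_track(positions, chrom_sizes)
}

#' Sliding-window density track
#'
#' Summarizes an insertion track as a sliding histogram: windows of `bin_size`
#' bp whose starts are the multiples of `slide` (anchored at coordinate 0, so
#' tracks from different samples are comparable bin-for-bin). Each window is
#' reported as a bar covering the center `slide` bp of the window, with height
#' the total insertion count in the full window — the representation used for
#' genome-browser density files.
#'
#' @param track An [insertion_track()].
#' @param bin_size Window width in bp (default 150).
#' @param slide Step between window starts in bp (default 20); must not exceed
#'   `bin_size`.
#' @param drop_empty Drop zero-height bars (default TRUE; set FALSE to emit
#'   every window).
#' @return data.frame with columns `chrom`, `window_start`, `window_end`,
#'   `bar_start`, `bar_end`, `height`; class `density_track`, with `bin_size`
#'   and `slide` attributes.
#' @export
density_track <- function(track, bin_size = 150L, slide = 20L, drop_empty = TRUE) {
  if (bin_size <= 0 || slide <= 0) stop("bin_size and slide must be positive", call. = FALSE)
  if (slide > bin_size) stop("slide must not exceed bin_size", call. = FALSE)
  bin_size <- as.integer(bin_size); slide <- as.integer(slide)
  pad <- (bin_size - slide) %/% 2L
  per_chrom <- lapply(names(track$chrom_sizes), function(chrom) {
    len <- track$chrom_sizes[[chrom]]
    last_start <- ((len - 1L) %/% slide) * slide
    starts <- seq.int(0L, last_start, by = slide)
    heights <- track_window_sums(track, chrom, starts, starts + bin_size)
    if (drop_empty) {
      keep <- heights > 0
      starts <- starts[keep]; heights <- heights[keep]
    }
    if (!length(starts)) return(NULL)
    data.frame(chrom = chrom,
               window_start = starts,
               window_end = starts + bin_size,
               bar_start = starts + pad,
               bar_end = starts + pad + slide,
               height = as.integer(heights),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  if (is.null(out))
    out <- data.frame(chrom = character(0), window_start = integer(0),
                      window_end = integer(0), bar_start = integer(0),
                      bar_end = integer(0), height = integer(0))
  attr(out, "bin_size") <- bin_size
  attr(out, "slide") <- slide
  class(out) <- c("density_track", "data.frame")
  out
}

#' Organellar read fractions
#'
#' Proportion of aligned reads (or fragments) on nuclear, plastid and
#' mitochondrial references — the standard contamination check for plant
#' ATAC-seq nuclei preparations.
#'
#' @param alignment_counts Named numeric vector of read counts with names among
#'   `nuclear`, `plastid`, `mitochondrial` (missing classes count 0), or a
#'   fragment data.frame with a `chrom` column (contigs `chrPt`/`chrMt` are
#'   organellar).
#' @return Named numeric vector of proportions over the three classes, summing
#'   to 1.
#' @export
organelle_fraction <- function(alignment_counts) {
  classes <- c("nuclear", "plastid", "mitochondrial")
  if (is.data.frame(alignment_counts)) {
    chrom <- alignment_counts$chrom
    alignment_counts <- c(
      nuclear = sum(!is_organelle_chrom(chrom)),
      plastid = sum(chrom == ORGANELLE_CHROMS[["plastid"]]),
      mitochondrial = sum(chrom == ORGANELLE_CHROMS[["mitochondrial"]])
    )
  }
  unknown <- setdiff(names(alignment_counts), classes)
  if (length(unknown))
    stop(sprintf("unknown reference class(es): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  counts <- stats::setNames(numeric(3), classes)
  counts[names(alignment_counts)] <- alignment_counts
  if (any(counts < 0)) stop("negative read count", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("all-zero alignment counts", call. = FALSE)
  counts / total
}

#' SPOT score (Signal Portion Of Tags)
#'
#' Fraction of Tn5 insertion events that fall inside peak regions; the
#' standard signal-to-noise measure for open-chromatin assays. Computed over
#' insertion events against the sample's own (merged) peak set.
#'
#' @param track An [insertion_track()] with at least one insertion.
#' @param peaks Peak data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open); overlapping peaks are unioned before counting.
#' @return Proportion in `[0, 1]`.
#' @export
spot_score <- function(track, peaks) {
  if (track$total_insertions <= 0) stop("empty insertion track", call. = FALSE)
  if (is.null(peaks) || nrow(peaks) == 0L) return(0)
  check_intervals(peaks$chrom, peaks$start, peaks$end, what = "peak")
  inside <- 0
  for (chrom in intersect(unique(peaks$chrom), names(track$chrom_sizes))) {
    p <- peaks[peaks$chrom == chrom, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    inside <- inside + sum(track_window_sums(track, chrom,
                                             IRanges::start(merged) - 1L,
                                             IRanges::end(merged)))
  }
  inside / track$total_insertions
}
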