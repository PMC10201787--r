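#' Construct a peak set
#'
#' Validates and sorts a table of scored peak intervals (0-based half-open),
#' the unit consumed by the merge / comparison / annotation functions. Peaks
#' normally come from an external caller (e.g. MACS2 narrowPeak output read
#' with [read_narrowpeak()]).
#'
#' @param chrom,start,end Interval columns (0-based half-open).
#' @param name Optional peak names (default `peak_1..n` after sorting).
#' @param score Optional numeric scores (default 0).
#' @return data.frame of class `peak_set`, sorted by (chrom, start), columns
#'   `chrom`, `start`, `end`, `name`, `score`.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  chrom <- rep(as.character(chrom), length.out = length(start))
  check_intervals(chrom, start, end, what = "peak")
  n <- length(chrom)
  if (is.null(score)) score <- rep(0, n)
  ord <- order(chrom, start, end)
  df <- data.frame(chrom = chrom[ord], start = start[ord], end = end[ord],
                   name = if (is.null(name)) sprintf("peak_%d", seq_len(n)) else as.character(name)[ord],
                   score = as.numeric(score)[ord],
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("chrom", "start", "end")]))
    stop("duplicate (chrom, start, end) peak", call. = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

as_peak_set <- function(df) {
  if (inherits(df, "peak_set")) return(df)
  peak_set(df$chrom, df$start, df$end,
           name = if ("name" %in% names(df)) df$name else NULL,
           score = if ("score" %in% names(df)) df$score else NULL)
}

#' Merge peaks separated by small gaps
#'
#' Merges (transitively) any peaks on the same chromosome whose gap — the
#' distance between proximal ends — is strictly less than `max_gap` bp. A
#' merged peak spans the members' full extent and takes the maximum member
#' score. Standard hygiene after peak calling, where fragmented calls split
#' single accessible regions.
#'
#' @param peaks A [peak_set()] (or coercible data.frame).
#' @param max_gap Gap threshold in bp (default 10; gaps `>= max_gap` are kept).
#' @return A merged `peak_set`. Idempotent.
#' @export
merge_peaks <- function(peaks, max_gap = 10L) {
  peaks <- as_peak_set(peaks)
  if (max_gap < 0) stop("max_gap must be non-negative", call. = FALSE)
  if (nrow(peaks) <= 1L) return(peaks)
  out <- lapply(split(peaks, peaks$chrom), function(p) {
    # sorted by start; a new cluster opens when the gap to the running
    # rightmost end is >= max_gap
    run_end <- cummax(p$end)
    new_cluster <- c(TRUE, p$start[-1L] - run_end[-nrow(p)] >= max_gap)
    grp <- cumsum(new_cluster)
    data.frame(
      chrom = p$chrom[1L],
      start = tapply(p$start, grp, min),
      end = tapply(p$end, grp, max),
      score = tapply(p$score, grp, max),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  peak_set(out$chrom, out$start, out$end, score = out$score)
}

# Bases of each query interval covered by the union of subject intervals.
covered_bases <- function(query, subject) {
  cov <- numeric(nrow(query))
  for (chrom in unique(query$chrom)) {
    qi <- which(query$chrom == chrom)
    s <- subject[subject$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0L) next
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end))
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits) == 0L) next
    ov <- IRanges::width(IRanges::pintersect(qr[S4Vectors::queryHits(hits)],
                                             sr[S4Vectors::subjectHits(hits)]))
    cov[qi] <- cov[qi] + as.numeric(tapply(ov, factor(S4Vectors::queryHits(hits),
                                                      levels = seq_along(qr)),
                                           sum, default = 0))
  }
  cov
}

#' Minimum-fraction overlap test
#'
#' TRUE for each query peak whose bases covered by the union of subject peaks
#' amount to at least `min_fraction` of the query's own length. Union coverage
#' means a query split across two subject peaks still counts as one overlap.
#'
#' @param query Peak data.frame (the peaks being classified).
#' @param subject_set Peak data.frame (the reference set).
#' @param min_fraction Minimum covered fraction of the query length
#'   (default 0.10).
#' @return Logical vector, one per query peak (in query's sorted order).
#' @export
overlaps_by_fraction <- function(query, subject_set, min_fraction = 0.10) {
  query <- as_peak_set(query)
  subject_set <- as_peak_set(subject_set)
  if (nrow(query) == 0L) return(logical(0))
  cov <- covered_bases(query, subject_set)
  # ratio comparison keeps exact boundaries (10 bp of 100 at 10%) exact
  cov / (query$end - query$start) >= min_fraction
}

#' Partition two peak sets by mutual overlap
#'
#' Classifies each peak of A as shared (overlapping B by at least
#' `min_fraction` of its own length) or A-only, and symmetrically for B. The
#' two directions are computed independently, so the shared counts need not
#' agree — a single broad peak in one set can absorb several in the other.
#'
#' @param A,B Peak data.frames.
#' @param min_fraction Overlap threshold as in [overlaps_by_fraction()].
#' @return List of class `overlap_partition` with `peak_set` elements
#'   `shared_A`, `only_A`, `shared_B`, `only_B` and a `counts` vector.
#' @export
partition_peak_sets <- function(A, B, min_fraction = 0.10) {
  A <- as_peak_set(A); B <- as_peak_set(B)
  in_b <- overlaps_by_fraction(A, B, min_fraction)
  in_a <- overlaps_by_fraction(B, A, min_fraction)
  out <- list(
    shared_A = A[in_b, , drop = FALSE],
    only_A = A[!in_b, , drop = FALSE],
    shared_B = B[in_a, , drop = FALSE],
    only_B = B[!in_a, , drop = FALSE]
  )
  out$counts <- vapply(out, nrow, integer(1))
  out$min_fraction <- min_fraction
  class(out) <- "overlap_partition"
  out
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("overlap_partition (min_fraction = %g):\n", x$min_fraction))
  cat(sprintf("  A: %d shared, %d only\n", x$counts[["shared_A"]], x$counts[["only_A"]]))
  cat(sprintf("  B: %d shared, %d only\n", x$counts[["shared_B"]], x$counts[["only_B"]]))
  invisible(x)
}

#' Down-sample fragments to a target depth
#'
#' Uniform random subset of read pairs without replacement, used to equalize
#' sequencing depth before comparing peak sets called at different depths.
#'
#' @param fragments Fragment data.frame (one row per read pair).
#' @param n Target number of fragments; if `n >= nrow(fragments)` all are kept.
#' @param seed Integer seed; the draw is deterministic given the seed and does
#'   not disturb the caller's RNG state.
#' @return Fragment data.frame with `min(n, nrow(fragments))` rows, in original
#'   row order.
#' @export
downsample_fragments <- function(fragments, n, seed) {
  stop_if_not_scalar_count(n, "n")
  if (n >= nrow(fragments)) return(fragments)
  keep <- with_seed(sub_seed(seed, "downsample"),
                    sort(sample.int(nrow(fragments), n)))
  fragments[keep, , drop = FALSE]
}
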