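#' Per-base Tn5 insertion track
#'
#' Sparse container for per-base Tn5 insertion counts: for each chromosome a
#' sorted vector of 0-based positions and the (positive) count at each. This is
#' the central accessibility signal all downstream profile and score functions
#' consume.
#'
#' @param positions Named list, one element per chromosome, each a data.frame
#'   with columns `pos` (0-based base) and `count` (positive integer), or an
#'   unnamed integer vector of raw insertion positions to be tabulated.
#' @param chrom_sizes Named vector of chromosome lengths (bp); must cover every
#'   chromosome in `positions`.
#' @return An object of class `insertion_track` with fields `counts` (per-chrom
#'   sorted sparse counts), `chrom_sizes`, `organelle` (logical per chrom),
#'   `total_insertions`, and nuclear totals used for background rates.
#' @export
insertion_track <- function(positions, chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("'chrom_sizes' must be a named vector", call. = FALSE)
  unknown <- setdiff(names(positions), names(chrom_sizes))
  if (length(unknown))
    stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  counts <- lapply(names(chrom_sizes), function(chrom) {
    x <- positions[[chrom]]
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L)
      return(list(pos = integer(0), count = integer(0)))
    if (!is.data.frame(x)) {  # raw positions: tabulate into sparse counts
      tab <- table(x)
      x <- data.frame(pos = as.integer(names(tab)), count = as.integer(tab))
    }
    if (any(x$pos < 0) || any(x$pos >= chrom_sizes[[chrom]]))
      stop(sprintf("insertion position outside chromosome '%s'", chrom), call. = FALSE)
    if (any(x$count < 0)) stop("negative insertion count", call. = FALSE)
    ord <- order(x$pos)
    list(pos = as.integer(x$pos[ord]), count = as.integer(x$count[ord]))
  })
  names(counts) <- names(chrom_sizes)
  organelle <- is_organelle_chrom(names(chrom_sizes))
  names(organelle) <- names(chrom_sizes)
  per_chrom <- vapply(counts, function(x) sum(x$count), numeric(1))
  structure(list(
    counts = counts,
    chrom_sizes = chrom_sizes,
    organelle = organelle,
    total_insertions = sum(per_chrom),
    nuclear_insertions = sum(per_chrom[!organelle]),
    nuclear_length = sum(as.numeric(chrom_sizes[!organelle]))
  ), class = "insertion_track")
}

#' @export
print.insertion_track <- function(x, ...) {
  cat(sprintf("insertion_track: %d chromosome(s), %s insertions (%s nuclear)\n",
              length(x$chrom_sizes),
              format(x$total_insertions, big.mark = ","),
              format(x$nuclear_insertions, big.mark = ",")))
  invisible(x)
}

#' Query an insertion track
#'
#' `track_counts_at` returns the insertion count at arbitrary 0-based
#' positions on one chromosome (0 where no insertion was recorded);
#' `track_window_sums` returns total counts over half-open windows
#' `[starts, ends)`, vectorized over windows.
#'
#' @param track An [insertion_track()].
#' @param chrom Chromosome name.
#' @param positions Integer vector of 0-based positions.
#' @return Integer (counts) or numeric (window sums) vector.
#' @export
track_counts_at <- function(track, chrom, positions) {
  x <- track$counts[[chrom]]
  if (is.null(x)) stop(sprintf("unknown chromosome: %s", chrom), call. = FALSE)
  out <- integer(length(positions))
  if (length(x$pos) == 0L || length(positions) == 0L) return(out)
  idx <- match(positions, x$pos)
  hit <- !is.na(idx)
  out[hit] <- x$count[idx[hit]]
  out
}

#' @rdname track_counts_at
#' @param starts,ends 0-based half-open window bounds (equal length).
#' @export
track_window_sums <- function(track, chrom, starts, ends) {
  x <- track$counts[[chrom]]
  if (is.null(x)) stop(sprintf("unknown chromosome: %s", chrom), call. = FALSE)
  if (length(x$pos) == 0L) return(numeric(length(starts)))
  cs <- c(0, cumsum(as.numeric(x$count)))
  hi <- findInterval(ends - 1L, x$pos)    # positions <= end-1
  lo <- findInterval(starts - 1L, x$pos)  # positions <= start-1
  cs[hi + 1L] - cs[lo + 1L]
}

# Genome-wide nuclear background rate: insertions per bp over nuclear contigs.
background_rate_of <- function(track) {
  if (track$nuclear_length <= 0) stop("track has no nuclear chromosomes", call. = FALSE)
  track$nuclear_insertions / track$nuclear_length
}
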