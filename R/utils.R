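# Internal helpers shared across modules.

# Reserved contig names for organellar genomes. Fragments on these contigs are
# counted as contamination and excluded from nuclear background rates.
ORGANELLE_CHROMS <- c(plastid = "chrPt", mitochondrial = "chrMt")

is_organelle_chrom <- function(chrom) chrom %in% ORGANELLE_CHROMS

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-generator substream offsets derived from the single config seed, so
# regenerating one output does not perturb the others. All stay below 2^31.
sub_seed <- function(seed, stream) {
  offsets <- c(annotation = 101L, expression = 202L, fragments = 303L,
               peaks = 404L, downsample = 505L)
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) %% 2000000011L) + offsets[[stream]]
}

stop_if_not_scalar_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", what), call. = FALSE)
  invisible(as.integer(x))
}

# 0-based half-open interval validation used by fragment/peak constructors.
check_intervals <- function(chrom, start, end, chrom_sizes = NULL, what = "interval") {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop(sprintf("%s columns have unequal lengths", what), call. = FALSE)
  if (length(start) && any(start < 0))
    stop(sprintf("%s starts must be >= 0", what), call. = FALSE)
  if (length(start) && any(end <= start))
    stop(sprintf("%s requires start < end (0-based half-open)", what), call. = FALSE)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown))
      stop(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    if (length(start) && any(end > chrom_sizes[chrom]))
      stop(sprintf("%s extends past chromosome end", what), call. = FALSE)
  }
  invisible(TRUE)
}

# data.frame (0-based half-open) -> GRanges (1-based closed) and back.
df_to_granges <- function(df, chrom_sizes = NULL) {
  seqinfo <- NULL
  if (!is.null(chrom_sizes))
    seqinfo <- GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                                     seqlengths = as.integer(chrom_sizes))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(seqinfo))
    GenomeInfoDb::seqinfo(gr) <- seqinfo[GenomeInfoDb::seqlevels(gr)]
  gr
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
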