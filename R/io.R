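# File I/O. Interval formats go through rtracklayer (which owns the
# 0-based/1-based conversions); narrowPeak is BED6+4 via extraCols on read and
# a plain 10-column writer. All in-memory coordinates are 0-based half-open.

#' Write / read a genome annotation as GFF3
#'
#' Gene models are emitted as `gene` / `mRNA` / `exon` features (one
#' transcript per gene). Chromosome sizes travel in `##sequence-region`
#' pragmas and are restored on read.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file.
#' @return `write_gff3`: the path, invisibly. `read_gff3`: a
#'   [genome_annotation()].
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chrom in names(annotation$chrom_sizes))
    writeLines(sprintf("##sequence-region %s 1 %d", chrom,
                       as.integer(annotation$chrom_sizes[[chrom]])), con)
  g <- annotation$genes
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    s <- g$start[i] + 1L; e <- g$end[i]
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], s, e, g$strand[i], id), con)
    writeLines(sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                       g$chrom[i], s, e, g$strand[i], id, id), con)
    ex <- annotation$exons[annotation$exons$gene_id == id, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.exon%d;Parent=%s.1",
                         ex$chrom[j], ex$start[j] + 1L, ex$end[j],
                         g$strand[i], id, j, id), con)
  }
  invisible(path)
}

#' @rdname write_gff3
#' @param chrom_sizes Optional named vector overriding sizes from the file's
#'   `##sequence-region` pragmas.
#' @export
read_gff3 <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(chrom_sizes)) {
    pragmas <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(pragmas) == 0L)
      stop("GFF3 lacks ##sequence-region pragmas; pass chrom_sizes", call. = FALSE)
    fields <- strsplit(trimws(pragmas), "[ \t]+")
    chrom_sizes <- stats::setNames(
      vapply(fields, function(x) as.numeric(x[4]), numeric(1)),
      vapply(fields, function(x) x[2], character(1)))
  }
  type <- as.character(gr$type)
  gg <- gr[type == "gene"]
  genes <- data.frame(gene_id = as.character(gg$ID),
                      chrom = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg) - 1L,
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  ge <- gr[type == "exon"]
  mrna <- gr[type == "mRNA"]
  tx2gene <- stats::setNames(as.character(mrna$Parent), as.character(mrna$ID))
  exon_parent <- as.character(ge$Parent)
  exons <- data.frame(gene_id = unname(tx2gene[exon_parent]),
                      chrom = as.character(GenomicRanges::seqnames(ge)),
                      start = GenomicRanges::start(ge) - 1L,
                      end = GenomicRanges::end(ge),
                      stringsAsFactors = FALSE)
  genome_annotation(chrom_sizes, genes, exons)
}

#' Read / write BED intervals
#'
#' @param path File path.
#' @return `read_bed`: data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) plus `name`, `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- granges_to_df(gr)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- as.numeric(gr$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

#' @rdname read_bed
#' @param df Interval data.frame (`chrom`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @export
write_bed <- function(df, path) {
  gr <- df_to_granges(df)
  if (!is.null(df$name)) gr$name <- df$name
  gr$score <- if (!is.null(df$score)) as.numeric(df$score) else 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write narrowPeak peak sets
#'
#' narrowPeak is BED6+4 (signalValue, pValue, qValue, summit offset); MACS2's
#' native output format. Missing statistics are written as -1 per the format
#' convention.
#'
#' @param path File path.
#' @return `read_narrowpeak`: a [peak_set()] (extra columns preserved).
#' @export
read_narrowpeak <- function(path) {
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  df <- granges_to_df(gr)
  ps <- peak_set(df$chrom, df$start, df$end, name = gr$name,
                 score = as.numeric(gr$score))
  ps
}

#' @rdname read_narrowpeak
#' @param peaks A [peak_set()].
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- as_peak_set(peaks)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    as.integer(pmin(pmax(peaks$score, 0), 1000)), ".",
                    -1, -1, -1, -1)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an insertion track or density track as bedGraph
#'
#' Per-base insertion counts (`write_insertion_bedgraph`) or sliding-window
#' density bars (`write_density_bedgraph`, bar = center slice of its window)
#' in bedGraph format for genome browsers such as IGV.
#'
#' @param track An [insertion_track()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_insertion_bedgraph <- function(track, path) {
  rows <- lapply(names(track$counts), function(chrom) {
    x <- track$counts[[chrom]]
    if (!length(x$pos)) return(NULL)
    data.frame(chrom = chrom, start = x$pos, end = x$pos + 1L,
               score = x$count, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- df_to_granges(df)
  gr$score <- df$score
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_insertion_bedgraph
#' @param density A [density_track()].
#' @export
write_density_bedgraph <- function(density, path) {
  df <- data.frame(chrom = density$chrom, start = density$bar_start,
                   end = density$bar_end, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- df_to_granges(df)
  gr$score <- density$height
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write a gene expression table
#'
#' Tab-delimited, first column `gene_id`, one numeric FPKM column per tissue.
#'
#' @param path File path.
#' @return `read_expression`: the expression data.frame.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'", call. = FALSE)
  df
}

#' @rdname read_expression
#' @param expression Expression data.frame.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path File path.
#' @return `read_sim_config`: a [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$chrom_sizes <- unlist(x$chrom_sizes)
  x$organelle_sizes <- unlist(x$organelle_sizes)
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$chrom_sizes <- as.list(x$chrom_sizes)
  x$organelle_sizes <- as.list(x$organelle_sizes)
  yaml::write_yaml(x, path)
  invisible(path)
}
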