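#' Classify genes as tissue-enriched by fold change
#'
#' A gene is enriched in the target tissue when its FPKM there is at least
#' `fold` times the FPKM in the other tissue and positive; with both FPKM 0
#' the gene is not enriched. The comparison is inclusive (`>=`).
#'
#' @param fpkm_target,fpkm_other Non-negative FPKM vectors (recycled).
#' @param fold Fold threshold (default 10).
#' @return Logical vector: TRUE = enriched.
#' @export
fold_enrichment_class <- function(fpkm_target, fpkm_other, fold = 10) {
  if (any(fpkm_target < 0, na.rm = TRUE) || any(fpkm_other < 0, na.rm = TRUE))
    stop("FPKM must be non-negative", call. = FALSE)
  fpkm_target > 0 & fpkm_target >= fold * fpkm_other
}

#' Chi-square test for differential enrichment between gene classes
#'
#' Builds the 2x2 contingency table of gene class x enrichment status and
#' applies Pearson's chi-square test (1 df, no continuity correction by
#' default), the standard test for comparing enriched-gene proportions
#' between two peak-associated gene classes.
#'
#' @param classA_genes,classB_genes Character vectors of gene ids (non-empty,
#'   treated as disjoint classes).
#' @param enriched Named logical vector (or character vector of enriched gene
#'   ids) giving each gene's enrichment status.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List of class `class_enrichment_test`: `table` (2x2 matrix),
#'   `chi2`, `p`, `proportions` (enriched share per class), `n` per class.
#' @export
class_enrichment_test <- function(classA_genes, classB_genes, enriched,
                                  correct = FALSE) {
  if (length(classA_genes) == 0L || length(classB_genes) == 0L)
    stop("both gene classes must be non-empty", call. = FALSE)
  status <- function(ids) {
    if (is.character(enriched)) ids %in% enriched
    else {
      miss <- setdiff(ids, names(enriched))
      if (length(miss))
        stop(sprintf("no enrichment label for gene(s): %s",
                     paste(utils::head(miss, 3), collapse = ", ")), call. = FALSE)
      unname(enriched[ids])
    }
  }
  ea <- status(classA_genes); eb <- status(classB_genes)
  tab <- matrix(c(sum(ea), sum(!ea), sum(eb), sum(!eb)), nrow = 2, byrow = TRUE,
                dimnames = list(class = c("A", "B"),
                                status = c("enriched", "not_enriched")))
  if (any(rowSums(tab) == 0))
    stop("degenerate margin: a gene class is empty", call. = FALSE)
  if (any(colSums(tab) == 0))
    stop(sprintf("degenerate margin: all genes are '%s'",
                 colnames(tab)[colSums(tab) > 0]), call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(table = tab,
                 chi2 = unname(ct$statistic),
                 p = ct$p.value,
                 proportions = c(A = tab[1, 1] / sum(tab[1, ]),
                                 B = tab[2, 1] / sum(tab[2, ])),
                 n = c(A = sum(tab[1, ]), B = sum(tab[2, ])),
                 correct = correct),
            class = "class_enrichment_test")
}

#' @export
print.class_enrichment_test <- function(x, ...) {
  cat(sprintf("class enrichment test: chi2 = %.4g, p = %.4g\n", x$chi2, x$p))
  cat(sprintf("  enriched: %.1f%% of %d (A) vs %.1f%% of %d (B)\n",
              100 * x$proportions[["A"]], x$n[["A"]],
              100 * x$proportions[["B"]], x$n[["B"]]))
  invisible(x)
}
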