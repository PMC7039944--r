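#' Relative expression by the delta-delta-Ct method
#'
#' Normalizes qPCR target Ct values against a housekeeping gene and a
#' reference line: `dCt = Ct_target - Ct_housekeeping`,
#' `ddCt = dCt - mean(dCt of the reference line)`, fold = `2^(-ddCt)`.
#' Folds are then divided by the reference line's mean fold so the
#' reference line's arithmetic mean fold is exactly 1 (a no-op when the
#' reference line has a single sample). Samples whose target Ct reaches
#' the cycle cap (default 35) are flagged not-detected (ND) and
#' excluded from folds, not silently dropped.
#'
#' @param ct data.frame with a `line` column and numeric Ct columns.
#' @param target Name of the target-gene Ct column.
#' @param housekeeping Name of the housekeeping-gene Ct column
#'   (default "Gapdh").
#' @param reference_line Line whose mean fold defines 1.
#' @param cycle_cap Ct at/above which the target is called ND
#'   (default 35).
#' @return data.frame with `line`, `fold` (NA for ND samples) and `nd`;
#'   attribute `n_nd` counts ND samples.
#' @export
relative_expression <- function(ct, target, housekeeping = "Gapdh",
                                reference_line, cycle_cap = 35) {
  for (col in c("line", target, housekeeping))
    if (!col %in% names(ct)) ccq_stop("column '%s' missing", col)
  if (!reference_line %in% ct$line)
    ccq_stop("reference line '%s' absent from the table", reference_line)
  ct_t <- ct[[target]]; ct_h <- ct[[housekeeping]]
  if (any(!is.finite(ct_h))) ccq_stop("housekeeping Ct must be finite")
  nd <- !is.finite(ct_t) | ct_t >= cycle_cap
  dct <- ct_t - ct_h
  ref <- ct$line == reference_line & !nd
  if (!any(ref))
    ccq_stop("reference line '%s' has no detected sample", reference_line)
  ddct <- dct - mean(dct[ref])
  fold <- 2^(-ddct)
  fold <- fold / mean(fold[ref])
  fold[nd] <- NA_real_
  out <- data.frame(line = ct$line, fold = fold, nd = nd)
  attr(out, "n_nd") <- sum(nd)
  out
}

#' Pearson correlation between line-level expression and a trait
#'
#' Plain Pearson correlation between per-line mean fold changes and
#' per-line trait means, aligned by line label.
#'
#' @param folds Named numeric vector of per-line mean folds (names are
#'   line labels), or the output of [relative_expression()] (averaged
#'   by line).
#' @param line_trait_means Named numeric vector of per-line trait
#'   means.
#' @return Pearson r (scalar). Fewer than 3 shared lines is an error;
#'   zero variance yields NA with a warning, never a silent NaN.
#' @export
expression_phenotype_correlation <- function(folds, line_trait_means) {
  if (is.data.frame(folds)) {
    fm <- tapply(folds$fold, folds$line, mean, na.rm = TRUE)
    folds <- setNames(as.numeric(fm), names(fm))
  }
  shared <- intersect(names(folds), names(line_trait_means))
  shared <- shared[is.finite(folds[shared]) &
                     is.finite(line_trait_means[shared])]
  if (length(shared) < 3) ccq_stop("need >= 3 lines with both measurements")
  x <- folds[shared]; y <- line_trait_means[shared]
  if (sd(x) == 0 || sd(y) == 0) {
    ccq_warn("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Genes and read counts in a window around a locus
#'
#' Reports every annotated gene overlapping
#' `[center - half_width, center + half_width]` with its raw count, a
#' signed count for display (minus-strand genes on a negative axis) and
#' an expressed flag (`count >= expressed_min`).
#'
#' @param counts Named numeric vector of raw counts per gene.
#' @param annotation data.frame: `gene`, `chrom`, `start_bp`, `end_bp`,
#'   `strand` ("+"/"-").
#' @param chrom,center Window chromosome and center (bp).
#' @param half_width Window half-width in bp.
#' @param expressed_min Minimum raw count to call a gene expressed
#'   (default 10).
#' @return data.frame `gene`, `strand`, `start_bp`, `end_bp`, `count`,
#'   `signed_count`, `expressed`; zero rows (not an error) when no gene
#'   overlaps.
#' @export
locus_expression_window <- function(counts, annotation, chrom, center,
                                    half_width, expressed_min = 10) {
  need <- c("gene", "chrom", "start_bp", "end_bp", "strand")
  if (!all(need %in% names(annotation)))
    ccq_stop("annotation needs columns: %s", paste(need, collapse = ", "))
  lo <- center - half_width; hi <- center + half_width
  ann <- annotation[annotation$chrom == chrom &
                      annotation$end_bp >= lo & annotation$start_bp <= hi, ,
                    drop = FALSE]
  if (nrow(ann) == 0)
    return(data.frame(gene = character(0), strand = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      count = numeric(0), signed_count = numeric(0),
                      expressed = logical(0)))
  missing_counts <- setdiff(ann$gene, names(counts))
  if (length(missing_counts) > 0)
    ccq_stop("no counts for gene(s): %s", paste(missing_counts, collapse = ", "))
  cnt <- counts[ann$gene]
  if (any(cnt < 0)) ccq_stop("counts must be >= 0")
  data.frame(gene = ann$gene, strand = ann$strand,
             start_bp = ann$start_bp, end_bp = ann$end_bp,
             count = as.numeric(cnt),
             signed_count = as.numeric(cnt) * ifelse(ann$strand == "-", -1, 1),
             expressed = as.numeric(cnt) >= expressed_min,
             row.names = NULL)
}
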