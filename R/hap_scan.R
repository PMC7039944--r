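#' Genome-wide haplotype association scan
#'
#' At every marker, compares a covariates-only null linear model with a
#' model adding the eight founder-descent probability columns (the
#' WSB/EiJ column dropped for identifiability) on mouse-level data, and
#' reports `logP`, the -log10 P value of the partial F test (7
#' numerator df on a full-rank marker). Founder effect estimates are
#' the full model's probability coefficients, expressed relative to the
#' dropped reference (WSB/EiJ = 0).
#'
#' Rank-deficient markers (e.g. monomorphic descent) get `logP = 0` and
#' a `degenerate` flag; logP is capped (default 50) so perfect fits do
#' not underflow.
#'
#' @param cohort A `cc_cohort`.
#' @param descent A `cc_descent` covering the cohort's lines.
#' @param trait Trait name.
#' @param covariates Covariate names (may be empty).
#' @param cap logP cap (default 50).
#' @return A `scan_result`: data.frame with `chrom`, `pos_bp`, `logP`,
#'   `df_num`, `degenerate`, plus attributes `effects` (markers x 8),
#'   `se`, `covb` (8 x 8 x markers coefficient covariance), `founders`,
#'   `reference`.
#' @export
scan_trait <- function(cohort, descent, trait, covariates = character(0),
                       cap = 50) {
  stopifnot(inherits(cohort, "cc_cohort"), inherits(descent, "cc_descent"))
  if (nrow(descent$map) == 0) ccq_stop("descent has no markers")
  y <- get_trait(cohort, trait)
  ok <- !is.na(y)
  mice <- cohort$mice[ok, , drop = FALSE]
  X <- covariate_design(list(mice = mice), covariates)
  li <- match(as.character(mice$line), descent$lines)
  if (anyNA(li)) ccq_stop("line '%s' missing from descent",
                          mice$line[which(is.na(li))[1]])
  res <- cpp_scan(y[ok], X, descent$probs, as.integer(li - 1L),
                  as.integer(WSB_INDEX - 1L), cap)
  out <- data.frame(chrom = descent$map$chrom, pos_bp = descent$map$pos_bp,
                    logP = as.numeric(res$logP),
                    df_num = as.integer(res$df_num),
                    degenerate = as.logical(res$degenerate))
  colnames(res$effects) <- colnames(res$se) <- descent$founders
  attr(out, "effects") <- res$effects
  attr(out, "se") <- res$se
  attr(out, "covb") <- res$covb
  attr(out, "founders") <- descent$founders
  attr(out, "reference") <- descent$founders[WSB_INDEX]
  attr(out, "trait") <- trait
  attr(out, "cap") <- cap
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Founder effect deviations relative to a reference strain
#'
#' Re-expresses the scan's founder coefficients at one marker as
#' deviations from a reference founder (default WSB/EiJ, the
#' wild-derived baseline), with standard errors from the coefficient
#' covariance. The reference deviation is exactly 0.
#'
#' @param scan A `scan_result`.
#' @param marker Marker row index in the scan.
#' @param reference Reference founder name (default "WSB/EiJ").
#' @return data.frame with `founder`, `deviation`, `se`.
#' @export
founder_effects <- function(scan, marker, reference = "WSB/EiJ") {
  stopifnot(inherits(scan, "scan_result"))
  founders <- attr(scan, "founders")
  ref <- match(reference, founders)
  if (is.na(ref)) ccq_stop("unknown reference founder '%s'", reference)
  if (!is_count(marker) || marker > nrow(scan))
    ccq_stop("marker index out of range")
  if (scan$degenerate[marker])
    ccq_warn("marker %d is degenerate; deviations may be unreliable", marker)
  beta <- attr(scan, "effects")[marker, ]
  C <- attr(scan, "covb")[, , marker]
  dev <- beta - beta[ref]
  v <- diag(C) + C[ref, ref] - 2 * C[, ref]
  se <- sqrt(pmax(v, 0))
  se[ref] <- 0
  data.frame(founder = founders, deviation = unname(dev), se = unname(se),
             row.names = NULL)
}

#' Trait means by marker genotype group
#'
#' Groups mice by their line's genotype at a marker (e.g. "T:T", "C:C",
#' "C:T") and reports per-group trait means; the two homozygote groups
#' are compared with Welch's t test. Groups with fewer than 2 mice are
#' excluded from testing but still reported.
#'
#' @param cohort A `cc_cohort`.
#' @param trait Trait name.
#' @param genotype_at_marker Named character vector: per-line genotype
#'   labels; homozygotes are labels whose two alleles (split on ":")
#'   agree.
#' @return List with `groups` (data.frame: genotype, n_mice, mean) and
#'   `welch` (result of [welch_t_test()] between the homozygote groups,
#'   or NULL if not testable) plus `excluded`.
#' @export
allele_group_means <- function(cohort, trait, genotype_at_marker) {
  y <- get_trait(cohort, trait)
  geno <- genotype_at_marker[as.character(cohort$mice$line)]
  if (anyNA(geno)) ccq_stop("genotype missing for line '%s'",
                            cohort$mice$line[which(is.na(geno))[1]])
  ok <- !is.na(y)
  tab <- data.frame(genotype = names(sort(tapply(y[ok], geno[ok], mean),
                                          decreasing = TRUE)))
  tab$n_mice <- as.integer(table(geno[ok])[tab$genotype])
  tab$mean <- as.numeric(tapply(y[ok], geno[ok], mean)[tab$genotype])
  excluded <- tab$genotype[tab$n_mice < 2]
  testable <- setdiff(tab$genotype, excluded)
  al <- strsplit(testable, ":", fixed = TRUE)
  hom <- testable[vapply(al, function(a) length(a) == 2 && a[1] == a[2] ||
                           length(a) == 1, logical(1))]
  welch <- NULL
  if (length(hom) >= 2) {
    hh <- tab$genotype[tab$genotype %in% hom][1:2]  # two extreme homozygotes
    welch <- welch_t_test(y[ok][geno[ok] == hh[1]], y[ok][geno[ok] == hh[2]])
    welch$groups <- hh
  }
  list(groups = tab, welch = welch, excluded = excluded)
}
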