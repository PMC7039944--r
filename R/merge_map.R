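#' Impute variant dosages through the founder mosaic
#'
#' For each catalogued biallelic variant, the expected alternate-allele
#' dosage of a CC line is imputed from the founder-descent probabilities
#' at the variant's nearest marker:
#' \deqn{d(line, v) = 2 \sum_s P(line, s) \cdot allele_s(v)}
#' so dosages lie in \[0, 2\] (lines are treated as homozygous diploid).
#' Variants outside the marker-map span of their chromosome (or on an
#' unmapped chromosome) are skipped with a warning.
#'
#' @param catalogue A `variant_catalogue` (see
#'   [founder_variant_catalogue()] / [read_variant_catalogue()]).
#' @param descent A `cc_descent`.
#' @return Lines x variants dosage matrix; attributes `variant_rows`
#'   (catalogue rows retained), `nearest_marker` (marker index per
#'   retained variant) and `skipped` (count).
#' @export
impute_dosages <- function(catalogue, descent) {
  stopifnot(inherits(catalogue, "variant_catalogue"),
            inherits(descent, "cc_descent"))
  sdp <- attr(catalogue, "sdp_matrix")
  map <- descent$map
  keep <- integer(0); nm <- integer(0)
  for (v in seq_len(nrow(catalogue))) {
    idx <- which(map$chrom == catalogue$chrom[v])
    if (length(idx) == 0 ||
        catalogue$pos_bp[v] < min(map$pos_bp[idx]) ||
        catalogue$pos_bp[v] > max(map$pos_bp[idx])) next
    keep <- c(keep, v)
    nm <- c(nm, idx[which.min(abs(map$pos_bp[idx] - catalogue$pos_bp[v]))])
  }
  skipped <- nrow(catalogue) - length(keep)
  if (skipped > 0)
    ccq_warn("%d variant(s) outside the marker map span skipped", skipped)
  D <- matrix(0, length(descent$lines), length(keep),
              dimnames = list(descent$lines, NULL))
  for (j in seq_along(keep)) {
    P <- descent_at(descent, nm[j])
    D[, j] <- 2 * as.numeric(P %*% sdp[keep[j], ])
  }
  attr(D, "variant_rows") <- keep
  attr(D, "nearest_marker") <- nm
  attr(D, "skipped") <- skipped
  D
}

#' Merge analysis: variant-dosage association versus the haplotype test
#'
#' For every imputed variant, adds its dosage (one value per line,
#' expanded to mice) to the covariate null model and reports the
#' -log10 P of the 1-df partial F test ("merge logP"), paired with the
#' haplotype-scan logP at the variant's nearest marker. A variant whose
#' merge logP exceeds the local haplotype logP is flagged as a
#' candidate causal variant.
#'
#' @param cohort A `cc_cohort`.
#' @param dosages Dosage matrix from [impute_dosages()].
#' @param trait Trait name.
#' @param covariates Covariate names.
#' @param hap_scan A `scan_result` for the same trait/covariates (for
#'   the local haplotype logP).
#' @param cap logP cap (default 50).
#' @param margin Optional margin: candidate flag requires
#'   `merge_logP > hap_logP + margin` (default 0).
#' @return A `merge_result` data.frame: `chrom`, `pos_bp`, `sdp`,
#'   `merge_logP`, `hap_logP`, `candidate`, `nearest_marker`; attribute
#'   `n_zero_variance` counts dropped constant-dosage variants.
#' @export
merge_scan <- function(cohort, dosages, trait, covariates = character(0),
                       hap_scan, cap = 50, margin = 0) {
  stopifnot(inherits(cohort, "cc_cohort"), inherits(hap_scan, "scan_result"))
  y <- get_trait(cohort, trait)
  ok <- !is.na(y)
  mice <- cohort$mice[ok, , drop = FALSE]
  X <- covariate_design(list(mice = mice), covariates)
  li <- match(as.character(mice$line), rownames(dosages))
  if (anyNA(li)) ccq_stop("line '%s' missing from dosage matrix",
                          mice$line[which(is.na(li))[1]])
  Dm <- dosages[li, , drop = FALSE]          # mouse-level dosages
  qx <- qr(X)
  yres <- qr.resid(qx, y[ok])
  Dres <- qr.resid(qx, Dm)
  rss0 <- sum(yres^2)
  n <- length(yres)
  dd <- colSums(Dres^2)
  zero_var <- dd < 1e-12
  dy <- colSums(Dres * yres)
  rss1 <- pmax(rss0 - ifelse(zero_var, 0, dy^2 / dd), 0)
  df2 <- n - ncol(X) - 1
  Fv <- ((rss0 - rss1) / 1) / (rss1 / df2)
  logP <- ifelse(rss1 <= 1e-14 * rss0, cap,
                 -pf(Fv, 1, df2, lower.tail = FALSE, log.p = TRUE) / log(10))
  logP <- pmin(pmax(logP, 0), cap)
  logP[zero_var] <- NA_real_
  nm <- attr(dosages, "nearest_marker")
  hapP <- hap_scan$logP[nm]
  vr <- attr(dosages, "variant_rows")
  out <- data.frame(
    chrom = hap_scan$chrom[nm], pos_bp = hap_scan$pos_bp[nm],
    variant_row = vr, merge_logP = logP, hap_logP = hapP,
    candidate = !is.na(logP) & logP > hapP + margin,
    nearest_marker = nm)
  if (any(zero_var))
    ccq_warn("%d zero-variance dosage variant(s) dropped from testing",
             sum(zero_var))
  attr(out, "n_zero_variance") <- sum(zero_var)
  class(out) <- c("merge_result", "data.frame")
  out
}

#' Rank genes by their best merge-analysis variant
#'
#' Assigns tested variants inside a genomic window to genes (overlap
#' first, otherwise nearest; a variant equidistant between two genes is
#' assigned to both and flagged ambiguous) and ranks genes by their
#' maximum merge logP.
#'
#' @param merge A `merge_result`.
#' @param window Numeric `c(chrom, start_bp, end_bp)` or a list with
#'   `chrom`, `start_bp`, `end_bp`.
#' @param annotation data.frame of gene intervals: `gene`, `chrom`,
#'   `start_bp`, `end_bp` (1-based closed; see [read_gene_bed()]).
#' @return data.frame ranked by descending `best_merge_logP`: `gene`,
#'   `best_merge_logP`, `n_variants`, `ambiguous`.
#' @export
shortlist_candidates <- function(merge, window, annotation) {
  stopifnot(inherits(merge, "merge_result"))
  if (is.list(window)) window <- c(window$chrom, window$start_bp, window$end_bp)
  if (length(window) != 3 || window[2] > window[3])
    ccq_stop("window must be (chrom, start_bp, end_bp) with start <= end")
  inw <- merge$chrom == window[1] & merge$pos_bp >= window[2] &
    merge$pos_bp <= window[3] & !is.na(merge$merge_logP)
  mv <- merge[inw, , drop = FALSE]
  ann <- annotation[annotation$chrom == window[1], , drop = FALSE]
  if (nrow(mv) == 0 || nrow(ann) == 0)
    return(data.frame(gene = character(0), best_merge_logP = numeric(0),
                      n_variants = integer(0), ambiguous = logical(0)))
  hits <- list()
  for (i in seq_len(nrow(mv))) {
    p <- mv$pos_bp[i]
    ov <- which(ann$start_bp <= p & ann$end_bp >= p)
    amb <- FALSE
    if (length(ov) == 0) {
      dist <- pmax(ann$start_bp - p, p - ann$end_bp, 0)
      ov <- which(dist == min(dist))
      amb <- length(ov) > 1
    }
    hits[[i]] <- data.frame(gene = ann$gene[ov], logP = mv$merge_logP[i],
                            ambiguous = amb)
  }
  h <- do.call(rbind, hits)
  agg <- do.call(rbind, lapply(split(h, h$gene), function(g) data.frame(
    gene = g$gene[1], best_merge_logP = max(g$logP), n_variants = nrow(g),
    ambiguous = any(g$ambiguous))))
  agg <- agg[order(-agg$best_merge_logP, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
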