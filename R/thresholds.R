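#' Permutation genome-wide significance thresholds
#'
#' Builds the empirical null distribution of the genome-wide maximum
#' logP by permuting the assignment of line genotypes (descent
#' probability rows) to lines: every mouse keeps its line-mates,
#' covariates and phenotype, and each line's haplotype mosaic is handed
#' to another line. Each permutation rescans the whole genome; the 95th
#' and 99th percentiles of the per-permutation maxima are the
#' genome-wide cut-offs (200 permutations by default).
#'
#' @inheritParams scan_trait
#' @param n_sim Number of permutations (>= 20; default 200).
#' @param seed Integer seed; the same seed reproduces the thresholds.
#' @param percentiles Percentiles to report (default 95 and 99).
#' @return A `threshold_set`: list with `cutoffs` (named by percentile),
#'   `n_sim` and the raw `maxima`.
#' @export
genome_thresholds <- function(cohort, descent, trait,
                              covariates = character(0), n_sim = 200,
                              seed = NULL, percentiles = c(95, 99),
                              cap = 50) {
  stopifnot(inherits(cohort, "cc_cohort"), inherits(descent, "cc_descent"))
  if (!is_count(n_sim, min = 20L)) ccq_stop("n_sim must be an integer >= 20")
  if (any(percentiles <= 0 | percentiles >= 100))
    ccq_stop("percentiles must lie in (0, 100)")
  n_lines <- length(descent$lines)
  if (n_lines < 5)
    ccq_stop("refusing to permute %d lines: permutation space too small",
             n_lines)
  y <- get_trait(cohort, trait)
  ok <- !is.na(y)
  mice <- cohort$mice[ok, , drop = FALSE]
  X <- covariate_design(list(mice = mice), covariates)
  li <- match(as.character(mice$line), descent$lines)
  maxima <- with_seed(seed, {
    perms <- t(vapply(seq_len(n_sim), function(i) sample.int(n_lines),
                      integer(n_lines)))
    cpp_perm_max(y[ok], X, descent$probs, as.integer(li - 1L),
                 perms - 1L, as.integer(WSB_INDEX - 1L), cap)
  })
  # type-6 empirical percentile: the probability that a fresh null scan
  # exceeds the estimated cut-off matches the nominal level
  cutoffs <- quantile(maxima, percentiles / 100, names = FALSE, type = 6)
  structure(list(cutoffs = setNames(cutoffs, as.character(percentiles)),
                 n_sim = n_sim, maxima = as.numeric(maxima)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("genome-wide thresholds (%d permutations): %s\n", x$n_sim,
              paste(sprintf("%s%% = %.2f", names(x$cutoffs), x$cutoffs),
                    collapse = ", ")))
  invisible(x)
}

#' Call QTLs from a scan against a genome-wide threshold
#'
#' Collapses each contiguous run of super-threshold markers on a
#' chromosome to a single call at its maximum-logP marker (ties broken
#' by leftmost position). Runs separated by less than `merge_gap_bp`
#' (default 2 Mb) are merged into one call, so a locus is reported as a
#' single peak.
#'
#' @param scan A `scan_result`.
#' @param thresholds A `threshold_set`.
#' @param percentile Which cut-off to use: 95 or 99 (default 99, the
#'   level at which loci are taken forward).
#' @param merge_gap_bp Sub-threshold gap below which adjacent runs are
#'   merged (default 2e6).
#' @return A `qtl_call` data.frame: `trait`, `chrom`, `peak_pos_bp`,
#'   `peak_logP`, `threshold`, `percentile`, `start_bp`, `end_bp` (the
#'   super-threshold run bounds). Zero rows when nothing exceeds the
#'   cut-off.
#' @export
call_qtls <- function(scan, thresholds, percentile = 99,
                      merge_gap_bp = 2e6) {
  stopifnot(inherits(scan, "scan_result"), inherits(thresholds, "threshold_set"))
  pc <- as.character(percentile)
  if (!pc %in% names(thresholds$cutoffs))
    ccq_stop("no %s%% cut-off in the threshold set", pc)
  cutoff <- thresholds$cutoffs[[pc]]
  calls <- list()
  for (cc in unique(scan$chrom)) {
    sc <- scan[scan$chrom == cc, , drop = FALSE]
    sup <- which(sc$logP >= cutoff)
    if (length(sup) == 0) next
    # contiguous runs of super-threshold markers
    runs <- split(sup, cumsum(c(1, diff(sup) != 1)))
    # merge runs whose bp gap is below merge_gap_bp
    merged <- list(runs[[1]])
    if (length(runs) > 1) for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      gap <- sc$pos_bp[r[1]] - sc$pos_bp[last[length(last)]]
      if (gap < merge_gap_bp) merged[[length(merged)]] <- c(last, r)
      else merged[[length(merged) + 1]] <- r
    }
    for (r in merged) {
      peak <- r[which.max(sc$logP[r])]   # which.max: leftmost tie
      calls[[length(calls) + 1]] <- data.frame(
        trait = attr(scan, "trait") %||% NA_character_,
        chrom = cc, peak_pos_bp = sc$pos_bp[peak],
        peak_logP = sc$logP[peak], threshold = cutoff,
        percentile = as.numeric(percentile),
        start_bp = sc$pos_bp[r[1]], end_bp = sc$pos_bp[r[length(r)]])
    }
  }
  out <- if (length(calls) == 0) data.frame(
    trait = character(0), chrom = integer(0), peak_pos_bp = numeric(0),
    peak_logP = numeric(0), threshold = numeric(0), percentile = numeric(0),
    start_bp = numeric(0), end_bp = numeric(0)) else do.call(rbind, calls)
  class(out) <- c("qtl_call", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regional heritability at a locus
#'
#' Fraction of (covariate-adjusted) line-mean variance explained by
#' founder descent at one marker:
#' `H2_r = (RSS_null - RSS_genetic) / RSS_null`, where the genetic fit
#' regresses line means on the descent probability matrix at the
#' marker, clipped to \[0, 1\].
#'
#' @inheritParams scan_trait
#' @param marker Marker row index on the descent map.
#' @return Numeric scalar in \[0, 1\].
#' @export
regional_h2 <- function(cohort, descent, trait, covariates = character(0),
                        marker) {
  stopifnot(inherits(cohort, "cc_cohort"), inherits(descent, "cc_descent"))
  if (!is_count(marker) || marker > nrow(descent$map))
    ccq_stop("marker index out of range")
  y <- get_trait(cohort, trait)
  ok <- !is.na(y)
  mice <- cohort$mice[ok, , drop = FALSE]
  X <- covariate_design(list(mice = mice), covariates)
  yadj <- lm.fit(X, y[ok])$residuals + mean(y[ok])
  lm_means <- tapply(yadj, as.character(mice$line), mean)
  lines_present <- names(lm_means)
  P <- descent_at(descent, marker)[match(lines_present, descent$lines), ,
                                   drop = FALSE]
  ybar <- as.numeric(lm_means)
  rss_null <- sum((ybar - mean(ybar))^2)
  if (rss_null == 0) return(0)
  Z <- cbind(1, P[, -WSB_INDEX, drop = FALSE])
  fit <- lm.fit(Z, ybar)
  h2r <- (rss_null - sum(fit$residuals^2)) / rss_null
  min(max(h2r, 0), 1)
}
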