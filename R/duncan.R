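#' Duncan's multiple range test (least significance ranges)
#'
#' Groups line means into letter groups that are not separable under
#' Duncan's multiple range procedure. Means are sorted in descending
#' order; the least significant range for a span of `p` means uses the
#' studentized range quantile at Duncan's protection level
#' `1 - (1 - alpha)^(p - 1)`:
#' \deqn{LSR_p = q_{(1-\alpha)^{p-1}, p, df} \sqrt{MSE / n_h}}
#' with `n_h` the harmonic mean of the per-line replicate counts. A
#' range is declared non-significant if its extremes differ by at most
#' its LSR, or if it is contained in a larger non-significant range
#' (the standard protection rule); maximal non-significant runs share a
#' letter, and letters are ordered by descending group mean.
#'
#' @param line_means Named numeric vector of per-line means.
#' @param mse Residual mean square from the underlying ANOVA (> 0).
#' @param df_error Residual degrees of freedom (> 0).
#' @param reps Per-line replicate counts (scalar or named vector
#'   aligned with `line_means`); unbalanced counts enter through their
#'   harmonic mean.
#' @param alpha Significance level per comparison (default 0.001).
#' @return List of class `lsr_grouping`: `table` (data.frame with
#'   `line`, `mean`, `group` letters, sorted by descending mean),
#'   `alpha`, `lsr` (the per-span least significant ranges).
#' @export
duncan_lsr <- function(line_means, mse, df_error, reps, alpha = 0.001) {
  if (!is.finite(mse) || mse <= 0) ccq_stop("mse must be > 0")
  if (!is.finite(df_error) || df_error <= 0) ccq_stop("df_error must be > 0")
  if (alpha <= 0 || alpha >= 1) ccq_stop("alpha must be in (0, 1)")
  k <- length(line_means)
  if (k < 1) ccq_stop("need at least one mean")
  if (length(reps) == 1) reps <- rep(reps, k)
  if (length(reps) != k) ccq_stop("reps must be scalar or match line_means")
  n_h <- k / sum(1 / reps)
  se <- sqrt(mse / n_h)
  ord <- order(line_means, decreasing = TRUE)
  m <- line_means[ord]
  lsr <- if (k >= 2)
    vapply(2:k, function(p) qtukey((1 - alpha)^(p - 1), p, df_error) * se,
           numeric(1)) else numeric(0)
  # raw non-significance of range (i, j) in sorted order
  raw <- matrix(TRUE, k, k)
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k)
    raw[i, j] <- (m[i] - m[j]) <= lsr[j - i]
  # protection closure: non-significant if contained in a larger
  # non-significant range
  C <- raw
  if (k >= 2) for (i in 1:k) for (j in k:i) {
    if (i > 1) C[i, j] <- C[i, j] || C[i - 1, j]
    if (j < k) C[i, j] <- C[i, j] || C[i, j + 1]
  }
  # maximal non-separable runs -> letters
  e <- vapply(1:k, function(i) max(which(C[i, i:k]) + i - 1L), integer(1))
  starts <- which(c(TRUE, diff(e) > 0))
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lab <- character(k)
  for (g in seq_along(starts)) {
    i <- starts[g]; j <- e[i]
    lab[i:j] <- paste0(lab[i:j], letters_pool[g])
  }
  tab <- data.frame(line = names(m), mean = unname(m), group = lab,
                    row.names = NULL)
  structure(list(table = tab, alpha = alpha, lsr = lsr, n_h = n_h),
            class = "lsr_grouping")
}

#' @export
print.lsr_grouping <- function(x, ...) {
  cat(sprintf("Duncan LSR grouping (alpha = %g): %d group letter(s)\n",
              x$alpha, length(unique(unlist(strsplit(x$table$group, ""))))))
  print(x$table)
  invisible(x)
}

#' Duncan grouping straight from a cohort
#'
#' Convenience wrapper: computes line means, the residual mean square
#' and degrees of freedom from the one-way (line) ANOVA of `trait`,
#' then calls [duncan_lsr()].
#'
#' @inheritParams broad_sense_h2
#' @param alpha Significance level (default 0.001, the level used for
#'   trait-by-line heterogeneity displays).
#' @return An `lsr_grouping`.
#' @export
duncan_grouping <- function(cohort, trait, alpha = 0.001) {
  y <- get_trait(cohort, trait)
  ok <- !is.na(y)
  line <- factor(as.character(cohort$mice$line)[ok])
  y <- y[ok]
  fit <- lm(y ~ line)
  mse <- sum(resid(fit)^2) / fit$df.residual
  means <- tapply(y, line, mean)
  duncan_lsr(setNames(as.numeric(means), names(means)), mse,
             fit$df.residual, as.numeric(table(line)), alpha)
}
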