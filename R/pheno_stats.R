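#' Min / max / mean of a trait over mice
#'
#' @param cohort A `cc_cohort`.
#' @param trait Trait column name.
#' @return Named numeric vector `(min, max, mean)` over non-missing
#'   mouse-level values.
#' @export
trait_summary <- function(cohort, trait) {
  y <- get_trait(cohort, trait)
  y <- y[!is.na(y)]
  c(min = min(y), max = max(y), mean = mean(y))
}

#' Pairwise Pearson correlations between traits
#'
#' Mouse-level Pearson correlation matrix. Pairs with fewer than 3
#' complete observations or a zero-variance member are flagged
#' (returned as NA and listed in the `undefined` attribute) rather than
#' silently propagated.
#'
#' @param cohort A `cc_cohort`.
#' @param traits Character vector of trait names (>= 2).
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `undefined` lists flagged pairs.
#' @export
pairwise_trait_correlation <- function(cohort, traits = colnames(cohort$traits)) {
  stopifnot(length(traits) >= 2)
  X <- cohort$traits[, traits, drop = FALSE]
  k <- ncol(X)
  r <- diag(1, k)
  dimnames(r) <- list(traits, traits)
  undef <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- complete.cases(X[, i], X[, j])
    if (sum(ok) < 3 || sd(X[ok, i]) == 0 || sd(X[ok, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      undef <- c(undef, paste(traits[i], traits[j], sep = ":"))
    } else {
      r[i, j] <- r[j, i] <- cor(X[ok, i], X[ok, j])
    }
  }
  if (length(undef) > 0)
    ccq_warn("undefined correlation for pair(s): %s", paste(undef, collapse = ", "))
  attr(r, "undefined") <- undef
  r
}

#' Multi-way covariate ANOVA with optional pairwise interactions
#'
#' Fits the trait on the listed covariates (type-II sums of squares,
#' appropriate for unbalanced nuisance factors) and reports per-covariate
#' P-values. With `with_interactions`, all pairwise interactions are
#' added and their cumulative sum of squares is expressed as a
#' percentage of the total sum of squares.
#'
#' Covariates aliased with earlier ones (confounded levels) are dropped
#' with a warning and reported.
#'
#' @param cohort A `cc_cohort`.
#' @param trait Trait name.
#' @param covariates Covariate column names (each needs >= 2 observed
#'   levels).
#' @param with_interactions Include pairwise interaction terms.
#' @return List with `p_values` (named, main effects),
#'   `interaction_percent` (NA unless requested), `dropped` (aliased
#'   covariates removed) and the fitted `model`.
#' @export
covariate_anova <- function(cohort, trait, covariates,
                            with_interactions = FALSE) {
  y <- get_trait(cohort, trait)
  df <- cohort$mice[, covariates, drop = FALSE]
  for (v in covariates) df[[v]] <- factor(df[[v]])
  keep <- vapply(covariates, function(v) nlevels(droplevels(df[!is.na(y), v])) >= 2,
                 logical(1))
  if (!all(keep))
    ccq_stop("covariate(s) with <2 observed levels: %s",
             paste(covariates[!keep], collapse = ", "))
  # drop covariates aliased with earlier ones
  dropped <- character(0)
  kept <- character(0)
  for (v in covariates) {
    trial <- c(kept, v)
    X <- model.matrix(as.formula(paste("~", paste(sprintf("`%s`", trial),
                                                  collapse = "+"))), df)
    if (qr(X)$rank < ncol(X)) dropped <- c(dropped, v) else kept <- trial
  }
  if (length(dropped) > 0)
    ccq_warn("aliased covariate(s) dropped: %s", paste(dropped, collapse = ", "))
  df$.y <- y
  main <- paste(sprintf("`%s`", kept), collapse = " + ")
  form <- if (with_interactions && length(kept) >= 2)
    as.formula(paste(".y ~ (", main, ")^2")) else
    as.formula(paste(".y ~", main))
  fit <- lm(form, data = df)
  a2 <- car::Anova(fit, type = 2, singular.ok = TRUE)
  tab <- as.data.frame(a2)
  term <- rownames(tab)
  is_main <- term %in% sprintf("`%s`", kept) | term %in% kept
  pv <- setNames(tab[is_main, "Pr(>F)"], gsub("`", "", term[is_main]))
  interaction_percent <- NA_real_
  if (with_interactions) {
    is_int <- grepl(":", term, fixed = TRUE)
    ss_int <- sum(tab[is_int, "Sum Sq"], na.rm = TRUE)
    ss_tot <- sum((y - mean(y, na.rm = TRUE))^2, na.rm = TRUE)
    interaction_percent <- 100 * ss_int / ss_tot
  }
  list(p_values = pv, interaction_percent = interaction_percent,
       dropped = dropped, model = fit)
}

#' Broad-sense heritability from replicated CC lines
#'
#' Compares a covariates-only null model with a covariates-plus-line
#' model on mouse-level data. `logP` is -log10 of the partial F test of
#' the line factor. H2 is the expected-mean-squares variance-component
#' estimate
#' \deqn{H^2 = (MS_{line} - MS_{resid}) / (MS_{line} + (n_0 - 1) MS_{resid})}
#' with the unbalanced-design effective replicate number
#' \eqn{n_0 = (N - \sum n_i^2 / N) / (k - 1)}, clipped to \[0, 1\].
#'
#' @param cohort A `cc_cohort`.
#' @param trait Trait name.
#' @param covariates Covariate names for the null model (may be empty).
#' @return List of class `heritability_result`: `H2`, `logP`, `H2n`
#'   (line-mean heritability at the observed mean replication), `n_bar`,
#'   `n0`, `F`, `df`.
#' @export
broad_sense_h2 <- function(cohort, trait, covariates = character(0)) {
  y <- get_trait(cohort, trait)
  ok <- !is.na(y)
  y <- y[ok]
  line <- factor(as.character(cohort$mice$line)[ok])
  ni <- table(line)
  if (sum(ni >= 2) < 2)
    ccq_stop("H2 undefined: need >=2 lines with >=2 mice")
  X <- covariate_design(list(mice = cohort$mice[ok, , drop = FALSE]), covariates)
  k <- nlevels(line)
  N <- length(y)
  fit0 <- lm.fit(X, y)
  Xl <- cbind(X, model.matrix(~ line)[, -1, drop = FALSE])
  fit1 <- lm.fit(Xl, y)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  df_line <- fit1$rank - fit0$rank
  df_res <- N - fit1$rank
  Fstat <- ((rss0 - rss1) / df_line) / (rss1 / df_res)
  logP <- -pf(Fstat, df_line, df_res, lower.tail = FALSE, log.p = TRUE) / log(10)
  ms_line <- (rss0 - rss1) / df_line
  ms_res <- rss1 / df_res
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  H2 <- (ms_line - ms_res) / (ms_line + (n0 - 1) * ms_res)
  H2 <- min(max(H2, 0), 1)
  n_bar <- N / k
  structure(list(H2 = H2, logP = logP, H2n = line_mean_h2(H2, n_bar),
                 n_bar = n_bar, n0 = n0, F = Fstat,
                 df = c(df_line, df_res)),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("H2 = %.3f (logP = %.2f), H2n = %.3f at n_bar = %.2f\n",
              x$H2, x$logP, x$H2n, x$n_bar))
  invisible(x)
}

#' Line-mean heritability
#'
#' Heritability of line means given an average of `n_bar` replicates per
#' line: `H2n = H2 / (H2 + (1 - H2) / n_bar)`.
#'
#' @param H2 Broad-sense heritability in \[0, 1\].
#' @param n_bar Mean replicates per line (>= 1).
#' @return Line-mean heritability in \[0, 1\].
#' @export
line_mean_h2 <- function(H2, n_bar) {
  if (any(H2 < 0 | H2 > 1)) ccq_stop("H2 must be in [0, 1]")
  if (any(n_bar < 1)) ccq_stop("n_bar must be >= 1")
  H2 / (H2 + (1 - H2) / n_bar)
}

#' Benjamini-Hochberg FDR adjustment with rejection flags
#'
#' Step-up BH adjusted P values (via [stats::p.adjust()]) and the
#' rejection set at FDR level `q`.
#'
#' @param pvalues Numeric vector in \[0, 1\]; may be empty.
#' @param q FDR level (default 0.01).
#' @return List with `adjusted` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.01) {
  if (length(pvalues) == 0)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    ccq_stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom (two-sided).
#' If both groups are constant and equal, P = 1 is returned with a
#' `degenerate` flag rather than NaN.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 finite values.
#' @return List with `t`, `df`, `p_value`, `degenerate`.
#' @export
welch_t_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    ccq_stop("each group needs >= 2 finite values")
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p_value = 1, degenerate = TRUE))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p_value = 0, degenerate = TRUE))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}
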