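# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation functions are deterministic without
# clobbering the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# stop() with a consistent prefix and no call noise
ccq_stop <- function(...) stop(sprintf(...), call. = FALSE)
ccq_warn <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}

# Build the covariate design matrix (with intercept) for a cohort,
# dropping aliased columns so downstream QR/SVD code sees full rank.
covariate_design <- function(cohort, covariates) {
  mice <- cohort$mice
  if (length(covariates) == 0) {
    X <- matrix(1, nrow(mice), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  missing_cov <- setdiff(covariates, names(mice))
  if (length(missing_cov) > 0)
    ccq_stop("unknown covariate(s): %s", paste(missing_cov, collapse = ", "))
  df <- mice[, covariates, drop = FALSE]
  for (v in covariates) {
    if (!is.numeric(df[[v]])) df[[v]] <- factor(df[[v]])
    else if (v %in% c("batch", "month", "year")) df[[v]] <- factor(df[[v]])
  }
  X <- model.matrix(as.formula(paste("~", paste(sprintf("`%s`", covariates),
                                                collapse = "+"))), data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

get_trait <- function(cohort, trait) {
  if (!trait %in% colnames(cohort$traits))
    ccq_stop("trait '%s' not found in cohort", trait)
  y <- cohort$traits[, trait]
  if (all(is.na(y))) ccq_stop("trait '%s' has no observations", trait)
  y
}

# Map each mouse to its line's row index in `lines`
line_index <- function(cohort, lines) {
  idx <- match(cohort$mice$line, lines)
  if (anyNA(idx)) ccq_stop("mouse assigned to unknown line '%s'",
                           cohort$mice$line[which(is.na(idx))[1]])
  idx
}
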