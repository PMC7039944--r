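# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# A small standard panel + descent reused by many tests.
fix_panel <- function(seed = 7, n_chrom = 2, n_markers = 100) {
  simulate_founder_panel(n_chrom, n_markers, c(0.1, 0.4), seed = seed)
}

fix_descent <- function(panel = fix_panel(), n_lines = 34, seed = 3,
                        sharpness = 0.95, het = 0.15) {
  simulate_cc_lines(panel, n_lines, 8, het, sharpness, seed = seed)$descent
}

# Hand-built tiny descent object: n_lines x 8 probabilities at given markers.
# prob_list: list of (n_lines x 8) matrices, one per marker.
manual_descent <- function(prob_list, chrom = 1,
                           pos = seq_along(prob_list) * 1e6) {
  L <- nrow(prob_list[[1]])
  lines <- sprintf("CC%03d", seq_len(L))
  probs <- array(0, dim = c(L, 8, length(prob_list)),
                 dimnames = list(lines, CC_FOUNDERS, NULL))
  for (m in seq_along(prob_list)) probs[, , m] <- prob_list[[m]]
  structure(list(probs = probs,
                 map = data.frame(chrom = rep(chrom, length(prob_list)),
                                  pos_bp = pos),
                 founders = CC_FOUNDERS, lines = lines),
            class = "cc_descent")
}

# Minimal cohort from a vector of line assignments + trait values.
manual_cohort <- function(line, y, trait = "BV/TV", extra = NULL) {
  mice <- data.frame(mouse_id = sprintf("M%03d", seq_along(line)),
                     line = line)
  if (!is.null(extra)) mice <- cbind(mice, extra)
  cc_cohort(mice, matrix(y, ncol = 1, dimnames = list(NULL, trait)))
}

# Independent brute-force haplotype-scan logP: plain lm() + partial F via
# anova(), no shared code with the scan core.
oracle_scan_logP <- function(cohort, descent, trait, covariates = character(0),
                             cap = 50) {
  y <- cohort$traits[, trait]
  li <- match(as.character(cohort$mice$line), descent$lines)
  vapply(seq_len(nrow(descent$map)), function(m) {
    P <- descent$probs[, , m][li, -8, drop = FALSE]
    colnames(P) <- paste0("f", 1:7)
    df <- data.frame(y = y, P, check.names = FALSE)
    for (v in covariates) df[[v]] <- factor(cohort$mice[[v]])
    f0 <- if (length(covariates))
      as.formula(paste("y ~", paste(covariates, collapse = "+"))) else y ~ 1
    f1 <- update.formula(f0, paste(". ~ . +", paste0("f", 1:7, collapse = "+")))
    a <- anova(lm(f0, df), lm(f1, df))
    p <- pf(a$F[2], a$Df[2], a$Res.Df[2], lower.tail = FALSE, log.p = TRUE)
    min(-p / log(10), cap)
  }, numeric(1))
}

# Brute-force BH: adjusted p_i = min over the upper tail of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m))
    adj[o[i]] <- min(1, min(sorted[i:m] * m / (i:m)))
  adj
}

# Brute-force Duncan grouping: recompute raw range significances, apply the
# containment protection rule by exhaustive enumeration, and enumerate
# maximal non-significant intervals.
oracle_duncan_groups <- function(means, mse, df_error, reps, alpha) {
  k <- length(means)
  n_h <- k / sum(1 / rep(reps, length.out = k))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  raw <- matrix(TRUE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    p <- j - i + 1
    lsr <- qtukey((1 - alpha)^(p - 1), p, df_error) * sqrt(mse / n_h)
    raw[i, j] <- (m[i] - m[j]) <= lsr
  }
  nonsig <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in i:k)
    for (a in 1:i) for (b in j:k)
      if (raw[a, b]) nonsig[i, j] <- TRUE
  # maximal intervals
  iv <- list()
  for (i in seq_len(k)) {
    j <- max(which(nonsig[i, i:k]) + i - 1L)
    iv[[i]] <- c(i, j)
  }
  keep <- vapply(seq_len(k), function(i) {
    !any(vapply(seq_len(k)[-i], function(i2)
      iv[[i2]][1] <= iv[[i]][1] && iv[[i2]][2] >= iv[[i]][2] &&
        !identical(iv[[i2]], iv[[i]]), logical(1)))
  }, logical(1))
  # de-duplicate
  ivk <- unique(iv[keep])
  # return membership matrix: line (sorted order) x group
  sapply(ivk, function(r) seq_len(k) >= r[1] & seq_len(k) <= r[2])
}

# Group membership matrix from an lsr_grouping (sorted order), for
# comparison with the oracle irrespective of letter naming.
grouping_membership <- function(g) {
  letters_used <- sort(unique(unlist(strsplit(g$table$group, ""))))
  sapply(letters_used, function(L) grepl(L, g$table$group, fixed = TRUE))
}
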