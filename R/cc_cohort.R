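#' Construct a CC cohort object
#'
#' Bundles the mouse table (line membership and covariates) with the
#' mouse-by-trait matrix. Validates that every mouse belongs to a line,
#' that every line has at least one mouse, and that recorded trait
#' values are finite (missing values are allowed and counted).
#'
#' @param mice data.frame with at least `mouse_id` and `line`; covariate
#'   columns (`sex`, `age_weeks`, `batch`, `month`, `season`, `year`,
#'   `experimenter`) are free-form.
#' @param traits Numeric matrix (mice x traits) with column names.
#' @return A `cc_cohort` list: `mice`, `traits`, `lines`.
#' @export
cc_cohort <- function(mice, traits) {
  stopifnot(is.data.frame(mice), !is.null(mice$line), !is.null(mice$mouse_id))
  if (anyDuplicated(mice$mouse_id))
    ccq_stop("duplicate mouse_id: %s",
             mice$mouse_id[anyDuplicated(mice$mouse_id)])
  traits <- as.matrix(traits)
  if (nrow(traits) != nrow(mice))
    ccq_stop("traits has %d rows but mice has %d", nrow(traits), nrow(mice))
  if (any(is.infinite(traits))) ccq_stop("trait values must be finite")
  structure(list(mice = mice, traits = traits,
                 lines = sort(unique(as.character(mice$line)))),
            class = "cc_cohort")
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("cc_cohort: %d mice in %d lines; traits: %s\n",
              nrow(x$mice), length(x$lines),
              paste(colnames(x$traits), collapse = ", ")))
  invisible(x)
}

#' Generate a replicated cohort design with covariates
#'
#' Produces the mouse table for a simulated cohort: `replicates` mice
#' per line with sex (~60% male, as in typical CC husbandry cohorts),
#' age 9-13 weeks, and batch / month / season / year / experimenter
#' drawn as categorical nuisance factors.
#'
#' @param lines Character vector of line labels (e.g. from
#'   [simulate_cc_lines()]).
#' @param replicates Mice per line (default 5, the panel average).
#' @param seed Integer seed.
#' @return data.frame with columns `mouse_id`, `line`, `sex`,
#'   `age_weeks`, `batch`, `month`, `season`, `year`, `experimenter`.
#' @export
cohort_design <- function(lines, replicates = 5, seed = NULL) {
  if (!is_count(replicates)) ccq_stop("replicates must be a positive integer")
  with_seed(seed, {
    n <- length(lines) * replicates
    month <- sample.int(12, n, replace = TRUE)
    season <- c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
                "Summer", "Summer", "Autumn", "Autumn", "Autumn", "Winter")[month]
    data.frame(
      mouse_id = sprintf("M%04d", seq_len(n)),
      line = rep(lines, each = replicates),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(71, 103) / 174),
      age_weeks = sample(9:13, n, replace = TRUE),
      batch = sample.int(6, n, replace = TRUE),
      month = month,
      season = season,
      year = sample(2013:2014, n, replace = TRUE),
      experimenter = sample(c("E1", "E2"), n, replace = TRUE)
    )
  })
}

#' Specify a planted QTL
#'
#' @param chrom Chromosome id.
#' @param pos_bp Position in bp (1-based); snapped to the nearest mapped
#'   marker with a warning if not on the map.
#' @param mode `"haplotype"` (effect carried by founder haplotype
#'   groups) or `"variant"` (effect carried by a biallelic variant).
#' @param founder_effects Numeric length-8 additive effects in canonical
#'   founder order (haplotype mode).
#' @param sdp Length-8 0/1 strain distribution pattern (variant mode);
#'   must not be monomorphic.
#' @param effect Per-dosage effect size (variant mode).
#' @param variance_explained Target fraction of line-mean variance
#'   attributable to this QTL, in \[0, 1); effects are rescaled to hit
#'   it. `NULL` uses the stated effects literally.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chrom, pos_bp, mode = c("haplotype", "variant"),
                     founder_effects = NULL, sdp = NULL, effect = 1,
                     variance_explained = NULL) {
  mode <- match.arg(mode)
  if (!is.null(variance_explained) &&
      (variance_explained < 0 || variance_explained >= 1))
    ccq_stop("variance_explained must be in [0, 1)")
  if (mode == "haplotype") {
    if (length(founder_effects) != 8)
      ccq_stop("haplotype mode needs 8 founder effects")
  } else {
    if (length(sdp) != 8 || !all(sdp %in% c(0, 1)))
      ccq_stop("variant mode needs a length-8 0/1 SDP")
    if (sum(sdp) %in% c(0, 8)) ccq_stop("SDP must not be monomorphic")
  }
  structure(list(chrom = chrom, pos_bp = pos_bp, mode = mode,
                 founder_effects = founder_effects, sdp = sdp,
                 effect = effect, variance_explained = variance_explained),
            class = "qtl_spec")
}

#' Simulate replicated phenotypes over a CC cohort
#'
#' Trait model for mouse j of line i:
#' \deqn{y_{ij} = \mu + covariates + \sum_q QTL_q(i) + g_i + e_{ij}}
#' with line effects \eqn{g_i \sim N(0, \sigma^2_L)} and residuals
#' \eqn{e_{ij} \sim N(0, \sigma^2_E)} scaled so that
#' \eqn{\sigma^2_L / (\sigma^2_L + \sigma^2_E) = } `h2_line` on the
#' single-mouse scale and \eqn{\sigma^2_L + \sigma^2_E = } `var_total`.
#' A haplotype QTL contributes \eqn{\sum_s p_{is} \beta_s} (additive in
#' the descent probabilities at its marker); a variant QTL contributes
#' `effect` times the imputed dosage. When a QTL states
#' `variance_explained`, its effects are rescaled so its line-level
#' variance equals that fraction of the line-mean variance
#' \eqn{\sigma^2_L + \sigma^2_E/\bar n}; the polygenic line variance is
#' reduced accordingly (planted QTL variance may not exceed
#' \eqn{\sigma^2_L}).
#'
#' `h2_line = 1` with a single literal-effect QTL gives the noiseless
#' limit in which each line's value is an exact function of its founder
#' descent.
#'
#' @param design Mouse table from [cohort_design()] (or equivalent).
#' @param descent A `cc_descent` covering every line in `design`.
#' @param qtls List of [qtl_spec()] objects (may be empty).
#' @param h2_line Broad-sense heritability on the single-mouse scale,
#'   in \[0, 1\].
#' @param covariate_effects Named list of additive level shifts, e.g.
#'   `list(sex = c(F = 0, M = 1.5))`.
#' @param seed Integer seed.
#' @param trait Trait name (default "BV/TV").
#' @param mu Trait grand mean (default 10.2, the panel BV/TV mean in %).
#' @param var_total Total single-mouse variance
#'   \eqn{\sigma^2_L + \sigma^2_E} (default 25, i.e. SD 5% BV/TV).
#' @return A `cc_cohort` with one trait column and attribute
#'   `qtl_truth`: per QTL, the marker index, realized (rescaled) founder
#'   effects, and per-line genetic values.
#' @export
simulate_phenotypes <- function(design, descent, qtls = list(),
                                h2_line = 0.6, covariate_effects = list(),
                                seed = NULL, trait = "BV/TV",
                                mu = 10.2, var_total = 25) {
  stopifnot(inherits(descent, "cc_descent"))
  if (h2_line < 0 || h2_line > 1) ccq_stop("h2_line must be in [0, 1]")
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  li <- match(as.character(design$line), descent$lines)
  if (anyNA(li)) ccq_stop("design references line '%s' absent from descent",
                          design$line[which(is.na(li))[1]])
  n <- nrow(design)
  n_lines <- length(descent$lines)
  n_bar <- n / n_lines
  s2L <- h2_line * var_total
  s2E <- (1 - h2_line) * var_total
  V_lm <- s2L + s2E / n_bar

  with_seed(seed, {
    y <- rep(mu, n)
    # covariate shifts
    for (v in names(covariate_effects)) {
      if (!v %in% names(design)) ccq_stop("covariate '%s' not in design", v)
      sh <- covariate_effects[[v]]
      lev <- as.character(design[[v]])
      if (!all(lev %in% names(sh)))
        ccq_stop("covariate_effects$%s misses level '%s'", v,
                 setdiff(lev, names(sh))[1])
      y <- y + unname(sh[lev])
    }
    # planted QTLs on the line scale
    truth <- list()
    ve_total <- 0
    q_line_total <- numeric(n_lines)
    for (k in seq_along(qtls)) {
      q <- qtls[[k]]
      m <- nearest_marker(descent$map, q$chrom, q$pos_bp)
      if (is.na(m)) ccq_stop("QTL chromosome %s not on the marker map", q$chrom)
      if (descent$map$pos_bp[m] != q$pos_bp || descent$map$chrom[m] != q$chrom)
        ccq_warn("QTL at %s:%d snapped to nearest marker %s:%d",
                 q$chrom, q$pos_bp, descent$map$chrom[m], descent$map$pos_bp[m])
      P <- descent_at(descent, m)
      if (q$mode == "haplotype") {
        beta <- q$founder_effects
        q_line <- as.numeric(P %*% beta)
      } else {
        beta <- 2 * q$effect * q$sdp   # per-founder contribution to dosage effect
        q_line <- as.numeric(P %*% q$sdp) * 2 * q$effect
      }
      scale <- 1
      if (!is.null(q$variance_explained)) {
        sdq <- sd(q_line)
        if (sdq == 0) {
          ccq_warn("planted QTL %d has zero line-level variance; skipped", k)
          next
        }
        scale <- sqrt(q$variance_explained * V_lm) / sdq
        q_line <- (q_line - mean(q_line)) * scale
        ve_total <- ve_total + q$variance_explained
      }
      q_line_total <- q_line_total + q_line
      truth[[k]] <- list(marker = m, chrom = descent$map$chrom[m],
                         pos_bp = descent$map$pos_bp[m], mode = q$mode,
                         founder_effects = beta * scale, line_values = q_line)
    }
    if (ve_total * V_lm > s2L + 1e-12)
      ccq_stop("planted QTL variance (%.3g) exceeds the line variance budget (%.3g)",
               ve_total * V_lm, s2L)
    s2_poly <- max(s2L - ve_total * V_lm, 0)
    g <- rnorm(n_lines, 0, sqrt(s2_poly))
    e <- rnorm(n, 0, sqrt(s2E))
    y <- y + q_line_total[li] + g[li] + e

    traits <- matrix(y, ncol = 1, dimnames = list(NULL, trait))
    out <- cc_cohort(design, traits)
    out$lines <- descent$lines[sort(unique(li))]
    attr(out, "qtl_truth") <- truth
    attr(out, "sim_params") <- list(h2_line = h2_line, mu = mu,
                                    var_total = var_total, sigma2_E = s2E,
                                    sigma2_line = s2L)
    out
  })
}
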