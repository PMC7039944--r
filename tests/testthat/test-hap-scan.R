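test_that("scan logP matches a from-scratch nested-F computation", {
  # 6 lines x 3 mice, 2 markers, hand-built probabilities
  set.seed(11)
  p1 <- matrix(runif(48), 6, 8); p1 <- p1 / rowSums(p1)
  p2 <- matrix(runif(48), 6, 8); p2 <- p2 / rowSums(p2)
  descent <- manual_descent(list(p1, p2))
  descent$probs <- descent$probs[1:6, , , drop = FALSE]
  descent$lines <- descent$lines[1:6]
  line <- rep(descent$lines, each = 3)
  y <- as.numeric(p1 %*% c(2, 0, -1, 1, 0, 0, 3, -2))[rep(1:6, each = 3)] +
    rnorm(18, 0, 0.8)
  coh <- manual_cohort(line, y)
  sc <- scan_trait(coh, descent, "BV/TV")
  expect_equal(sc$logP, oracle_scan_logP(coh, descent, "BV/TV"),
               tolerance = 1e-8)

  # with a covariate in the model
  coh2 <- manual_cohort(line, y + rep(c(0, 2), 9),
                        extra = data.frame(sex = rep(c("F", "M"), 9)))
  sc2 <- scan_trait(coh2, descent, "BV/TV", "sex")
  expect_equal(sc2$logP, oracle_scan_logP(coh2, descent, "BV/TV", "sex"),
               tolerance = 1e-8)
})

test_that("scan handles degenerate designs and perfect fits", {
  descent <- manual_descent(list(diag(1, 8), matrix(1 / 8, 8, 8)))
  line <- rep(descent$lines, each = 2)
  # constant trait: logP 0 everywhere
  sc0 <- scan_trait(manual_cohort(line, rep(3, 16)), descent, "BV/TV")
  expect_true(all(sc0$logP == 0))
  # monomorphic descent (uniform rows): rank 0, degenerate flag
  y <- rnorm(16)
  sc1 <- scan_trait(manual_cohort(line, y), descent, "BV/TV")
  expect_true(sc1$degenerate[2])
  expect_equal(sc1$logP[2], 0)
  # noiseless founder-probability trait hits the cap at its marker
  y2 <- diag(1, 8)[rep(1:8, each = 2), 3]
  sc2 <- scan_trait(manual_cohort(line, y2), descent, "BV/TV")
  expect_equal(sc2$logP[1], 50)
})

test_that("scan logP is invariant under affine trait transformations", {
  panel <- simulate_founder_panel(1, 20, c(0.1, 0.4), seed = 2)
  descent <- simulate_cc_lines(panel, 12, 8, 0.15, 0.95, seed = 3)$descent
  des <- cohort_design(descent$lines, 3, seed = 4)
  coh <- simulate_phenotypes(des, descent, list(), h2_line = 0.5, seed = 5)
  sc <- scan_trait(coh, descent, "BV/TV")
  coh2 <- coh
  coh2$traits[, 1] <- 3.7 * coh2$traits[, 1] - 11
  sc2 <- scan_trait(coh2, descent, "BV/TV")
  expect_equal(sc$logP, sc2$logP, tolerance = 1e-9)
})

test_that("permutation thresholds are ordered, reproducible and guarded", {
  panel <- simulate_founder_panel(1, 30, c(0.1, 0.4), seed = 6)
  descent <- simulate_cc_lines(panel, 15, 8, 0.15, 0.95, seed = 7)$descent
  des <- cohort_design(descent$lines, 4, seed = 8)
  coh <- simulate_phenotypes(des, descent, list(), h2_line = 0.5, seed = 9)
  th <- genome_thresholds(coh, descent, "BV/TV", n_sim = 50, seed = 10)
  expect_gte(th$cutoffs[["99"]], th$cutoffs[["95"]])
  expect_gte(th$cutoffs[["95"]], 0)
  th2 <- genome_thresholds(coh, descent, "BV/TV", n_sim = 50, seed = 10)
  expect_identical(th$cutoffs, th2$cutoffs)
  # too few lines
  small <- simulate_cc_lines(panel, 4, 8, 0.15, 0.95, seed = 1)$descent
  des_s <- cohort_design(small$lines, 4, seed = 2)
  coh_s <- simulate_phenotypes(des_s, small, list(), h2_line = 0.5, seed = 3)
  expect_error(genome_thresholds(coh_s, small, "BV/TV", n_sim = 20, seed = 1),
               "permutation space")
  expect_error(genome_thresholds(coh, descent, "BV/TV", n_sim = 10, seed = 1),
               "n_sim")
})

test_that("a one-marker genome reproduces the pointwise F tail", {
  # iid phenotypes (h2 = 0): the permutation distribution of logP at a
  # single marker approximates the parametric F reference, so the 95th
  # percentile of maxima ~ -log10(0.05)
  # thresholds are conditional on the phenotype draw, so average a few
  panel <- simulate_founder_panel(1, 2, c(0.25, 0.5), seed = 11)
  descent <- simulate_cc_lines(panel, 30, 8, 0.15, 1, seed = 12)$descent
  descent$probs <- descent$probs[, , 1, drop = FALSE]
  descent$map <- descent$map[1, , drop = FALSE]
  des <- cohort_design(descent$lines, 5, seed = 13)
  ths <- vapply(1:6, function(i) {
    coh <- simulate_phenotypes(des, descent, list(), h2_line = 0,
                               seed = 6000 + i)
    genome_thresholds(coh, descent, "BV/TV", n_sim = 300,
                      seed = 70 + i)$cutoffs
  }, numeric(2))
  expect_lt(abs(mean(ths["95", ]) - (-log10(0.05))), 0.25)
  expect_lt(abs(mean(ths["99", ]) - 2), 0.45)
})

test_that("QTL calling collapses runs and honors the merge gap", {
  mk_scan <- function(logP, pos = seq_along(logP) * 1e6, chrom = 1) {
    out <- data.frame(chrom = chrom, pos_bp = pos, logP = logP,
                      df_num = 7L, degenerate = FALSE)
    attr(out, "trait") <- "BV/TV"
    class(out) <- c("scan_result", "data.frame")
    out
  }
  th <- structure(list(cutoffs = c("95" = 3, "99" = 5), n_sim = 200,
                       maxima = numeric(0)), class = "threshold_set")
  # everything below: no calls
  expect_equal(nrow(call_qtls(mk_scan(rep(1, 10)), th, 99)), 0)
  # one spike
  q1 <- call_qtls(mk_scan(c(1, 1, 8, 1, 1)), th, 99)
  expect_equal(nrow(q1), 1)
  expect_equal(q1$peak_pos_bp, 3e6)
  expect_equal(q1$peak_logP, 8)
  # two spikes separated by a wide sub-threshold valley: two calls
  lp <- c(8, rep(1, 8), 7)
  q2 <- call_qtls(mk_scan(lp), th, 99)
  expect_equal(nrow(q2), 2)
  # same two spikes within the merge gap: one call at the higher peak
  q3 <- call_qtls(mk_scan(c(8, 1, 7), pos = c(1e6, 1.5e6, 2e6)), th, 99)
  expect_equal(nrow(q3), 1)
  expect_equal(q3$peak_pos_bp, 1e6)
  # tie broken to the leftmost marker
  q4 <- call_qtls(mk_scan(c(6, 6), pos = c(1e6, 1.2e6)), th, 99)
  expect_equal(q4$peak_pos_bp, 1e6)
})

test_that("regional heritability brackets its limiting cases", {
  panel <- simulate_founder_panel(1, 40, c(0.1, 0.4), seed = 16)
  # many lines: the null 7-df fit on line means has expectation 7/(k-1)
  descent <- simulate_cc_lines(panel, 100, 8, 0.15, 0.95, seed = 17)$descent
  des <- cohort_design(descent$lines, 5, seed = 18)
  # trait independent of the locus
  coh0 <- simulate_phenotypes(des, descent, list(), h2_line = 0, seed = 19)
  expect_lte(regional_h2(coh0, descent, "BV/TV", character(0), 20), 0.25)
  # line means exactly determined by descent at the locus
  q <- qtl_spec(1, descent$map$pos_bp[20], "haplotype",
                founder_effects = rnorm(8))
  coh1 <- simulate_phenotypes(des, descent, list(q), h2_line = 1, seed = 20,
                              var_total = 0)
  expect_equal(regional_h2(coh1, descent, "BV/TV", character(0), 20), 1)
})

test_that("planted regional heritability is recovered on line means", {
  # 100 lines: the 7-df fit overstates H2_r by ~(1 - H2_r) * 7/(k - 1),
  # so recovery is assessed where that term is small
  panel <- simulate_founder_panel(1, 40, c(0.1, 0.4), seed = 21)
  descent <- simulate_cc_lines(panel, 100, 8, 0.15, 0.95, seed = 22)$descent
  des <- cohort_design(descent$lines, 5, seed = 23)
  h2r <- vapply(1:100, function(r) {
    q <- qtl_spec(1, descent$map$pos_bp[20], "haplotype",
                  founder_effects = rnorm(8), variance_explained = 0.5)
    coh <- simulate_phenotypes(des, descent, list(q), h2_line = 0.6,
                               seed = 300 + r)
    regional_h2(coh, descent, "BV/TV", character(0), 20)
  }, numeric(1))
  expect_lt(abs(mean(h2r) - 0.5), 0.1)
})

test_that("founder effect deviations are anchored to the reference", {
  panel <- simulate_founder_panel(1, 30, c(0.1, 0.4), seed = 24)
  descent <- simulate_cc_lines(panel, 34, 8, 0.15, 0.95, seed = 25)$descent
  des <- cohort_design(descent$lines, 5, seed = 26)
  beta <- c(2, -1, 0.5, 1, -2, 0, 1.5, 0)
  q <- qtl_spec(1, descent$map$pos_bp[15], "haplotype", founder_effects = beta,
                variance_explained = 0.7)
  coh <- simulate_phenotypes(des, descent, list(q), h2_line = 0.7, seed = 27)
  sc <- scan_trait(coh, descent, "BV/TV")
  fe <- founder_effects(sc, 15)
  expect_equal(fe$deviation[8], 0)
  expect_equal(fe$se[8], 0)
  expect_error(founder_effects(sc, 15, "NOT/AStrain"), "unknown reference")
  # re-basing on another founder keeps pairwise contrasts
  fe2 <- founder_effects(sc, 15, "A/J")
  expect_equal(fe$deviation - fe$deviation[1], fe2$deviation, tolerance = 1e-9)
  expect_equal(fe2$deviation[1], 0)
  # planted deviations recovered within 2 SE (realized truth from generator)
  truth <- attr(coh, "qtl_truth")[[1]]$founder_effects
  tdev <- truth - truth[8]
  expect_true(all(abs(fe$deviation[-8] - tdev[-8]) <= 2.5 * fe$se[-8]))
  # constant shift of the trait leaves deviations unchanged
  coh2 <- coh
  coh2$traits[, 1] <- coh2$traits[, 1] + 5
  fe3 <- founder_effects(scan_trait(coh2, descent, "BV/TV"), 15)
  expect_equal(fe3$deviation, fe$deviation, tolerance = 1e-9)
})

test_that("allele group means separate a planted biallelic QTL", {
  panel <- simulate_founder_panel(1, 30, c(0.25, 0.5), seed = 28)
  descent <- simulate_cc_lines(panel, 34, 8, 0.15, 0.95, seed = 29)$descent
  des <- cohort_design(descent$lines, 5, seed = 30)
  sdp <- c(1, 1, 1, 1, 0, 0, 0, 0)
  q <- qtl_spec(1, descent$map$pos_bp[10], "variant", sdp = sdp,
                variance_explained = 0.7)
  coh <- simulate_phenotypes(des, descent, list(q), h2_line = 0.7, seed = 31)
  # per-line genotype from the dominant founder at the marker
  P <- descent$probs[, , 10]
  hard <- apply(P, 1, which.max)
  geno <- setNames(ifelse(sdp[hard] == 1, "T:T", "C:C"), descent$lines)
  out <- allele_group_means(coh, "BV/TV", geno)
  expect_equal(out$groups$genotype[1], "T:T")  # alt group planted higher
  expect_lt(out$welch$p_value, 0.01)
  # all lines identical genotype: single group, no test
  out2 <- allele_group_means(coh, "BV/TV",
                             setNames(rep("C:C", 34), descent$lines))
  expect_equal(nrow(out2$groups), 1)
  expect_null(out2$welch)
})

test_that("null allele-group P values are uniform", {
  panel <- simulate_founder_panel(1, 5, c(0.25, 0.5), seed = 32)
  descent <- simulate_cc_lines(panel, 20, 8, 0.15, 0.95, seed = 33)$descent
  des <- cohort_design(descent$lines, 5, seed = 34)
  set.seed(35)
  ps <- vapply(1:80, function(r) {
    coh <- simulate_phenotypes(des, descent, list(), h2_line = 0,
                               seed = 400 + r)
    geno <- setNames(sample(rep(c("T:T", "C:C"), 10)), descent$lines)
    allele_group_means(coh, "BV/TV", geno)$welch$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a paper-scale planted QTL is detected at the 99% threshold", {
  # power check at the regional-heritability level of the panel's median
  # detected locus (H2_r ~ 0.74)
  panel <- simulate_founder_panel(2, 100, c(0.1, 0.4), seed = 36)
  descent <- simulate_cc_lines(panel, 34, 8, 0.15, 0.95, seed = 37)$descent
  set.seed(38)
  det <- vapply(1:50, function(r) {
    des <- cohort_design(descent$lines, 5, seed = 500 + r)
    q <- qtl_spec(1, descent$map$pos_bp[50], "haplotype",
                  founder_effects = rnorm(8), variance_explained = 0.74)
    coh <- simulate_phenotypes(des, descent, list(q), h2_line = 0.6,
                               seed = 600 + r)
    sc <- scan_trait(coh, descent, "BV/TV")
    th <- genome_thresholds(coh, descent, "BV/TV", n_sim = 200,
                            seed = 700 + r)
    max(sc$logP) >= th$cutoffs[["99"]]
  }, logical(1))
  expect_gte(mean(det), 0.8)
})
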