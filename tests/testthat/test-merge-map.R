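test_that("dosage imputation follows the probability-weighted formula", {
  # 3 lines: one-hot on an alt founder, uniform, one-hot on a ref founder
  P <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0),
             rep(1 / 8, 8),
             c(0, 0, 0, 0, 0, 0, 0, 1))
  descent <- manual_descent(list(P))
  descent$probs <- descent$probs[1:3, , , drop = FALSE]
  descent$lines <- descent$lines[1:3]
  cat_df <- data.frame(chrom = 1, pos_bp = 1e6, ref = "A", alt = "T",
                       sdp = "11110000", monomorphic = FALSE)
  attr(cat_df, "sdp_matrix") <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 1)
  class(cat_df) <- c("variant_catalogue", "data.frame")
  D <- impute_dosages(cat_df, descent)
  expect_equal(as.numeric(D), c(2, 1, 0))  # one-hot alt; uniform 4/8; ref

  # all-reference SDP gives dosage 0 everywhere
  attr(cat_df, "sdp_matrix") <- matrix(0L, 1, 8)
  expect_true(all(impute_dosages(cat_df, descent) == 0))

  # variant outside the map span is skipped with a warning
  cat2 <- data.frame(chrom = c(1, 2), pos_bp = c(1e6, 5e5), ref = "A",
                     alt = "T", sdp = "10000000", monomorphic = FALSE)
  attr(cat2, "sdp_matrix") <- rbind(c(1, rep(0, 7)), c(1, rep(0, 7)))
  class(cat2) <- c("variant_catalogue", "data.frame")
  expect_warning(D2 <- impute_dosages(cat2, descent), "skipped")
  expect_equal(ncol(D2), 1)
})

test_that("dosages converge to true genotypes as probabilities sharpen", {
  panel <- simulate_founder_panel(1, 30, c(0.25, 0.5), seed = 51)
  cat_full <- founder_variant_catalogue(panel)
  errs <- vapply(c(0.7, 0.9, 1), function(sh) {
    sim <- simulate_cc_lines(panel, 20, 8, 0, sh, seed = 52)
    D <- impute_dosages(cat_full, sim$descent)
    # true genotype from the hard mosaic (sharpness 1, same seed)
    simT <- simulate_cc_lines(panel, 20, 8, 0, 1, seed = 52)
    DT <- impute_dosages(cat_full, simT$descent)
    mean(abs(D - DT))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_equal(errs[3], 0)
})

test_that("merge logP is small under the null and capped for perfect fits", {
  panel <- simulate_founder_panel(1, 30, c(0.25, 0.5), seed = 53)
  descent <- simulate_cc_lines(panel, 34, 8, 0.15, 0.95, seed = 54)$descent
  des <- cohort_design(descent$lines, 5, seed = 55)
  coh <- simulate_phenotypes(des, descent, list(), h2_line = 0, seed = 56)
  cat_full <- founder_variant_catalogue(panel)
  D <- impute_dosages(cat_full, descent)
  sc <- scan_trait(coh, descent, "BV/TV")
  mg <- merge_scan(coh, D, "BV/TV", character(0), sc)
  expect_lt(mg$merge_logP[1], 2.5)

  # trait exactly equal to a variant dosage: capped, never beyond
  li <- match(coh$mice$line, descent$lines)
  coh2 <- coh
  coh2$traits[, 1] <- D[li, 5]
  mg2 <- merge_scan(coh2, D, "BV/TV", character(0),
                    scan_trait(coh2, descent, "BV/TV"))
  expect_equal(max(mg2$merge_logP, na.rm = TRUE), 50)
  expect_equal(mg2$merge_logP[5], 50)

  # zero-variance dosage is dropped with a count
  Dz <- D[, 1, drop = FALSE]
  Dz[] <- 1
  attr(Dz, "variant_rows") <- attr(D, "variant_rows")[1]
  attr(Dz, "nearest_marker") <- attr(D, "nearest_marker")[1]
  expect_warning(mgz <- merge_scan(coh, Dz, "BV/TV", character(0), sc),
                 "zero-variance")
  expect_true(is.na(mgz$merge_logP[1]))
  expect_equal(attr(mgz, "n_zero_variance"), 1)
})

test_that("merge beats the haplotype test for a true biallelic QTL", {
  panel <- simulate_founder_panel(1, 60, c(0.25, 0.5), seed = 57)
  descent <- simulate_cc_lines(panel, 34, 8, 0.15, 0.95, seed = 58)$descent
  cat_full <- founder_variant_catalogue(panel)
  sdp30 <- attr(cat_full, "sdp_matrix")[30, ]
  wins <- vapply(1:25, function(r) {
    des <- cohort_design(descent$lines, 5, seed = 800 + r)
    q <- qtl_spec(1, descent$map$pos_bp[30], "variant", sdp = sdp30,
                  variance_explained = 0.6)
    coh <- simulate_phenotypes(des, descent, list(q), h2_line = 0.6,
                               seed = 900 + r)
    sc <- scan_trait(coh, descent, "BV/TV")
    D <- impute_dosages(cat_full, descent)
    mg <- merge_scan(coh, D, "BV/TV", character(0), sc)
    i <- which(mg$variant_row == 30)
    mg$merge_logP[i] > mg$hap_logP[i]
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("the haplotype test beats merge for non-biallelic architectures", {
  panel <- simulate_founder_panel(1, 60, c(0.25, 0.5), seed = 59)
  descent <- simulate_cc_lines(panel, 34, 8, 0.15, 0.95, seed = 60)$descent
  cat_full <- founder_variant_catalogue(panel)
  set.seed(61)
  wins <- vapply(1:25, function(r) {
    des <- cohort_design(descent$lines, 5, seed = 1000 + r)
    # continuous founder-effect spectrum: no SDP can represent it
    q <- qtl_spec(1, descent$map$pos_bp[30], "haplotype",
                  founder_effects = rnorm(8), variance_explained = 0.6)
    coh <- simulate_phenotypes(des, descent, list(q), h2_line = 0.6,
                               seed = 1100 + r)
    sc <- scan_trait(coh, descent, "BV/TV")
    D <- impute_dosages(cat_full, descent)
    mg <- merge_scan(coh, D, "BV/TV", character(0), sc)
    i <- which(mg$variant_row == 30)
    sc$logP[30] > mg$merge_logP[i]
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("candidate shortlisting ranks, ties and windows correctly", {
  mk_merge <- function(pos, logP, chrom = 1) {
    out <- data.frame(chrom = chrom, pos_bp = pos,
                      variant_row = seq_along(pos), merge_logP = logP,
                      hap_logP = 0, candidate = TRUE,
                      nearest_marker = seq_along(pos))
    class(out) <- c("merge_result", "data.frame")
    out
  }
  ann <- data.frame(gene = c("G1", "G2"), chrom = 1,
                    start_bp = c(1e6, 4e6), end_bp = c(2e6, 5e6),
                    strand = "+")
  # single variant inside G1
  s1 <- shortlist_candidates(mk_merge(1.5e6, 7), c(1, 0, 1e7), ann)
  expect_equal(s1$gene[1], "G1")
  expect_false(s1$ambiguous[1])
  # variant exactly between the genes: assigned to both, ambiguous
  s2 <- shortlist_candidates(mk_merge(3e6, 4), c(1, 0, 1e7), ann)
  expect_setequal(s2$gene, c("G1", "G2"))
  expect_true(all(s2$ambiguous))
  # window excludes everything
  s3 <- shortlist_candidates(mk_merge(1.5e6, 7), c(1, 8e6, 9e6), ann)
  expect_equal(nrow(s3), 0)
})

test_that("a planted causal gene outranks decoys", {
  panel <- simulate_founder_panel(1, 60, c(0.25, 0.5), seed = 62)
  descent <- simulate_cc_lines(panel, 34, 8, 0.15, 0.95, seed = 63)$descent
  cat_full <- founder_variant_catalogue(panel)
  sdp30 <- attr(cat_full, "sdp_matrix")[30, ]
  pos30 <- panel$map$pos_bp[30]
  # 21 genes: the causal one around marker 30 plus 20 decoys elsewhere
  starts <- seq(1e6, 9.6e7, length.out = 21)
  ann <- data.frame(gene = sprintf("G%02d", 1:21), chrom = 1,
                    start_bp = starts, end_bp = starts + 1e6, strand = "+")
  ann$start_bp[11] <- pos30 - 5e5
  ann$end_bp[11] <- pos30 + 5e5
  top <- vapply(1:30, function(r) {
    des <- cohort_design(descent$lines, 5, seed = 1200 + r)
    q <- qtl_spec(1, pos30, "variant", sdp = sdp30, variance_explained = 0.6)
    coh <- simulate_phenotypes(des, descent, list(q), h2_line = 0.6,
                               seed = 1300 + r)
    sc <- scan_trait(coh, descent, "BV/TV")
    D <- impute_dosages(cat_full, descent)
    mg <- merge_scan(coh, D, "BV/TV", character(0), sc)
    sl <- shortlist_candidates(mg, c(1, 1, 1e8), ann)
    sl$gene[1] == "G11"
  }, logical(1))
  expect_gte(mean(top), 0.9)
})
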