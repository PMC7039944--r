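#' Simulate CC line haplotype mosaics and founder-descent probabilities
#'
#' Each Collaborative Cross line is a fixed mosaic of founder haplotypes.
#' Segments are laid down per chromosome with a Poisson number of
#' breakpoints and a founder drawn uniformly from the eight strains per
#' segment. Residual heterozygosity (lines are 80-90% homozygous, not
#' fully inbred) is modeled as segments that carry two founders with
#' probability 1/2 each. The emitted descent probabilities are the mosaic
#' memberships blurred toward uniform: `(1 - eps) * mosaic + eps / 8`
#' with `eps = 1 - prob_sharpness`, standing in for haplotype
#' reconstruction uncertainty.
#'
#' @param panel A `founder_panel` giving the marker map.
#' @param n_lines Number of CC lines to simulate.
#' @param expected_segments_per_chrom Expected number of mosaic segments
#'   per chromosome; the breakpoint count is Poisson with mean
#'   `expected_segments_per_chrom - 1`.
#' @param residual_het Probability that a segment is residually
#'   heterozygous (carries two founders at probability 1/2 each).
#'   Default 0.15, the midpoint of 80-90% genome-wide homozygosity.
#' @param prob_sharpness In \[0, 1\]; 1 emits exact mosaic memberships,
#'   smaller values mix in uniform noise.
#' @param seed Integer seed.
#'
#' @return A list with `mosaics` (per line, a data.frame of segments:
#'   `chrom`, `start_bp`, `end_bp`, `founder`, `founder2` (NA when
#'   homozygous), and attribute `residual_het_fraction`) and `descent`,
#'   a `cc_descent` object: `probs` is a lines x 8 x markers array whose
#'   rows sum to 1, plus `map`, `founders` and `lines` (labels
#'   "CC001"...).
#' @export
simulate_cc_lines <- function(panel, n_lines,
                              expected_segments_per_chrom = 8,
                              residual_het = 0.15,
                              prob_sharpness = 0.95,
                              seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"))
  if (!is_count(n_lines)) ccq_stop("n_lines must be a positive integer")
  if (expected_segments_per_chrom < 1)
    ccq_stop("expected_segments_per_chrom must be >= 1")
  if (residual_het < 0 || residual_het > 0.2)
    ccq_stop("residual_het must be in [0, 0.2]")
  if (prob_sharpness < 0 || prob_sharpness > 1)
    ccq_stop("prob_sharpness must be in [0, 1]")

  chroms <- unique(panel$map$chrom)
  clen <- panel$chrom_length_bp
  M <- nrow(panel$map)
  eps <- 1 - prob_sharpness
  lines <- sprintf("CC%03d", seq_len(n_lines))

  with_seed(seed, {
    probs <- array(0, dim = c(n_lines, 8, M),
                   dimnames = list(lines, CC_FOUNDERS, NULL))
    mosaics <- vector("list", n_lines)
    names(mosaics) <- lines
    for (i in seq_len(n_lines)) {
      segs <- do.call(rbind, lapply(chroms, function(cc) {
        nb <- rpois(1, max(expected_segments_per_chrom - 1, 0))
        brk <- if (nb > 0) sort(sample.int(clen - 1L, min(nb, clen - 1L))) else integer(0)
        start <- c(1L, brk + 1L)
        end <- c(brk, clen)
        ns <- length(start)
        f1 <- sample.int(8, ns, replace = TRUE)
        het <- runif(ns) < residual_het
        f2 <- ifelse(het, sample.int(8, ns, replace = TRUE), NA_integer_)
        data.frame(chrom = cc, start_bp = start, end_bp = end,
                   founder = f1, founder2 = f2)
      }))
      # enforce the 80% homozygosity floor: if sampling overshot the target
      # fraction, revert the longest heterozygous segments to homozygous
      genome_len <- length(chroms) * clen
      is_het <- function(s) !is.na(s$founder2) & s$founder2 != s$founder
      seg_len <- segs$end_bp - segs$start_bp + 1
      while (sum(seg_len[is_het(segs)]) / genome_len > 0.2) {
        h <- which(is_het(segs))
        segs$founder2[h[which.max(seg_len[h])]] <- NA_integer_
      }
      het_len <- sum(seg_len[is_het(segs)])
      attr(segs, "residual_het_fraction") <- het_len / (length(chroms) * clen)
      mosaics[[i]] <- segs
      # per-marker base membership -> blurred probabilities
      for (cc in chroms) {
        midx <- which(panel$map$chrom == cc)
        s <- segs[segs$chrom == cc, , drop = FALSE]
        seg_of <- findInterval(panel$map$pos_bp[midx], s$start_bp)
        for (j in seq_along(midx)) {
          base <- numeric(8)
          f1 <- s$founder[seg_of[j]]; f2 <- s$founder2[seg_of[j]]
          if (is.na(f2) || f2 == f1) base[f1] <- 1
          else { base[f1] <- 0.5; base[f2] <- 0.5 }
          probs[i, , midx[j]] <- (1 - eps) * base + eps / 8
        }
      }
    }
    descent <- structure(list(probs = probs, map = panel$map,
                              founders = CC_FOUNDERS, lines = lines),
                         class = "cc_descent")
    list(mosaics = mosaics, descent = descent)
  })
}

#' @export
print.cc_descent <- function(x, ...) {
  cat(sprintf("cc_descent: %d lines x 8 founders x %d markers\n",
              length(x$lines), nrow(x$map)))
  invisible(x)
}

#' Validate a descent-probability object
#'
#' Checks that every (line, marker) probability row is non-negative and
#' sums to 1 within `tol`.
#' @param descent A `cc_descent`.
#' @param tol Row-sum tolerance.
#' @return `descent`, invisibly; errors with the offending line and
#'   marker otherwise.
#' @export
validate_descent <- function(descent, tol = 1e-9) {
  stopifnot(inherits(descent, "cc_descent"))
  sums <- apply(descent$probs, c(1, 3), sum)
  bad <- which(abs(sums - 1) > tol | apply(descent$probs, c(1, 3), min) < 0,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    ccq_stop("descent probabilities invalid at line '%s', marker %d (row sum %.6g)",
             descent$lines[bad[1, 1]], bad[1, 2], sums[bad[1, 1], bad[1, 2]])
  invisible(descent)
}

# descent probabilities at one marker: lines x 8 matrix
descent_at <- function(descent, marker) {
  descent$probs[, , marker, drop = TRUE]
}

# nearest marker index on the map for (chrom, pos); NA if chrom absent
nearest_marker <- function(map, chrom, pos_bp) {
  idx <- which(map$chrom == chrom)
  if (length(idx) == 0) return(NA_integer_)
  idx[which.min(abs(map$pos_bp[idx] - pos_bp))]
}
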