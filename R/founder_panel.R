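#' Simulate a biallelic founder panel for the eight CC strains
#'
#' Generates a marker map and a marker-by-founder allele matrix for the
#' eight Collaborative Cross founder strains. Each marker is biallelic
#' (0 = reference, 1 = alternate) and the number of alternate-carrying
#' founders is drawn so that the folded founder-level allele frequency
#' falls inside `maf_range`.
#'
#' @param n_chrom Number of chromosomes to simulate.
#' @param n_markers_per_chrom Markers per chromosome (at least 2).
#' @param maf_range Length-2 numeric interval in (0, 0.5]; the folded
#'   founder allele frequency (k/8 for k alternate founders) of every
#'   marker is constrained to this interval. With 8 founders the
#'   attainable frequencies are multiples of 1/8.
#' @param seed Integer seed; the same seed reproduces the same panel.
#' @param chrom_length_bp Chromosome length in bp (positions are drawn
#'   uniformly and sorted; default 100 Mb, a typical mouse autosome).
#'
#' @return An object of class `founder_panel`: a list with
#'   `founders` (the 8 strain names), `map` (data.frame with `chrom`,
#'   `pos_bp`, 1-based, strictly increasing within chromosome) and
#'   `alleles` (marker x 8 integer matrix of 0/1).
#' @export
#' @examples
#' panel <- simulate_founder_panel(1, 50, c(0.1, 0.4), seed = 1)
#' range(colMeans(panel$alleles))
simulate_founder_panel <- function(n_chrom, n_markers_per_chrom,
                                   maf_range = c(0.1, 0.4), seed = NULL,
                                   chrom_length_bp = 1e8) {
  if (!is_count(n_chrom)) ccq_stop("n_chrom must be a positive integer")
  if (!is_count(n_markers_per_chrom, min = 2L))
    ccq_stop("n_markers_per_chrom must be an integer >= 2")
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    ccq_stop("maf_range must be a non-empty interval within (0, 0.5]")
  # attainable alt-founder counts: folded frequency min(k, 8-k)/8 in range
  ks <- 1:7
  ok <- pmin(ks, 8L - ks) / 8 >= maf_range[1] &
        pmin(ks, 8L - ks) / 8 <= maf_range[2]
  if (!any(ok))
    ccq_stop("maf_range [%g, %g] admits no allele count on 8 founders",
             maf_range[1], maf_range[2])
  k_choices <- ks[ok]

  with_seed(seed, {
    M <- n_chrom * n_markers_per_chrom
    chrom <- rep(seq_len(n_chrom), each = n_markers_per_chrom)
    pos <- unlist(lapply(seq_len(n_chrom), function(cc) {
      p <- sort(sample.int(chrom_length_bp, n_markers_per_chrom))
      # enforce strict increase (sample.int without replacement guarantees it)
      p
    }))
    alleles <- matrix(0L, M, 8, dimnames = list(NULL, CC_FOUNDERS))
    k <- if (length(k_choices) == 1) rep(k_choices, M)
         else sample(k_choices, M, replace = TRUE)
    for (m in seq_len(M)) alleles[m, sample.int(8, k[m])] <- 1L
    structure(list(
      founders = CC_FOUNDERS,
      map = data.frame(chrom = chrom, pos_bp = pos),
      alleles = alleles,
      chrom_length_bp = chrom_length_bp
    ), class = "founder_panel")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: 8 founders, %d markers on %d chromosome(s)\n",
              nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

#' Turn a founder panel into a variant catalogue
#'
#' Reinterprets the panel's markers as a catalogue of biallelic variants
#' segregating among the eight founders, the input to merge analysis.
#' Monomorphic markers are flagged and excluded from testing downstream.
#'
#' @param panel A `founder_panel`.
#' @param ref,alt Reference / alternate allele characters used for all
#'   variants (simulated panels carry abstract 0/1 alleles).
#' @return A `variant_catalogue`: data.frame with `chrom`, `pos_bp`,
#'   `ref`, `alt`, `sdp` (8-character strain distribution pattern in
#'   canonical founder order) and `monomorphic`, plus an `sdp_matrix`
#'   attribute (variant x 8 of 0/1).
#' @export
founder_variant_catalogue <- function(panel, ref = "A", alt = "T") {
  stopifnot(inherits(panel, "founder_panel"))
  sdp <- panel$alleles
  mono <- rowSums(sdp) %in% c(0L, 8L)
  out <- data.frame(
    chrom = panel$map$chrom,
    pos_bp = panel$map$pos_bp,
    ref = ref, alt = alt,
    sdp = apply(sdp, 1, paste0, collapse = ""),
    monomorphic = mono
  )
  attr(out, "sdp_matrix") <- sdp
  class(out) <- c("variant_catalogue", "data.frame")
  out
}
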