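# Readers and writers for the pipeline's standard file formats:
# phenotype CSV, descent-probability TSV, founder variant VCF, gene BED.

COVARIATE_COLS <- c("sex", "age_weeks", "batch", "month", "season", "year",
                    "experimenter")

#' Write cohort phenotypes to CSV
#'
#' Columns: `mouse_id`, `line`, the covariates present, then one column
#' per trait.
#' @param cohort A `cc_cohort`.
#' @param path Output file.
#' @export
write_phenotypes <- function(cohort, path) {
  covs <- intersect(COVARIATE_COLS, names(cohort$mice))
  df <- cbind(cohort$mice[, c("mouse_id", "line", covs), drop = FALSE],
              as.data.frame(cohort$traits, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read cohort phenotypes from CSV
#'
#' Recognized covariate columns are kept as covariates; every other
#' numeric column beyond `mouse_id`/`line` is treated as a trait
#' (unknown columns are preserved as extra traits). Missing trait cells
#' are recorded; duplicate `mouse_id` or a missing `line` column is an
#' error.
#'
#' @param path CSV file as written by [write_phenotypes()].
#' @return A `cc_cohort`; attribute `n_missing` counts missing trait
#'   cells.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"line" %in% names(df)) ccq_stop("%s: missing 'line' column", path)
  if (!"mouse_id" %in% names(df)) ccq_stop("%s: missing 'mouse_id' column", path)
  if (anyDuplicated(df$mouse_id))
    ccq_stop("%s: duplicate mouse_id '%s'", path,
             df$mouse_id[anyDuplicated(df$mouse_id)])
  covs <- intersect(COVARIATE_COLS, names(df))
  trait_cols <- setdiff(names(df), c("mouse_id", "line", covs))
  traits <- as.matrix(df[, trait_cols, drop = FALSE])
  storage.mode(traits) <- "double"
  out <- cc_cohort(df[, c("mouse_id", "line", covs), drop = FALSE], traits)
  attr(out, "n_missing") <- sum(is.na(traits))
  out
}

#' Write founder-descent probabilities to a flat TSV
#'
#' One row per (line, marker): `line`, `chromosome`, `position_bp`,
#' then eight probability columns headed by the canonical founder
#' names.
#' @param descent A `cc_descent`.
#' @param path Output file.
#' @export
write_descent <- function(descent, path) {
  L <- length(descent$lines); M <- nrow(descent$map)
  rows <- do.call(rbind, lapply(seq_len(L), function(i) {
    cbind(data.frame(line = descent$lines[i],
                     chromosome = descent$map$chrom,
                     position_bp = descent$map$pos_bp),
          as.data.frame(t(descent$probs[i, , ]),
                        col.names = descent$founders, check.names = FALSE))
  }))
  names(rows)[4:11] <- descent$founders
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read founder-descent probabilities from a flat TSV
#'
#' Expects `line`, `chromosome`, `position_bp` and eight probability
#' columns headed by the founder names; column order is normalized to
#' the canonical founder order using the headers. Any probability row
#' whose sum deviates from 1 by more than `tol` is rejected with the
#' offending line and marker named.
#'
#' @param path TSV as written by [write_descent()].
#' @param tol Row-sum tolerance (default 1e-6).
#' @return A `cc_descent`.
#' @export
read_descent_probs <- function(path, tol = 1e-6) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("line", "chromosome", "position_bp")
  if (!all(need %in% names(df)))
    ccq_stop("%s: missing column(s) %s", path,
             paste(setdiff(need, names(df)), collapse = ", "))
  missing_f <- setdiff(CC_FOUNDERS, names(df))
  if (length(missing_f) > 0)
    ccq_stop("%s: missing founder column(s) %s", path,
             paste(missing_f, collapse = ", "))
  pm <- as.matrix(df[, CC_FOUNDERS])   # header-based canonical reorder
  sums <- rowSums(pm)
  bad <- which(abs(sums - 1) > tol | apply(pm, 1, min) < 0)
  if (length(bad) > 0)
    ccq_stop("%s: probability row for line '%s' at %s:%d sums to %.6g",
             path, df$line[bad[1]], df$chromosome[bad[1]],
             df$position_bp[bad[1]], sums[bad[1]])
  lines <- unique(df$line)
  map <- unique(df[, c("chromosome", "position_bp")])
  names(map) <- c("chrom", "pos_bp")
  map <- map[order(map$chrom, map$pos_bp), , drop = FALSE]
  rownames(map) <- NULL
  M <- nrow(map)
  probs <- array(NA_real_, dim = c(length(lines), 8, M),
                 dimnames = list(lines, CC_FOUNDERS, NULL))
  key <- paste(df$chromosome, df$position_bp)
  midx <- match(key, paste(map$chrom, map$pos_bp))
  lidx <- match(df$line, lines)
  for (r in seq_len(nrow(df))) probs[lidx[r], , midx[r]] <- pm[r, ]
  if (anyNA(probs)) ccq_stop("%s: incomplete line x marker grid", path)
  structure(list(probs = probs, map = map, founders = CC_FOUNDERS,
                 lines = lines), class = "cc_descent")
}

#' Write a founder variant catalogue as VCF
#'
#' Minimal VCFv4.2 with eight founder sample columns carrying
#' homozygous GT calls (0/0 or 1/1).
#' @param catalogue A `variant_catalogue`.
#' @param path Output file.
#' @export
write_founder_vcf <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "variant_catalogue"))
  sdp <- attr(catalogue, "sdp_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", CC_FOUNDERS), collapse = "\t")), con)
  for (v in seq_len(nrow(catalogue))) {
    gt <- ifelse(sdp[v, ] == 1, "1/1", "0/0")
    writeLines(paste(c(catalogue$chrom[v], catalogue$pos_bp[v],
                       sprintf("var%05d", v), catalogue$ref[v],
                       catalogue$alt[v], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a founder variant catalogue from VCF
#'
#' Requires the eight founder sample columns (matched by name; order is
#' normalized). Multiallelic records are skipped and counted.
#' Heterozygous founder calls (founders are inbred) are resolved by
#' majority over the called alleles, ties to reference, with a warning.
#' All-reference / all-alternate records are flagged monomorphic and
#' excluded from testing downstream.
#'
#' @param path VCF file.
#' @return A `variant_catalogue`; attribute `n_multiallelic` counts
#'   skipped records.
#' @export
read_variant_catalogue <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  missing_f <- setdiff(CC_FOUNDERS, colnames(gt))
  if (length(missing_f) > 0)
    ccq_stop("%s: missing founder sample(s) %s", path,
             paste(missing_f, collapse = ", "))
  gt <- gt[, CC_FOUNDERS, drop = FALSE]
  multi <- grepl(",", fx$ALT, fixed = TRUE)
  if (any(multi)) {
    fx <- fx[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  n <- nrow(fx)
  sdp <- matrix(0L, n, 8, dimnames = list(NULL, CC_FOUNDERS))
  het_seen <- FALSE
  for (i in seq_len(n)) for (j in 1:8) {
    al <- as.integer(strsplit(gt[i, j], "[/|]")[[1]])
    al <- al[!is.na(al)]
    if (length(al) == 0) { sdp[i, j] <- 0L; next }
    if (length(unique(al)) > 1) het_seen <- TRUE
    sdp[i, j] <- as.integer(mean(al) > 0.5)   # majority; tie -> reference
  }
  if (het_seen)
    ccq_warn("heterozygous founder call(s) resolved by majority rule")
  out <- data.frame(chrom = fx$CHROM,
                    pos_bp = as.numeric(fx$POS),
                    ref = fx$REF, alt = fx$ALT,
                    sdp = apply(sdp, 1, paste0, collapse = ""),
                    monomorphic = rowSums(sdp) %in% c(0L, 8L))
  attr(out, "sdp_matrix") <- sdp
  attr(out, "n_multiallelic") <- sum(multi)
  class(out) <- c("variant_catalogue", "data.frame")
  out
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based closed convention on read (via [rtracklayer::import()],
#' which performs the conversion to GRanges coordinates).
#'
#' @param path BED file (chrom, start, end, name, \[score, strand\]).
#' @return data.frame: `gene`, `chrom`, `start_bp`, `end_bp`, `strand`.
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    gene = if (!is.null(gr$name)) gr$name else as.character(seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Write a scan result as TSV
#'
#' Columns: chromosome, position (bp and Mb, 2 dp), logP, and the eight
#' founder effect columns.
#' @param scan A `scan_result`.
#' @param path Output file.
#' @export
write_scan_tsv <- function(scan, path) {
  eff <- attr(scan, "effects")
  df <- data.frame(chromosome = scan$chrom, position_bp = scan$pos_bp,
                   position_Mb = round(scan$pos_bp / 1e6, 2),
                   logP = scan$logP, check.names = FALSE)
  df <- cbind(df, as.data.frame(eff, check.names = FALSE))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
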