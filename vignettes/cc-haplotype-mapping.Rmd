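---
title: "Haplotype-based QTL mapping in Collaborative Cross panels with ccqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based QTL mapping in Collaborative Cross panels with ccqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the design

The Collaborative Cross (CC) is a panel of recombinant inbred mouse lines,
each a fixed mosaic of haplotypes from eight founder strains (A/J,
C57BL/6J, 129S1/SvImJ, NOD/LtJ, NZO/HiLtJ, CAST/EiJ, PWK/PhJ, WSB/EiJ).
Because every line is (nearly) homozygous, it can be phenotyped with
replicate animals, which separates line-level genetic variance from
within-line environmental variance and gives small panels surprising power
for complex traits such as bone microarchitecture.

`ccqtl` implements the full analysis chain for such panels:

1. **Cohort simulation** (`simulate_founder_panel`, `simulate_cc_lines`,
   `simulate_phenotypes`): genomes, founder-descent probabilities and
   replicated phenotypes with planted QTLs, so every downstream stage is
   testable without access to any animal data.
2. **Phenotype statistics** (`broad_sense_h2`, `line_mean_h2`,
   `covariate_anova`, `duncan_lsr`, `bh_fdr`, `welch_t_test`,
   `pairwise_trait_correlation`).
3. **Haplotype scans** (`scan_trait`, `genome_thresholds`, `call_qtls`,
   `regional_h2`, `founder_effects`, `allele_group_means`).
4. **Merge analysis** (`impute_dosages`, `merge_scan`,
   `shortlist_candidates`) for fine mapping with an ancestral variant
   catalogue.
5. **Location confidence intervals** (`simulate_ci`) by residual
   resampling.
6. **Expression linking** (`relative_expression`,
   `expression_phenotype_correlation`, `locus_expression_window`).

## The haplotype association test

At marker $m$, line $i$ carries a vector of founder-descent probabilities
$p_{i\cdot m}$ (8 entries summing to 1). For mouse $j$ of line $i$ the scan
compares

$$\text{null: } y_{ij} = X_{ij}\gamma + e_{ij}
\qquad\text{vs.}\qquad
\text{full: } y_{ij} = X_{ij}\gamma + \sum_{s=1}^{8} p_{ism}\beta_s + e_{ij},$$

where $X$ holds the covariates (sex, age, batch, month, season, year,
experimenter — all categorical shifts). One founder column (WSB/EiJ, the
wild-derived reference) is dropped for identifiability, so the test has 7
numerator degrees of freedom at a full-rank marker; the reported strength
is $\log P = -\log_{10}$ of the partial-F P value, capped at 50 to avoid
underflow. Founder effects are reported as deviations from WSB/EiJ with
standard errors from the coefficient covariance. This is the classical
fixed-effects version of the haplotype regression; Bayesian random-effect
shrinkage of founder effects is deliberately out of scope.

Rank-deficient markers (monomorphic descent, or descent columns aliased
with covariates) are flagged `degenerate` and get $\log P = 0$ with their
actual rank as the numerator df, never a silent crash.

### Genome-wide thresholds

Significance is calibrated by permutation: the assignment of haplotype
mosaics to lines is permuted, every mouse keeping its line-mates, its
covariates and its phenotype. This respects the line as the unit of
replication — mouse-level F statistics are strongly inflated by line
effects, and the permutation null carries exactly the same inflation, so
the genome-wide maxima are compared like with like. With 200 permutations
the 95th and 99th percentiles of the per-permutation maxima are the
cut-offs; we use the type-6 empirical percentile because the probability
that a fresh null scan exceeds that estimate matches the nominal level
(the default interpolation would give ~1.5% exceedance at the 99% level).
Calls at the 99% cut-off collapse super-threshold runs to their peak
marker (ties to the leftmost), merging runs separated by less than 2 Mb.

### Power profile

With 34 lines the 7-df test pays a real price: under permutation a random
marker's descent already "explains" a sizeable share of the 33 line-mean
degrees of freedom, so the genome-wide null maximum is high. A planted QTL
explaining 50% of line-mean variance is detected at the 99% cut-off in
only roughly 40–50% of replicates; detection becomes reliable (≥80%)
around a regional heritability of ~0.65–0.75, which matches the fact that
loci detected in panels of this size carry regional heritabilities of
~0.6 and above. The packaged power check therefore plants its QTL at
regional heritability 0.74, the median of the detected-locus range.

## Heritability

Broad-sense heritability uses the covariate-adjusted one-way ANOVA on the
line factor with expected mean squares,

$$\hat H^2 = \frac{MS_{line} - MS_{resid}}
                 {MS_{line} + (n_0 - 1)\,MS_{resid}},
\qquad n_0 = \frac{N - \sum_i n_i^2/N}{k - 1},$$

clipped to $[0,1]$; `logP` is the partial-F test of the line factor. The
line-mean heritability is $H^2_n = H^2 / (H^2 + (1 - H^2)/\bar n)$, the
reliability of a line mean at average replication $\bar n$; with
$\bar n = 5$ replicates, $H^2 \approx 0.5$–$0.65$ maps to
$H^2_n \approx 0.83$–$0.90$.

Regional heritability at a marker is the $R^2$ of the covariate-adjusted
line means on the descent matrix. Being a 7-df fit on $k$ line means it
overstates the truth by roughly $(1 - H^2_r)\cdot 7/(k-1)$ — about +0.06
at 34 lines — which is inherent to the definition and worth remembering
when comparing loci across panels of different size.

## Merge analysis

A biallelic variant with strain distribution pattern (SDP)
$a \in \{0,1\}^8$ is pushed through the mosaic:
$d_{iv} = 2\sum_s p_{ism(v)}\,a_s$, with $m(v)$ the variant's nearest
marker (the paper-gap choice; interval interpolation was rejected for
simplicity). The merge test adds this single dosage column to the
covariate null (1 df — CC lines are essentially homozygous, so no
dominance term). If the causal architecture truly is that variant, the
1-df test concentrates the signal and its $\log P$ exceeds the local 7-df
haplotype $\log P$; if the architecture is a founder-effect spectrum no
catalogued SDP can express, the ordering reverses. The candidate flag
implements exactly that comparison, and `shortlist_candidates` ranks genes
by their best in-window merge variant (overlap first, then nearest;
equidistant variants count for both genes and are flagged).

## Confidence intervals for QTL location

`simulate_ci` refits the full model at the observed peak, then builds
bootstrap phenotypes as fitted values plus resampled residuals, rescans
all markers within 10 Mb (half-width, tunable) of the peak, and takes
equal-tail quantiles of the simulated argmax positions as the 50/90/95%
intervals — nested by construction, and equal-tail rather than
highest-density so asymmetric peak distributions keep their skew.

Two numerical choices matter and were settled by measurement:

* **Residuals are resampled within line** (`within_line = TRUE`). The
  polygenic line deviations live in the peak-model residuals; pooling
  residuals across lines understates line-mean noise and produced 95%
  intervals covering the true position only ~84% of the time, versus ~91%
  with within-line resampling.
* **Exact ties are resolved uniformly.** Markers inside one mosaic
  segment carry identical descent profiles, so rescans tie exactly;
  taking the leftmost tied marker systematically displaced bootstrap
  peaks to plateau edges (coverage as low as 20% on unlucky maps). The
  peak is drawn uniformly over the tied set instead. `call_qtls` still
  reports the leftmost peak — a reporting convention, not a distribution.

In the zero-residual limit every bootstrap peak lands on the true marker
and all widths are exactly 0 — provided markers are distinguishable at
all; a marker sharing its profile with neighbours can only ever be
localized to the shared plateau.

## Duncan's least significance ranges

Line means are sorted descending; the range of a block of $p$ means is
compared with
$LSR_p = q_{(1-\alpha)^{p-1},\,p,\,df}\sqrt{MSE/n_h}$
(studentized range at Duncan's protection level, harmonic-mean
replication for unbalanced counts). A block is non-separable if its range
is within $LSR_p$ or if it sits inside a larger non-separable block;
maximal non-separable blocks share a letter. The display level follows
the panel convention $\alpha = 0.001$.

## What the synthetic cohorts do and do not emulate

The generator reproduces the statistical structure the analysis relies
on: eight-founder mosaics with a Poisson number of segments (default 8
expected segments per chromosome), residual heterozygosity as
two-founder segments (default 15%, i.e. 80–90% homozygosity, capped at
20%), descent probabilities blurred toward uniform by a sharpness knob
standing in for haplotype-reconstruction uncertainty, replicated mice
(default 5 per line, ~60% male) with categorical covariates, line-level
polygenic effects sized by `h2_line` (default 0.6, the observed range
being ~0.5–0.65), and planted QTLs whose line-level variance is an exact
stated fraction of line-mean variance. Default trait scale mimics
trabecular bone volume fraction (mean 10.2%, SD 5%).

It does **not** emulate: the funnel breeding pedigree, realistic
linkage-disequilibrium decay within segments (markers in one segment are
exchangeable), X-chromosome dosage, array genotyping error, or epistasis.
Passing tests therefore demonstrate correctness of the estimators and
calibration under the assumed generating process, not robustness to
array artefacts or pedigree structure.

Problem sizes used by the packaged checks — 34 lines × 5 replicates,
genomes of 100–200 markers, 200 permutations, 300 bootstrap rescans,
replicate counts of 40–250 — were chosen as the smallest sizes at which
the binomial noise of the measured rates is well inside the asserted
bounds.

## Degenerate inputs and numerical conventions

Positions are 1-based bp, closed intervals; BED input is converted on
read; reports print Mb to 2 decimals. Probability rows must sum to 1
(1e-9 in generated data, 1e-6 on file read, with the offending line and
marker named). Constant traits give $\log P = 0$ everywhere (a squared-norm
guard distinguishes true zero RSS from rounding dust); perfect fits hit
the cap; $\log P$ is invariant under affine rescaling of the trait.
Heterozygous founder VCF calls are resolved by majority with ties to
reference and a warning; multiallelic records are skipped and counted;
monomorphic variants are flagged and excluded from testing. In the
ddCt step, folds are rescaled by the reference line's mean fold so the
reference line's arithmetic mean is exactly 1 whatever its replication.

## Known limitations

* Fixed-effects founder coefficients are noisy where a founder is rare at
  a locus; the random-effects shrinkage used by some haplotype-mapping
  software is out of scope.
* Thresholds are conditional on the observed phenotype draw; they match
  the parametric F tail on average but can sit above or below it for a
  single cohort (that is what makes them calibrated).
* CI coverage of the 95% interval is ~91%, not 95%: the bootstrap centers
  on the observed argmax, and no resampling scheme removes that bias.
* Kinship among CC lines is ignored (lines are treated as exchangeable),
  and only autosomal, additive, single-trait architectures are simulated.
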