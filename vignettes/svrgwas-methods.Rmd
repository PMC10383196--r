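---
title: "Models and methods behind svrgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svrgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`svrgwas` implements a genome-wide association pipeline for plot-level
plant breeding trials — soybean seed-quality panels are the motivating
use case — with two complementary genome scans: FarmCPU, a conventional
multi-locus method, and an SVR-mediated scan that ranks SNPs by support
vector regression variable importance under a permutation-based
significance threshold. This vignette describes the statistical models,
the tunable parameters and their defaults, the synthetic-data generator
used for verification, and the numerical and design choices a user
should know about.

## From field plots to genotype values

### Spatial adjustment (first-order Papadakis)

Field trials carry smooth spatial variation (fertility gradients, soil
moisture) that inflates the residual variance if ignored. `nna_adjust()`
applies the classical Papadakis nearest-neighbour correction within each
environment:

1. compute each plot's residual from the additive
   randomized-complete-block fit (genotype mean + block mean − grand
   mean);
2. form a covariate as the mean residual of the plot's rook neighbours
   (same field row or column, within `neighborhood_radius` grid steps;
   default 1);
3. regress residuals on the covariate and subtract the fitted component
   from the raw value.

Removing genotype means *before* forming the neighbour covariate
matters: plot residuals from block means alone are dominated by genetic
variance, which carries no spatial information, and the regression slope
collapses toward zero. Even so, Papadakis adjustment removes only the
locally predictable share of the field trend; with two replicates per
environment a non-negligible share remains in the residual, which is
why heritability estimated from spatially noisy trials is biased
slightly downward. This is visible in the package's own recovery tests
(generator target 0.69, recovered means around 0.65 with the default
field-trend magnitude) and mirrors what practitioners see on real
trials.

### Outliers

`detect_outliers()` standardizes residuals from environment-block means
and sets values with `|z| > z_cut` (default 3.5) to missing, the common
pre-mixed-model screen. The default keeps the false-flag rate under
normality below about 5 per 10,000 plots.

### Mixed model, BLUPs and heritability

`fit_blup()` fits, by REML through `lme4`,

\[
y = \mu + \text{env} + \text{block(env)} + g + (g \times \text{env}) + \varepsilon,
\qquad g \sim N(0, \sigma^2_G),\;
g\times e \sim N(0, \sigma^2_{G\times E}),\;
\varepsilon \sim N(0, \sigma^2_E),
\]

with environments and blocks fixed and genotype and
genotype-by-environment random. One modelling note: a bare
"block + genotype + interaction" specification leaves the environment
main effect implicit; because each environment of a multi-location,
multi-year trial is an RCBD of its own, the package includes environment
as a fixed effect with blocks nested inside it. Per-genotype BLUPs
(`mu` plus the shrunken genotype effect) feed the genome scans.

Heritability is reported on the plot basis exactly as the variance
ratio

\[ H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_E}, \]

without dividing the residual by replicate or environment counts; the
entry-mean version
\(\sigma^2_G / (\sigma^2_G + \sigma^2_{G\times E}/n_E + \sigma^2_E/(n_E n_B))\)
is available behind the `entry_mean` flag for comparison with trial
reports that use it.

## Genotype quality control

`filter_samples()` (default: drop samples > 50% missing),
`filter_snps()` (defaults: per-SNP missingness > 20%, minor allele
frequency < 0.05 computed on non-missing calls, heterozygote fraction
> 50% — the standard GBS marker screens; a SNP failing several rules is
counted once, in the order missingness, MAF, heterozygosity), and
`impute_markov()` complete the matrix. Imputation walks each chromosome
left to right: a missing dosage is drawn from the empirical conditional
distribution of the current SNP given its left neighbour, estimated
from originally observed pairs only; left-most missing values come from
the marginal. This is a single-pass, first-order scheme — deliberately
simpler than haplotype-phasing imputers, adequate for dosage-level
scans, and deterministic given a seed. Observed calls are never
altered.

`ld_r2()` defines linkage disequilibrium as the squared Pearson
correlation of dosages; `ld_decay()` bins intra-chromosome pairs by
physical distance and reports the distance at which mean R² first falls
below half the first bin's mean (linearly interpolated; a fixed-level
alternative such as R² = 0.2 is available via `r2_threshold`). A panel
with no detectable LD never crosses the half-initial level, in which
case the decay distance is `NA` with a message rather than a fabricated
number.

## Population structure

`kinship_vanraden()` builds the method-1 VanRaden genomic relationship
matrix \(K = ZZ^\top / (2\sum_j p_j(1-p_j))\) from allele-frequency
centered dosages — the default choice of the mainstream GWAS stacks.
`structure_covariates()` provides the scan cofactors: the top `k − 1`
principal components of the centered dosage matrix (default `k = 7`,
a typical subpopulation count for diverse soybean panels), or an
imported admixture-proportion (Q) matrix matched by sample id with the
last column dropped against collinearity. Principal components are used
instead of a variational admixture model because the cofactor role in a
genome scan needs axes of genetic differentiation, not ancestry
estimates; externally computed Q matrices can be imported where
ancestry-model output is preferred.

## FarmCPU

FarmCPU circulates between two models. The fixed-effect model (FEM)
tests one SNP at a time with the current pseudo-QTNs as covariates:

\[
y_i = \sum_t C_{it} D_t + M_{ij} K_j + e_i ,
\]

where \(C_{it}\) are pseudo-QTN dosages with effects \(D_t\), and
\(M_{ij}\) is the tested SNP with effect \(K_j\); the p-value is the
two-sided t-test on \(K_j\) (plus intercept and structure covariates in
the design). Any pseudo-QTN within `bin_size_bp` of the tested SNP on
the same chromosome is excluded from the covariate set so a SNP is
never tested against itself; a SNP collinear with an included
pseudo-QTN gets p = 1 by convention, and constant-dosage SNPs are `NA`.

The random-effect model (REM) selects the pseudo-QTNs: SNPs are binned
by `(chromosome, position div bin_size)`, the lowest-p SNP represents
each bin, and for every cell of the `bin_sizes_bp x qtn_counts` grid
(defaults 500 kb / 5 Mb / 50 Mb by 5 / 10 / 15) the top representatives
define a VanRaden-style kinship whose single-random-effect REML
likelihood \(y_i = u_i + e_i\), \(\operatorname{var}(u) \propto K\),
scores the cell. The best cell's representatives become the next FEM's
covariates; iteration stops when the set repeats (cycle detection
against all previous sets) or after `max_iterations` (default 10).

Two entry thresholds guard calibration, both following the reference
FarmCPU conventions: a bin representative must beat
`qtn_p_threshold` (default 0.01) to be a candidate at all, and the
iteration beyond the plain scan only starts when the first scan's
minimum p-value beats `p_threshold` (default `0.01 / m`). Without the
gate, top-ranked null SNPs absorbed as covariates deflate the residual
and inflate every remaining t-statistic — the package's null
calibration test fails visibly if the gate is removed. Significance is
declared by Benjamini–Hochberg FDR (default q = 0.05) on the final
scan; `NA` p-values are excluded from the ranking.

## SVR-mediated GWAS

The SVR scan treats association as variable importance in the
epsilon-SVR model \(Y = W\beta(c) + b\). With the (default) linear
kernel the primal weight vector is recovered from the dual solution,
\(w = \sum_i \alpha_i x_i\), and the per-SNP importance is \(|w_j|\),
averaged over `n_folds x n_repeats` cross-validation training fits
(defaults 5 x 10). For the RBF kernel, where no primal weight exists,
importance is the root-mean-square kernel gradient
\(\partial f/\partial x_j\) over training points. Dosage columns and
the phenotype are standardized internally; zero-variance SNPs get
importance 0 with a warning. Importance is then affinely mapped to
0–100 (`scale_importance()`).

Because importance scores have no null distribution in closed form,
significance uses a global empirical (max-statistic) threshold:
permute the phenotype, refit, record the maximum importance over SNPs,
repeat `n_permutations` times (default 1000), and cut at the
`(1 − alpha)` empirical quantile (default alpha 0.05). Two conventions
matter and are deliberate:

* **One scale.** Null maxima are kept on the raw importance scale and
  mapped through the original (unpermuted) min–max scaling. Rescaling
  each permutation to 0–100 would force every null maximum to 100 and
  destroy the threshold.
* **Permutation economy vs exchangeability.** By default each
  permutation uses one full-data fit (`perm_cv = FALSE`) — cheap, and
  conservative, because the observed statistic is a CV average whose
  maxima are noise-shrunken relative to single-fit maxima. With
  `perm_cv = TRUE` every permutation recomputes the full
  cross-validated importance, making permuted and observed statistics
  exchangeable, hence exact family-wise error control at level alpha.
  The package's calibration and power studies run with
  `perm_cv = TRUE` and matched repeat counts for exactly this reason;
  the economy mode is appropriate when a conservative screen is
  acceptable.

Computation: the solver is `kernlab::ksvm` on a precomputed Gram
matrix. The kernel depends only on the genotypes, so it is computed
once per dataset and sub-indexed for every fold and permutation; this
is what makes thousand-fold permutation studies tractable. Solver
hyperparameters default to C = 1 and epsilon = 0.1 on the standardized
phenotype scale.

## QTL regions and co-localization

Significant SNPs are clumped around local peaks (`peak_select()`): the
best-statistic SNP absorbs all significant SNPs within
`cluster_window_bp` (default 150 kb) on its chromosome, then the
procedure repeats — so every significant SNP lies within the window of
its peak. `flanking_regions()` builds `[peak − window, peak + window)`
regions (clipped at zero, default window 150 kb, a flank of the scale
suggested by LD decay in soybean panels; `ld_decay()` lets you
recompute it from your own data) and merges same-chromosome overlaps.
`allelic_effect()` reports the per-allele regression slope and
dosage-class means for any peak SNP. `colocalize()` intersects regions
with user-supplied annotations (BED or GFF3 via `rtracklayer`) under
the half-open `[start, end)` convention; positions are 1-based
(VCF/HapMap convention) everywhere inside the package, with the
half-open convention applied at interval arithmetic and BED export.

## The synthetic-data generator

`simulate_genotypes()` and `simulate_phenotypes()` generate panels with
known truth so that calibration, power and recovery are checkable:

* **Allele frequencies**: ancestral MAFs uniform in `maf_range`
  (default 0.05–0.5), drifted per subpopulation by the Balding–Nichols
  Beta model at the configured `fst` (default 0.15, 7 subpopulations —
  a panel of distinct breeding-program origins).
* **LD**: a first-order haplotype copy chain — each SNP copies the
  previous SNP's allele with probability `ld_rho` (default 0.9),
  otherwise draws fresh. The chain has a closed form: haplotype
  correlation at lag d is `ld_rho^d`, so dosage-level mean R² at lag d
  is `ld_rho^(2d)`. This is deliberately not a coalescent: the closed
  form is what makes the LD tests exact. Note the chain correlates
  SNPs by *index*, not by physical distance, so base-pair LD decay
  reflects the SNP density you configure.
* **Phenotypes**: `n_qtl` planted additive QTL with N(0,
  `qtl_effect_sd`²) effects (optionally diluted to a fraction
  `qtl_var_frac` of the genetic variance, the rest spread over non-QTL
  SNPs as polygenic background); residual variance scaled so that the
  plot-basis ratio σ²G/(σ²G+σ²E) equals `h2_target` *exactly* in the
  generating model; genotype-by-environment effects at
  `gxe_ratio x σ²G` (default 0.25, a conventional magnitude — trial
  reports rarely publish one); block effects and a smooth spatial
  field (low-order polynomial plus AR(1)-style row noise) whose
  magnitudes are expressed as multiples of the residual SD
  (`block_sd = 0.25`, `spatial_sd = 0.5`), keeping the variance
  contract scale-free.

What the generator does *not* emulate: coalescent LD structure,
selection, dominance and epistasis, genotyping error, sequencing reads,
and trait-specific error distributions. Passing tests therefore
demonstrate statistical correctness of the machinery under a known,
idealized generating model — not performance guarantees on any
particular real panel.

## Verification design and problem sizes

The test suite checks each operation against an independent oracle
(per-SNP OLS for the FEM scan, method-of-moments ANOVA for balanced
REML, an alternative SVR solver for the dual weights, brute-force
enumeration for filters, BH, interval merging and overlap), and the
statistical properties at these scales, chosen to finish on a single
CPU in well under half an hour:

* oracle equivalence: 100 genotypes x 500 SNPs;
* FarmCPU null calibration: 200 null panels of 100 x 500 at BH q = 0.05;
* SVR null calibration: 100 null panels of 100 x 300, 200 permutations,
  alpha = 0.05, with matched 2-fold cross-validation on both sides of
  the permutation comparison (exchangeability holds for any matched
  scheme, so the cheapest one is used);
* heritability recovery: 30 panels at the default trial geometry
  (227 genotypes, 4 environments, 2 blocks, target 0.69);
* power: 20 panels of 250 x 2000 with 5 QTL carrying 40% of the
  genetic variance at h² = 0.7, scanned by both methods with the
  five-fold, ten-repeat CV protocol and 60 matched permutations;
* determinism: the full pipeline run twice at 227 x 2000 must be
  byte-identical.

`scripts/acceptance.R` recomputes the same quantities from scratch at
reduced replicate counts and writes them as JSON.

## Known limitations

* The Papadakis adjustment is single-pass; iterated variants recover
  slightly more spatial variance.
* The REM likelihood grid refits a small eigendecomposition per cell;
  for panels far beyond ~10⁴ SNPs and ~10³ samples the FarmCPU scan is
  the dominant cost and would benefit from compiled code.
* The copy-chain LD model makes index-lag, not physical-distance, the
  natural LD unit.
* The SVR importance is a ranking statistic; its scale depends on C,
  epsilon and standardization, which is why significance is defined
  only through the permutation threshold, never by an absolute cutoff.
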