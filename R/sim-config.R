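#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator: a
#' soybean-scale association panel (a few hundred inbred-ish genotypes,
#' thousands of SNPs on 20 chromosomes, 4-7 subpopulations) phenotyped in a
#' multi-environment randomized complete block trial with spatial field
#' trends, planted additive QTL and genotype-by-environment interaction.
#'
#' @param n_genotypes Number of genotypes (panel size). Default 227.
#' @param n_snps Total number of SNPs across the genome. Default 2000.
#' @param n_chromosomes Number of chromosomes. Default 20.
#' @param chrom_length_bp Length of each chromosome in base pairs.
#' @param maf_range Length-2 numeric in (0, 0.5]: ancestral minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param ld_rho Copy probability in `[0, 1)` of the first-order haplotype
#'   copy chain: along a chromosome each SNP copies the previous SNP's
#'   allele with probability `ld_rho`, giving geometric LD decay
#'   (`r ~ ld_rho^lag` at the haplotype level).
#' @param n_subpops Number of subpopulations. Default 7, matching the
#'   typical K chosen for diverse soybean panels.
#' @param fst Balding-Nichols differentiation among subpopulations, in
#'   `[0, 1)`.
#' @param n_qtl Number of planted additive QTL per trait.
#' @param qtl_effect_sd Standard deviation of per-QTL additive effects
#'   (arbitrary trait units; only ratios matter, see `h2_target`).
#' @param qtl_var_frac Fraction of the genetic variance carried by the
#'   planted QTL; the remainder is spread as a polygenic background over
#'   non-QTL SNPs. Default 1 (no background).
#' @param h2_target Plot-basis heritability sigma2_G / (sigma2_G +
#'   sigma2_E) of the generating model, strictly inside (0, 1). The
#'   residual variance is scaled so this ratio holds exactly.
#' @param n_envs Number of environments (location x year combinations).
#' @param n_blocks Number of complete blocks (replicates) per environment.
#' @param gxe_ratio Genotype-by-environment variance as a fraction of the
#'   genetic variance (sigma2_GxE = gxe_ratio * sigma2_G). Default 0.25.
#' @param block_sd Block-effect standard deviation as a multiple of the
#'   residual SD. Default 0.25.
#' @param spatial_sd Field-trend standard deviation as a multiple of the
#'   residual SD; 0 disables the trend. Default 0.5.
#' @param missing_rate Fraction of genotype calls set to missing by
#'   [inject_missing()], in `[0, 1)`.
#' @param seed Integer RNG seed; every generator is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 50, n_snps = 200, seed = 1)
#' cfg$n_subpops
sim_config <- function(n_genotypes = 227,
                       n_snps = 2000,
                       n_chromosomes = 20,
                       chrom_length_bp = 5e7,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.9,
                       n_subpops = 7,
                       fst = 0.15,
                       n_qtl = 10,
                       qtl_effect_sd = 1,
                       qtl_var_frac = 1,
                       h2_target = 0.69,
                       n_envs = 4,
                       n_blocks = 2,
                       gxe_ratio = 0.25,
                       block_sd = 0.25,
                       spatial_sd = 0.5,
                       missing_rate = 0,
                       seed = NULL) {
  cfg <- list(
    n_genotypes = as.integer(n_genotypes), n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    maf_range = as.numeric(maf_range), ld_rho = as.numeric(ld_rho),
    n_subpops = as.integer(n_subpops), fst = as.numeric(fst),
    n_qtl = as.integer(n_qtl), qtl_effect_sd = as.numeric(qtl_effect_sd),
    qtl_var_frac = as.numeric(qtl_var_frac),
    h2_target = as.numeric(h2_target),
    n_envs = as.integer(n_envs), n_blocks = as.integer(n_blocks),
    gxe_ratio = as.numeric(gxe_ratio), block_sd = as.numeric(block_sd),
    spatial_sd = as.numeric(spatial_sd),
    missing_rate = as.numeric(missing_rate),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genotypes", "n_snps", "n_chromosomes", "n_subpops",
              "n_envs", "n_blocks")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) abort(sprintf("`%s` must be >= 1.", f))
  }
  if (cfg$n_qtl < 0L) abort("`n_qtl` must be >= 0.")
  if (cfg$n_snps < cfg$n_chromosomes) {
    abort("`n_snps` must be at least `n_chromosomes` (>= 1 SNP per chromosome).")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2]) {
    abort("`maf_range` must be an interval within (0, 0.5].")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) abort("`ld_rho` must be in [0, 1).")
  if (cfg$fst < 0 || cfg$fst >= 1) abort("`fst` must be in [0, 1).")
  if (cfg$h2_target <= 0 || cfg$h2_target >= 1) {
    abort("`h2_target` must be strictly inside (0, 1).")
  }
  if (cfg$qtl_var_frac <= 0 || cfg$qtl_var_frac > 1) {
    abort("`qtl_var_frac` must be in (0, 1].")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d genotypes x %d SNPs (%d chromosomes), ",
           "%d subpops (Fst %.2f), LD rho %.2f\n",
           "  %d QTL, h2 target %.2f, %d envs x %d blocks\n"),
    x$n_genotypes, x$n_snps, x$n_chromosomes, x$n_subpops, x$fst, x$ld_rho,
    x$n_qtl, x$h2_target, x$n_envs, x$n_blocks
  ))
  invisible(x)
}
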