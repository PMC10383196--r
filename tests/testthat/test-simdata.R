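test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_genotypes = 0), ">= 1")
  expect_error(sim_config(n_snps = 5, n_chromosomes = 10), "n_chromosomes")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(h2_target = 1), "h2_target")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("genotype simulation is reproducible and respects the dosage domain", {
  cfg <- sim_config(n_genotypes = 40, n_snps = 120, n_chromosomes = 3,
                    seed = 5)
  g1 <- simulate_genotypes(cfg)$genotypes
  g2 <- simulate_genotypes(cfg)$genotypes
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$snp_info, g2$snp_info)
  expect_true(all(g1$dosages %in% 0:2))
  expect_true(all(tapply(g1$snp_info$pos, g1$snp_info$chrom,
                         function(p) all(diff(p) > 0))))
})

test_that("realized minor allele frequencies stay near the configured range", {
  cfg <- sim_config(n_genotypes = 300, n_snps = 400, n_chromosomes = 4,
                    maf_range = c(0.2, 0.4), n_subpops = 1, fst = 0,
                    ld_rho = 0, seed = 8)
  g <- simulate_genotypes(cfg)$genotypes
  maf <- pmin(colMeans(g$dosages) / 2, 1 - colMeans(g$dosages) / 2)
  se <- sqrt(0.25 / (2 * 300))
  expect_true(all(maf >= 0.2 - 3 * se - 0.02))
  expect_true(all(maf <= 0.4 + 3 * se + 0.02))
})

test_that("ld_rho = 0 gives uncorrelated adjacent SNPs", {
  cfg <- sim_config(n_genotypes = 400, n_snps = 200, n_chromosomes = 2,
                    ld_rho = 0, n_subpops = 1, fst = 0, seed = 3)
  g <- simulate_genotypes(cfg)$genotypes
  rs <- sapply(seq_len(199)[-100], function(j)
    cor(g$dosages[, j], g$dosages[, j + 1]))
  expect_lt(mean(abs(rs)), 3 / sqrt(400))
})

test_that("copy-chain LD follows the geometric closed form", {
  # haplotype-level correlation at lag d is ld_rho^d, so dosage-level
  # mean r at lag d matches rho^d within Monte-Carlo tolerance
  cfg <- sim_config(n_genotypes = 1000, n_snps = 150, n_chromosomes = 1,
                    ld_rho = 0.9, n_subpops = 1, fst = 0, seed = 13)
  g <- simulate_genotypes(cfg)$genotypes
  for (lag in c(1, 2, 5)) {
    rs <- sapply(seq_len(150 - lag), function(j) {
      d1 <- g$dosages[, j]; d2 <- g$dosages[, j + lag]
      if (sd(d1) == 0 || sd(d2) == 0) return(NA)
      cor(d1, d2)
    })
    rs <- rs[!is.na(rs)]
    mc_se <- sd(rs) / sqrt(length(rs))
    expect_lt(abs(mean(rs) - 0.9^lag), 3 * mc_se + 0.01)
  }
})

test_that("phenotype generating model hits the target variance ratio exactly", {
  cfg <- sim_config(n_genotypes = 100, n_snps = 200, n_chromosomes = 2,
                    n_qtl = 5, h2_target = 0.69, seed = 21)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$genotypes, cfg)
  tr <- ph$truth
  expect_equal(tr$sigma2_g / (tr$sigma2_g + tr$sigma2_e), 0.69,
               tolerance = 1e-12)
  expect_equal(length(tr$qtl_snp_indices), length(tr$qtl_effects))
  expect_equal(unname(tr$genetic_values),
               unname(drop(
                 sim$genotypes$dosages[, tr$qtl_snp_indices] %*%
                   tr$qtl_effects) -
                   mean(sim$genotypes$dosages[, tr$qtl_snp_indices] %*%
                          tr$qtl_effects)))
})

test_that("null heritability: no QTL means near-zero estimated H2", {
  cfg <- sim_config(n_genotypes = 200, n_snps = 100, n_chromosomes = 2,
                    n_qtl = 0, n_envs = 4, seed = 31)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$genotypes, cfg)
  b <- fit_blup(ph$phenotypes)
  expect_lt(b$h2, 0.1)
})

test_that("high heritability: BLUPs track true genetic values", {
  cfg <- sim_config(n_genotypes = 200, n_snps = 150, n_chromosomes = 2,
                    n_qtl = 10, h2_target = 0.95, gxe_ratio = 0.05,
                    spatial_sd = 0.2, seed = 33)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$genotypes, cfg)
  b <- fit_blup(ph$phenotypes)
  g_true <- ph$truth$genetic_values[b$blups$genotype_id]
  expect_gt(cor(b$blups$blup, g_true), 0.95)
})

test_that("spatial_sd = 0 leaves only block and residual structure", {
  cfg <- sim_config(n_genotypes = 50, n_snps = 60, n_chromosomes = 2,
                    spatial_sd = 0, n_envs = 1, n_blocks = 2, seed = 41)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$genotypes, cfg)
  tr <- ph$truth
  # within genotype x env, the two block values differ by block effect
  # plus iid noise: the across-genotype variance of that difference is
  # 2 * sigma2_e (block effect is common to all genotypes in a block)
  w <- tidyr::pivot_wider(ph$phenotypes,
                          id_cols = "genotype_id",
                          names_from = "block_id",
                          values_from = "value")
  d <- w$block1 - w$block2
  expect_lt(abs(var(d) - 2 * tr$sigma2_e) / (2 * tr$sigma2_e), 0.45)
})

test_that("inject_missing masks the expected fraction, reproducibly", {
  g <- quick_panel(50, 200, seed = 2)
  expect_identical(inject_missing(g, 0), g)
  gm1 <- inject_missing(g, 0.2, seed = 9)
  gm2 <- inject_missing(g, 0.2, seed = 9)
  expect_identical(gm1$dosages, gm2$dosages)
  n_na <- sum(is.na(inject_missing(g, 0.5, seed = 4)$dosages))
  n_tot <- length(g$dosages)
  # binomial 99% bounds
  expect_gt(n_na, n_tot * 0.5 - 2.58 * sqrt(n_tot * 0.25))
  expect_lt(n_na, n_tot * 0.5 + 2.58 * sqrt(n_tot * 0.25))
  expect_error(inject_missing(g, 1), "missing_rate")
})
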