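test_that("sample filter removes exactly the high-missing samples", {
  g <- rand_geno(20, 50, seed = 1)
  expect_identical(filter_samples(g)$dosages, g$dosages)     # no missing
  d <- g$dosages
  d[3, 1:30] <- NA_integer_                                   # 60% missing
  gm <- geno_from(d)
  out <- filter_samples(gm, 0.5)
  expect_equal(n_samples(out), 19)
  expect_false("i3" %in% out$sample_ids)
  expect_equal(qc_report(out)$n_samples_removed, 1L)
  expect_equal(n_samples(filter_samples(gm, 1.0)), 20)
  allmiss <- geno_from(matrix(NA_integer_, 3, 4))
  expect_error(filter_samples(allmiss, 0.5), "All samples")
})

test_that("SNP filters apply the MAF, heterozygosity and missingness rules", {
  # SNP1: MAF 0.02 (96 x 0, 4 x 1 in 100) -> removed
  # SNP2: 51 heterozygotes of 100 -> removed
  # SNP3: monomorphic -> removed (MAF 0)
  # SNP4: healthy
  d <- cbind(
    c(rep(0L, 96), rep(1L, 4)),
    c(rep(1L, 51), rep(0L, 25), rep(2L, 24)),
    rep(0L, 100),
    rep(c(0L, 1L, 2L), length.out = 100)
  )
  g <- geno_from(d)
  out <- filter_snps(g, maf_min = 0.05, max_het = 0.5, max_missing = 0.2)
  expect_equal(out$snp_info$snp_id, "s4")
  rep <- qc_report(out)
  expect_equal(rep$n_snps_removed_maf, 2L)   # SNP1 and monomorphic SNP3
  expect_equal(rep$n_snps_removed_het, 1L)
  expect_error(filter_snps(geno_from(matrix(0L, 10, 2))), "All SNPs")
})

test_that("filters match a brute-force recount on random matrices", {
  for (s in 1:15) {
    g <- rand_geno(30, 40, seed = 100 + s, miss = 0.15)
    d <- g$dosages
    # brute force, same precedence: missing -> MAF -> het
    keep <- logical(40)
    nm <- im <- hm <- 0
    for (j in 1:40) {
      v <- d[, j]
      fm <- mean(is.na(v)) > 0.2
      p <- mean(v, na.rm = TRUE) / 2
      fa <- !fm && (min(p, 1 - p) < 0.05)
      fh <- !fm && !fa && mean(v == 1, na.rm = TRUE) > 0.5
      keep[j] <- !(fm || fa || fh)
      nm <- nm + fm; im <- im + fa; hm <- hm + fh
    }
    out <- filter_snps(g, 0.05, 0.5, 0.2)
    expect_equal(out$snp_info$snp_id, paste0("s", which(keep)))
    rep <- qc_report(out)
    expect_equal(rep$n_snps_removed_missing, nm)
    expect_equal(rep$n_snps_removed_maf, im)
    expect_equal(rep$n_snps_removed_het, hm)
  }
})

test_that("Markov imputation completes the matrix without touching observed calls", {
  g <- rand_geno(40, 60, seed = 7)
  expect_identical(impute_markov(g)$dosages, g$dosages)       # complete input
  gm <- inject_missing(g, 0.15, seed = 8)
  obs <- !is.na(gm$dosages)
  out1 <- impute_markov(gm, seed = 3)
  out2 <- impute_markov(gm, seed = 3)
  expect_identical(out1$dosages, out2$dosages)                # determinism
  expect_false(anyNA(out1$dosages))
  expect_true(all(out1$dosages %in% 0:2))
  expect_identical(out1$dosages[obs], gm$dosages[obs])
  expect_equal(qc_report(out1)$n_imputed, sum(!obs))
})

test_that("imputation follows a degenerate conditional distribution exactly", {
  # two perfectly correlated adjacent SNPs; missing at the second must
  # copy the first
  set.seed(5)
  a <- sample(0:2, 50, replace = TRUE)
  d <- cbind(a, a)
  d[1:10, 2] <- NA_integer_
  out <- impute_markov(geno_from(d), seed = 1)
  expect_equal(unname(out$dosages[1:10, 2]), a[1:10])
})

test_that("imputation errors on a SNP with no observations", {
  d <- matrix(c(0L, 1L, NA, NA), 2, 2)
  expect_error(impute_markov(geno_from(d)), "zero complete observations")
})

test_that("imputed marginal frequencies track the observed ones", {
  g <- quick_panel(150, 100, seed = 10)
  gm <- inject_missing(g, 0.3, seed = 11)
  out <- impute_markov(gm, seed = 12)
  p_obs <- colMeans(gm$dosages, na.rm = TRUE) / 2
  p_imp <- colMeans(out$dosages) / 2
  se <- sqrt(p_obs * (1 - p_obs) / (2 * 150))
  expect_true(all(abs(p_imp - p_obs) <= 3 * se + 0.02))
})

test_that("ld_r2 is the squared dosage correlation with its invariances", {
  d <- cbind(rep(0:2, 20), rep(0:2, 20))
  d[, 2] <- sample(d[, 2])
  g <- geno_from(d)
  expect_equal(ld_r2(g, 1, 1), 1)
  # allele flip invariance
  gf <- geno_from(cbind(d[, 1], 2L - d[, 2]))
  expect_equal(ld_r2(g, 1, 2), ld_r2(gf, 1, 2))
  expect_equal(ld_r2(g, 1, 2), ld_r2(g, 2, 1))
  # hand-computable zero: (0,1,2,0,1,2) vs (0,1,2,2,1,0)
  gz <- geno_from(cbind(c(0L, 1L, 2L, 0L, 1L, 2L),
                        c(0L, 1L, 2L, 2L, 1L, 0L)))
  expect_equal(ld_r2(gz, 1, 2), 0)
  mono <- geno_from(cbind(rep(1L, 10), rep(0:1, 5)))
  expect_error(ld_r2(mono, 1, 2), "zero dosage variance")
})

test_that("ld_decay: no LD gives a flat near-zero curve with no decay point", {
  cfg <- sim_config(n_genotypes = 300, n_snps = 150, n_chromosomes = 2,
                    ld_rho = 0, n_subpops = 1, fst = 0, seed = 15)
  g <- simulate_genotypes(cfg)$genotypes
  ld <- suppressMessages(ld_decay(g, max_dist_bp = 2e7, n_bins = 10))
  expect_true(all(ld$curve$mean_r2 < 0.05, na.rm = TRUE))
  expect_true(is.na(ld$decay_distance_bp))
})

test_that("ld_decay detects strong local LD from duplicated columns", {
  set.seed(16)
  base <- matrix(sample(0:2, 80 * 10, replace = TRUE), 80, 10)
  d <- cbind(base, base[, 10])                  # duplicate at 1 kb away
  pos <- c(seq_len(10) * 100000L, 10L * 100000L + 1000L)
  g <- geno_from(d, pos = pos)
  ld <- suppressMessages(ld_decay(g, max_dist_bp = 1e6, n_bins = 10))
  first_bin <- ld$curve$mean_r2[1]      # contains the duplicated pair
  expect_gt(first_bin, mean(ld$curve$mean_r2[-1], na.rm = TRUE))
})

test_that("ld_decay reproduces the copy-chain geometric curve", {
  cfg <- sim_config(n_genotypes = 500, n_snps = 200, n_chromosomes = 1,
                    chrom_length_bp = 2e6, ld_rho = 0.8, n_subpops = 1,
                    fst = 0, seed = 17)
  g <- simulate_genotypes(cfg)$genotypes
  ld <- ld_decay(g, max_dist_bp = 1e6, n_bins = 10)
  expect_false(is.na(ld$decay_distance_bp))
  # mean r2 at lag 1 (expected rho^2) exceeds the far-distance mean
  expect_gt(ld$curve$mean_r2[1], ld$curve$mean_r2[10])
})
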