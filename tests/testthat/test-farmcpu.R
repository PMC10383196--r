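test_that("iteration-1 scan equals the independent OLS oracle", {
  g <- quick_panel(80, 150, seed = 1, n_subpops = 1, fst = 0)
  set.seed(2)
  y <- rnorm(80)
  scan <- fem_scan(g, y)
  for (j in sample(150, 25)) {
    d <- g$dosages[, j]
    if (sd(d) == 0) {
      expect_true(is.na(scan$pvalue[j]))
    } else {
      sm <- summary(lm(y ~ d))$coefficients
      expect_equal(scan$pvalue[j], sm["d", 4], tolerance = 1e-8)
      expect_equal(scan$effect[j], sm["d", 1], tolerance = 1e-8)
    }
  }
  # and with structure covariates in the design
  Q <- structure_covariates(g, k = 3)
  scan2 <- fem_scan(g, y, covariates = Q)
  j <- which(apply(g$dosages, 2, sd) > 0)[1]
  sm2 <- summary(lm(y ~ Q + g$dosages[, j]))$coefficients
  expect_equal(scan2$pvalue[j], sm2[nrow(sm2), 4], tolerance = 1e-8)
})

test_that("null p-values are uniform", {
  g <- quick_panel(100, 500, n_chrom = 10, seed = 5, n_subpops = 1,
                   fst = 0, ld_rho = 0)
  set.seed(6)
  y <- rnorm(100)
  scan <- fem_scan(g, y)
  p <- scan$pvalue[!is.na(scan$pvalue)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate SNPs are flagged, duplicates of pseudo-QTNs get p = 1", {
  d <- cbind(rep(1L, 40), matrix(sample(0:2, 40 * 9, TRUE), 40, 9))
  d[, 5] <- d[, 2]                       # duplicate of SNP 2
  # place the duplicate on another chromosome so it is not excluded
  g <- geno_from(d, chrom = rep(c("chr01", "chr02"), each = 5))
  set.seed(7)
  y <- rnorm(40)
  scan <- fem_scan(g, y, pseudo_qtns = 2L, bin_size_bp = 1000)
  expect_true(is.na(scan$pvalue[1]))     # constant dosage
  expect_equal(scan$pvalue[5], 1)        # collinear with pseudo-QTN 2
})

test_that("p-values are invariant under affine dosage recoding", {
  g <- quick_panel(50, 40, seed = 8, n_subpops = 1, fst = 0)
  set.seed(9)
  y <- rnorm(50)
  p1 <- fem_scan(g, y)$pvalue
  gflip <- geno_from(2L - g$dosages, pos = g$snp_info$pos,
                     chrom = g$snp_info$chrom)
  p2 <- fem_scan(gflip, y)$pvalue
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("binning keeps one representative per bin, lowest p first", {
  # two SNPs in one 1 Mb bin, a third in another
  d <- matrix(sample(0:2, 60 * 3, TRUE), 60, 3)
  g <- geno_from(d, pos = c(100000L, 200000L, 1500000L))
  set.seed(10)
  y <- rnorm(60)
  cfg <- farmcpu_config(bin_sizes_bp = 1e6, qtn_counts = 2,
                        qtn_p_threshold = 1)
  pv <- c(0.004, 0.001, 0.009)
  sel <- rem_select(g, y, pv, cfg)
  expect_setequal(as.integer(sel), c(2L, 3L))   # SNP2 beats SNP1 in bin 1
})

test_that("a planted strong QTL is selected as pseudo-QTN", {
  hits <- sapply(1:10, function(r) {
    g <- quick_panel(120, 200, n_chrom = 4, seed = 20 + r,
                     n_subpops = 1, fst = 0, ld_rho = 0)
    j <- 77L
    set.seed(40 + r)
    d <- g$dosages[, j]
    y <- sqrt(0.3 / var(d)) * d + rnorm(120, 0, sqrt(0.7))
    scan <- fem_scan(g, y)
    sel <- suppressWarnings(rem_select(g, y, scan$pvalue, farmcpu_config()))
    j %in% sel
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Benjamini-Hochberg set matches the hand computation", {
  expect_equal(fdr_threshold(c(0.01, 0.02, 0.2), q = 0.05), c(1L, 2L))
  expect_equal(fdr_threshold(rep(1, 5), q = 0.05), integer(0))
  expect_equal(fdr_threshold(c(0.5, NA, 0.2), q = 1), c(1L, 3L))
  expect_error(fdr_threshold(numeric(0)), "Empty")
  # brute-force step-up oracle on random inputs
  set.seed(31)
  for (s in 1:20) {
    p <- runif(30)^2
    q <- 0.1
    o <- order(p)
    k <- which(p[o] <= q * seq_along(p) / length(p))
    oracle <- if (length(k) == 0) integer(0) else sort(o[seq_len(max(k))])
    expect_equal(sort(fdr_threshold(p, q)), oracle)
  }
})

test_that("max_iterations = 1 reduces to the plain covariate-adjusted scan", {
  g <- quick_panel(60, 80, seed = 33, n_subpops = 1, fst = 0)
  set.seed(34)
  y <- rnorm(60)
  plain <- fem_scan(g, y)
  fit <- suppressWarnings(
    farmcpu_run(g, y, farmcpu_config(max_iterations = 1)))
  expect_equal(fit$results$pvalue, plain$pvalue)
  expect_equal(fit$n_iterations, 1L)
})

test_that("a large-effect QTL is declared significant and sharpened by iteration", {
  wins <- sapply(1:10, function(r) {
    g <- quick_panel(150, 300, n_chrom = 6, seed = 50 + r,
                     n_subpops = 1, fst = 0, ld_rho = 0.3)
    j <- 123L
    set.seed(70 + r)
    d <- g$dosages[, j]
    y <- sqrt(0.5 / var(d)) * d + rnorm(150, 0, sqrt(0.5))
    fit <- suppressWarnings(farmcpu_run(g, y))
    plain <- fem_scan(g, y)
    c(sig = fit$results$significant[j],
      sharper = fit$results$pvalue[j] <= plain$pvalue[j])
  })
  expect_gte(mean(wins["sig", ]), 0.9)
  expect_gte(mean(wins["sharper", ]), 0.9)
})

test_that("phenotypes align by genotype id, misalignment errors", {
  g <- quick_panel(30, 40, seed = 60)
  y <- rnorm(30)
  names(y) <- rev(g$sample_ids)        # scrambled names get realigned
  s1 <- fem_scan(g, y)
  s2 <- fem_scan(g, unname(y[g$sample_ids]))
  expect_equal(s1$pvalue, s2$pvalue)
  expect_error(fem_scan(g, y[-1]), "missing for sample")
  expect_error(fem_scan(g, rnorm(29)), "length")
})
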