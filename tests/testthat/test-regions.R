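sig_tbl <- function(pos, score = NULL, chrom = "chr01") {
  tibble::tibble(
    snp_id = paste0("s", seq_along(pos)), chrom = chrom,
    pos = as.integer(pos),
    score = score %||% rev(seq_along(pos))
  )
}

test_that("peak clustering follows the window rule", {
  one <- peak_select(sig_tbl(500000), 150000)
  expect_equal(nrow(one), 1)
  expect_equal(one$snp_id, "s1")
  # 10 kb apart, 150 kb window -> one peak (the better score)
  two_close <- peak_select(sig_tbl(c(500000, 510000), score = c(3, 8)),
                           150000)
  expect_equal(nrow(two_close), 1)
  expect_equal(two_close$snp_id, "s2")
  expect_equal(two_close$n_member_snps, 2L)
  # 400 kb apart -> two peaks
  two_far <- peak_select(sig_tbl(c(500000, 900000)), 150000)
  expect_equal(nrow(two_far), 2)
  # score tie broken by lower position
  tie <- peak_select(sig_tbl(c(100000, 120000), score = c(5, 5)), 150000)
  expect_equal(tie$pos, 100000L)
})

test_that("empty significant set yields an empty peak table, not an error", {
  g <- quick_panel(30, 20, seed = 2)
  set.seed(3)
  fit <- suppressWarnings(farmcpu_run(g, rnorm(30)))
  fit$results$significant <- FALSE
  expect_equal(nrow(peak_select(fit)), 0)
  expect_equal(nrow(flanking_regions(peak_select(fit))), 0)
})

test_that("flanking regions clip at zero and merge overlaps", {
  pk <- peak_select(sig_tbl(200000), 150000)
  r <- flanking_regions(pk, 150000)
  expect_equal(c(r$start, r$end), c(50000, 350000))
  # boundary clip
  r0 <- flanking_regions(peak_select(sig_tbl(100000)), 150000)
  expect_equal(c(r0$start, r0$end), c(0, 250000))
  # peaks 200 kb apart merge into one region
  pk2 <- peak_select(sig_tbl(c(200000, 400000), score = c(2, 9)), 50000)
  r2 <- flanking_regions(pk2, 150000)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(50000, 550000))
  expect_equal(r2$peak_snp, "s2")
  expect_equal(r2$n_member_snps, 2L)
})

test_that("merged regions are disjoint and cover every member SNP", {
  set.seed(5)
  for (s in 1:10) {
    pos <- sort(sample.int(5e6, 12))
    pk <- peak_select(sig_tbl(pos, score = runif(12)), 150000)
    r <- flanking_regions(pk, 150000)
    # disjoint and sorted
    by_chr <- split(r, r$chrom)
    for (rr in by_chr) {
      if (nrow(rr) > 1) expect_true(all(rr$start[-1] >= rr$end[-nrow(rr)]))
    }
    # every significant SNP inside some region
    covered <- sapply(pos, function(p)
      any(r$start <= p & p < r$end))
    expect_true(all(covered))
  }
})

test_that("allelic effect equals the regression slope with its symmetries", {
  set.seed(7)
  g <- quick_panel(100, 30, seed = 7)
  j <- which(apply(g$dosages, 2, sd) > 0)[1]
  d <- g$dosages[, j]
  ae <- suppressWarnings(allelic_effect(g, 2 * d + 5, j))
  expect_equal(ae$effect, 2, tolerance = 1e-10)
  # closed form: cov / var
  y <- rnorm(100)
  ae2 <- allelic_effect(g, y, j)
  expect_equal(ae2$effect, cov(y, d) / var(d), tolerance = 1e-10)
  expect_lt(abs(ae2$effect), 3 * ae2$se + 1e-9)
  # coding flip negates the effect
  gflip <- geno_from(2L - g$dosages, pos = g$snp_info$pos,
                     chrom = g$snp_info$chrom)
  ae3 <- suppressWarnings(allelic_effect(gflip, as.numeric(2 * d + 5), j))
  expect_equal(ae3$effect, -2, tolerance = 1e-10)
  mono <- geno_from(cbind(rep(1L, 10), rep(0:1, 5)))
  expect_error(allelic_effect(mono, rnorm(10), 1), "monomorphic")
})

test_that("colocalize reports half-open overlaps exactly", {
  regions <- flanking_regions(peak_select(sig_tbl(200000)), 150000)
  ann <- tibble::tibble(chrom = "chr01", start = 340000, end = 400000,
                        name = "qtl_A")
  hit <- colocalize(regions, ann)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$overlap_bp, 10000)
  # disjoint
  far <- tibble::tibble(chrom = "chr01", start = 360000, end = 400000,
                        name = "qtl_B")
  expect_equal(nrow(colocalize(regions, far)), 0)
  # touching half-open intervals do not overlap
  touch <- tibble::tibble(chrom = "chr01", start = 350000, end = 360000,
                          name = "qtl_C")
  expect_equal(nrow(colocalize(regions, touch)), 0)
  # contained annotation overlaps by its own length
  inside <- tibble::tibble(chrom = "chr01", start = 100000, end = 120000,
                           name = "qtl_D")
  expect_equal(colocalize(regions, inside)$overlap_bp, 20000)
  bad <- tibble::tibble(chrom = "chr01", start = 5, end = 1, name = "x")
  expect_error(colocalize(regions, bad), "Malformed")
})

test_that("colocalize matches a brute-force all-pairs oracle", {
  set.seed(11)
  for (s in 1:15) {
    n_r <- sample(2:5, 1); n_a <- sample(2:8, 1)
    rs <- sort(sample.int(1e6, n_r))
    regions <- flanking_regions(
      peak_select(sig_tbl(rs, score = runif(n_r)), 50000), 50000)
    ann <- tibble::tibble(
      chrom = sample(c("chr01", "chr02"), n_a, TRUE),
      start = sample.int(1e6, n_a))
    ann$end <- ann$start + sample.int(200000, n_a)
    ann$name <- paste0("a", seq_len(n_a))
    got <- colocalize(regions, ann)
    want <- 0L
    for (i in seq_len(nrow(regions))) for (j in seq_len(n_a)) {
      if (regions$chrom[i] == ann$chrom[j]) {
        ov <- min(regions$end[i], ann$end[j]) -
          max(regions$start[i], ann$start[j])
        if (ov > 0) {
          want <- want + 1L
          expect_true(any(got$annotation == ann$name[j] &
                            got$region_start == regions$start[i] &
                            got$overlap_bp == ov))
        }
      }
    }
    expect_equal(nrow(got), want)
  }
})
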