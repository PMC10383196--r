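#' Remove samples with excessive missing genotype calls
#'
#' @param genotypes A [geno_matrix()].
#' @param max_missing_fraction Samples whose fraction of missing calls
#'   exceeds this threshold (in `(0, 1]`) are removed. Default 0.5.
#'
#' @return The filtered [geno_matrix()] with an accumulated QC report in
#'   `attr(, "qc_report")` (see [qc_report()]).
#' @export
filter_samples <- function(genotypes, max_missing_fraction = 0.5) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (max_missing_fraction <= 0 || max_missing_fraction > 1) {
    abort("`max_missing_fraction` must be in (0, 1].")
  }
  miss <- rowMeans(is.na(genotypes$dosages))
  keep <- miss <= max_missing_fraction
  if (!any(keep)) abort("All samples exceed the missingness threshold.")
  out <- subset_geno(genotypes, samples = which(keep))
  add_qc(out, n_samples_removed = sum(!keep))
}

#' Filter SNPs on missingness, minor allele frequency and heterozygosity
#'
#' Applies the standard GBS marker filters: SNPs with too many missing
#' calls, minor allele frequency below `maf_min` (computed on non-missing
#' calls), or a heterozygote fraction above `max_het` are removed. A SNP
#' failing several rules is counted once, under the first rule in the
#' order missing, MAF, heterozygosity.
#'
#' @param genotypes A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency. Default 0.05.
#' @param max_het Maximum fraction of heterozygous (dosage 1) calls among
#'   non-missing calls. Default 0.5.
#' @param max_missing Maximum fraction of missing calls per SNP.
#'   Default 0.2.
#'
#' @return The filtered [geno_matrix()] with an accumulated QC report.
#' @export
filter_snps <- function(genotypes, maf_min = 0.05, max_het = 0.5,
                        max_missing = 0.2) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (maf_min < 0 || maf_min > 0.5) abort("`maf_min` must be in [0, 0.5].")
  if (max_het < 0 || max_het > 1) abort("`max_het` must be in [0, 1].")
  if (max_missing < 0 || max_missing > 1) abort("`max_missing` must be in [0, 1].")
  d <- genotypes$dosages
  miss <- colMeans(is.na(d))
  maf <- minor_allele_freq(genotypes)
  het <- colMeans(d == 1L, na.rm = TRUE)
  fail_miss <- miss > max_missing
  fail_maf <- !fail_miss & (is.nan(maf) | maf < maf_min)
  fail_het <- !fail_miss & !fail_maf & !is.nan(het) & het > max_het
  keep <- !(fail_miss | fail_maf | fail_het)
  if (!any(keep)) abort("All SNPs removed by the marker filters.")
  out <- subset_geno(genotypes, snps = which(keep))
  add_qc(out,
         n_snps_removed_missing = sum(fail_miss),
         n_snps_removed_maf = sum(fail_maf),
         n_snps_removed_het = sum(fail_het))
}

#' First-order Markov imputation of missing genotype calls
#'
#' Walks each chromosome left to right by position; a missing dosage at
#' SNP `j` is drawn from the empirical conditional distribution of
#' `dosage_j` given `dosage_{j-1}` (estimated from samples complete at
#' both SNPs), and missing values at the left-most SNP of a chromosome
#' from its marginal distribution. Observed entries are never altered.
#'
#' @param genotypes A [geno_matrix()].
#' @param seed Integer RNG seed; the imputation is deterministic given it.
#'
#' @return A complete [geno_matrix()] with `n_imputed` recorded in the
#'   QC report.
#' @export
impute_markov <- function(genotypes, seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosages
  n_missing <- sum(is.na(d))
  if (n_missing == 0) return(add_qc(genotypes, n_imputed = 0L))
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0)) {
    abort(sprintf("%d SNP(s) have zero complete observations; cannot impute.",
                  sum(n_obs == 0)))
  }
  observed <- !is.na(d)
  with_seed_(seed, {
    for (cc in unique(genotypes$snp_info$chrom)) {
      idx <- which(genotypes$snp_info$chrom == cc)
      j0 <- idx[1]
      if (anyNA(d[, j0])) {
        marg <- tabulate(d[observed[, j0], j0] + 1L, 3L)
        miss_i <- which(is.na(d[, j0]))
        d[miss_i, j0] <- sample(0:2, length(miss_i), replace = TRUE,
                                prob = marg / sum(marg))
      }
      for (j in idx[-1]) {
        if (!anyNA(d[, j])) next
        prev <- idx[match(j, idx) - 1L]
        # transitions from originally-observed pairs only
        ok <- observed[, prev] & observed[, j]
        trans <- matrix(0, 3, 3)
        if (any(ok)) {
          tt <- table(factor(d[ok, prev], levels = 0:2),
                      factor(d[ok, j], levels = 0:2))
          trans <- matrix(as.numeric(tt), 3, 3)
        }
        marg <- tabulate(d[!is.na(d[, j]), j] + 1L, 3L)
        marg <- marg / sum(marg)
        for (i in which(is.na(d[, j]))) {
          v <- d[i, prev] + 1L  # previous SNP already complete
          p <- trans[v, ]
          if (sum(p) == 0) p <- marg else p <- p / sum(p)
          d[i, j] <- sample(0:2, 1L, prob = p)
        }
      }
    }
    out <- geno_matrix(d, genotypes$snp_info, genotypes$sample_ids)
    attr(out, "qc_report") <- attr(genotypes, "qc_report")
    add_qc(out, n_imputed = n_missing)
  })
}

#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' @param genotypes A [geno_matrix()].
#' @param snp_i,snp_j SNP column indices (or snp_id names).
#'
#' @return Squared Pearson correlation of dosages over samples complete at
#'   both SNPs, in `[0, 1]`.
#' @export
ld_r2 <- function(genotypes, snp_i, snp_j) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (is.character(snp_i)) snp_i <- match(snp_i, genotypes$snp_info$snp_id)
  if (is.character(snp_j)) snp_j <- match(snp_j, genotypes$snp_info$snp_id)
  x <- genotypes$dosages[, snp_i]
  y <- genotypes$dosages[, snp_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) abort("Need at least 3 complete sample pairs.")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("LD undefined: a SNP has zero dosage variance on the complete pairs.")
  }
  cor(x[ok], y[ok])^2
}

#' LD decay curve and decay distance
#'
#' Computes mean R-squared per physical-distance bin over all
#' intra-chromosome SNP pairs up to `max_dist_bp`, and the decay
#' distance: the interpolated distance at which mean R-squared first
#' falls below half the first bin's mean (or, with `r2_threshold`, below
#' that fixed level). A curve that never drops below the level yields
#' `NA` with a message (no decay observed within `max_dist_bp`).
#'
#' @param genotypes A [geno_matrix()].
#' @param max_dist_bp Maximum pair distance considered.
#' @param n_bins Number of equal-width distance bins.
#' @param r2_threshold Optional fixed R-squared level (e.g. 0.2) replacing
#'   the half-initial rule.
#'
#' @return Object of class `ld_decay`: list with `curve` (tibble:
#'   `dist_mid`, `mean_r2`, `n_pairs`) and `decay_distance_bp`.
#' @export
ld_decay <- function(genotypes, max_dist_bp = 1e6, n_bins = 20,
                     r2_threshold = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  info <- genotypes$snp_info
  breaks <- seq(0, max_dist_bp, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  sum_r2 <- numeric(n_bins)
  n_pair <- integer(n_bins)
  for (cc in unique(info$chrom)) {
    idx <- which(info$chrom == cc)
    if (length(idx) < 2) next
    d <- genotypes$dosages[, idx, drop = FALSE]
    keep <- apply(d, 2, function(v) sd(v, na.rm = TRUE) > 0)
    idx <- idx[keep]
    if (length(idx) < 2) next
    d <- genotypes$dosages[, idx, drop = FALSE]
    r2 <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
    dist <- abs(outer(info$pos[idx], info$pos[idx], "-"))
    ut <- upper.tri(dist)
    dd <- dist[ut]
    rr <- r2[ut]
    ok <- dd <= max_dist_bp & !is.na(rr)
    if (!any(ok)) next
    bin <- pmin(pmax(ceiling(dd[ok] / (max_dist_bp / n_bins)), 1L), n_bins)
    sum_r2 <- sum_r2 + as.numeric(tapply(rr[ok], factor(bin, seq_len(n_bins)),
                                         sum, default = 0))
    n_pair <- n_pair + as.integer(tapply(rep(1, sum(ok)),
                                         factor(bin, seq_len(n_bins)),
                                         sum, default = 0))
  }
  if (sum(n_pair) == 0) abort("No intra-chromosome SNP pairs within `max_dist_bp`.")
  mean_r2 <- ifelse(n_pair > 0, sum_r2 / n_pair, NA_real_)
  curve <- tibble(dist_mid = mids, mean_r2 = mean_r2, n_pairs = n_pair)
  obs <- which(!is.na(mean_r2))
  level <- if (is.null(r2_threshold)) mean_r2[obs[1]] / 2 else r2_threshold
  decay <- NA_real_
  below <- obs[mean_r2[obs] < level]
  if (length(below) > 0) {
    k <- below[1]
    prev <- obs[obs < k]
    if (length(prev) == 0) {
      decay <- mids[k]
    } else {
      k0 <- max(prev)
      # linear interpolation between bin midpoints across the crossing
      f <- (mean_r2[k0] - level) / (mean_r2[k0] - mean_r2[k])
      decay <- mids[k0] + f * (mids[k] - mids[k0])
    }
  } else {
    inform("LD does not fall below the decay level within `max_dist_bp`; decay distance is NA.")
  }
  structure(list(curve = curve, decay_distance_bp = decay,
                 level = level),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("<ld_decay> %d bins; decay distance = %s bp (level %.3g)\n",
              nrow(x$curve),
              ifelse(is.na(x$decay_distance_bp), "NA",
                     format(round(x$decay_distance_bp))),
              x$level))
  invisible(x)
}

#' Manhattan-style plot of an LD decay curve
#' @param object An [ld_decay()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$dist_mid / 1e3, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$level, linetype = 2) +
    ggplot2::labs(x = "Distance (kb)", y = expression(mean ~ R^2)) +
    ggplot2::theme_minimal()
}

#' Accumulated quality-control report
#'
#' @param genotypes A [geno_matrix()] that has passed through the QC
#'   filters or imputation.
#' @return One-row tibble with counts `n_samples_removed`,
#'   `n_snps_removed_missing`, `n_snps_removed_maf`, `n_snps_removed_het`,
#'   `n_imputed` (zero when a step has not run).
#' @export
qc_report <- function(genotypes) {
  rep <- attr(genotypes, "qc_report") %||% list()
  defaults <- list(n_samples_removed = 0L, n_snps_removed_missing = 0L,
                   n_snps_removed_maf = 0L, n_snps_removed_het = 0L,
                   n_imputed = 0L)
  as_tibble(modifyList(defaults, rep))
}

add_qc <- function(genotypes, ...) {
  rep <- attr(genotypes, "qc_report") %||% list()
  new <- list(...)
  for (k in names(new)) {
    rep[[k]] <- (rep[[k]] %||% 0L) + as.integer(new[[k]])
  }
  attr(genotypes, "qc_report") <- rep
  genotypes
}
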