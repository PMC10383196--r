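#' Simulate a structured SNP panel
#'
#' Generates diploid biallelic genotypes with population structure and
#' linkage disequilibrium. Ancestral allele frequencies are drawn uniformly
#' from `maf_range`; subpopulation frequencies drift from them under the
#' Balding-Nichols model at the configured Fst; and along each chromosome
#' every haplotype copies the previous SNP's allele with probability
#' `ld_rho` (drawing fresh from the subpopulation frequency otherwise),
#' which gives geometric LD decay: the haplotype-level correlation at lag
#' `d` is approximately `ld_rho^d`.
#'
#' @param config A [sim_config()].
#'
#' @return A list with elements
#'   * `genotypes`: a [geno_matrix()] with dosages in 0/1/2 and SNP
#'     positions uniform-sorted per chromosome;
#'   * `truth`: a list carrying `subpop_labels` (per-genotype) and the
#'     per-SNP ancestral allele frequencies.
#' @export
#' @examples
#' sim <- simulate_genotypes(sim_config(n_genotypes = 40, n_snps = 100,
#'                                      n_chromosomes = 2, seed = 1))
#' sim$genotypes
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed_(config$seed, simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(config) {
  n <- config$n_genotypes
  m <- config$n_snps
  k <- config$n_subpops
  fst <- config$fst

  # SNP map: near-even split across chromosomes, positions uniform-sorted
  chrom_sizes <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1)))
  chrom <- rep(seq_len(config$n_chromosomes), chrom_sizes)
  pos <- unlist(lapply(chrom_sizes, function(cm) {
    sort(sample.int(config$chrom_length_bp, cm, replace = FALSE))
  }))
  snp_info <- tibble(
    snp_id = sprintf("chr%02d_%d", chrom, pos),
    chrom = paste0("chr", sprintf("%02d", chrom)),
    pos = as.integer(pos), ref = "A", alt = "B"
  )

  p_anc <- runif(m, config$maf_range[1], config$maf_range[2])

  # Balding-Nichols drift: Beta(p(1-F)/F, (1-p)(1-F)/F) per subpopulation
  p_sub <- if (fst > 0 && k > 1) {
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    vapply(seq_len(k), function(s) rbeta(m, a, b), numeric(m))
  } else {
    matrix(p_anc, m, k)
  }

  subpop <- sort(rep_len(seq_len(k), n))
  n_hap <- 2L * n
  hap_subpop <- rep(subpop, each = 2L)

  # First-order copy chain per chromosome, vectorized over haplotypes
  hap <- matrix(0L, n_hap, m)
  for (cc in seq_len(config$n_chromosomes)) {
    idx <- which(chrom == cc)
    p1 <- p_sub[idx[1], hap_subpop]
    hap[, idx[1]] <- as.integer(runif(n_hap) < p1)
    for (j in idx[-1]) {
      copy <- runif(n_hap) < config$ld_rho
      fresh <- as.integer(runif(n_hap) < p_sub[j, hap_subpop])
      hap[, j] <- ifelse(copy, hap[, j - 1L], fresh)
    }
  }
  dos <- hap[seq(1, n_hap, by = 2L), , drop = FALSE] +
    hap[seq(2, n_hap, by = 2L), , drop = FALSE]

  ids <- sprintf("G%03d", seq_len(n))
  list(
    genotypes = geno_matrix(dos, snp_info, ids),
    truth = list(subpop_labels = subpop, ancestral_freq = p_anc)
  )
}

#' Inject missing genotype calls
#'
#' Masks a random fraction of dosage entries as missing, for exercising
#' quality-control filters and imputation.
#'
#' @param genotypes A [geno_matrix()].
#' @param missing_rate Fraction of entries set to `NA`, in `[0, 1)`.
#' @param seed Integer RNG seed.
#'
#' @return A [geno_matrix()] with entries masked.
#' @export
inject_missing <- function(genotypes, missing_rate, seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  if (missing_rate == 0) return(genotypes)
  with_seed_(seed, {
    d <- genotypes$dosages
    mask <- runif(length(d)) < missing_rate
    d[mask] <- NA_integer_
    geno_matrix(d, genotypes$snp_info, genotypes$sample_ids)
  })
}
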