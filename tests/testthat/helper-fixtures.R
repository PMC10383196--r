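# Small simulated panels and hand-built genotype objects shared across
# test files. Everything is generated in code; no stored fixtures.

quick_panel <- function(n = 60, m = 200, n_chrom = 4, seed = 1, ...) {
  cfg <- sim_config(n_genotypes = n, n_snps = m, n_chromosomes = n_chrom,
                    seed = seed, ...)
  simulate_genotypes(cfg)$genotypes
}

# geno_matrix straight from a dosage matrix, SNPs evenly spaced on one
# chromosome unless positions are given.
geno_from <- function(dos, pos = NULL, chrom = NULL) {
  m <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("chr01", m)
  geno_matrix(
    dos,
    data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
               pos = as.integer(pos)),
    sample_ids = paste0("i", seq_len(nrow(dos)))
  )
}

rand_geno <- function(n, m, seed, miss = 0) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(.4, .3, .3)), n, m)
  if (miss > 0) dos[runif(n * m) < miss] <- NA_integer_
  geno_from(dos)
}

# Balanced RCBD plot table from per-genotype values.
plots_from <- function(g_values, n_envs = 2, n_blocks = 2, noise_sd = 1,
                       seed = 1) {
  set.seed(seed)
  n <- length(g_values)
  ids <- sprintf("G%03d", seq_len(n))
  out <- list()
  for (e in seq_len(n_envs)) for (b in seq_len(n_blocks)) {
    ord <- sample.int(n)   # genotypes randomized within each block
    idx <- seq_len(n)
    out[[length(out) + 1]] <- tibble::tibble(
      genotype_id = ids[ord],
      env_id = paste0("env", e), block_id = paste0("block", b),
      row = ((idx - 1) %/% 15) + 1 + (b - 1) * 20,
      column = ((idx - 1) %% 15) + 1,
      value = g_values[ord] + rnorm(n, 0, noise_sd)
    )
  }
  dplyr::bind_rows(out)
}
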