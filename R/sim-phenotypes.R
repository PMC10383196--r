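#' Simulate plot-level phenotypes over planted QTL
#'
#' Realizes a multi-environment randomized complete block trial on top of a
#' simulated genotype panel. Each genotype's genetic value is the sum of
#' planted additive QTL effects (`g_i = sum_k effect_k * dosage_ik`), plus
#' an optional polygenic background over non-QTL SNPs when
#' `qtl_var_frac < 1`. The residual variance is scaled so that the
#' plot-basis heritability `sigma2_G / (sigma2_G + sigma2_E)` equals
#' `h2_target` exactly in the generating model; genotype-by-environment,
#' block, and smooth spatial field effects are layered on top.
#'
#' @param genotypes A complete (no missing calls) [geno_matrix()].
#' @param config A [sim_config()].
#' @param seed Integer RNG seed; defaults to `config$seed + 1` when the
#'   config carries a seed.
#'
#' @return A list with elements
#'   * `phenotypes`: tibble of plot records with columns `genotype_id`,
#'     `env_id`, `block_id`, `row`, `column`, `value`;
#'   * `truth`: list with `qtl_snp_indices`, `qtl_effects`,
#'     `genetic_values`, `sigma2_g`, `sigma2_e`, `sigma2_gxe`, and
#'     `subpop_labels` (when present on the genotype simulation).
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 30, n_snps = 100, n_chromosomes = 2,
#'                   n_qtl = 3, seed = 7)
#' sim <- simulate_genotypes(cfg)
#' ph <- simulate_phenotypes(sim$genotypes, cfg)
#' head(ph$phenotypes)
simulate_phenotypes <- function(genotypes, config, seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  if (anyNA(genotypes$dosages)) {
    abort("`genotypes` must be complete (impute or simulate without missing).")
  }
  if (config$n_qtl > n_snps(genotypes)) {
    abort("`n_qtl` cannot exceed the number of SNPs.")
  }
  if (is.null(seed) && !is.null(config$seed)) seed <- config$seed + 1L
  with_seed_(seed, simulate_phenotypes_impl(genotypes, config))
}

simulate_phenotypes_impl <- function(genotypes, config) {
  M <- genotypes$dosages
  n <- nrow(M)
  m <- ncol(M)

  # genetic values: planted QTL plus optional polygenic background
  if (config$n_qtl > 0) {
    qtl_idx <- sort(sample.int(m, config$n_qtl))
    effects <- rnorm(config$n_qtl, 0, config$qtl_effect_sd)
    g_qtl <- drop(M[, qtl_idx, drop = FALSE] %*% effects)
  } else {
    qtl_idx <- integer(0)
    effects <- numeric(0)
    g_qtl <- rep(0, n)
  }
  g <- g_qtl
  if (config$qtl_var_frac < 1 && config$n_qtl > 0) {
    bg_idx <- setdiff(seq_len(m), qtl_idx)
    bg_eff <- rnorm(length(bg_idx), 0, 1)
    g_bg <- drop(M[, bg_idx, drop = FALSE] %*% bg_eff)
    target_bg_var <- var(g_qtl) * (1 - config$qtl_var_frac) / config$qtl_var_frac
    if (var(g_bg) > 0) g_bg <- g_bg * sqrt(target_bg_var / var(g_bg))
    g <- g_qtl + g_bg
  }
  g <- g - mean(g)

  sigma2_g <- var(g)
  sigma2_e <- if (sigma2_g > 0) {
    sigma2_g * (1 - config$h2_target) / config$h2_target
  } else {
    1
  }
  sigma_e <- sqrt(sigma2_e)
  sigma2_gxe <- config$gxe_ratio * sigma2_g

  gxe <- matrix(rnorm(n * config$n_envs, 0, sqrt(sigma2_gxe)),
                n, config$n_envs)

  n_plots <- n * config$n_blocks
  n_col <- ceiling(sqrt(n_plots))

  env_tbl <- vector("list", config$n_envs)
  for (e in seq_len(config$n_envs)) {
    block_eff <- rnorm(config$n_blocks, 0, config$block_sd * sigma_e)
    geno_order <- unlist(lapply(seq_len(config$n_blocks),
                                function(b) sample.int(n)))
    plot_i <- seq_len(n_plots)
    frow <- (plot_i - 1L) %/% n_col + 1L
    fcol <- (plot_i - 1L) %% n_col + 1L
    spatial <- field_trend(frow, fcol, config$spatial_sd * sigma_e)
    block_of <- rep(seq_len(config$n_blocks), each = n)
    env_tbl[[e]] <- tibble(
      genotype_id = genotypes$sample_ids[geno_order],
      env_id = sprintf("env%d", e),
      block_id = sprintf("block%d", block_of),
      row = frow, column = fcol,
      value = unname(g[geno_order]) + gxe[cbind(geno_order, e)] +
        block_eff[block_of] + spatial + rnorm(n_plots, 0, sigma_e)
    )
  }

  truth <- list(
    qtl_snp_indices = qtl_idx, qtl_effects = effects,
    genetic_values = setNames(g, genotypes$sample_ids),
    sigma2_g = sigma2_g, sigma2_e = sigma2_e, sigma2_gxe = sigma2_gxe
  )
  list(phenotypes = bind_rows(env_tbl), truth = truth)
}

# Smooth low-order polynomial surface plus AR(1)-style row noise, rescaled
# to the requested standard deviation (0 disables the trend entirely).
field_trend <- function(frow, fcol, trend_sd) {
  if (trend_sd <= 0) return(rep(0, length(frow)))
  r <- scale(frow)[, 1]
  c <- scale(fcol)[, 1]
  r[is.na(r)] <- 0
  c[is.na(c)] <- 0
  b <- rnorm(5)
  surf <- b[1] * r + b[2] * c + b[3] * r * c + b[4] * r^2 + b[5] * c^2
  # AR(1) noise along each field row
  ar <- numeric(length(frow))
  for (rr in unique(frow)) {
    i <- which(frow == rr)
    i <- i[order(fcol[i])]
    z <- numeric(length(i))
    z[1] <- rnorm(1)
    if (length(i) > 1) {
      eps <- rnorm(length(i) - 1, 0, sqrt(1 - 0.6^2))
      for (t in 2:length(i)) z[t] <- 0.6 * z[t - 1] + eps[t - 1]
    }
    ar[i] <- z
  }
  x <- surf + 0.5 * ar
  s <- sd(x)
  if (s == 0) return(rep(0, length(frow)))
  x / s * trend_sd
}
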