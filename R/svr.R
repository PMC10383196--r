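#' SVR-GWAS configuration
#'
#' Settings for the support-vector-regression association scan:
#' epsilon-SVR hyperparameters, the cross-validation scheme used to
#' average per-SNP variable importance, and the phenotype-permutation
#' scheme that sets the global empirical significance threshold.
#'
#' @param kernel `"linear"` (default; importance is `|w_j|` of the primal
#'   weight vector) or `"rbf"` (kernel-gradient sensitivity importance).
#' @param cost SVR cost parameter C (> 0). Default 1.
#' @param epsilon Epsilon-insensitive margin (>= 0), on the standardized
#'   phenotype scale. Default 0.1.
#' @param n_folds Cross-validation folds (>= 2). Default 5.
#' @param n_repeats Cross-validation repetitions. Default 10.
#' @param n_permutations Phenotype permutations for the empirical
#'   threshold (>= 20). Default 1000.
#' @param alpha Significance level in (0, 1) for the empirical threshold:
#'   the cut is the `(1 - alpha)` quantile of the per-permutation maxima.
#'   Default 0.05; any value in (0, 1) is accepted, so laxer conventions
#'   (e.g. 0.5) can be reproduced if needed.
#' @param perm_cv If `TRUE`, each permutation recomputes the full
#'   cross-validated importance (exchangeable with the observed statistic,
#'   exact FWER); if `FALSE` (default), one full-data fit per permutation
#'   is used, which is cheaper and conservative because the observed
#'   CV-averaged maxima are noise-shrunken relative to single-fit maxima.
#' @param rbf_sigma Inverse-width of the RBF kernel; default `1 / n_snps`.
#' @param seed Integer RNG seed for fold assignment and permutations.
#'
#' @return List of class `svr_config`.
#' @export
svr_config <- function(kernel = c("linear", "rbf"), cost = 1, epsilon = 0.1,
                       n_folds = 5, n_repeats = 10, n_permutations = 1000,
                       alpha = 0.05, perm_cv = FALSE, rbf_sigma = NULL,
                       seed = NULL) {
  kernel <- match.arg(kernel)
  if (cost <= 0) abort("`cost` must be > 0.")
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  if (n_folds < 2) abort("`n_folds` must be >= 2.")
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  if (n_permutations < 20) abort("`n_permutations` must be >= 20.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(list(
    kernel = kernel, cost = cost, epsilon = epsilon,
    n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
    n_permutations = as.integer(n_permutations), alpha = alpha,
    perm_cv = isTRUE(perm_cv), rbf_sigma = rbf_sigma,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "svr_config")
}

# Standardize columns to mean 0 / sd 1; zero-variance columns become all
# zero and are reported via the "constant" attribute.
standardize_cols <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(matrixStats_colVars(X))
  const <- s == 0
  s[const] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  attr(Xs, "constant") <- const
  Xs
}

# Fit epsilon-SVR on rows `idx` against y[idx] using a precomputed kernel
# matrix, returning the signed dual coefficient vector over those rows.
svr_alpha <- function(K, y, idx, cost, epsilon) {
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K[idx, idx, drop = FALSE]),
                       y[idx], type = "eps-svr", C = cost,
                       epsilon = epsilon, scaled = FALSE)
  a <- numeric(length(idx))
  a[kernlab::SVindex(fit)] <- unlist(kernlab::coef(fit))
  a
}

# Per-SNP importance from one fit on rows `idx`:
# linear: |w_j|, w = X' alpha; rbf: RMS of the kernel-gradient df/dx_j
# over the training points.
svr_fit_importance <- function(Xs, K, y, idx, config) {
  a <- svr_alpha(K, y, idx, config$cost, config$epsilon)
  if (config$kernel == "linear") {
    return(abs(drop(crossprod(Xs[idx, , drop = FALSE], a))))
  }
  sig <- config$rbf_sigma %||% (1 / ncol(Xs))
  Ktr <- K[idx, idx, drop = FALSE]
  Xtr <- Xs[idx, , drop = FALSE]
  s_t <- drop(crossprod(Ktr, a))                      # sum_i a_i K_it
  C1 <- crossprod(Ktr, a * Xtr)                       # sum_i a_i K_it x_ij
  grad <- 2 * sig * (C1 - s_t * Xtr)
  sqrt(colMeans(grad^2))
}

# Full kernel matrix on the standardized dosages.
svr_kernel <- function(Xs, config) {
  if (config$kernel == "linear") return(tcrossprod(Xs))
  sig <- config$rbf_sigma %||% (1 / ncol(Xs))
  sq <- rowSums(Xs^2)
  exp(-sig * pmax(outer(sq, sq, "+") - 2 * tcrossprod(Xs), 0))
}

cv_importance <- function(Xs, K, y, config) {
  n <- length(y)
  imp <- numeric(ncol(Xs))
  for (r in seq_len(config$n_repeats)) {
    fold <- sample(rep_len(seq_len(config$n_folds), n))
    for (f in seq_len(config$n_folds)) {
      idx <- which(fold != f)
      imp <- imp + svr_fit_importance(Xs, K, y, idx, config)
    }
  }
  imp / (config$n_repeats * config$n_folds)
}

#' Cross-validated SVR variable importance per SNP
#'
#' Fits epsilon-SVR on each of `n_repeats x n_folds` training folds and
#' averages a per-SNP importance over the fits: the absolute primal
#' weight `|w_j|` for the linear kernel, or a kernel-gradient sensitivity
#' norm for the RBF kernel. Dosage columns are standardized internally
#' (the phenotype too); zero-variance SNPs get importance 0 with a
#' warning.
#'
#' @param genotypes A complete [geno_matrix()] (or a plain numeric
#'   samples x SNPs matrix).
#' @param y Phenotype, one value per sample (see [fem_scan()] for
#'   accepted forms when `genotypes` is a `geno_matrix`).
#' @param config An [svr_config()].
#'
#' @return Numeric vector of raw importance scores, one per SNP.
#' @export
svr_importance <- function(genotypes, y, config = svr_config()) {
  X <- dosage_of(genotypes)
  y <- if (inherits(genotypes, "geno_matrix")) align_phenotype(genotypes, y)
  else as.numeric(y)
  if (anyNA(X)) abort("SVR requires complete (imputed) genotypes.")
  if (nrow(X) < config$n_folds) abort("Fewer samples than folds.")
  if (sd(y) == 0) abort("Phenotype is constant.")
  Xs <- standardize_cols(X)
  const <- attr(Xs, "constant")
  if (any(const)) {
    warn(sprintf("%d zero-variance SNP(s): importance set to 0.", sum(const)))
  }
  ys <- (y - mean(y)) / sd(y)
  K <- svr_kernel(Xs, config)
  imp <- with_seed_(config$seed, cv_importance(Xs, K, ys, config))
  imp[const] <- 0
  names(imp) <- colnames(X)
  imp
}

#' Scale importance scores to 0-100
#'
#' Affine map `(v - min) / (max - min) * 100`. An all-equal input maps to
#' all zero with a warning.
#'
#' @param raw Numeric vector of raw importance scores.
#' @return Numeric vector in `[0, 100]`.
#' @export
#' @examples
#' scale_importance(c(2, 5, 8))
scale_importance <- function(raw) {
  if (length(raw) == 0) abort("Empty importance vector.")
  rng <- range(raw)
  if (diff(rng) == 0) {
    warn("All importance scores equal; scaled importance set to 0.")
    return(rep(0, length(raw)))
  }
  (raw - rng[1]) / diff(rng) * 100
}

#' Global empirical significance threshold by phenotype permutation
#'
#' Shuffles the phenotype `n_permutations` times; for each permutation
#' records the maximum raw importance over SNPs (from one full-data fit,
#' or the full cross-validated importance when `perm_cv = TRUE`); the
#' threshold is the `(1 - alpha)` empirical quantile of those maxima.
#' Thresholding on the raw scale and mapping through the original
#' (unpermuted) 0-100 scaling keeps significance decisions on one scale.
#'
#' @inheritParams svr_importance
#'
#' @return List with `threshold_raw` and `null_max` (the per-permutation
#'   maxima).
#' @export
empirical_threshold <- function(genotypes, y, config = svr_config()) {
  X <- dosage_of(genotypes)
  y <- if (inherits(genotypes, "geno_matrix")) align_phenotype(genotypes, y)
  else as.numeric(y)
  if (sd(y) == 0) abort("Phenotype is constant; permutations are undefined.")
  Xs <- standardize_cols(X)
  ys <- (y - mean(y)) / sd(y)
  K <- svr_kernel(Xs, config)
  n <- length(ys)
  seeds <- derive_seeds(config$seed %||% 0L, 1)
  null_max <- with_seed_(
    if (is.null(config$seed)) NULL else seeds[[1]],
    vapply(seq_len(config$n_permutations), function(b) {
      yp <- ys[sample.int(n)]
      imp <- if (config$perm_cv) {
        cv_importance(Xs, K, yp, config)
      } else {
        svr_fit_importance(Xs, K, yp, seq_len(n), config)
      }
      max(imp)
    }, numeric(1))
  )
  list(threshold_raw = unname(quantile(null_max, 1 - config$alpha, type = 1)),
       null_max = null_max)
}

#' Run the SVR-mediated genome scan
#'
#' Composes [svr_importance()], [scale_importance()] and
#' [empirical_threshold()]: per-SNP cross-validated importance scaled to
#' 0-100, a permutation-based global threshold mapped onto the same
#' scale, and the significant SNP set.
#'
#' @inheritParams svr_importance
#'
#' @return Object of class `svr_gwas_fit`: list with `results` (tibble:
#'   `snp_id`, `chrom`, `pos`, `importance_raw`, `importance`,
#'   `significant`), `threshold_scaled`, `threshold_raw`, `null_max`,
#'   and `alpha`.
#' @seealso [tidy.svr_gwas_fit()], [autoplot.svr_gwas_fit()]
#' @export
svr_gwas_run <- function(genotypes, y, config = svr_config()) {
  raw <- svr_importance(genotypes, y, config)
  scaled <- scale_importance(raw)
  thr <- empirical_threshold(genotypes, y, config)
  rng <- range(raw)
  threshold_scaled <- if (diff(rng) > 0) {
    (thr$threshold_raw - rng[1]) / diff(rng) * 100
  } else {
    Inf
  }
  info <- if (inherits(genotypes, "geno_matrix")) genotypes$snp_info
  else tibble(snp_id = colnames(dosage_of(genotypes)) %||%
                paste0("snp", seq_along(raw)),
              chrom = NA_character_, pos = NA_integer_)
  results <- tibble(
    snp_id = info$snp_id, chrom = info$chrom, pos = info$pos,
    importance_raw = unname(raw), importance = unname(scaled),
    significant = unname(scaled >= threshold_scaled)
  )
  structure(list(
    results = results,
    threshold_scaled = threshold_scaled,
    threshold_raw = thr$threshold_raw,
    null_max = thr$null_max,
    alpha = config$alpha
  ), class = "svr_gwas_fit")
}

dosage_of <- function(x) {
  if (inherits(x, "geno_matrix")) {
    d <- x$dosages
    storage.mode(d) <- "double"
    d
  } else {
    as.matrix(x)
  }
}

#' @export
print.svr_gwas_fit <- function(x, ...) {
  cat(sprintf(
    "<svr_gwas_fit> %d SNPs; threshold %.2f (scaled, alpha = %g); %d significant\n",
    nrow(x$results), x$threshold_scaled, x$alpha,
    sum(x$results$significant)
  ))
  invisible(x)
}

#' Tidy SVR-GWAS results into a per-SNP table
#' @param x An [svr_gwas_run()] result.
#' @param ... Unused.
#' @return Tibble with raw and 0-100 scaled importance and the
#'   significance flag.
#' @method tidy svr_gwas_fit
#' @export
tidy.svr_gwas_fit <- function(x, ...) x$results

#' One-row summary of an SVR-GWAS run
#' @param x An [svr_gwas_run()] result.
#' @param ... Unused.
#' @return Tibble with the threshold and significant-SNP count.
#' @method glance svr_gwas_fit
#' @export
glance.svr_gwas_fit <- function(x, ...) {
  tibble(
    n_snps = nrow(x$results),
    n_significant = sum(x$results$significant),
    threshold_scaled = x$threshold_scaled,
    alpha = x$alpha,
    n_permutations = length(x$null_max)
  )
}
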