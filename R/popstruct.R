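#' VanRaden genomic relationship matrix
#'
#' Method-1 VanRaden kinship: `K = Z Z' / (2 * sum_j p_j (1 - p_j))` with
#' `Z` the dosage matrix centered by twice the alternate allele frequency.
#' Symmetric and positive semi-definite by construction; under
#' Hardy-Weinberg equilibrium the diagonal averages about 1.
#'
#' @param genotypes A complete (imputed) [geno_matrix()] with at least two
#'   polymorphic SNPs.
#'
#' @return An n x n numeric matrix of class `kinship_matrix` with sample
#'   ids as dimnames.
#' @export
kinship_vanraden <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosages
  if (anyNA(d)) abort("Kinship requires a complete (imputed) matrix.")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) abort("Need at least 2 polymorphic SNPs for kinship.")
  Z <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  K <- tcrossprod(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(K) <- list(genotypes$sample_ids, genotypes$sample_ids)
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Structure covariates for GWAS
#'
#' Population-structure cofactors: by default the top `k - 1` principal
#' components of the centered dosage matrix (mean-centered columns); or a
#' pass-through of an externally computed admixture proportion (Q) matrix
#' whose rows are matched by sample id, with the last column dropped to
#' avoid collinearity with the intercept.
#'
#' @param genotypes A complete [geno_matrix()].
#' @param k Assumed number of subpopulations (>= 2); yields `k - 1`
#'   covariate columns. Default 7.
#' @param q Optional data frame of admixture proportions with a
#'   `sample_id` column (or row names) and one column per subpopulation;
#'   rows must sum to 1.
#'
#' @return Numeric matrix `n x (k - 1)` of class `structure_covariates`
#'   with attribute `method` (`"pca"` or `"imported"`), columns
#'   mean-centered.
#' @export
structure_covariates <- function(genotypes, k = 7, q = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!is.null(q)) return(import_q(genotypes, q))
  if (k < 2) abort("`k` must be >= 2.")
  if (k - 1 >= n_samples(genotypes)) {
    abort("`k - 1` must be smaller than the number of samples.")
  }
  d <- genotypes$dosages
  if (anyNA(d)) abort("Structure covariates require a complete matrix.")
  keep <- apply(d, 2, function(v) sd(v) > 0)
  pc <- prcomp(d[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  Q <- pc$x[, seq_len(k - 1), drop = FALSE]
  Q <- sweep(Q, 2, colMeans(Q))
  rownames(Q) <- genotypes$sample_ids
  colnames(Q) <- paste0("PC", seq_len(ncol(Q)))
  structure(Q, method = "pca", class = c("structure_covariates", class(Q)))
}

import_q <- function(genotypes, q) {
  q <- as.data.frame(q)
  if ("sample_id" %in% names(q)) {
    rownames(q) <- q$sample_id
    q$sample_id <- NULL
  }
  miss <- setdiff(genotypes$sample_ids, rownames(q))
  if (length(miss) > 0) {
    abort(paste0("Q matrix is missing sample id(s): ",
                 paste(head(miss, 10), collapse = ", ")))
  }
  Qm <- as.matrix(q[genotypes$sample_ids, , drop = FALSE])
  rs <- rowSums(Qm)
  if (any(abs(rs - 1) > 1e-6)) {
    abort("Q matrix rows must sum to 1 (admixture proportions).")
  }
  Qm <- Qm[, -ncol(Qm), drop = FALSE]
  Qm <- sweep(Qm, 2, colMeans(Qm))
  structure(Qm, method = "imported",
            class = c("structure_covariates", class(Qm)))
}
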