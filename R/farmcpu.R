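#' FarmCPU configuration
#'
#' Tuning grid and thresholds for the fixed/random model circulation.
#' At each iteration the random-effect model scores every combination of
#' `bin_sizes_bp` x `qtn_counts` by REML likelihood and the winning
#' pseudo-QTN set becomes the covariate set of the next fixed-effect scan.
#'
#' @param bin_sizes_bp Candidate genome bin widths (bp) used to pick at
#'   most one pseudo-QTN candidate per bin. Defaults 500 kb / 5 Mb / 50 Mb.
#' @param qtn_counts Candidate numbers of pseudo-QTNs. Defaults 5, 10, 15.
#' @param max_iterations Maximum fixed/random circulations. Default 10.
#' @param fdr_q Benjamini-Hochberg FDR level for the final scan, in
#'   `(0, 1]`. Default 0.05.
#' @param qtn_p_threshold Entry p-value a bin representative must beat to
#'   qualify as a pseudo-QTN candidate. Default 0.01 (the conventional
#'   FarmCPU setting); guards null calibration by keeping unassociated
#'   SNPs out of the covariate set.
#' @param p_threshold Gate on entering the iteration at all: if the
#'   minimum p-value of the first (plain) scan exceeds it, the run stops
#'   at iteration 1, as in the reference FarmCPU algorithm. `NULL`
#'   (default) means `0.01 / n_snps`. Without this gate, absorbing
#'   top-ranked null SNPs as covariates deflates the residual and
#'   inflates the remaining tests under the null.
#'
#' @return List of class `farmcpu_config`.
#' @export
farmcpu_config <- function(bin_sizes_bp = c(5e5, 5e6, 5e7),
                           qtn_counts = c(5, 10, 15),
                           max_iterations = 10,
                           fdr_q = 0.05,
                           qtn_p_threshold = 0.01,
                           p_threshold = NULL) {
  if (length(bin_sizes_bp) == 0 || length(qtn_counts) == 0) {
    abort("`bin_sizes_bp` and `qtn_counts` must be non-empty.")
  }
  if (fdr_q <= 0 || fdr_q > 1) abort("`fdr_q` must be in (0, 1].")
  structure(list(
    bin_sizes_bp = as.numeric(bin_sizes_bp),
    qtn_counts = as.integer(qtn_counts),
    max_iterations = as.integer(max_iterations),
    fdr_q = as.numeric(fdr_q),
    qtn_p_threshold = as.numeric(qtn_p_threshold),
    p_threshold = if (is.null(p_threshold)) NULL else as.numeric(p_threshold)
  ), class = "farmcpu_config")
}

#' Fixed-effect per-SNP scan with pseudo-QTN covariates
#'
#' For every SNP `j`, fits ordinary least squares of the phenotype on
#' `[intercept, structure covariates, pseudo-QTN dosages, dosage_j]`,
#' excluding from the covariate set any pseudo-QTN lying within
#' `bin_size_bp` of SNP `j` on the same chromosome (so a SNP is never
#' tested against itself). The p-value is the two-sided t-test on the SNP
#' effect. Constant-dosage SNPs get `NA`; SNPs collinear with the design
#' (e.g. a duplicate of an included pseudo-QTN) get p = 1.
#'
#' @param genotypes A complete [geno_matrix()].
#' @param y Numeric phenotype, one value per sample (typically BLUPs), or
#'   a data frame with `genotype_id` and a value column.
#' @param covariates Optional numeric matrix of structure covariates
#'   (e.g. [structure_covariates()]).
#' @param pseudo_qtns Integer SNP indices used as covariates.
#' @param bin_size_bp Exclusion window around each tested SNP.
#'
#' @return Tibble with `snp_id`, `chrom`, `pos`, `effect`, `pvalue`.
#' @export
fem_scan <- function(genotypes, y, covariates = NULL,
                     pseudo_qtns = integer(0), bin_size_bp = 0) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  M <- genotypes$dosages
  if (anyNA(M)) abort("FEM scan requires complete (imputed) genotypes.")
  y <- align_phenotype(genotypes, y)
  n <- length(y)
  info <- genotypes$snp_info
  m <- ncol(M)
  pseudo_qtns <- sort(unique(as.integer(pseudo_qtns)))
  if (length(pseudo_qtns) > 0 &&
      (min(pseudo_qtns) < 1 || max(pseudo_qtns) > m)) {
    abort("`pseudo_qtns` must be valid SNP indices.")
  }
  X_base <- cbind(`(Intercept)` = rep(1, n), covariates)

  # which pseudo-QTNs are excluded for each SNP (same chrom, within window)
  excl_key <- rep("", m)
  if (length(pseudo_qtns) > 0) {
    for (q in pseudo_qtns) {
      hit <- info$chrom == info$chrom[q] &
        abs(info$pos - info$pos[q]) <= bin_size_bp
      excl_key[hit] <- paste(excl_key[hit], q)
    }
  }

  pval <- rep(NA_real_, m)
  eff <- rep(NA_real_, m)
  for (key in unique(excl_key)) {
    snps <- which(excl_key == key)
    excl <- as.integer(strsplit(trimws(key), " +")[[1]])
    keep_q <- setdiff(pseudo_qtns, excl)
    Xg <- if (length(keep_q) > 0) cbind(X_base, M[, keep_q, drop = FALSE])
    else X_base
    qrX <- qr(Xg)
    df <- n - qrX$rank - 1L
    if (df <= 0) next
    ry <- qr.resid(qrX, y)
    RM <- qr.resid(qrX, M[, snps, drop = FALSE])
    ss <- colSums(RM^2)
    raw_var <- matrixStats_colVars(M[, snps, drop = FALSE])
    b <- ifelse(ss > 0, colSums(RM * ry) / ss, 0)
    rss <- sum(ry^2) - b^2 * ss
    sigma2 <- pmax(rss, 0) / df
    tstat <- ifelse(ss > 0 & sigma2 > 0, b / sqrt(sigma2 / ss), 0)
    p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
    # zero-variance SNP: untestable; collinear-with-design SNP: p = 1
    degenerate <- ss <= 1e-10 * n
    p[degenerate] <- 1
    b[degenerate] <- 0
    p[raw_var == 0] <- NA_real_
    b[raw_var == 0] <- NA_real_
    pval[snps] <- p
    eff[snps] <- b
  }
  tibble(snp_id = info$snp_id, chrom = info$chrom, pos = info$pos,
         effect = eff, pvalue = pval)
}

# colVars without extra dependencies
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  (colSums(x^2) - colSums(x)^2 / n) / (n - 1)
}

#' Select pseudo-QTNs with the random-effect model
#'
#' Bins SNPs by `(chromosome, position %/% bin_size)` and keeps the
#' lowest-p SNP per bin; bin representatives beating the entry p-value
#' threshold are candidates. For every `(bin_size, qtn_count)` cell of
#' the configuration grid, the top candidates define a VanRaden-style
#' kinship whose single-random-effect REML likelihood scores the cell;
#' the representative set of the best-likelihood cell is returned.
#'
#' @inheritParams fem_scan
#' @param pvalues Per-SNP p-values from the preceding [fem_scan()].
#' @param config A [farmcpu_config()].
#'
#' @return Integer vector of selected SNP indices (possibly empty), with
#'   attribute `bin_size_bp` of the winning grid cell.
#' @export
rem_select <- function(genotypes, y, pvalues, config = farmcpu_config()) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  y <- align_phenotype(genotypes, y)
  info <- genotypes$snp_info
  ok <- !is.na(pvalues)
  best <- list(ll = -Inf, set = integer(0), bin = config$bin_sizes_bp[1])
  warned <- FALSE
  for (bs in config$bin_sizes_bp) {
    bin_id <- paste(info$chrom, info$pos %/% bs)
    ord <- order(pvalues, info$pos)     # ties broken by lower position
    ord <- ord[ok[ord]]
    reps <- ord[!duplicated(bin_id[ord])]
    cand <- reps[pvalues[reps] < config$qtn_p_threshold]
    if (length(cand) == 0) next
    if (length(cand) < min(config$qtn_counts) && !warned) {
      warn(sprintf(
        "Only %d candidate bin(s) beat the pseudo-QTN entry threshold; counts shrunk.",
        length(cand)))
      warned <- TRUE
    }
    for (qc in config$qtn_counts) {
      set <- cand[seq_len(min(qc, length(cand)))]
      K <- kinship_from_snps(genotypes, set)
      ll <- reml_1vc(y, K)$loglik
      if (ll > best$ll) best <- list(ll = ll, set = sort(set), bin = bs)
    }
  }
  structure(best$set, bin_size_bp = best$bin)
}

# VanRaden-style kinship restricted to the given SNP columns (allows a
# single SNP, unlike the user-facing kinship builder).
kinship_from_snps <- function(genotypes, snps) {
  d <- genotypes$dosages[, snps, drop = FALSE]
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) return(diag(nrow(d)) * 0)
  Z <- sweep(d, 2, 2 * p)
  tcrossprod(Z) / denom
}

# Single-variance-component REML (EMMA-style): y = X b + u + e with
# u ~ N(0, s2u * K). Profiles the variance ratio on an eigendecomposition
# of K; returns the REML log-likelihood at the optimum.
reml_1vc <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  nd <- n - p
  ll_at <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (delta * lam + 1)
    xwx <- crossprod(Xt, w * Xt)
    bhat <- solve(xwx, crossprod(Xt, w * yt))
    r <- yt - Xt %*% bhat
    s2 <- sum(w * r^2) / nd
    -0.5 * (nd * (log(2 * pi * s2) + 1) + sum(log(delta * lam + 1)) +
              determinant(xwx, logarithm = TRUE)$modulus[1])
  }
  opt <- optimize(ll_at, interval = c(-12, 12), maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- 1 / (delta * lam + 1)
  xwx <- crossprod(Xt, w * Xt)
  bhat <- solve(xwx, crossprod(Xt, w * yt))
  s2e <- sum(w * (yt - Xt %*% bhat)^2) / nd
  # boundary: compare against delta -> 0 (pure residual model)
  ll0 <- ll_at(-30)
  if (ll0 > opt$objective) {
    return(list(loglik = ll0, sigma2_u = 0,
                sigma2_e = sum((yt - Xt %*% solve(crossprod(Xt),
                                                  crossprod(Xt, yt)))^2) / nd,
                delta = 0))
  }
  list(loglik = opt$objective, sigma2_u = delta * s2e, sigma2_e = s2e,
       delta = delta)
}

#' Benjamini-Hochberg significant set
#'
#' Step-up FDR control over the non-missing p-values.
#'
#' @param pvalues Numeric p-values (`NA` entries are excluded from the
#'   ranking and never declared significant).
#' @param q FDR level in `(0, 1]`.
#'
#' @return Integer indices of significant SNPs (into the input vector).
#' @export
#' @examples
#' fdr_threshold(c(0.01, 0.02, 0.2), q = 0.05)
fdr_threshold <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) abort("Empty p-value vector.")
  if (q <= 0 || q > 1) abort("`q` must be in (0, 1].")
  padj <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  padj[ok] <- p.adjust(pvalues[ok], method = "BH")
  which(!is.na(padj) & padj <= q)
}

#' Run the FarmCPU genome scan
#'
#' Iterates the fixed-effect per-SNP scan ([fem_scan()]) and the
#' random-effect pseudo-QTN selection ([rem_select()]): iteration 1 is a
#' plain covariate-adjusted scan; thereafter the best pseudo-QTN set
#' enters the next scan as covariates, until the set repeats or
#' `max_iterations` is reached. Significance is declared by
#' Benjamini-Hochberg FDR on the final scan's p-values.
#'
#' @inheritParams fem_scan
#' @param config A [farmcpu_config()].
#'
#' @return Object of class `farmcpu_fit`: list with `results` (tibble:
#'   `snp_id`, `chrom`, `pos`, `effect`, `pvalue`, `padj`,
#'   `significant`), `pseudo_qtns` (per-iteration index lists),
#'   `n_iterations`, `converged`, and `fdr_q`.
#' @seealso [tidy.farmcpu_fit()], [autoplot.farmcpu_fit()]
#' @export
farmcpu_run <- function(genotypes, y, config = farmcpu_config(),
                        covariates = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  y <- align_phenotype(genotypes, y)
  history <- list(integer(0))
  scan <- fem_scan(genotypes, y, covariates = covariates)
  converged <- FALSE
  iter <- 1L
  # iteration gate (reference FarmCPU): only circulate when the plain
  # scan shows a signal stronger than p_threshold (default 0.01 / m)
  gate <- config$p_threshold %||% (0.01 / n_snps(genotypes))
  if (min(scan$pvalue, na.rm = TRUE) > gate) converged <- TRUE
  while (!converged && iter < config$max_iterations) {
    sel <- rem_select(genotypes, y, scan$pvalue, config)
    if (any(vapply(history, function(h) setequal(h, sel), logical(1)))) {
      converged <- TRUE
      break
    }
    history <- c(history, list(as.integer(sel)))
    iter <- iter + 1L
    scan <- fem_scan(genotypes, y, covariates = covariates,
                     pseudo_qtns = sel,
                     bin_size_bp = attr(sel, "bin_size_bp"))
  }
  if (iter >= config$max_iterations && !converged) {
    warn("FarmCPU did not converge within `max_iterations`; returning last iteration.")
  }
  sig <- fdr_threshold(scan$pvalue, config$fdr_q)
  padj <- rep(NA_real_, nrow(scan))
  okp <- !is.na(scan$pvalue)
  padj[okp] <- p.adjust(scan$pvalue[okp], method = "BH")
  results <- scan %>%
    mutate(padj = padj,
           significant = dplyr::row_number() %in% sig)
  structure(list(
    results = results,
    pseudo_qtns = history[-1],
    n_iterations = iter,
    converged = converged,
    fdr_q = config$fdr_q
  ), class = "farmcpu_fit")
}

#' @export
print.farmcpu_fit <- function(x, ...) {
  cat(sprintf(
    "<farmcpu_fit> %d SNPs; %d iteration(s)%s; %d significant at BH q = %g\n",
    nrow(x$results), x$n_iterations,
    if (x$converged) " (converged)" else "",
    sum(x$results$significant), x$fdr_q
  ))
  invisible(x)
}

#' Tidy FarmCPU results into a per-SNP table
#' @param x A [farmcpu_run()] result.
#' @param ... Unused.
#' @return Tibble with per-SNP effect, p-value, BH-adjusted p-value and
#'   significance flag.
#' @method tidy farmcpu_fit
#' @export
tidy.farmcpu_fit <- function(x, ...) x$results

#' One-row summary of a FarmCPU run
#' @param x A [farmcpu_run()] result.
#' @param ... Unused.
#' @return Tibble with counts and convergence status.
#' @method glance farmcpu_fit
#' @export
glance.farmcpu_fit <- function(x, ...) {
  tibble(
    n_snps = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_iterations = x$n_iterations,
    n_pseudo_qtns = if (length(x$pseudo_qtns) > 0)
      length(x$pseudo_qtns[[length(x$pseudo_qtns)]]) else 0L,
    converged = x$converged,
    fdr_q = x$fdr_q
  )
}

# Align a phenotype to the genotype samples: accepts a bare numeric
# vector (positional), a named vector, a blup_fit, or a data frame with
# genotype_id plus blup/value.
align_phenotype <- function(genotypes, y) {
  if (inherits(y, "blup_fit")) y <- y$blups
  if (is.data.frame(y)) {
    vc <- intersect(c("blup", "value"), names(y))
    if (!("genotype_id" %in% names(y)) || length(vc) == 0) {
      abort("Phenotype data frame needs `genotype_id` and `blup` or `value`.")
    }
    y <- setNames(y[[vc[1]]], y$genotype_id)
  }
  if (!is.null(names(y))) {
    miss <- setdiff(genotypes$sample_ids, names(y))
    if (length(miss) > 0) {
      abort(paste0("Phenotype missing for sample(s): ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    y <- y[genotypes$sample_ids]
  }
  if (length(y) != n_samples(genotypes)) {
    abort("Phenotype length must equal the number of samples.")
  }
  if (anyNA(y)) abort("Phenotype contains missing values after alignment.")
  as.numeric(y)
}
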