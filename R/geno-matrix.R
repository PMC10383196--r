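#' Construct a genotype matrix object
#'
#' Container for a diploid biallelic SNP panel: an integer dosage matrix
#' (samples x SNPs, values 0/1/2 counting copies of the alternate allele,
#' `NA` for missing calls) together with per-SNP metadata.
#'
#' @param dosages Integer matrix, samples in rows and SNPs in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param snp_info Data frame with one row per SNP and columns `snp_id`,
#'   `chrom`, `pos` (base pairs, 1-based), and optionally `ref` and `alt`
#'   alleles. Positions must be strictly increasing within a chromosome.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   the row names of `dosages`.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosages`, `snp_info` (tibble) and `sample_ids`.
#' @export
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("snp1", "snp2"))),
#'   data.frame(snp_id = c("snp1", "snp2"), chrom = "chr1",
#'              pos = c(100L, 200L))
#' )
#' g
geno_matrix <- function(dosages, snp_info, sample_ids = rownames(dosages)) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix.")
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) abort("Dosages must be 0, 1, 2 or NA.")
  snp_info <- as_tibble(snp_info)
  req <- c("snp_id", "chrom", "pos")
  if (!all(req %in% names(snp_info))) {
    abort(paste0("`snp_info` must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(snp_info) != ncol(dosages)) {
    abort("`snp_info` must have one row per SNP column.")
  }
  incr <- tapply(snp_info$pos, snp_info$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(incr))) {
    abort("SNP positions must be strictly increasing within each chromosome.")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(dosages)))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_info$snp_id
  structure(
    list(dosages = dosages, snp_info = snp_info,
         sample_ids = as.character(sample_ids)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs on %d chromosome(s); %d missing call(s)\n",
    nrow(x$dosages), ncol(x$dosages),
    length(unique(x$snp_info$chrom)), nmiss
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of samples / SNPs in a genotype matrix
#' @param x A [geno_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$dosages)

#' @rdname n_samples
#' @export
n_snps <- function(x) ncol(x$dosages)

# Subset a geno_matrix by sample and/or SNP index, keeping metadata aligned.
subset_geno <- function(x, samples = NULL, snps = NULL) {
  d <- x$dosages
  info <- x$snp_info
  ids <- x$sample_ids
  if (!is.null(samples)) {
    d <- d[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    info <- info[snps, , drop = FALSE]
  }
  out <- geno_matrix(d, info, ids)
  attr(out, "qc_report") <- attr(x, "qc_report")
  out
}

# Per-SNP alternate allele frequency over non-missing calls.
allele_freq <- function(x) {
  colMeans(x$dosages, na.rm = TRUE) / 2
}

# Per-SNP minor allele frequency.
minor_allele_freq <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}
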