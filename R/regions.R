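#' Select peak SNPs from a genome scan
#'
#' Clumps significant SNPs around local peaks: the best-statistic
#' significant SNP (lowest p-value for FarmCPU, highest scaled importance
#' for SVR; ties broken by lower position) becomes a peak and absorbs all
#' significant SNPs within `cluster_window_bp` on its chromosome; the
#' procedure repeats on the remainder. Every significant SNP therefore
#' lies within the window of its cluster's peak.
#'
#' @param x A `farmcpu_fit`, an `svr_gwas_fit`, or a tibble with columns
#'   `snp_id`, `chrom`, `pos`, `score` (higher = stronger association)
#'   already restricted to significant SNPs.
#' @param cluster_window_bp Clustering gap in bp. Default 150000.
#'
#' @return Tibble of peaks: `snp_id`, `chrom`, `pos`, `score`,
#'   `n_member_snps`, and list-column `member_snps` (ids). Empty when
#'   there are no significant SNPs.
#' @export
peak_select <- function(x, cluster_window_bp = 150000) {
  sig <- significant_table(x)
  if (nrow(sig) == 0) {
    return(tibble(snp_id = character(), chrom = character(),
                  pos = integer(), score = numeric(),
                  n_member_snps = integer(), member_snps = list()))
  }
  sig <- sig %>% arrange(desc(.data$score), .data$pos)  # ties: lower pos
  peaks <- list()
  while (nrow(sig) > 0) {
    best <- sig[1, ]
    member <- sig$chrom == best$chrom &
      abs(sig$pos - best$pos) <= cluster_window_bp
    peaks[[length(peaks) + 1]] <- tibble(
      snp_id = best$snp_id, chrom = best$chrom, pos = best$pos,
      score = best$score, n_member_snps = sum(member),
      member_snps = list(sig$snp_id[member])
    )
    sig <- sig[!member, ]
  }
  bind_rows(peaks) %>% arrange(.data$chrom, .data$pos)
}

significant_table <- function(x) {
  if (inherits(x, "farmcpu_fit")) {
    r <- x$results %>% filter(.data$significant)
    return(tibble(snp_id = r$snp_id, chrom = r$chrom, pos = r$pos,
                  score = -log10(pmax(r$pvalue, 1e-300))))
  }
  if (inherits(x, "svr_gwas_fit")) {
    r <- x$results %>% filter(.data$significant)
    return(tibble(snp_id = r$snp_id, chrom = r$chrom, pos = r$pos,
                  score = r$importance))
  }
  x <- as_tibble(x)
  req <- c("snp_id", "chrom", "pos", "score")
  if (!all(req %in% names(x))) {
    abort(paste0("Need columns: ", paste(req, collapse = ", ")))
  }
  x
}

#' Flanking QTL regions around peak SNPs
#'
#' Builds `[peak - window, peak + window)` regions (clipped at 0) around
#' each peak and merges overlapping same-chromosome regions, unioning
#' their member SNPs; the merged region's peak is the best-statistic one.
#'
#' @param peaks A [peak_select()] tibble.
#' @param window_bp Flank size in bp on each side. Default 150000
#'   (the conventional flank derived from LD decay in soybean panels; see
#'   [ld_decay()] to recompute it from data).
#'
#' @return Tibble of class `qtl_regions`: `chrom`, `start`, `end`
#'   (half-open, bp), `peak_snp`, `peak_pos`, `peak_score`,
#'   `n_member_snps`, `member_snps` (list-column); disjoint and sorted.
#' @export
flanking_regions <- function(peaks, window_bp = 150000) {
  if (window_bp < 0) abort("`window_bp` must be >= 0.")
  if (nrow(peaks) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  peak_snp = character(), peak_pos = integer(),
                  peak_score = numeric(), n_member_snps = integer(),
                  member_snps = list())
    return(structure(out, class = c("qtl_regions", class(out))))
  }
  regs <- peaks %>%
    mutate(start = pmax(.data$pos - window_bp, 0),
           end = .data$pos + window_bp) %>%
    arrange(.data$chrom, .data$start)
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    if (!is.null(cur) && cur$chrom == r$chrom && r$start <= cur$end) {
      cur$end <- max(cur$end, r$end)
      cur$member_snps <- list(union(cur$member_snps[[1]], r$member_snps[[1]]))
      if (r$score > cur$peak_score) {
        cur$peak_snp <- r$snp_id
        cur$peak_pos <- r$pos
        cur$peak_score <- r$score
      }
    } else {
      if (!is.null(cur)) merged <- c(merged, list(cur))
      cur <- tibble(chrom = r$chrom, start = r$start, end = r$end,
                    peak_snp = r$snp_id, peak_pos = r$pos,
                    peak_score = r$score, member_snps = r$member_snps)
    }
  }
  merged <- c(merged, list(cur))
  out <- bind_rows(merged) %>%
    mutate(n_member_snps = lengths(.data$member_snps)) %>%
    select("chrom", "start", "end", "peak_snp", "peak_pos", "peak_score",
           "n_member_snps", "member_snps") %>%
    arrange(.data$chrom, .data$start)
  structure(out, class = c("qtl_regions", class(out)))
}

#' Per-allele additive effect of a SNP
#'
#' Slope of the phenotype regressed on allele dosage (trait units per
#' copy of the alternate allele), with dosage-class means.
#'
#' @param genotypes A [geno_matrix()].
#' @param y Phenotype aligned to samples (see [fem_scan()]).
#' @param snp SNP column index or `snp_id`.
#'
#' @return List with `effect`, `se`, and `class_means` (named mean
#'   phenotype per dosage class present).
#' @export
allelic_effect <- function(genotypes, y, snp) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (is.character(snp)) snp <- match(snp, genotypes$snp_info$snp_id)
  y <- align_phenotype(genotypes, y)
  d <- genotypes$dosages[, snp]
  ok <- !is.na(d)
  d <- d[ok]
  yy <- y[ok]
  if (sd(d) == 0) abort("SNP is monomorphic; allelic effect undefined.")
  fit <- lm(yy ~ d)
  cm <- tapply(yy, d, mean)
  list(effect = unname(coef(fit)[2]),
       se = unname(summary(fit)$coefficients[2, 2]),
       class_means = cm)
}

#' Co-localize QTL regions with interval annotations
#'
#' Reports every (region, annotation) pair overlapping by at least 1 bp,
#' under the half-open interval convention `[start, end)`.
#'
#' @param regions A [flanking_regions()] tibble (`chrom`, `start`, `end`,
#'   half-open).
#' @param annotations Tibble with `chrom`, `start`, `end`, `name`
#'   (half-open; see [read_annotations()]).
#'
#' @return Tibble of hits sorted by chromosome then start: region
#'   coordinates, `peak_snp`, `annotation`, and `overlap_bp`.
#' @export
colocalize <- function(regions, annotations) {
  annotations <- as_tibble(annotations)
  req <- c("chrom", "start", "end", "name")
  if (!all(req %in% names(annotations))) {
    abort(paste0("`annotations` needs columns: ", paste(req, collapse = ", ")))
  }
  bad <- which(annotations$start > annotations$end)
  if (length(bad) > 0) {
    abort(paste0("Malformed annotation interval(s) (start > end) at row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    a <- annotations %>% filter(.data$chrom == r$chrom)
    if (nrow(a) == 0) next
    ov <- pmin(a$end, r$end) - pmax(a$start, r$start)
    sel <- ov > 0
    if (!any(sel)) next
    hits[[length(hits) + 1]] <- tibble(
      chrom = r$chrom, region_start = r$start, region_end = r$end,
      peak_snp = r$peak_snp, annotation = a$name[sel],
      annotation_start = a$start[sel], annotation_end = a$end[sel],
      overlap_bp = ov[sel]
    )
  }
  if (length(hits) == 0) {
    return(tibble(chrom = character(), region_start = numeric(),
                  region_end = numeric(), peak_snp = character(),
                  annotation = character(), annotation_start = numeric(),
                  annotation_end = numeric(), overlap_bp = numeric()))
  }
  bind_rows(hits) %>% arrange(.data$chrom, .data$region_start,
                              .data$annotation_start)
}

#' Read interval annotations from BED or GFF3
#'
#' BED input (0-based half-open) is passed through; GFF3 (1-based closed)
#' is converted to the half-open convention used by [colocalize()].
#' Requires the `rtracklayer` package.
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return Tibble with `chrom`, `start`, `end` (half-open), `name`.
#' @export
read_annotations <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading annotations requires the 'rtracklayer' package.")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  nm <- if ("Name" %in% names(df)) df$Name
  else if ("name" %in% names(df)) df$name
  else if ("ID" %in% names(df)) df$ID
  else paste0("feature_", seq_len(nrow(df)))
  tibble(
    chrom = as.character(df$seqnames),
    start = df$start - 1,   # GRanges is 1-based closed; emit half-open
    end = df$end,
    name = as.character(nm)
  )
}
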