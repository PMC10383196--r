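#' Read genotypes from VCF or HapMap
#'
#' Reads diploid biallelic SNPs into a [geno_matrix()]; GT fields are
#' mapped to alternate-allele dosage. Multiallelic records are skipped
#' with a message. Positions must be sorted and unique within each
#' chromosome.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"hapmap"`.
#'
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
    else if (grepl("\\.(hmp|hapmap)(\\.txt)?$", path, ignore.case = TRUE)) "hapmap"
    else abort("Cannot infer format from extension; pass `format`.")
  }
  switch(format, vcf = read_vcf_geno(path), hapmap = read_hapmap_geno(path))
}

read_vcf_geno <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  dimnames(fix) <- list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                "QUAL", "FILTER")[seq_len(ncol(fix))])
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi)) {
    inform(sprintf("Skipping %d multiallelic record(s).", sum(multi)))
  }
  keep <- which(!multi)
  if (length(keep) == 0) abort("No biallelic SNPs in VCF.")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    g <- gt[j, ]
    g <- gsub("\\|", "/", g)
    dos[, j] <- dplyr::case_when(
      g %in% c("0/0") ~ 0L,
      g %in% c("0/1", "1/0") ~ 1L,
      g %in% c("1/1") ~ 2L,
      TRUE ~ NA_integer_
    )
  }
  info <- tibble(
    snp_id = unname(ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                           paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"]),
                           fix[keep, "ID"])),
    chrom = unname(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    ref = unname(fix[keep, "REF"]), alt = unname(fix[keep, "ALT"])
  )
  dup <- duplicated(paste(info$chrom, info$pos))
  if (any(dup)) abort("Duplicated positions within a chromosome.")
  geno_matrix(dos, info, colnames(gt))
}

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

read_hapmap_geno <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    comment.char = "", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 12) abort("HapMap file needs 11 leading columns plus samples.")
  samples <- names(tab)[-(1:11)]
  alleles <- strsplit(tab[[2]], "/")
  m <- nrow(tab)
  dos <- matrix(NA_integer_, length(samples), m)
  for (j in seq_len(m)) {
    a <- alleles[[j]]
    if (length(a) != 2) next  # non-biallelic row: left missing, dropped below
    codes <- toupper(unlist(tab[j, -(1:11)], use.names = FALSE))
    hom_ref <- c(a[1], paste0(a[1], a[1]))
    hom_alt <- c(a[2], paste0(a[2], a[2]))
    het2 <- c(paste0(a[1], a[2]), paste0(a[2], a[1]))
    het1 <- names(IUPAC_HET)[IUPAC_HET %in% c(paste0(sort(a), collapse = ""))]
    dos[, j] <- dplyr::case_when(
      codes %in% hom_ref ~ 0L,
      codes %in% hom_alt ~ 2L,
      codes %in% c(het2, het1) ~ 1L,
      TRUE ~ NA_integer_
    )
  }
  biallelic <- lengths(alleles) == 2
  if (any(!biallelic)) {
    inform(sprintf("Skipping %d non-biallelic record(s).", sum(!biallelic)))
  }
  keep <- which(biallelic)
  info <- tibble(
    snp_id = tab[[1]][keep], chrom = tab[[3]][keep],
    pos = as.integer(tab[[4]][keep]),
    ref = vapply(alleles[keep], `[`, "", 1),
    alt = vapply(alleles[keep], `[`, "", 2)
  )
  geno_matrix(dos[, keep, drop = FALSE], info, samples)
}

#' Write genotypes to VCF or HapMap
#'
#' Plain-text writers producing deterministic output: dosage 0/1/2 maps
#' to `0/0`, `0/1`, `1/1` (`./.` when missing) in VCF, and to two-letter
#' allele pairs (`NN` when missing) in the HapMap dialect with the
#' standard 11 leading columns.
#'
#' @param genotypes A [geno_matrix()].
#' @param path Output file.
#' @param format `"vcf"` or `"hapmap"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, format = c("vcf", "hapmap")) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  format <- match.arg(format)
  info <- genotypes$snp_info
  d <- genotypes$dosages
  ref <- if ("ref" %in% names(info)) info$ref else rep("A", nrow(info))
  alt <- if ("alt" %in% names(info)) info$alt else rep("T", nrow(info))
  if (format == "vcf") {
    gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d), ncol(d))
    gt[is.na(d)] <- "./."
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=svrgwas",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", genotypes$sample_ids), collapse = "\t"),
      vapply(seq_len(nrow(info)), function(j) {
        paste(c(info$chrom[j], info$pos[j], info$snp_id[j], ref[j], alt[j],
                ".", ".", ".", "GT", gt[, j]), collapse = "\t")
      }, character(1))
    )
  } else {
    code <- function(j) {
      g <- c(paste0(ref[j], ref[j]), paste0(ref[j], alt[j]),
             paste0(alt[j], alt[j]))[d[, j] + 1L]
      g[is.na(d[, j])] <- "NN"
      g
    }
    lines <- c(
      paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
              genotypes$sample_ids), collapse = "\t"),
      vapply(seq_len(nrow(info)), function(j) {
        paste(c(info$snp_id[j], paste0(ref[j], "/", alt[j]), info$chrom[j],
                info$pos[j], "+", "NA", "NA", "NA", "NA", "NA", "NA",
                code(j)), collapse = "\t")
      }, character(1))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Writes the genotypes as VCF (or HapMap), the plot-level phenotypes as
#' CSV, and the simulation ground truth (planted QTL, effects, variance
#' components, subpopulation labels) as a JSON sidecar, so a simulated
#' study can be re-analyzed like a real one while keeping the truth for
#' recovery checks.
#'
#' @param genotypes A [geno_matrix()], e.g. from [simulate_genotypes()].
#' @param phenotypes Plot-record tibble from [simulate_phenotypes()].
#' @param truth Truth list from [simulate_phenotypes()] (fields
#'   `qtl_snp_indices`, `qtl_effects`, variance components, ...).
#' @param dir Output directory (created if needed).
#' @param format Genotype format, `"vcf"` or `"hapmap"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(genotypes, phenotypes, truth, dir,
                             format = c("vcf", "hapmap")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(genotypes, file.path(
    dir, if (format == "vcf") "genotypes.vcf" else "genotypes.hmp.txt"),
    format)
  readr::write_csv(phenotypes, file.path(dir, "phenotypes.csv"))
  truth_out <- truth
  if (!is.null(truth_out$genetic_values)) {
    truth_out$genetic_values <- as.list(truth_out$genetic_values)
  }
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read plot-level phenotypes from CSV
#'
#' @param path CSV with columns `genotype_id`, `env_id`, `block_id`,
#'   optionally `row` and `column`, and one column per trait.
#' @return Tibble of plot records.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_csv(path, show_col_types = FALSE)
  check_plot_cols(ph, value_col = setdiff(
    names(ph), c("genotype_id", "env_id", "block_id", "row", "column"))[1])
  ph
}

#' Write QTL regions as BED
#'
#' Emits the standard 0-based half-open BED convention (internal starts
#' are already half-open base-pair offsets); score is the peak statistic.
#'
#' @param regions A [flanking_regions()] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- vapply(seq_len(nrow(regions)), function(i) {
    paste(c(regions$chrom[i], format(regions$start[i], scientific = FALSE),
            format(regions$end[i], scientific = FALSE),
            regions$peak_snp[i],
            formatC(regions$peak_score[i], digits = 6, format = "g")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
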