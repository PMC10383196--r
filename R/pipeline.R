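#' Run the full association pipeline
#'
#' Genotype QC (sample/SNP filters, Markov imputation), structure
#' covariates, per-trait phenotype preparation (nearest-neighbour spatial
#' adjustment, outlier screening, mixed-model BLUPs), one or both genome
#' scans, and peak-anchored QTL regions; all results are written to
#' `out_dir` as plain-text tables plus a machine-readable manifest. The
#' run is deterministic given `seed`.
#'
#' @param genotypes A [geno_matrix()] or path to a VCF/HapMap file.
#' @param phenotypes Tibble of plot records or path to a CSV (see
#'   [read_phenotypes()]).
#' @param traits Character vector of trait column names.
#' @param methods `"farmcpu"`, `"svr"`, or both (default).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed propagated to every stochastic stage.
#' @param k Assumed number of subpopulations for structure covariates.
#' @param sample_max_missing,snp_maf_min,snp_max_het,snp_max_missing QC
#'   thresholds (see [filter_samples()], [filter_snps()]).
#' @param farmcpu A [farmcpu_config()].
#' @param svr An [svr_config()] (its `seed` is overridden by `seed`).
#' @param window_bp Flank size for QTL regions.
#' @param annotations Optional annotation tibble or BED/GFF3 path for
#'   co-localization.
#'
#' @return Invisibly, a list with the fitted objects per trait/method and
#'   the manifest; files are written under `out_dir`.
#' @export
run_pipeline <- function(genotypes, phenotypes, traits,
                         methods = c("farmcpu", "svr"),
                         out_dir, seed = 1,
                         k = 7,
                         sample_max_missing = 0.5, snp_maf_min = 0.05,
                         snp_max_het = 0.5, snp_max_missing = 0.2,
                         farmcpu = farmcpu_config(),
                         svr = svr_config(n_permutations = 100),
                         window_bp = 150000,
                         annotations = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  phenotypes <- as_tibble(phenotypes)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4 + length(traits) * length(methods))

  g <- genotypes %>%
    filter_samples(sample_max_missing) %>%
    filter_snps(maf_min = snp_maf_min, max_het = snp_max_het,
                max_missing = snp_max_missing) %>%
    impute_markov(seed = seeds[[1]])
  qc <- qc_report(g)
  jsonlite::write_json(as.list(qc), file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE)

  covar <- structure_covariates(g, k = min(k, n_samples(g)))

  fits <- list()
  si <- 4L
  for (trait in traits) {
    plots <- phenotypes %>%
      nna_adjust(value_col = trait) %>%
      detect_outliers(value_col = trait)
    blup <- fit_blup(plots, value_col = trait, trait = trait)
    readr::write_csv(tidy(blup), file.path(out_dir,
                                           paste0("blup_", trait, ".csv")))
    fits[[trait]] <- list(blup = blup)
    for (method in methods) {
      si <- si + 1L
      fit <- if (method == "farmcpu") {
        farmcpu_run(g, blup, config = farmcpu, covariates = covar)
      } else {
        cfg <- svr
        cfg$seed <- as.integer(seeds[[si]])
        svr_gwas_run(g, blup, config = cfg)
      }
      res <- tidy(fit)
      readr::write_tsv(res, file.path(out_dir,
                                      paste0("gwas_", method, "_", trait, ".tsv")))
      regions <- flanking_regions(peak_select(fit, window_bp), window_bp)
      write_regions_bed(regions,
                        file.path(out_dir,
                                  paste0("regions_", method, "_", trait, ".bed")))
      if (!is.null(annotations) && nrow(regions) > 0) {
        hits <- colocalize(regions, annotations)
        readr::write_tsv(hits, file.path(out_dir,
                                         paste0("coloc_", method, "_", trait, ".tsv")))
      }
      fits[[trait]][[method]] <- fit
      fits[[trait]][[paste0(method, "_regions")]] <- regions
    }
  }

  manifest <- list(
    package = "svrgwas",
    version = as.character(utils::packageVersion("svrgwas")),
    seed = seed,
    traits = traits, methods = methods,
    n_samples = n_samples(g), n_snps = n_snps(g),
    qc = as.list(qc),
    thresholds = list(fdr_q = farmcpu$fdr_q, svr_alpha = svr$alpha,
                      window_bp = window_bp),
    outputs = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genotypes = g, fits = fits, manifest = manifest))
}

#' Benchmark the two scans on simulated data with known QTL
#'
#' Simulates `n_reps` panels from `config`, runs the full phenotype
#' preparation and the requested genome scans on each, and scores every
#' method against the planted truth: recall (fraction of planted QTL with
#' a significant SNP within `window_bp`), whether the largest-effect QTL
#' was hit, and the count of significant SNPs outside every QTL window
#' (false positives).
#'
#' @param config A [sim_config()] (its seed is re-derived per replicate).
#' @param n_reps Number of simulation replicates.
#' @param methods Scans to run.
#' @param farmcpu,svr Method configurations.
#' @param window_bp Hit window around each planted QTL.
#' @param seed Master seed.
#'
#' @return Tibble with one row per replicate x method: `rep`, `method`,
#'   `recall`, `hit_largest`, `n_significant`, `n_false_positive`.
#' @export
benchmark_methods <- function(config = sim_config(),
                              n_reps = 10,
                              methods = c("farmcpu", "svr"),
                              farmcpu = farmcpu_config(),
                              svr = svr_config(n_permutations = 100),
                              window_bp = 150000,
                              seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  seeds <- derive_seeds(seed, n_reps)
  out <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[[r]])
    sim <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(sim$genotypes, cfg)
    plots <- ph$phenotypes %>% nna_adjust() %>% detect_outliers()
    blup <- fit_blup(plots)
    covar <- structure_covariates(sim$genotypes,
                                  k = min(cfg$n_subpops + 1L,
                                          cfg$n_genotypes - 1L))
    truth <- ph$truth
    for (method in methods) {
      fit <- if (method == "farmcpu") {
        farmcpu_run(sim$genotypes, blup, config = farmcpu,
                    covariates = covar)
      } else {
        scfg <- svr
        scfg$seed <- as.integer(seeds[[r]] %% 2147480000 + 1)
        svr_gwas_run(sim$genotypes, blup, config = scfg)
      }
      out[[length(out) + 1]] <- score_against_truth(
        fit, sim$genotypes, truth, window_bp) %>%
        mutate(rep = r, method = method, .before = 1)
    }
  }
  bind_rows(out)
}

# Recall / false-positive scoring of one fit against planted QTL.
score_against_truth <- function(fit, genotypes, truth, window_bp) {
  res <- tidy(fit)
  sig <- res[res$significant, ]
  info <- genotypes$snp_info
  qtl <- truth$qtl_snp_indices
  if (length(qtl) == 0) {
    return(tibble(recall = NA_real_, hit_largest = NA,
                  n_significant = nrow(sig), n_false_positive = nrow(sig)))
  }
  near_qtl <- function(chrom, pos) {
    any(info$chrom[qtl] == chrom & abs(info$pos[qtl] - pos) <= window_bp)
  }
  hit <- vapply(qtl, function(q) {
    any(sig$chrom == info$chrom[q] &
          abs(sig$pos - info$pos[q]) <= window_bp)
  }, logical(1))
  largest <- qtl[which.max(abs(truth$qtl_effects))]
  fp <- if (nrow(sig) == 0) 0L else {
    sum(!vapply(seq_len(nrow(sig)),
                function(i) near_qtl(sig$chrom[i], sig$pos[i]), logical(1)))
  }
  tibble(recall = mean(hit),
         hit_largest = hit[match(largest, qtl)],
         n_significant = nrow(sig),
         n_false_positive = fp)
}
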