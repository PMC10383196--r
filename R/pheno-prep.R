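#' Nearest-neighbour (Papadakis) spatial adjustment of field plots
#'
#' Removes smooth spatial field variation from plot values by first-order
#' Papadakis adjustment. Within each environment, residuals from the
#' additive randomized-complete-block fit (genotype plus block means) are
#' computed; each plot's residual is regressed on the mean residual of
#' its neighbouring plots (rook neighbours within `neighborhood_radius`
#' grid steps along the same field row or column), and the fitted spatial
#' component is subtracted from the raw value. Removing the genotype
#' means first is what makes the neighbour covariate informative: raw
#' block-mean residuals are dominated by genetic variance, which carries
#' no spatial signal. Plots with no neighbours are returned unchanged.
#'
#' @param plots Tibble of plot records with columns `genotype_id`,
#'   `env_id`, `block_id`, `row`, `column`, `value`.
#' @param neighborhood_radius Neighbourhood radius in grid steps (>= 1).
#' @param value_col Name of the trait column to adjust. Default `"value"`.
#'
#' @return The input tibble with the trait column replaced by adjusted
#'   values (original values kept in `<value_col>_raw`).
#' @export
nna_adjust <- function(plots, neighborhood_radius = 1, value_col = "value") {
  plots <- as_tibble(plots)
  check_plot_cols(plots, value_col)
  if (!all(c("row", "column") %in% names(plots))) {
    abort("`plots` must carry `row` and `column` coordinates for NNA.")
  }
  if (neighborhood_radius < 1) abort("`neighborhood_radius` must be >= 1.")

  out <- plots
  out[[paste0(value_col, "_raw")]] <- plots[[value_col]]
  for (e in unique(plots$env_id)) {
    i <- which(plots$env_id == e)
    sub <- plots[i, ]
    if (nrow(sub) > 1 &&
        length(unique(paste(sub$row, sub$column))) == 1) {
      abort(sprintf(
        "All plots in environment '%s' share one coordinate; no spatial information.", e))
    }
    y <- sub[[value_col]]
    # residuals from the additive RCBD fit within the environment:
    # y - genotype mean - block mean + grand mean
    gm <- stats::ave(y, sub$genotype_id, FUN = function(v) mean(v, na.rm = TRUE))
    bm <- stats::ave(y, sub$block_id, FUN = function(v) mean(v, na.rm = TRUE))
    res <- y - gm - bm + mean(y, na.rm = TRUE)
    cov <- neighbour_mean_residual(sub$row, sub$column, res,
                                   neighborhood_radius)
    ok <- !is.na(res) & !is.na(cov)
    if (sum(ok) >= 3 && sd(cov[ok]) > 0) {
      slope <- coef(lm(res[ok] ~ cov[ok]))[2]
      adj <- y
      adj[ok] <- y[ok] - slope * cov[ok]
      out[[value_col]][i] <- adj
    }
  }
  out
}

# Mean residual over rook neighbours within `radius` steps on the plot
# grid; NA when a plot has no neighbour with an observed residual.
neighbour_mean_residual <- function(row, col, res, radius) {
  n <- length(row)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dr <- abs(row - row[i])
    dc <- abs(col - col[i])
    nb <- ((dr <= radius & dc == 0) | (dr == 0 & dc <= radius)) &
      !(dr == 0 & dc == 0)
    v <- res[nb]
    v <- v[!is.na(v)]
    if (length(v) > 0) out[i] <- mean(v)
  }
  out
}

#' Flag outlying plot values
#'
#' Standardizes each plot's residual from its environment-block mean and
#' marks values whose absolute standardized residual exceeds `z_cut` as
#' missing, the conventional treatment before mixed-model analysis.
#'
#' @inheritParams nna_adjust
#' @param z_cut Positive threshold on the absolute standardized residual.
#'   Default 3.5.
#'
#' @return The input tibble with flagged values set to `NA`, a logical
#'   `outlier` column, and attribute `n_outliers` with the count.
#' @export
detect_outliers <- function(plots, z_cut = 3.5, value_col = "value") {
  plots <- as_tibble(plots)
  check_plot_cols(plots, value_col)
  if (!is.numeric(z_cut) || is.na(z_cut) || z_cut <= 0) {
    abort("`z_cut` must be > 0.")
  }
  if (nrow(plots) < 10) abort("Need at least 10 plots to screen outliers.")
  y <- plots[[value_col]]
  grp <- paste(plots$env_id, plots$block_id)
  res <- y - stats::ave(y, grp, FUN = function(v) mean(v, na.rm = TRUE))
  s <- sd(res, na.rm = TRUE)
  z <- if (is.na(s) || s == 0) rep(0, length(res)) else res / s
  flag <- !is.na(z) & abs(z) > z_cut
  out <- plots
  out[[value_col]][flag] <- NA_real_
  out$outlier <- flag
  attr(out, "n_outliers") <- sum(flag)
  out
}

#' Fit the plot-level mixed model and extract genotype BLUPs
#'
#' Fits, by REML, the randomized-complete-block mixed model
#' `value = mu + block(fixed) + genotype(random) + genotype x env(random)
#' + residual`, with blocks nested in environments when several
#' environments are present. Returns shrunken per-genotype predictions
#' (BLUPs), the variance components, and the plot-basis heritability
#' `H2 = sigma2_G / (sigma2_G + sigma2_E)`.
#'
#' @inheritParams nna_adjust
#' @param trait Optional trait name used in messages.
#' @param entry_mean Also report entry-mean heritability
#'   `sigma2_G / (sigma2_G + sigma2_GxE/n_env + sigma2_E/(n_env*n_block))`.
#'
#' @return An object of class `blup_fit` with elements `blups` (tibble:
#'   `genotype_id`, `blup`), `vc` (list: `sigma2_g`, `sigma2_gxe`,
#'   `sigma2_e`, `mu`, `block_effects`), `h2`, optionally
#'   `h2_entry_mean`, and `n_outliers_removed`.
#' @seealso [heritability()], [tidy.blup_fit()], [glance.blup_fit()]
#' @export
fit_blup <- function(plots, value_col = "value", trait = value_col,
                     entry_mean = FALSE) {
  plots <- as_tibble(plots)
  check_plot_cols(plots, value_col)
  df <- data.frame(
    y = plots[[value_col]],
    genotype = factor(plots$genotype_id),
    env = factor(plots$env_id),
    block = factor(plots$block_id)
  )
  df <- df[!is.na(df$y), ]
  if (nlevels(droplevels(df$genotype)) < 2) {
    abort(sprintf("Trait '%s': need >= 2 genotypes to separate genetic variance.", trait))
  }
  multi_env <- nlevels(droplevels(df$env)) > 1
  multi_block <- nlevels(droplevels(factor(paste(df$env, df$block)))) >
    nlevels(droplevels(df$env))
  fixed <- if (multi_env && multi_block) "y ~ env + env:block"
  else if (multi_env) "y ~ env"
  else if (multi_block) "y ~ block"
  else "y ~ 1"
  form <- paste(fixed, "+ (1 | genotype)",
                if (multi_env) "+ (1 | genotype:env)" else "")
  fit <- tryCatch(
    lme4::lmer(stats::as.formula(form), data = df, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    error = function(e) abort(sprintf(
      "Trait '%s': mixed model failed to converge (%s).", trait, conditionMessage(e)))
  )
  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc_tab$vcov[vc_tab$grp == g]
    if (length(v) == 0) 0 else max(v, 0)
  }
  sigma2_g <- getv("genotype")
  sigma2_gxe <- getv("genotype:env")
  sigma2_e <- getv("Residual")
  fe <- lme4::fixef(fit)
  mu <- unname(fe[1])
  re <- lme4::ranef(fit)$genotype
  blups <- tibble(
    genotype_id = rownames(re),
    blup = mu + re[["(Intercept)"]]
  )
  h2 <- heritability(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e))
  out <- list(
    trait = trait,
    blups = blups,
    vc = list(sigma2_g = sigma2_g, sigma2_gxe = sigma2_gxe,
              sigma2_e = sigma2_e, mu = mu,
              block_effects = fe[-1]),
    h2 = h2,
    n_outliers_removed = attr(plots, "n_outliers") %||% 0L,
    model = fit
  )
  if (entry_mean) {
    ne <- max(nlevels(droplevels(df$env)), 1L)
    nb <- max(round(nrow(df) / (nlevels(droplevels(df$genotype)) * ne)), 1L)
    out$h2_entry_mean <-
      sigma2_g / (sigma2_g + sigma2_gxe / ne + sigma2_e / (ne * nb))
  }
  structure(out, class = "blup_fit")
}

#' Plot-basis heritability from variance components
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_E)`: the fraction of plot-level
#' phenotypic variance attributable to genotype, with the residual on the
#' single-plot basis (no division by replicate or environment counts).
#'
#' @param vc List (or `blup_fit$vc`) with non-negative `sigma2_g` and
#'   `sigma2_e`.
#'
#' @return Heritability in `[0, 1]`.
#' @export
#' @examples
#' heritability(list(sigma2_g = 0.69, sigma2_e = 0.31))
heritability <- function(vc) {
  sg <- vc$sigma2_g
  se <- vc$sigma2_e
  if (is.null(sg) || is.null(se) || sg < 0 || se < 0) {
    abort("`vc` must carry non-negative `sigma2_g` and `sigma2_e`.")
  }
  if (sg + se <= 0) abort("sigma2_g + sigma2_e must be > 0.")
  sg / (sg + se)
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf(
    "<blup_fit> trait '%s': %d genotypes; H2 = %.3f\n  sigma2_G = %.4g, sigma2_GxE = %.4g, sigma2_E = %.4g; %d outlier(s) removed\n",
    x$trait, nrow(x$blups), x$h2,
    x$vc$sigma2_g, x$vc$sigma2_gxe, x$vc$sigma2_e, x$n_outliers_removed
  ))
  invisible(x)
}

#' Tidy a BLUP fit into per-genotype predictions
#'
#' @param x A [fit_blup()] result.
#' @param ... Unused.
#' @return Tibble with `genotype_id` and `blup` (trait units).
#' @method tidy blup_fit
#' @export
tidy.blup_fit <- function(x, ...) x$blups

#' One-row summary of a BLUP fit
#'
#' @param x A [fit_blup()] result.
#' @param ... Unused.
#' @return Tibble with the variance components, heritability, and counts.
#' @method glance blup_fit
#' @export
glance.blup_fit <- function(x, ...) {
  tibble(
    trait = x$trait,
    sigma2_g = x$vc$sigma2_g, sigma2_gxe = x$vc$sigma2_gxe,
    sigma2_e = x$vc$sigma2_e, h2 = x$h2,
    n_genotypes = nrow(x$blups),
    n_outliers_removed = x$n_outliers_removed
  )
}

check_plot_cols <- function(plots, value_col = "value") {
  req <- c("genotype_id", "env_id", "block_id", value_col)
  miss <- setdiff(req, names(plots))
  if (length(miss) > 0) {
    abort(paste0("Plot table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(plots)
}
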