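# Cumulative genome coordinate for Manhattan panels.
manhattan_coords <- function(res) {
  chroms <- unique(res$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc)
    max(res$pos[res$chrom == cc]), numeric(1))))
  names(offs) <- c(chroms, "_end")
  res$genome_pos <- res$pos + offs[res$chrom]
  centers <- vapply(chroms, function(cc)
    mean(range(res$genome_pos[res$chrom == cc])), numeric(1))
  list(res = res, centers = centers, chroms = chroms)
}

#' Manhattan plot of a FarmCPU scan
#'
#' @param object A [farmcpu_run()] result.
#' @param ... Unused.
#' @return A ggplot object (`-log10 p` against genome position, with the
#'   effective Benjamini-Hochberg cut as a dashed line when any SNP is
#'   significant).
#' @method autoplot farmcpu_fit
#' @export
autoplot.farmcpu_fit <- function(object, ...) {
  mc <- manhattan_coords(object$results)
  res <- mc$res
  res$logp <- -log10(pmax(res$pvalue, 1e-300))
  p <- ggplot2::ggplot(res[!is.na(res$pvalue), ],
                       ggplot2::aes(x = .data$genome_pos, y = .data$logp,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_x_continuous(breaks = mc$centers, labels = mc$chroms,
                                guide = ggplot2::guide_axis(angle = 45)) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (any(object$results$significant)) {
    cut <- max(object$results$pvalue[object$results$significant], na.rm = TRUE)
    p <- p + ggplot2::geom_hline(yintercept = -log10(cut), linetype = 2)
  }
  p
}

#' Manhattan plot of an SVR-mediated scan
#'
#' @param object An [svr_gwas_run()] result.
#' @param ... Unused.
#' @return A ggplot object (scaled importance against genome position,
#'   with the permutation threshold as a dashed line).
#' @method autoplot svr_gwas_fit
#' @export
autoplot.svr_gwas_fit <- function(object, ...) {
  mc <- manhattan_coords(object$results)
  ggplot2::ggplot(mc$res,
                  ggplot2::aes(x = .data$genome_pos, y = .data$importance,
                               colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$threshold_scaled, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = mc$centers, labels = mc$chroms,
                                guide = ggplot2::guide_axis(angle = 45)) +
    ggplot2::labs(x = NULL, y = "Scaled importance (0-100)") +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of FarmCPU p-values
#'
#' @param fit A [farmcpu_run()] result.
#' @return A ggplot object comparing observed against uniform expected
#'   `-log10 p`.
#' @export
plot_qq <- function(fit) {
  stopifnot(inherits(fit, "farmcpu_fit"))
  p <- sort(fit$results$pvalue[!is.na(fit$results$pvalue)])
  df <- tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(pmax(p, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}
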