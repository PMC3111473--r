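#' Plot a per-sample distance profile
#'
#' Scatter of the per-sample D values by class with an overlaid boxplot —
#' the standard view of whether cases sit above controls for a SNP set.
#'
#' @param object A `poda_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' g <- sim_null_gwas(n_cases = 15, n_controls = 15, n_snps = 8, seed = 1)
#' prof <- sample_distance_statistics(g$genotypes, snp_ids(g$genotypes))
#' ggplot2::autoplot(prof)
#' @method autoplot poda_profile
#' @export
autoplot.poda_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$status, y = .data$D,
                                       colour = .data$status)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4,
                          colour = "grey40", fill = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(control = "black", case = "red"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "relative distance statistic D") +
    ggplot2::theme_minimal()
}

#' Plot per-pathway distinction scores against resampling significance
#'
#' @param object A `poda_fit` object.
#' @param label_top Label the `label_top` pathways with the smallest
#'   resampling p (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot poda_fit
#' @export
autoplot.poda_fit <- function(object, label_top = 5, ...) {
  df <- object$results
  df$neglogp <- -log10(df$p_resample)
  lab <- df[order(df$p_resample), ][seq_len(min(label_top, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$DS, y = .data$neglogp)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_snps), alpha = 0.7) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = .data$pathway),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "distinction score DS",
                  y = expression(-log[10] ~ "resampled p"),
                  size = "SNPs") +
    ggplot2::theme_minimal()
}
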