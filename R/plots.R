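# ggplot2 views of scan results and Bayes-factor curves.

#' Plot an introgression scan
#'
#' Genome-scan scatter of the df-theta estimate along each chromosome,
#' coloured by the supported introgression model and sized by the df-BF
#' evidence, so that high-estimate/low-evidence windows (few supporting
#' SNPs) are visually distinct from well-supported ones.
#'
#' @param object An [scan_introgression()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.introgression_scan <- function(object, ...) {
  d <- as_tibble(object)
  d <- filter(d, !is.na(.data$df_theta))
  d$mid <- (d$start + d$end) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid / 1e6, y = .data$df_theta,
                                  colour = .data$supported_model,
                                  size = .data$df_bf)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_size_continuous(name = "df-BF") +
    ggplot2::labs(x = "position (Mb)", y = expression(df[theta]),
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.introgression_scan
#' @param x An [scan_introgression()] result.
#' @param y Unused.
#' @export
plot.introgression_scan <- function(x, y, ...) {
  print(autoplot(x, ...))
  invisible(x)
}

#' Plot Bayes-factor scaling curves
#'
#' df-BF versus the number of maximally introgressed SNPs for each prior
#' combination, with Jeffreys' critical thresholds as horizontal
#' references.
#'
#' @param object A [bf_curve()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dfbf_curve <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_snps, y = .data$df_bf,
                                  colour = factor(.data$lambda_p))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(3, 10, 30, 100), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~lambda_s, labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "supporting SNPs", y = "df-BF",
                  colour = expression(lambda[p])) +
    ggplot2::theme_minimal()
}
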