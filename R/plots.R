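#' Boxplot of founder genome shares
#'
#' @param shares Tibble from [founder_shares()].
#' @return A ggplot; the dashed line marks the 12.5% funnel expectation.
#' @export
plot_founder_shares <- function(shares) {
  ggplot2::ggplot(shares, ggplot2::aes(.data$founder, 100 * .data$share)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 12.5, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "genome share (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Segregation-distortion profile along the genome
#'
#' Deviation of the observed reference-allele frequency from the
#' allele-frequency-group expectation, per SNP, faceted by chromosome;
#' significant SNPs (adjusted p below `alpha`) are highlighted.
#'
#' @param sd_results Tibble from [sd_test()].
#' @param map Genetic map.
#' @param alpha Highlight threshold on adjusted p (default 0.01).
#' @return A ggplot.
#' @export
plot_segregation <- function(sd_results, map, alpha = 0.01) {
  dat <- dplyr::inner_join(map, sd_results, by = "snp")
  dat$significant <- dat$p_adj < alpha
  ggplot2::ggplot(dat, ggplot2::aes(.data$pos, .data$deviation,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::facet_wrap(~chr, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (cM)", y = "allele-frequency deviation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
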