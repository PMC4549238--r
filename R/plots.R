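#' MA-style plot of tail-length change
#'
#' Plots each gene's interaction log2 fold change of the long/short ratio
#' against its average expression, highlighting genes below the FDR
#' threshold.
#'
#' @param results A [test_tail_change()] result.
#' @param fdr Highlight threshold on `BH_p_value`.
#' @return A ggplot object.
#' @export
plot_tail_ma <- function(results, fdr = 0.05) {
  df <- mutate(results,
               significant = !is.na(.data$BH_p_value) & .data$BH_p_value < fdr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logCPM, y = .data$log2FC_ratio,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red3")) +
    ggplot2::labs(x = "average log2 CPM",
                  y = "log2 FC of long/short ratio (mut vs wt)",
                  colour = sprintf("BH < %.2g", fdr)) +
    ggplot2::theme_bw()
}

#' ECDF comparison of modules against the background
#'
#' @param compare Result of [module_cdf_compare()].
#' @param modules Module ids to show (default: all in the result).
#' @return A ggplot object with one panel per module, background curve
#'   included.
#' @export
plot_module_ecdf <- function(compare, modules = NULL) {
  ec <- compare$ecdf
  if (!is.null(modules)) ec <- filter(ec, .data$module %in% modules)
  ggplot2::ggplot(ec, ggplot2::aes(x = .data$value, y = .data$ecdf,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = "log2 FC of long/short ratio", y = "ECDF",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Base-composition profile around the cleavage site
#'
#' @param profile A [base_composition_profile()] result.
#' @return A ggplot object (per-base frequency by position; 0 = first base
#'   after the cleavage site).
#' @export
plot_composition_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, c("A", "C", "G", "T"),
                              names_to = "base", values_to = "frequency")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$frequency,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "position relative to cleavage site (nt)",
                  y = "base frequency") +
    ggplot2::theme_bw()
}

#' Spike-in fraction-allocation summary plot
#'
#' @param spike_tbl A [spike_proxy_table()] result.
#' @return A ggplot object of short/long proxy ratios per spike and
#'   genotype; ratios above 1 indicate predominance in the short fraction.
#' @export
plot_spike_summary <- function(spike_tbl) {
  ggplot2::ggplot(spike_tbl,
                  ggplot2::aes(x = .data$spike, y = .data$ratio_short_long,
                               colour = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.shape = NA, position = "dodge") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.75)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "short/long abundance proxy ratio") +
    ggplot2::theme_bw()
}

#' ePAT difference curves
#'
#' @param diff Tibble from [epat_difference()].
#' @return A ggplot object.
#' @export
plot_epat_difference <- function(diff) {
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$size, y = .data$difference,
                                     colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "product size (bp)",
                  y = "normalized ePAT - control intensity") +
    ggplot2::theme_bw()
}
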