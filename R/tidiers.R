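#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a chi-square goodness-of-fit result
#'
#' @param x A `tailfrac_chisq` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
tidy.tailfrac_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @rdname tidy.tailfrac_chisq
#' @export
glance.tailfrac_chisq <- function(x, ...) tidy(x)

#' Tidy a Wilcoxon rank-sum result
#'
#' @param x A `tailfrac_wilcox` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `z`, `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
tidy.tailfrac_wilcox <- function(x, ...) {
  tibble(statistic = x$statistic, z = x$z, p_value = x$p_value,
         method = x$method, n_x = x$n_x, n_y = x$n_y)
}

#' Glance at a tail-change result table
#'
#' @param x A `tail_change_result` tibble.
#' @param fdr FDR threshold for the significant-gene count.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `n_tested`, `n_significant`,
#'   `median_log2FC`.
#' @export
glance.tail_change_result <- function(x, fdr = 0.05, ...) {
  tibble(n_genes = nrow(x),
         n_tested = sum(!is.na(x$p_value)),
         n_significant = sum(x$BH_p_value < fdr, na.rm = TRUE),
         median_log2FC = median(x$log2FC_ratio, na.rm = TRUE))
}
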