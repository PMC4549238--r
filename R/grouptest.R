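#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test. With 12 or fewer total
#' observations and no ties the p-value is exact, by enumeration of all rank
#' assignments; otherwise a normal approximation with tie-corrected variance
#' and a 0.5 continuity correction is used. This single implementation backs
#' every rank-sum comparison in the package (category sweeps, module
#' comparisons, motif association).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return Object of class `tailfrac_wilcox`: list with `statistic` (the
#'   Mann-Whitney U for `x`), `z` (NA for exact), `p_value`, `method`
#'   (`"exact"` or `"approx"`), `n_x`, `n_y`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value # exactly 1/3
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop_tailfrac("both groups must be non-empty", "tailfrac_domain_error")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  mu <- nx * ny / 2
  if (n <= 12 && !ties) {
    # enumerate all C(n, nx) rank assignments of the x group
    combs <- combn(n, nx)
    u_all <- colSums(matrix(seq_len(n)[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    out <- list(statistic = u, z = NA_real_, p_value = p, method = "exact",
                n_x = nx, n_y = ny)
  } else {
    tab <- rle(sort(r))$lengths
    tie_term <- sum(tab^3 - tab) / ((n) * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      z <- 0
    } else {
      cc <- sign(u - mu) * 0.5
      z <- (u - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    out <- list(statistic = u, z = z, p_value = p, method = "approx",
                n_x = nx, n_y = ny)
  }
  structure(out, class = "tailfrac_wilcox")
}

#' @export
print.tailfrac_wilcox <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): U = %g, p = %.4g (n = %d + %d)\n",
              x$method, x$statistic, x$p_value, x$n_x, x$n_y))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity. `NA` p-values are
#' passed through unchanged and excluded from the number of tests m.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_tailfrac("p-values must lie in [0, 1]", "tailfrac_domain_error")
  out <- p
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  out
}

#' Rank-sum sweep of gene categories against the background
#'
#' For every category with at least `min_size` members among the tested
#' genes, compares the members' values (tail-length or abundance log2 fold
#' changes) against all other tested genes — the transcriptome-wide
#' background — with [wilcoxon_rank_sum()], reports the members' median
#' value, and BH-adjusts across the tested categories. Categories may
#' overlap; each is tested independently. Undersized categories are skipped.
#'
#' @param values Tibble with columns `gene` and `value` (one value per tested
#'   gene, e.g. `log2FC_ratio`).
#' @param categories Tibble with columns `category_id`, `gene` (optionally
#'   `category_name`), many-to-many.
#' @param min_size Minimum tested members for a category to be tested.
#' @return Tibble of class `group_test_result`, sorted by p: `category_id`,
#'   `category_name`, `n`, `median_log2FC`, `p_value`, `BH_p_value`.
#' @export
category_sweep <- function(values, categories, min_size = 5) {
  stopifnot(all(c("gene", "value") %in% names(values)),
            all(c("category_id", "gene") %in% names(categories)))
  if (!"category_name" %in% names(categories))
    categories$category_name <- categories$category_id
  v <- stats::setNames(values$value, values$gene)
  universe <- names(v)
  rows <- categories |>
    filter(.data$gene %in% universe) |>
    group_by(.data$category_id, .data$category_name) |>
    summarise(members = list(unique(.data$gene)), .groups = "drop") |>
    mutate(n = purrr::map_int(.data$members, length)) |>
    filter(.data$n >= min_size)
  if (nrow(rows) == 0) {
    out <- tibble(category_id = character(), category_name = character(),
                  n = integer(), median_log2FC = double(),
                  p_value = double(), BH_p_value = double())
    class(out) <- c("group_test_result", class(out))
    return(out)
  }
  stats_tbl <- purrr::map(rows$members, function(mem) {
    inside <- v[mem]
    outside <- v[setdiff(universe, mem)]
    w <- wilcoxon_rank_sum(inside, outside)
    tibble(median_log2FC = median(inside), p_value = w$p_value)
  }) |> bind_rows()
  out <- bind_cols(rows[, c("category_id", "category_name", "n")], stats_tbl)
  out$BH_p_value <- benjamini_hochberg(out$p_value)
  out <- arrange(out, .data$p_value)
  class(out) <- c("group_test_result", class(out))
  out
}

#' Compare co-expression modules to all other genes
#'
#' For each module, the members' values are compared to all other tested
#' genes by [wilcoxon_rank_sum()]; modules are ranked by the absolute
#' difference between the module median and the median of the complement.
#' ECDF step coordinates for each module and its background are returned for
#' plotting.
#'
#' @param values Tibble with columns `gene`, `value`.
#' @param modules Tibble with columns `gene`, `module`; each gene belongs to
#'   at most one module.
#' @param min_size Minimum tested members for a module to be compared.
#' @return List with `result` (tibble: `module`, `n`, `median_module`,
#'   `median_others`, `median_diff`, `p_value`, `BH_p_value`, `rank`) and
#'   `ecdf` (tidy tibble of ECDF curves: `module`, `group`, `value`, `ecdf`).
#' @export
module_cdf_compare <- function(values, modules, min_size = 5) {
  stopifnot(all(c("gene", "value") %in% names(values)),
            all(c("gene", "module") %in% names(modules)))
  if (anyDuplicated(modules$gene))
    stop_tailfrac("each gene may be assigned to at most one module",
                  "tailfrac_data_error")
  v <- stats::setNames(values$value, values$gene)
  modules <- filter(modules, .data$gene %in% names(v))
  split_genes <- split(modules$gene, modules$module)
  split_genes <- split_genes[purrr::map_int(split_genes, length) >= min_size]
  res <- purrr::imap(split_genes, function(mem, mod) {
    outside_genes <- setdiff(names(v), mem)
    if (length(outside_genes) == 0)
      stop_tailfrac("module contains every tested gene (empty complement)",
                    "tailfrac_data_error")
    inside <- v[mem]; outside <- v[outside_genes]
    w <- wilcoxon_rank_sum(inside, outside)
    tibble(module = mod, n = length(mem),
           median_module = median(inside), median_others = median(outside),
           median_diff = median(inside) - median(outside),
           p_value = w$p_value)
  }) |> bind_rows()
  res$BH_p_value <- benjamini_hochberg(res$p_value)
  res <- arrange(res, desc(abs(.data$median_diff)))
  res$rank <- seq_len(nrow(res))
  ecdf_tbl <- purrr::imap(split_genes, function(mem, mod) {
    bind_rows(
      ecdf_steps(v[mem]) |> mutate(module = mod, group = "module"),
      ecdf_steps(v[setdiff(names(v), mem)]) |>
        mutate(module = mod, group = "background"))
  }) |> bind_rows()
  list(result = res, ecdf = ecdf_tbl[, c("module", "group", "value", "ecdf")])
}

ecdf_steps <- function(x) {
  x <- sort(x)
  tibble(value = x, ecdf = seq_along(x) / length(x))
}

#' Overlap of a gene list with reference lists
#'
#' Counts the overlap of a query gene list (e.g. the top-N most strongly
#' affected genes) with each of a set of reference lists, computes the
#' hypergeometric upper-tail p-value P(X >= k) with the list sizes as draws
#' from a universe of `universe_size` genes, and ranks the references by
#' overlap count with p-value as tie-break.
#'
#' @param query Character vector of gene ids (no duplicates).
#' @param references Named list of character vectors (no duplicates within a
#'   list).
#' @param universe_size Number of genes in the universe both lists are drawn
#'   from.
#' @return Tibble of class `overlap_result`: `list_id`, `overlap`, `n_query`,
#'   `n_reference`, `universe_size`, `p_value`, `rank`.
#' @export
list_overlap <- function(query, references, universe_size) {
  if (anyDuplicated(query))
    stop_tailfrac("duplicate ids in query list", "tailfrac_data_error")
  if (length(query) > universe_size)
    stop_tailfrac("query larger than universe", "tailfrac_domain_error")
  if (is.null(names(references)))
    names(references) <- sprintf("list_%03d", seq_along(references))
  rows <- purrr::imap(references, function(ref, id) {
    if (anyDuplicated(ref))
      stop_tailfrac(sprintf("duplicate ids in reference list '%s'", id),
                    "tailfrac_data_error")
    k <- length(intersect(query, ref))
    tibble(list_id = id, overlap = k, n_query = length(query),
           n_reference = length(ref), universe_size = universe_size,
           p_value = phyper(k - 1, length(query),
                            universe_size - length(query), length(ref),
                            lower.tail = FALSE))
  })
  out <- bind_rows(rows) |> arrange(desc(.data$overlap), .data$p_value)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("overlap_result", class(out))
  out
}

#' Select the top fraction of ranked overlap results
#'
#' Returns the `ceiling(fraction * m)` best-ranked reference lists, e.g. the
#' top 3% of 600 ranked experiments is exactly 18 lists.
#'
#' @param overlaps An [list_overlap()] result.
#' @param fraction Fraction of lists to keep, in (0, 1].
#' @return The selected rows.
#' @export
top_overlaps <- function(overlaps, fraction = 0.03) {
  stopifnot(fraction > 0, fraction <= 1)
  head(arrange(overlaps, .data$rank), ceiling(fraction * nrow(overlaps)))
}
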