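#' Filter genes with low counts
#'
#' Removes every gene whose count is 5 or less in one or more samples, i.e.
#' retains exactly the genes whose minimum count across all samples is at
#' least `min_count`. Spike-in rows are exempt: they are kept regardless and
#' remain flagged. The operation is idempotent.
#'
#' @param fc A [fraction_counts()] object.
#' @param min_count Minimum per-sample count a gene must reach everywhere
#'   (default 6, the boundary of the "5 or less reads" rule).
#' @return Filtered `fraction_counts` object.
#' @export
filter_low_counts <- function(fc, min_count = 6L) {
  stopifnot(inherits(fc, "fraction_counts"))
  if (nrow(fc$counts) == 0) return(fc)
  keep <- apply(fc$counts, 1, min) >= min_count | rownames(fc$counts) %in% fc$spike
  fraction_counts(fc$counts[keep, , drop = FALSE], fc$samples, spike = fc$spike)
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors. The reference sample is
#' the one whose 75th-percentile count fraction is closest to the mean across
#' samples. For every other sample, gene-wise M (log2 ratio) and A (average
#' log2 abundance) values versus the reference are computed on
#' library-size-scaled counts, genes with a zero in either library are
#' dropped, the top and bottom `trim_m` of M and `trim_a` of A are trimmed,
#' and the factor is 2 to the precision-weighted mean of the remaining M
#' values (weights = inverse delta-method variances). Factors are rescaled to
#' geometric mean 1. Spike-in rows are excluded from the M/A computation
#' (their fraction allocation differs by design and would distort trimming)
#' but are normalized by the resulting factors like any other gene.
#'
#' @param fc A [fraction_counts()] object (ideally after
#'   [filter_low_counts()]).
#' @param trim_m,trim_a Trim proportions for M and A values (defaults 0.30
#'   and 0.05).
#' @return Tibble of class `tailfrac_norm` with columns `sample`, `lib_size`,
#'   `tmm_factor`, `effective_lib_size`.
#' @export
tmm_factors <- function(fc, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(fc, "fraction_counts"))
  y_all <- fc$counts
  if (ncol(y_all) < 2)
    stop_tailfrac("TMM needs at least 2 samples", "tailfrac_data_error")
  lib <- colSums(y_all)
  if (any(lib == 0))
    stop_tailfrac(sprintf("all-zero sample: %s",
                          colnames(y_all)[which(lib == 0)[1]]),
                  "tailfrac_data_error")
  y <- y_all[setdiff(rownames(y_all), fc$spike), , drop = FALSE]
  if (!any(apply(y, 1, function(r) all(r > 0))))
    stop_tailfrac("need at least one gene with positive counts in all samples",
                  "tailfrac_data_error")
  f75 <- apply(y, 2, function(col) quantile(col, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    2^tmm_pair(y[, j], y[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))   # geometric mean 1
  tbl <- tibble(sample = colnames(y_all), lib_size = as.numeric(lib),
                tmm_factor = fac, effective_lib_size = as.numeric(lib) * fac)
  class(tbl) <- c("tailfrac_norm", class(tbl))
  tbl
}

# weighted trimmed mean of M values for one sample against the reference
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & w > 0
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  if (n == 0) return(0)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(0)
  f <- sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) 0 else f
}

#' Counts per million
#'
#' CPM on effective (TMM-scaled) library sizes. The `log2` variant adds a
#' prior count to stabilize low counts: the prior is scaled per sample in
#' proportion to its effective library size, added to the count, and twice
#' the scaled prior is added to the library size before taking log2.
#'
#' @param fc A [fraction_counts()] object.
#' @param state Normalization state from [tmm_factors()]; `NULL` uses raw
#'   library sizes with factor 1.
#' @param log2 Return log2 CPM?
#' @param prior_count Prior count for the log2 variant.
#' @return Numeric matrix, genes x samples.
#' @export
counts_per_million <- function(fc, state = NULL, log2 = FALSE,
                               prior_count = 0.5) {
  stopifnot(inherits(fc, "fraction_counts"))
  eff <- effective_sizes(fc, state)
  y <- fc$counts
  if (!log2) return(t(t(y) / eff) * 1e6)
  pc <- prior_count * eff / mean(eff)
  base::log2(t((t(y) + pc) / (eff + 2 * pc)) * 1e6)
}

effective_sizes <- function(fc, state) {
  if (is.null(state)) {
    eff <- colSums(fc$counts)
  } else {
    i <- match(colnames(fc$counts), state$sample)
    if (anyNA(i))
      stop_tailfrac("normalization state does not cover all samples",
                    "tailfrac_data_error")
    eff <- state$effective_lib_size[i]
  }
  stats::setNames(as.numeric(eff), colnames(fc$counts))
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param counts Numeric vector or matrix of fragment counts.
#' @param gene_lengths Exonic lengths in bp (> 0), recycled across columns
#'   for a matrix.
#' @param library_size Mapped fragments per library.
#' @return FPKM values with the shape of `counts`.
#' @export
fpkm <- function(counts, gene_lengths, library_size) {
  if (any(gene_lengths <= 0))
    stop_tailfrac("gene lengths must be > 0", "tailfrac_domain_error")
  counts / (gene_lengths / 1e3) / (library_size / 1e6)
}

#' Hierarchical clustering of samples by long/short ratio profiles
#'
#' Diagnostic clustering of the per-replicate tail-length proxy: the distance
#' between two samples is one minus the Pearson correlation of their per-gene
#' long/short log-ratio vectors over retained genes, followed by
#' average-linkage hierarchical clustering. Columns are ordered
#' lexicographically before clustering so the leaf order is deterministic.
#'
#' @param ratios Tibble with a `gene` column and one numeric column of
#'   long/short log-ratios per (genotype, replicate) sample, e.g. from
#'   [tail_ratio_matrix()].
#' @param expr Optional tibble (`gene`, `expr`) of mean expression used to
#'   drop lowly expressed genes.
#' @param min_expr Genes with `expr` below this are excluded (default 0.5,
#'   the fpkm filter used for this diagnostic).
#' @return List with `dist` (the `dist` object) and `hclust` (average
#'   linkage tree).
#' @export
cluster_samples <- function(ratios, expr = NULL, min_expr = 0.5) {
  stopifnot("gene" %in% names(ratios))
  m <- as.matrix(ratios[, setdiff(names(ratios), "gene"), drop = FALSE])
  rownames(m) <- ratios$gene
  if (!is.null(expr)) {
    keep <- expr$gene[expr$expr >= min_expr]
    m <- m[rownames(m) %in% keep, , drop = FALSE]
  }
  if (ncol(m) < 2)
    stop_tailfrac("need at least 2 ratio columns", "tailfrac_data_error")
  m <- m[, order(colnames(m)), drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop_tailfrac(sprintf("constant ratio vector (correlation undefined): %s",
                          colnames(m)[which(sds == 0)[1]]),
                  "tailfrac_data_error")
  d <- as.dist(1 - cor(m))
  list(dist = d, hclust = hclust(d, method = "average"))
}

#' Per-replicate long/short log2-ratio matrix
#'
#' For each (genotype, replicate) pair, the gene-wise log2 ratio of
#' prior-stabilized CPM in the long fraction over the short fraction — the
#' per-replicate poly(A)-tail-length proxy used for sample clustering.
#'
#' @inheritParams counts_per_million
#' @return Tibble with `gene` plus one column per (genotype, replicate),
#'   named `genotype_replicate`.
#' @export
tail_ratio_matrix <- function(fc, state = NULL, prior_count = 0.5) {
  lc <- counts_per_million(fc, state, log2 = TRUE, prior_count = prior_count)
  s <- fc$samples
  pairs <- distinct(s[, c("genotype", "replicate")])
  cols <- purrr::pmap(pairs, function(genotype, replicate) {
    long <- s$sample[s$genotype == genotype & s$replicate == replicate &
                       s$fraction == "long"]
    short <- s$sample[s$genotype == genotype & s$replicate == replicate &
                        s$fraction == "short"]
    lc[, long] - lc[, short]
  })
  names(cols) <- paste(pairs$genotype, pairs$replicate, sep = "_")
  bind_cols(tibble(gene = rownames(lc)), as_tibble(cols))
}
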