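## Per-gene negative-binomial GLM machinery.
##
## Model per gene: log mu = b0 + b1*long + b2*mut + b3*long:mut + offset,
## offset = log(effective library size). b3 is the log ratio-of-ratios: the
## change of the long/short capture odds between genotypes, i.e. the
## tail-length-change signal. Fitting is IRLS with a fixed per-gene
## dispersion; significance is a likelihood-ratio test against chi-square(1).

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi <= 0) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
              (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi <= 0) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# IRLS fit of an NB GLM with log link, fixed dispersion phi and offset.
nb_glm_fit <- function(y, X, offset, phi, max_iter = 50, tol = 1e-8) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  dev <- nb_deviance(y, mu, phi)
  beta <- rep(NA_real_, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta <- fit$coefficients
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    dev_new <- nb_deviance(y, mu, phi)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(beta = beta, mu = mu, deviance = dev,
       loglik = nb_loglik(y, mu, phi), converged = converged)
}

# build the fraction x genotype design from sample metadata
tail_design <- function(samples, reference) {
  genotype <- factor(samples$genotype,
                     levels = c(reference,
                                setdiff(unique(samples$genotype), reference)))
  fraction <- factor(samples$fraction, levels = c("short", "long"))
  if (nlevels(genotype) != 2)
    stop_tailfrac("exactly two genotype levels required", "tailfrac_data_error")
  if (nlevels(droplevels(fraction)) != 2)
    stop_tailfrac("both fractions must be present", "tailfrac_data_error")
  model.matrix(~ fraction * genotype)
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments dispersion from the squared residuals of a per-gene
#' Poisson fit of the full design, floored at zero, then shrunk toward the
#' common dispersion with a prior weight equivalent to 10 residual degrees
#' of freedom. The common dispersion is the mean of the per-gene raw
#' estimates: their sampling distribution at few residual df is strongly
#' right-skewed, so the median would systematically underestimate the common
#' value and inflate the type-I error of downstream tests.
#'
#' @param fc A filtered [fraction_counts()] object.
#' @param state Normalization state from [tmm_factors()].
#' @param reference Reference genotype label (default: first genotype in the
#'   sample table).
#' @return Tibble with columns `gene`, `dispersion_raw`, `dispersion`.
#' @export
estimate_dispersions <- function(fc, state = NULL, reference = NULL) {
  stopifnot(inherits(fc, "fraction_counts"))
  if (is.null(reference)) reference <- fc$samples$genotype[1]
  X <- tail_design(fc$samples, reference)
  if (qr(X)$rank < ncol(X))
    stop_tailfrac("design matrix is not full rank", "tailfrac_data_error")
  n <- nrow(X); p <- ncol(X)
  if (n - p < 1)
    stop_tailfrac("no residual degrees of freedom for dispersion estimation",
                  "tailfrac_data_error")
  off <- log(effective_sizes(fc, state))
  raw <- apply(fc$counts, 1, function(y) {
    fit <- nb_glm_fit(y, X, off, phi = 0)
    mu <- fit$mu
    # E[(y-mu)^2] = mu + phi mu^2 under NB; only the squared residuals lose
    # p degrees of freedom to the fit, so the df correction applies to them
    max(0, (sum((y - mu)^2) * n / (n - p) - sum(mu)) / sum(mu^2))
  })
  common <- mean(raw)
  df_resid <- n - p
  shrunk <- (df_resid * raw + 10 * common) / (df_resid + 10)
  tibble(gene = rownames(fc$counts), dispersion_raw = as.numeric(raw),
         dispersion = as.numeric(shrunk))
}

#' Test for genotype-dependent poly(A)-tail-length change
#'
#' Per-gene negative-binomial GLM of counts on fraction, genotype and their
#' interaction, with offset log(effective library size). The interaction
#' coefficient is the log ratio-of-ratios — how much the long/short fraction
#' ratio (the tail-length proxy) changes in the test genotype relative to the
#' reference — reported as `log2FC_ratio`; negative values indicate shorter
#' poly(A) tails in the test genotype. Significance is a likelihood-ratio
#' test of the interaction against chi-square(1); p-values are
#' Benjamini-Hochberg adjusted over all tested genes. Spike-in rows are not
#' tested. Genes whose fit fails to converge are reported with `NA` p-values
#' and excluded from the BH denominator.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions Optional result of [estimate_dispersions()]; computed
#'   if missing.
#' @param prior_count Prior used for the descriptive per-genotype long/short
#'   log2-ratios and logCPM.
#' @return Tibble of class `tail_change_result`: `gene`, `log2FC_ratio`, one
#'   `log2_ls_<genotype>` column per genotype, `logCPM`, `p_value`,
#'   `BH_p_value`, sorted by `p_value`.
#' @export
test_tail_change <- function(fc, state = NULL, reference = NULL,
                             dispersions = NULL, prior_count = 0.5) {
  stopifnot(inherits(fc, "fraction_counts"))
  if (is.null(reference)) reference <- fc$samples$genotype[1]
  X <- tail_design(fc$samples, reference)
  X0 <- X[, -ncol(X), drop = FALSE]   # drop interaction
  off <- log(effective_sizes(fc, state))
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(fc, state, reference)
  keep <- setdiff(rownames(fc$counts), fc$spike)
  phi <- stats::setNames(dispersions$dispersion, dispersions$gene)[keep]
  y_mat <- fc$counts[keep, , drop = FALSE]

  fits <- purrr::map(seq_along(keep), function(i) {
    y <- y_mat[i, ]
    full <- nb_glm_fit(y, X, off, phi[i])
    red <- nb_glm_fit(y, X0, off, phi[i])
    if (!full$converged || !red$converged) {
      return(list(log2fc = NA_real_, p = NA_real_))
    }
    lrt <- max(0, red$deviance - full$deviance)
    list(log2fc = full$beta[ncol(X)] / log(2),
         p = pchisq(lrt, df = 1, lower.tail = FALSE))
  })
  log2fc <- purrr::map_dbl(fits, "log2fc")
  p <- purrr::map_dbl(fits, "p")
  if (anyNA(p))
    rlang::warn(sprintf("%d gene(s) failed to converge; reported as NA",
                        sum(is.na(p))))

  genos <- unique(fc$samples$genotype)
  ls <- purrr::map(genos, function(g) tail_proxy(fc, state, g, prior_count)[keep])
  names(ls) <- paste0("log2_ls_", genos)

  cpm_raw <- counts_per_million(fc, state, log2 = FALSE)[keep, , drop = FALSE]
  logcpm <- base::log2(rowMeans(cpm_raw) + prior_count)

  out <- bind_cols(
    tibble(gene = keep, log2FC_ratio = log2fc),
    as_tibble(ls),
    tibble(logCPM = as.numeric(logcpm), p_value = p,
           BH_p_value = benjamini_hochberg(p))
  ) |> arrange(.data$p_value)
  class(out) <- c("tail_change_result", class(out))
  out
}

#' Per-gene long/short tail-length proxy for one genotype
#'
#' The log2 ratio of prior-stabilized CPM summed over the genotype's long-
#' fraction libraries to that summed over its short-fraction libraries — the
#' relative abundance of each gene in the long versus the short fraction,
#' used as a proxy for its poly(A)-tail length distribution.
#'
#' @inheritParams estimate_dispersions
#' @param genotype Genotype label to summarize.
#' @param prior_count Prior added to each summed side before the ratio.
#' @return Named numeric vector of per-gene log2(long/short) values.
#' @export
tail_proxy <- function(fc, state = NULL, genotype, prior_count = 0.5) {
  s <- fc$samples
  if (!genotype %in% s$genotype)
    stop_tailfrac(sprintf("genotype '%s' not present", genotype),
                  "tailfrac_data_error")
  cpm <- counts_per_million(fc, state, log2 = FALSE)
  long <- s$sample[s$genotype == genotype & s$fraction == "long"]
  short <- s$sample[s$genotype == genotype & s$fraction == "short"]
  num <- rowSums(cpm[, long, drop = FALSE]) + prior_count
  den <- rowSums(cpm[, short, drop = FALSE]) + prior_count
  base::log2(num / den)
}

#' Test for overall transcript-abundance change
#'
#' Approximates the change in total transcript abundance between genotypes by
#' summing each (genotype, replicate) pair's long- and short-fraction counts
#' and fitting a per-gene negative-binomial GLM on genotype with offset
#' log(sum of the pair's effective library sizes); likelihood-ratio test on
#' the genotype coefficient, BH-adjusted over genes.
#'
#' @inheritParams test_tail_change
#' @return Tibble of class `abundance_change_result`: `gene`,
#'   `log2FC_abundance`, `p_value`, `BH_p_value`, sorted by `p_value`.
#' @export
test_abundance_change <- function(fc, state = NULL, reference = NULL,
                                  dispersions_combined = NULL) {
  stopifnot(inherits(fc, "fraction_counts"))
  s <- fc$samples
  if (is.null(reference)) reference <- s$genotype[1]
  eff <- effective_sizes(fc, state)
  pairs <- distinct(s[, c("genotype", "replicate")])
  comb <- vapply(seq_len(nrow(pairs)), function(i) {
    cols <- s$sample[s$genotype == pairs$genotype[i] &
                       s$replicate == pairs$replicate[i]]
    rowSums(fc$counts[, cols, drop = FALSE])
  }, numeric(nrow(fc$counts)))
  colnames(comb) <- paste(pairs$genotype, pairs$replicate, sep = "_")
  eff_comb <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(eff[s$sample[s$genotype == pairs$genotype[i] &
                       s$replicate == pairs$replicate[i]]])
  }, numeric(1))
  genotype <- factor(pairs$genotype,
                     levels = c(reference, setdiff(unique(pairs$genotype), reference)))
  X <- model.matrix(~ genotype)
  X0 <- X[, 1, drop = FALSE]
  off <- log(eff_comb)
  keep <- setdiff(rownames(comb), fc$spike)

  if (is.null(dispersions_combined)) {
    n <- nrow(X); p2 <- ncol(X)
    raw <- apply(comb[keep, , drop = FALSE], 1, function(y) {
      fit <- nb_glm_fit(y, X, off, phi = 0)
      max(0, (sum((y - fit$mu)^2) * n / (n - p2) - sum(fit$mu)) / sum(fit$mu^2))
    })
    common <- mean(raw)
    phi <- stats::setNames((( n - p2) * raw + 10 * common) / ((n - p2) + 10), keep)
  } else {
    phi <- stats::setNames(dispersions_combined$dispersion,
                           dispersions_combined$gene)[keep]
  }

  res <- purrr::map(keep, function(g) {
    y <- comb[g, ]
    full <- nb_glm_fit(y, X, off, phi[g])
    red <- nb_glm_fit(y, X0, off, phi[g])
    if (!full$converged || !red$converged)
      return(list(log2fc = NA_real_, p = NA_real_))
    lrt <- max(0, red$deviance - full$deviance)
    list(log2fc = full$beta[2] / log(2),
         p = pchisq(lrt, df = 1, lower.tail = FALSE))
  })
  out <- tibble(gene = keep,
                log2FC_abundance = purrr::map_dbl(res, "log2fc"),
                p_value = purrr::map_dbl(res, "p"))
  out$BH_p_value <- benjamini_hochberg(out$p_value)
  out <- arrange(out, .data$p_value)
  class(out) <- c("abundance_change_result", class(out))
  out
}

#' Spike-in abundance proxy
#'
#' Reference-free absolute-abundance proxy for spike-in controls: the
#' within-library fpkm multiplied by the sample's overall RNA concentration
#' and corrected by its proportion of mapped non-rRNA reads.
#'
#' @param data Tibble with numeric columns `fpkm`, `rna_concentration`,
#'   `mapped_nonrrna_fraction` (and any id columns, carried through).
#' @return The input with an added `proxy` column.
#' @export
spike_in_abundance_proxy <- function(data) {
  need <- c("fpkm", "rna_concentration", "mapped_nonrrna_fraction")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop_tailfrac(paste("missing columns:", paste(miss, collapse = ", ")),
                  "tailfrac_data_error")
  for (cn in c("rna_concentration", "mapped_nonrrna_fraction")) {
    bad <- which(is.na(data[[cn]]) | data[[cn]] <= 0)
    if (length(bad) > 0) {
      id <- if ("sample" %in% names(data)) data$sample[bad[1]] else bad[1]
      stop_tailfrac(sprintf("non-positive or missing %s for sample %s", cn, id),
                    "tailfrac_data_error")
    }
  }
  if (any(is.na(data$fpkm) | data$fpkm < 0))
    stop_tailfrac("fpkm values must be non-negative", "tailfrac_data_error")
  mutate(data, proxy = .data$fpkm * .data$rna_concentration *
           .data$mapped_nonrrna_fraction)
}

#' Spike-in fraction-allocation summary
#'
#' Computes the abundance proxy of every spike-in in every library and the
#' short/long proxy ratio per (spike, genotype, replicate). Ratios above 1
#' mean the spike is more abundant in the short fraction; the 30A control is
#' expected above 1 and the 75A/134A controls below 1.
#'
#' @param fc A [fraction_counts()] object whose sample table carries
#'   `rna_concentration` and `mapped_nonrrna_fraction`.
#' @param gene_lengths Named vector of transcript lengths (bp) covering the
#'   spike ids.
#' @return Tibble with one row per (spike, genotype, replicate):
#'   `proxy_short`, `proxy_long`, `ratio_short_long`.
#' @export
spike_proxy_table <- function(fc, gene_lengths) {
  if (length(fc$spike) == 0)
    stop_tailfrac("no spike-in rows flagged", "tailfrac_data_error")
  s <- fc$samples
  rows <- purrr::map(fc$spike, function(sp) {
    fp <- fpkm(fc$counts[sp, ], gene_lengths[[sp]], s$lib_size)
    tibble(spike = sp, sample = s$sample, genotype = s$genotype,
           replicate = s$replicate, fraction = s$fraction, fpkm = fp,
           rna_concentration = s$rna_concentration,
           mapped_nonrrna_fraction = s$mapped_nonrrna_fraction)
  })
  long <- spike_in_abundance_proxy(bind_rows(rows))
  long |>
    select("spike", "genotype", "replicate", "fraction", "proxy") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "proxy",
                       names_prefix = "proxy_") |>
    mutate(ratio_short_long = .data$proxy_short / .data$proxy_long)
}

#' qPCR abundance estimate
#'
#' Reference-free abundance proxy from a quantification cycle: the assay's
#' PCR efficiency raised to the power of minus ct.
#'
#' @param efficiency Per-cycle amplification efficiency, in (1, 2].
#' @param ct Quantification cycle(s).
#' @return `efficiency^(-ct)`.
#' @examples
#' qpcr_abundance(2, 10) # 1/1024
#' @export
qpcr_abundance <- function(efficiency, ct) {
  if (any(efficiency <= 1))
    stop_tailfrac("PCR efficiency must be > 1", "tailfrac_domain_error")
  efficiency^(-ct)
}
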