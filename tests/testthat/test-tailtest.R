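test_that("dispersion estimation needs residual degrees of freedom", {
  samples <- tidyr::expand_grid(genotype = c("wt", "mut"), replicate = 1,
                                fraction = c("short", "long"))
  samples$sample <- with(samples, paste(genotype, replicate, fraction, sep = "_"))
  counts <- matrix(50L, 3, 4, dimnames = list(paste0("g", 1:3), samples$sample))
  fc <- fraction_counts(counts, samples)
  expect_error(estimate_dispersions(fc), class = "tailfrac_data_error")
})

test_that("dispersion estimates recover Poisson and NB truth", {
  sim0 <- simulate_experiment(sim_config(
    n_genes = 1000, seed = 31, effect_fraction = 0, dispersion = 0,
    mean_expression = c(meanlog = log(1000), sdlog = 0)))
  fc0 <- filter_low_counts(sim0$counts)
  d0 <- estimate_dispersions(fc0, tmm_factors(fc0))
  expect_lt(median(d0$dispersion), 0.02)

  sim1 <- simulate_experiment(sim_config(
    n_genes = 1000, seed = 32, effect_fraction = 0, dispersion = 0.1,
    mean_expression = c(meanlog = log(1000), sdlog = 0)))
  fc1 <- filter_low_counts(sim1$counts)
  d1 <- estimate_dispersions(fc1, tmm_factors(fc1))
  expect_gt(median(d1$dispersion), 0.07)
  expect_lt(median(d1$dispersion), 0.13)
})

test_that("a flat gene gives zero interaction and p near 1", {
  m <- tiny_fc()$counts
  m[1, ] <- 80L
  fc <- tiny_fc(m)
  st <- tibble::tibble(sample = fc$samples$sample, lib_size = 1e6,
                       tmm_factor = 1, effective_lib_size = 1e6)
  res <- test_tail_change(fc, st)
  flat <- res[res$gene == "g1", ]
  expect_equal(flat$log2FC_ratio, 0, tolerance = 1e-6)
  expect_gt(flat$p_value, 0.95)
})

test_that("interaction estimate matches the plug-in ratio-of-ratios oracle", {
  # balanced zero-free high-count data: beta3/ln2 must equal the statistic
  # computed from mean CPMs directly
  sim <- simulate_experiment(sim_config(
    n_genes = 150, seed = 17, effect_fraction = 0.3, dispersion = 0.02,
    mean_expression = c(meanlog = log(5000), sdlog = 0)))
  fc <- filter_low_counts(sim$counts)
  st <- tmm_factors(fc)
  res <- test_tail_change(fc, st)
  cpm <- counts_per_million(fc, st)
  s <- fc$samples
  grp_mean <- function(g, f) rowMeans(cpm[, s$sample[s$genotype == g & s$fraction == f],
                                          drop = FALSE])
  plug <- log2(grp_mean("mut", "long") / grp_mean("mut", "short")) -
    log2(grp_mean("wt", "long") / grp_mean("wt", "short"))
  expect_equal(res$log2FC_ratio, unname(plug[res$gene]), tolerance = 0.02)
})

test_that("per-gene fits are independent of the rest of the matrix", {
  sim <- cached_sim()
  fc <- filter_low_counts(sim$counts)
  st <- tmm_factors(fc)
  disp <- estimate_dispersions(fc, st)
  res_all <- test_tail_change(fc, st, dispersions = disp)
  drop_gene <- res_all$gene[5]
  keep <- setdiff(rownames(fc$counts), drop_gene)
  fc2 <- fraction_counts(fc$counts[keep, ], fc$samples, spike = fc$spike)
  res_sub <- test_tail_change(fc2, st, dispersions = disp[disp$gene != drop_gene, ])
  shared <- intersect(res_all$gene, res_sub$gene)
  expect_equal(res_sub$log2FC_ratio[match(shared, res_sub$gene)],
               res_all$log2FC_ratio[match(shared, res_all$gene)],
               tolerance = 1e-12)
  expect_equal(res_sub$p_value[match(shared, res_sub$gene)],
               res_all$p_value[match(shared, res_all$gene)],
               tolerance = 1e-12)
})

test_that("the NB fit agrees with a reference GLM at fixed dispersion", {
  skip_if_not_installed("MASS")
  set.seed(5)
  fc <- tiny_fc()
  st <- tmm_factors(fc)
  y <- fc$counts[1, ]
  s <- fc$samples
  df <- data.frame(y = y,
                   fraction = factor(s$fraction, c("short", "long")),
                   genotype = factor(s$genotype, c("wt", "mut")),
                   off = log(st$effective_lib_size))
  ref <- glm(y ~ fraction * genotype + offset(off),
             family = MASS::negative.binomial(theta = 10), data = df)
  disp <- tibble::tibble(gene = rownames(fc$counts),
                         dispersion_raw = 0.1, dispersion = 0.1)
  res <- test_tail_change(fc, st, dispersions = disp)
  expect_equal(res$log2FC_ratio[res$gene == "g1"],
               unname(coef(ref)[4]) / log(2), tolerance = 1e-4)
})

test_that("tail proxy computes prior-stabilized long/short log2 ratios", {
  samples <- tidyr::expand_grid(genotype = "wt", replicate = 1:2,
                                fraction = c("short", "long"))
  samples$sample <- with(samples, paste(genotype, replicate, fraction, sep = "_"))
  counts <- matrix(0L, 2, 4, dimnames = list(c("gA", "gB"), samples$sample))
  counts["gA", samples$sample[samples$fraction == "long"]] <- 10L
  counts["gA", samples$sample[samples$fraction == "short"]] <- 10L
  counts["gB", samples$sample[samples$fraction == "long"]] <- 0L
  counts["gB", samples$sample[samples$fraction == "short"]] <- c(8L, 0L)
  fc <- fraction_counts(counts, samples)
  st <- tibble::tibble(sample = samples$sample, lib_size = 1e6,
                       tmm_factor = 1, effective_lib_size = 1e6)
  pr <- tail_proxy(fc, st, "wt")
  expect_equal(unname(pr["gA"]), 0)
  expect_equal(unname(pr["gB"]), log2(0.5 / 8.5))
  # doubling the long side gives +1
  counts["gA", samples$sample[samples$fraction == "long"]] <- 20L
  pr2 <- tail_proxy(fraction_counts(counts, samples), st, "wt")
  expect_equal(unname(pr2["gA"]), log2(40.5 / 20.5))
  expect_error(tail_proxy(fc, st, "nope"), class = "tailfrac_data_error")
})

test_that("abundance test recovers a planted twofold drop and stays null otherwise", {
  sim <- simulate_experiment(sim_config(
    n_genes = 800, seed = 23, effect_fraction = 0,
    abundance_effect_fraction = 0.1, abundance_log2 = -1,
    mean_expression = c(meanlog = log(400), sdlog = 0)))
  fc <- filter_low_counts(sim$counts)
  st <- tmm_factors(fc)
  res <- test_abundance_change(fc, st)
  tr <- sim$truth[match(res$gene, sim$truth$gene), ]
  expect_gt(mean(res$log2FC_abundance[tr$abundance_effect], na.rm = TRUE), -1.15)
  expect_lt(mean(res$log2FC_abundance[tr$abundance_effect], na.rm = TRUE), -0.85)
  flat <- res[res$gene %in% tr$gene[!tr$abundance_effect], ]
  expect_lt(mean(flat$p_value < 0.05, na.rm = TRUE), 0.12)
})

test_that("spike-in abundance proxy multiplies out and tracks tail length", {
  tb <- tibble::tibble(sample = "s1", fpkm = 10, rna_concentration = 20,
                       mapped_nonrrna_fraction = 0.5)
  expect_equal(spike_in_abundance_proxy(tb)$proxy, 100)
  expect_error(spike_in_abundance_proxy(dplyr::mutate(tb, rna_concentration = NA)),
               class = "tailfrac_data_error", regexp = "s1")
  expect_error(spike_in_abundance_proxy(tb[, -2]), class = "tailfrac_data_error")

  sim <- cached_sim()
  sp <- spike_proxy_table(sim$counts, sim$gene_lengths)
  r30 <- sp$ratio_short_long[sp$spike == "spike_30A"]
  expect_true(all(r30 > 1))
  expect_true(all(sp$ratio_short_long[sp$spike %in% c("spike_75A", "spike_134A")] < 1))
})

test_that("qPCR abundance proxy is efficiency to the power of minus ct", {
  expect_equal(qpcr_abundance(2, 10), 1 / 1024)
  expect_equal(qpcr_abundance(2, 9) / qpcr_abundance(2, 10), 2)
  expect_error(qpcr_abundance(1, 10), class = "tailfrac_domain_error")
})
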