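test_that("exact Wilcoxon p comes from full enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, 1 / 3, tolerance = 1e-12)
  # same multiset in both groups: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), class = "tailfrac_domain_error")
})

test_that("Wilcoxon is symmetric and matches the reference implementation", {
  set.seed(12)
  x <- rnorm(200); y <- rnorm(200, 1)
  w <- wilcoxon_rank_sum(x, y)
  expect_lt(w$p_value, 1e-10)
  expect_identical(w$p_value, wilcoxon_rank_sum(y, x)$p_value)
  ref <- wilcox.test(x, y, correct = TRUE)$p.value
  expect_equal(w$p_value, ref, tolerance = 1e-8)
  # small tie-free samples: exact path vs stats reference
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("exact and approximate Wilcoxon agree at the size boundary", {
  set.seed(3)
  for (rep in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    approx <- wilcoxon_rank_sum(a, b)      # n = 20: approximation
    expect_equal(approx$method, "approx")
    exact <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_lt(abs(approx$p_value - exact), 0.02)
  }
})

test_that("BH adjustment follows the step-up formula and handles NAs", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.4, 5)), rep(0.4, 5))
  p <- c(0.001, NA, 0.04, 0.9, NA, 0.013)
  adj <- benjamini_hochberg(p)
  expect_true(all(is.na(adj[c(2, 5)])))
  # NAs excluded from m: compare against p.adjust on the complete subset
  expect_equal(adj[!is.na(p)], p.adjust(p[!is.na(p)], "BH"))
  expect_true(all(adj >= p, na.rm = TRUE))
  expect_true(all(adj <= 1, na.rm = TRUE))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "tailfrac_domain_error")
})

test_that("category sweep finds a planted shift and skips small categories", {
  set.seed(21)
  values <- tibble::tibble(gene = sprintf("g%04d", 1:5050),
                           value = c(rnorm(5000), rnorm(50, -1)))
  categories <- dplyr::bind_rows(
    tibble::tibble(category_id = "hit", gene = sprintf("g%04d", 5001:5050)),
    tibble::tibble(category_id = "tiny", gene = sprintf("g%04d", 1:4)),
    tibble::tibble(category_id = "null", gene = sample(values$gene[1:5000], 60)))
  res <- category_sweep(values, categories, min_size = 5)
  expect_false("tiny" %in% res$category_id)
  hit <- res[res$category_id == "hit", ]
  expect_lt(hit$p_value, 1e-6)
  expect_equal(hit$median_log2FC, -1, tolerance = 0.35)
  expect_gt(res$p_value[res$category_id == "null"], 0.001)

  # invariant to gene ordering
  perm <- sample(nrow(values))
  res2 <- category_sweep(values[perm, ], categories, min_size = 5)
  expect_equal(res2$p_value, res$p_value)
})

test_that("category sweep p-values are roughly uniform under the null", {
  set.seed(9)
  values <- tibble::tibble(gene = sprintf("g%04d", 1:2000), value = rnorm(2000))
  cats <- dplyr::bind_rows(lapply(1:60, function(k)
    tibble::tibble(category_id = sprintf("c%02d", k),
                   gene = sample(values$gene, 50))))
  res <- category_sweep(values, cats)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("module comparison ranks a planted module first", {
  set.seed(33)
  n <- 3000
  values <- tibble::tibble(gene = sprintf("g%04d", 1:n), value = rnorm(n))
  modules <- tibble::tibble(gene = values$gene,
                            module = sprintf("M%02d", sample(1:30, n, TRUE)))
  planted <- modules$module == "M07"
  values$value[planted] <- values$value[planted] - 0.5
  cmp <- module_cdf_compare(values, modules)
  expect_equal(cmp$result$module[1], "M07")
  expect_equal(cmp$result$rank[1], 1L)
  # ECDFs are proper step functions from 0 to 1
  e <- cmp$ecdf[cmp$ecdf$module == "M07" & cmp$ecdf$group == "module", ]
  expect_true(all(diff(e$ecdf) >= 0))
  expect_equal(max(e$ecdf), 1)
  expect_gt(min(e$ecdf), 0)

  dup <- dplyr::bind_rows(modules, modules[1, ])
  expect_error(module_cdf_compare(values, dup), class = "tailfrac_data_error")
  allmod <- tibble::tibble(gene = values$gene, module = "M01")
  expect_error(module_cdf_compare(values, allmod), class = "tailfrac_data_error")
})

test_that("a null module matching the background ranks last with ~0 shift", {
  set.seed(4)
  values <- tibble::tibble(gene = sprintf("g%04d", 1:2000), value = rnorm(2000))
  modules <- tibble::tibble(gene = values$gene[1:400],
                            module = rep(c("null_copy", "shifted"), each = 200))
  values$value[values$gene %in% modules$gene[modules$module == "shifted"]] <-
    values$value[values$gene %in% modules$gene[modules$module == "shifted"]] + 1
  cmp <- module_cdf_compare(values, modules)
  expect_equal(cmp$result$module[1], "shifted")
  last <- cmp$result[cmp$result$module == "null_copy", ]
  expect_lt(abs(last$median_diff), 0.25)
})

test_that("hypergeometric overlap p equals exhaustive enumeration", {
  universe <- 20
  query <- sprintf("u%02d", 1:5)
  ref <- sprintf("u%02d", c(1, 2, 3, 10, 11))   # overlap 3
  res <- list_overlap(query, list(r = ref), universe_size = universe)
  expect_equal(res$overlap, 3L)
  # brute force over all C(20,5) reference draws
  draws <- combn(universe, 5)
  ks <- colSums(draws <= 5)                     # query = elements 1..5
  p_enum <- mean(ks >= 3)
  expect_equal(res$p_value, p_enum, tolerance = 1e-12)
})

test_that("overlap ranking and the top-fraction selector behave", {
  query <- sprintf("g%03d", 1:40)
  refs <- list(identical = query,
               disjoint = sprintf("g%03d", 101:140),
               partial = sprintf("g%03d", 21:60))
  res <- list_overlap(query, refs, universe_size = 500)
  expect_equal(res$list_id[1], "identical")
  expect_equal(res$overlap[res$list_id == "identical"], 40L)
  expect_equal(res$overlap[res$list_id == "disjoint"], 0L)
  expect_equal(res$overlap[res$list_id == "partial"], 20L)
  expect_error(list_overlap(c("a", "a"), refs, 500), class = "tailfrac_data_error")
  expect_error(list_overlap(query, list(x = c("b", "b")), 500),
               class = "tailfrac_data_error")
  expect_equal(nrow(top_overlaps(res, 0.5)), 2L)  # ceiling(0.5 * 3)
})
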