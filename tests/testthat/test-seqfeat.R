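toy_annotation <- function() {
  utr_annotation(tibble::tibble(
    gene = c("gp", "gm"), chrom = c("cp", "cm"), strand = c("+", "-"),
    stop_pos = c(2L, 8L), cleavage_sites = list(6L, 4L)))
}

test_that("terminal windows are strand-aware and end at the cleavage site", {
  genome <- c(cp = "TTACGTGGCC", cm = "AAAACCCGGT")
  ann <- toy_annotation()
  # plus strand: window 4 ending at site 6 covers 0-based [2,6) = "ACGT"
  w <- extract_terminal_window(ann, genome, window = 4)
  expect_equal(unname(w["gp"]), "ACGT")
  # minus strand: bases at 0-based coords 4..7 = "CCCG", reverse complement
  expect_equal(unname(w["gm"]), "CGGG")
  # a short UTR returns its full length (plus gene UTR length is 4)
  w10 <- extract_terminal_window(ann, genome, window = 10)
  expect_equal(nchar(unname(w10["gp"])), 4L)
  bad <- utr_annotation(tibble::tibble(gene = "gx", chrom = "cp", strand = "+",
                                       stop_pos = 2L, cleavage_sites = list(50L)))
  expect_error(extract_terminal_window(bad, genome), class = "tailfrac_data_error")
})

test_that("windows are invariant to reverse-complementing the genome", {
  sim <- cached_sim()
  w1 <- extract_terminal_window(sim$annotation, sim$genome, window = 80)
  # flip every contig and mirror the coordinates and strands
  flipped <- Biostrings::reverseComplement(sim$genome)
  L <- Biostrings::width(sim$genome)[match(sim$annotation$chrom,
                                           names(sim$genome))]
  ann2 <- utr_annotation(tibble::tibble(
    gene = sim$annotation$gene, chrom = sim$annotation$chrom,
    strand = ifelse(sim$annotation$strand == "+", "-", "+"),
    stop_pos = L - sim$annotation$stop_pos,
    cleavage_sites = purrr::map2(sim$annotation$cleavage_sites, L,
                                 function(cs, l) sort(l - cs))))
  w2 <- extract_terminal_window(ann2, flipped, window = 80)
  expect_identical(w1, w2[names(w1)])
})

test_that("a planted motif dominates the hexamer sweep", {
  set.seed(14)
  n <- 400
  genes <- sprintf("g%03d", 1:n)
  wins <- vapply(genes, function(g)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""), character(1))
  shifted <- genes[1:60]
  wins[shifted] <- plant_motif(wins[shifted], "CTGACA", shifted, window = 80,
                               seed = 2)
  values <- tibble::tibble(gene = genes,
                           value = ifelse(genes %in% shifted, rnorm(n, -1), rnorm(n)))
  res <- hexamer_sweep(wins, values)
  expect_equal(res$motif[1], "CTGACA")
  expect_lt(res$BH_p_value[1], 0.05)
  expect_equal(res$n_with[res$motif == "CTGACA"] +
                 res$n_without[res$motif == "CTGACA"], n)
})

test_that("degenerate motif configurations are skipped", {
  wins <- c(a = strrep("ACGTAC", 10), b = strrep("ACGTAC", 10))
  values <- tibble::tibble(gene = c("a", "b"), value = c(0, 1))
  res <- hexamer_sweep(wins, values)
  # identical windows: every present motif lacks a 'without' group
  expect_equal(nrow(res), 0L)
  vt <- variant_signal_test(c(a = strrep("C", 50), b = strrep("G", 50)),
                            tibble::tibble(gene = c("a", "b"), value = 0:1),
                            variants = "AATAAA")
  expect_equal(nrow(vt$result), 0L)
  expect_error(variant_signal_test(wins, values, variants = "AAUAAA"),
               class = "tailfrac_domain_error")
})

test_that("variant test covers the canonical signal and its 18 variants", {
  v <- aataaa_variants()
  expect_equal(length(v), 19L)
  expect_equal(v[1], "AATAAA")
  expect_true(all(nchar(v) == 6))
  expect_equal(anyDuplicated(v), 0L)

  set.seed(6)
  genes <- sprintf("g%03d", 1:300)
  wins <- vapply(genes, function(g)
    paste(sample(c("C", "G", "T"), 70, TRUE), collapse = ""), character(1))
  hit <- genes[1:50]
  wins[hit] <- plant_motif(wins[hit], "AAGAAA", hit, window = 70, seed = 3)
  values <- tibble::tibble(gene = genes,
                           value = ifelse(genes %in% hit, rnorm(300, -1), rnorm(300)))
  vt <- variant_signal_test(wins, values)
  row <- vt$result[vt$result$motif == "AAGAAA", ]
  expect_lt(row$BH_p_value, 0.05)
  # positional profile conserves the total occurrence count
  total <- sum(stringr::str_count(wins, "AAGAAA"))
  expect_equal(sum(vt$positions$count[vt$positions$motif == "AAGAAA"]), total)
  expect_true(all(vt$positions$position < 0))
})

test_that("base composition profile matches hand-tabulated toy counts", {
  genome <- c(cp = "TTACGTGGCC", cm = "AAAACCCGGT")
  ann <- toy_annotation()
  prof <- base_composition_profile(ann, genome, flank = 2)
  # positions -2,-1,0,1 relative to each cleavage site:
  # gp (+, cs=6): bases at 0-based 4..7 = G,T,G,G
  # gm (-, cs=4): transcript positions map to coords 5,4,3,2 complemented:
  #   C->G, C->G, A->T, A->T
  expect_equal(prof$position, c(-2L, -1L, 0L, 1L))
  expect_equal(prof$G, c(1, 0.5, 0.5, 0.5))
  expect_equal(prof$T, c(0, 0.5, 0.5, 0.5))
  expect_equal(prof$n, rep(2L, 4))
  rs <- rowSums(prof[, c("A", "C", "G", "T")])
  expect_equal(rs, rep(1, 4))
})

test_that("an all-A genome yields frequency one for A everywhere", {
  genome <- c(c1 = strrep("A", 400))
  ann <- utr_annotation(tibble::tibble(gene = "g1", chrom = "c1", strand = "+",
                                       stop_pos = 100L, cleavage_sites = list(200L)))
  prof <- base_composition_profile(ann, genome, flank = 50)
  expect_true(all(prof$A == 1))
  expect_true(all(prof[, c("C", "G", "T")] == 0))
  expect_error(base_composition_profile(ann[0, ], genome),
               class = "tailfrac_data_error")
})

test_that("feature correlations recover exact and degenerate relationships", {
  metric <- tibble::tibble(gene = sprintf("g%02d", 1:30), value = rnorm(30))
  features <- tibble::tibble(gene = metric$gene,
                             same = metric$value,
                             opposite = -metric$value,
                             flat = 1)
  res <- suppressWarnings(feature_correlations(metric, features))
  expect_equal(res$r[res$feature == "same"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$feature == "opposite"], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$feature == "flat"]))
  expect_warning(feature_correlations(metric, features[, c("gene", "flat")]),
                 regexp = "flat")
  # agrees with cor.test on a noisy feature
  features$noisy <- metric$value + rnorm(30)
  res2 <- suppressWarnings(feature_correlations(metric, features))
  ref <- cor.test(metric$value, features$noisy)
  expect_equal(res2$r[res2$feature == "noisy"], unname(ref$estimate))
  expect_equal(res2$p_value[res2$feature == "noisy"], ref$p.value)
})
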