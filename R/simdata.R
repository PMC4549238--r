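#' Configuration for a synthetic fractionation experiment
#'
#' Builds a validated configuration list for [simulate_experiment()]. The
#' defaults reproduce the study design the generator emulates: two genotypes
#' with four biological replicates each, two tail-length fractions separated
#' around a 50-nt oligo(dT)-capture cutoff (16 libraries), three spike-in RNAs
#' with defined tails of 30, 75 and 134 adenosines, negative-binomial count
#' noise, and a designated subset of genes whose poly(A) tails shorten in the
#' mutant genotype.
#'
#' @param n_genes Number of endogenous genes to simulate.
#' @param n_replicates Biological replicates per genotype (must be >= 2;
#'   downstream inference needs replication).
#' @param genotypes Two genotype labels; the first is the reference
#'   (wild type).
#' @param cutoff_nt Tail length (nt) at which a transcript is equally likely
#'   to elute in either fraction.
#' @param capture_steepness Logistic steepness of the capture curve, per nt.
#'   The default 0.15/nt gives ~95% long-fraction capture at cutoff + 20 nt.
#' @param tail_mean_range Range (nt) from which per-gene mean tail lengths are
#'   drawn uniformly.
#' @param tail_max Truncation point (nt) of the per-gene tail-length
#'   distribution; tails beyond ~150-200 nt are not observed in seedlings.
#' @param tail_shape Gamma shape of the within-gene tail-length distribution.
#' @param dispersion Negative-binomial dispersion phi of the count noise;
#'   0 gives Poisson counts.
#' @param mean_expression Named vector `c(meanlog=, sdlog=)` of the log-normal
#'   distribution of expected per-gene totals.
#' @param effect_fraction Proportion of genes with a genotype-dependent tail
#'   shortening.
#' @param effect_log2 Target interaction log2 fold change of the long/short
#'   capture odds for effect genes (negative = shorter tails in the mutant).
#' @param abundance_effect_fraction,abundance_log2 Optional overall-abundance
#'   effect: proportion of genes and log2 fold change of total expression in
#'   the mutant.
#' @param spike_tails Defined tail lengths (nt) of the spike-in control RNAs.
#' @param spike_mean Expected total count for each spike-in per sample.
#' @param planted_motif Optional hexamer planted into the terminal 3'-UTR
#'   window of every effect gene (ground truth for motif-association tests).
#' @param motif_window Length (nt) of the terminal window used when planting.
#' @param n_categories Number of random functional categories to emit in
#'   addition to the planted category of effect genes.
#' @param category_size_range Size range of the random categories.
#' @param n_modules Number of co-expression modules genes are partitioned
#'   into; effect genes are concentrated in the module named `"M10"`.
#' @param halflife_r Target Pearson correlation between generated half-lives
#'   and true wild-type mean tail length.
#' @param seed Root seed; all randomness derives from it.
#'
#' @return A list of class `tailfrac_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_replicates = 4,
                       genotypes = c("wt", "mut"),
                       cutoff_nt = 50,
                       capture_steepness = 0.15,
                       tail_mean_range = c(30, 150),
                       tail_max = 200,
                       tail_shape = 8,
                       dispersion = 0.1,
                       mean_expression = c(meanlog = log(150), sdlog = 1),
                       effect_fraction = 0.1,
                       effect_log2 = -1,
                       abundance_effect_fraction = 0,
                       abundance_log2 = 0,
                       spike_tails = c(30, 75, 134),
                       spike_mean = 500,
                       planted_motif = NULL,
                       motif_window = 100,
                       n_categories = 30,
                       category_size_range = c(20, 100),
                       n_modules = 60,
                       halflife_r = -0.21,
                       seed = 1L) {
  if (cutoff_nt <= 0) stop_tailfrac("`cutoff_nt` must be > 0", "tailfrac_config_error")
  if (effect_fraction < 0 || effect_fraction > 1)
    stop_tailfrac("`effect_fraction` must be in [0, 1]", "tailfrac_config_error")
  if (dispersion < 0) stop_tailfrac("`dispersion` must be >= 0", "tailfrac_config_error")
  if (any(spike_tails <= 0))
    stop_tailfrac("`spike_tails` must be strictly positive", "tailfrac_config_error")
  if (n_replicates < 2)
    stop_tailfrac("`n_replicates` must be >= 2: downstream inference requires replication",
                  "tailfrac_config_error")
  if (length(genotypes) != 2L || anyDuplicated(genotypes))
    stop_tailfrac("`genotypes` must be two distinct labels", "tailfrac_config_error")
  if (!is.null(planted_motif) && !grepl("^[ACGT]+$", planted_motif))
    stop_tailfrac("`planted_motif` must be an ACGT string", "tailfrac_config_error")
  cfg <- list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    genotypes = genotypes, cutoff_nt = cutoff_nt,
    capture_steepness = capture_steepness, tail_mean_range = tail_mean_range,
    tail_max = tail_max, tail_shape = tail_shape, dispersion = dispersion,
    mean_expression = mean_expression, effect_fraction = effect_fraction,
    effect_log2 = effect_log2,
    abundance_effect_fraction = abundance_effect_fraction,
    abundance_log2 = abundance_log2,
    spike_tails = spike_tails, spike_mean = spike_mean,
    planted_motif = planted_motif, motif_window = as.integer(motif_window),
    n_categories = as.integer(n_categories),
    category_size_range = as.integer(category_size_range),
    n_modules = as.integer(n_modules),
    halflife_r = halflife_r, seed = as.integer(seed)
  )
  structure(cfg, class = "tailfrac_config")
}

#' Probability that a transcript elutes in the long-tail fraction
#'
#' Logistic model of oligo(dT)-capture fractionation: a transcript with tail
#' length equal to `cutoff` is captured in the long fraction with probability
#' 0.5, and the probability increases with tail length at rate `steepness`.
#'
#' @param tail_length Tail length(s) in nucleotides; must be >= 0.
#' @param cutoff Fractionation cutoff (nt).
#' @param steepness Logistic steepness (1/nt).
#' @return Capture probabilities in (0, 1), same length as `tail_length`.
#' @examples
#' capture_probability(50, 50, 0.15) # 0.5 at the cutoff
#' capture_probability(30, 50, 0.15) # ~0.047
#' @export
capture_probability <- function(tail_length, cutoff = 50, steepness = 0.15) {
  if (any(tail_length < 0))
    stop_tailfrac("`tail_length` must be non-negative", "tailfrac_domain_error")
  plogis(steepness * (tail_length - cutoff))
}

# deterministic per-gene seed so gene order never changes a gene's draws
gene_seed <- function(root, i) {
  x <- (as.numeric(root) %% 99991 + 1) * 7919 + as.numeric(i) * 104729
  as.integer(x %% 2147483629)
}

# mean long-fraction capture probability of a gamma tail distribution,
# truncated at tail_max, by 201-point trapezoid quadrature
mean_capture <- function(tail_mean, shape, cutoff, steepness, tail_max = 200) {
  grid <- seq(0, tail_max, length.out = 201L)
  w <- dgamma(grid, shape = shape, rate = shape / tail_mean)
  w[c(1L, 201L)] <- w[c(1L, 201L)] / 2   # trapezoid end weights
  sum(w * plogis(steepness * (grid - cutoff))) / sum(w)
}

# shrinkage s of the mean tail that realises a target log2 odds-ratio of the
# mean capture probability (monotone in s, solved by uniroot)
solve_tail_shrink <- function(tail_mean, shape, cutoff, steepness, tail_max,
                              effect_log2) {
  if (effect_log2 == 0) return(1)
  p0 <- mean_capture(tail_mean, shape, cutoff, steepness, tail_max)
  target <- log2(p0 / (1 - p0)) + effect_log2
  f <- function(s) {
    p <- mean_capture(s * tail_mean, shape, cutoff, steepness, tail_max)
    log2(p / (1 - p)) - target
  }
  uniroot(f, lower = 0.02, upper = 5, tol = 1e-8)$root
}

#' Simulate a fractionation experiment with known ground truth
#'
#' Generates a full synthetic experiment: a gene-by-sample count matrix over
#' `2 genotypes x n_replicates x 2 fractions` libraries, spike-in control
#' rows, per-gene 3'-region sequences with annotation, functional categories,
#' co-expression module assignments, a per-gene feature table (half-lives,
#' 3'-UTR statistics), and a truth table recording each gene's true capture
#' probabilities and interaction log2 fold change.
#'
#' For each gene a mean tail length is drawn; the within-gene tail
#' distribution is gamma (shape `tail_shape`, truncated at `tail_max`), and
#' its mean long-fraction capture probability is obtained by numerical
#' quadrature over [capture_probability()]. Effect genes have their mutant
#' mean tail shrunk multiplicatively so that the log2 ratio of capture odds
#' between genotypes equals `effect_log2` exactly; that value is recorded as
#' the true interaction log2FC. Expected totals are split between fractions
#' by the capture probability, scaled by per-sample size factors (log-uniform
#' in \[0.7, 1.4\]), and counts are drawn negative-binomially with dispersion
#' `dispersion` (Poisson when 0). Spike-in rows receive identical expected
#' totals in every sample and genotype-independent tails.
#'
#' All randomness derives from `config$seed`; per-gene draws use seeded
#' substreams indexed by gene so results are reproducible bit-for-bit.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `tailfrac_sim` with elements `counts`
#'   (a [fraction_counts()] object), `truth`, `annotation`, `genome`
#'   (a `DNAStringSet`, one contig per gene), `categories`, `modules`,
#'   `features`, `gene_lengths` and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "tailfrac_config"))
  cf <- config
  n <- cf$n_genes
  genes <- sprintf("G%05d", seq_len(n))

  ## sample-level draws (root seed)
  set.seed(cf$seed)
  samples <- tidyr::expand_grid(
    genotype = cf$genotypes,
    replicate = seq_len(cf$n_replicates),
    fraction = c("short", "long")
  )
  samples$sample <- with(samples, paste(genotype, replicate, fraction, sep = "_"))
  n_smp <- nrow(samples)
  size_factor <- exp(runif(n_smp, log(0.7), log(1.4)))
  nonrrna <- runif(n_smp, 0.5, 0.8)

  n_eff <- round(cf$effect_fraction * n)
  eff_idx <- sort(sample.int(n, n_eff))
  n_ab <- round(cf$abundance_effect_fraction * n)
  ab_idx <- sort(sample.int(n, n_ab))

  ## per-gene parameters and counts, each from its own substream
  is_mut <- samples$genotype == cf$genotypes[2]
  is_long <- samples$fraction == "long"
  counts <- matrix(0L, n, n_smp, dimnames = list(genes, samples$sample))
  utr_len <- integer(n); n_utrs <- integer(n); strand <- character(n)
  gene_len <- integer(n)
  t_tm_wt <- numeric(n); t_tm_mut <- numeric(n)
  t_p_wt <- numeric(n); t_p_mut <- numeric(n)
  t_total <- numeric(n)
  t_effect <- logical(n); t_ab <- logical(n)

  for (i in seq_len(n)) {
    set.seed(gene_seed(cf$seed, i))
    tm_wt <- runif(1, cf$tail_mean_range[1], cf$tail_mean_range[2])
    total <- rlnorm(1, cf$mean_expression[["meanlog"]], cf$mean_expression[["sdlog"]])
    utr_len[i] <- sample(60:300, 1)
    n_utrs[i] <- 1L + rbinom(1, 1, 0.3)
    strand[i] <- sample(c("+", "-"), 1)
    gene_len[i] <- sample(800:3000, 1)

    effect <- i %in% eff_idx
    tm_mut <- tm_wt
    if (effect) {
      s <- solve_tail_shrink(tm_wt, cf$tail_shape, cf$cutoff_nt,
                             cf$capture_steepness, cf$tail_max, cf$effect_log2)
      tm_mut <- s * tm_wt
    }
    p_wt <- mean_capture(tm_wt, cf$tail_shape, cf$cutoff_nt,
                         cf$capture_steepness, cf$tail_max)
    p_mut <- if (effect) {
      mean_capture(tm_mut, cf$tail_shape, cf$cutoff_nt,
                   cf$capture_steepness, cf$tail_max)
    } else p_wt

    ab_effect <- i %in% ab_idx
    tot_mut <- total * if (ab_effect) 2^cf$abundance_log2 else 1

    p_smp <- ifelse(is_mut, p_mut, p_wt)
    tot_smp <- ifelse(is_mut, tot_mut, total)
    mu <- tot_smp * ifelse(is_long, p_smp, 1 - p_smp) * size_factor
    counts[i, ] <- if (cf$dispersion > 0) {
      rnbinom(n_smp, mu = mu, size = 1 / cf$dispersion)
    } else {
      rpois(n_smp, mu)
    }

    t_tm_wt[i] <- tm_wt; t_tm_mut[i] <- tm_mut
    t_p_wt[i] <- p_wt; t_p_mut[i] <- p_mut
    t_total[i] <- total; t_effect[i] <- effect; t_ab[i] <- ab_effect
  }
  truth <- tibble(
    gene = genes, spike = FALSE, effect = t_effect,
    tail_mean_wt = t_tm_wt, tail_mean_mut = t_tm_mut,
    p_capture_wt = t_p_wt, p_capture_mut = t_p_mut,
    true_log2fc_ratio = ifelse(t_effect, cf$effect_log2, 0),
    abundance_effect = t_ab,
    true_log2fc_abundance = ifelse(t_ab, cf$abundance_log2, 0),
    mean_expression = t_total
  )

  ## spike-in rows: equal expected totals in all samples, fixed tails
  spike_ids <- sprintf("spike_%dA", round(cf$spike_tails))
  spike_counts <- matrix(0L, length(cf$spike_tails), n_smp,
                         dimnames = list(spike_ids, samples$sample))
  set.seed(gene_seed(cf$seed, n + 1L))
  for (j in seq_along(cf$spike_tails)) {
    p <- capture_probability(cf$spike_tails[j], cf$cutoff_nt, cf$capture_steepness)
    mu <- cf$spike_mean * ifelse(is_long, p, 1 - p) * size_factor
    spike_counts[j, ] <- if (cf$dispersion > 0) {
      rnbinom(n_smp, mu = mu, size = 1 / cf$dispersion)
    } else rpois(n_smp, mu)
    truth <- bind_rows(truth, tibble(
      gene = spike_ids[j], spike = TRUE, effect = FALSE,
      tail_mean_wt = cf$spike_tails[j], tail_mean_mut = cf$spike_tails[j],
      p_capture_wt = p, p_capture_mut = p,
      true_log2fc_ratio = 0, abundance_effect = FALSE,
      true_log2fc_abundance = 0, mean_expression = cf$spike_mean
    ))
  }
  counts <- rbind(counts, spike_counts)

  ## sample metadata; concentration tracks total RNA per depth unit so that
  ## fpkm x concentration x non-rRNA fraction recovers absolute-scale amounts
  lib <- colSums(counts)
  samples$lib_size <- as.numeric(lib)
  samples$rna_concentration <- 50 * lib / (size_factor * 1e6 * nonrrna)
  samples$mapped_nonrrna_fraction <- nonrrna
  samples <- samples[, c("sample", "genotype", "replicate", "fraction",
                         "lib_size", "rna_concentration",
                         "mapped_nonrrna_fraction")]

  fc <- fraction_counts(counts, samples, spike = spike_ids)

  ## per-gene contigs: 120 nt upstream, the 3' UTR, 200 nt downstream flank;
  ## a random half of the genes sit on the minus strand
  genome_and_ann <- sim_gene_contigs(genes, utr_len, n_utrs, strand, cf$seed)
  genome <- genome_and_ann$genome
  annotation <- genome_and_ann$annotation

  if (!is.null(cf$planted_motif) && n_eff > 0) {
    wins <- extract_terminal_window(annotation, genome, window = cf$motif_window)
    planted <- plant_motif(wins, cf$planted_motif, genes[eff_idx],
                           window = cf$motif_window,
                           seed = gene_seed(cf$seed, n + 2L))
    genome <- replace_terminal_window(annotation, genome, planted)
  }

  half_life <- generate_half_lives(truth, target_r = cf$halflife_r,
                                   seed = gene_seed(cf$seed, n + 3L))
  features <- tibble(
    gene = genes,
    half_life = half_life[genes],
    utr_length = utr_len,
    n_utrs = n_utrs,
    mean_abundance = truth$mean_expression[match(genes, truth$gene)]
  )

  set.seed(gene_seed(cf$seed, n + 4L))
  categories <- sim_categories(genes, eff_idx, cf)
  modules <- sim_modules(genes, eff_idx, cf)

  gene_lengths <- c(stats::setNames(gene_len, genes),
                    stats::setNames(rep(1000L, length(spike_ids)), spike_ids))

  structure(list(counts = fc, truth = truth, annotation = annotation,
                 genome = genome, categories = categories, modules = modules,
                 features = features, gene_lengths = gene_lengths,
                 config = cf),
            class = "tailfrac_sim")
}

# builds one contig per gene plus its UTR annotation (internal 0-based
# half-open convention; see read_utr_annotation)
sim_gene_contigs <- function(genes, utr_len, n_utrs, strand, seed) {
  n <- length(genes)
  seqs <- character(n)
  stop0 <- integer(n)
  sites <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(gene_seed(seed, 3L * n + i))
    L <- 120L + utr_len[i] + 200L
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                            prob = c(0.32, 0.17, 0.17, 0.34)),
                     collapse = "")
    stop0[i] <- 120L
    cs <- 120L + utr_len[i]
    sites[[i]] <- if (n_utrs[i] > 1L)
      c(120L + as.integer(round(utr_len[i] * 0.6)), cs) else cs
    if (strand[i] == "-") {
      stop0[i] <- L - stop0[i]
      sites[[i]] <- sort(L - sites[[i]])
    }
  }
  minus <- strand == "-"
  genome <- DNAStringSet(stats::setNames(seqs, genes))
  genome[minus] <- reverseComplement(genome[minus])
  ann <- tibble(gene = genes, chrom = genes, strand = strand,
                stop_pos = stop0, cleavage_sites = sites)
  list(genome = genome, annotation = utr_annotation(ann))
}

sim_categories <- function(genes, eff_idx, cf) {
  cats <- purrr::map(seq_len(cf$n_categories), function(k) {
    sz <- min(sample(cf$category_size_range[1]:cf$category_size_range[2], 1),
              length(genes))
    tibble(category_id = sprintf("C%03d", k),
           category_name = sprintf("random category %d", k),
           gene = sample(genes, sz))
  })
  out <- bind_rows(cats)
  if (length(eff_idx) > 0) {
    out <- bind_rows(out, tibble(
      category_id = "C_target", category_name = "planted target genes",
      gene = genes[eff_idx]))
  }
  out
}

sim_modules <- function(genes, eff_idx, cf) {
  module <- sprintf("M%02d", sample.int(cf$n_modules, length(genes), replace = TRUE))
  if (length(eff_idx) > 0) module[eff_idx] <- "M10"  # planted target module
  tibble(gene = genes, module = module)
}

#' Generate per-gene mRNA half-lives correlated with tail length
#'
#' Draws positive half-lives (hours) whose Pearson correlation with the true
#' wild-type mean tail length matches `target_r`; the default reproduces the
#' moderate negative correlation between transcript stability and tail length
#' used as the generator's target. Spike-in rows receive `NA`.
#'
#' @param truth Truth table from [simulate_experiment()] (or any tibble with
#'   columns `gene`, `spike`, `tail_mean_wt`).
#' @param target_r Target Pearson correlation, strictly inside (-1, 1).
#' @param seed Integer seed.
#' @return Named numeric vector of half-lives (hours) for non-spike genes.
#' @export
generate_half_lives <- function(truth, target_r = -0.21, seed = 1L) {
  if (abs(target_r) >= 1)
    stop_tailfrac("`target_r` must be strictly inside (-1, 1)",
                  "tailfrac_domain_error")
  tr <- truth[!truth$spike, ]
  set.seed(seed)
  x <- as.numeric(scale(tr$tail_mean_wt))
  z <- target_r * x + sqrt(1 - target_r^2) * rnorm(nrow(tr))
  hl <- pmax(10 + 2 * z, 0.1)   # hours; clamp keeps half-lives positive
  stats::setNames(hl, tr$gene)
}

#' Plant a motif into the terminal window of selected sequences
#'
#' Inserts (overwrites in place) `motif` at a seeded random offset within the
#' last `window` nucleotides of each sequence named in `genes`. Used to create
#' ground truth for motif-association tests.
#'
#' @param sequences Named character vector or `DNAStringSet` of sequences
#'   whose last base is the cleavage site (or see `cleavage_pos`).
#' @param motif ACGT string, typically a hexamer.
#' @param genes Gene ids to plant into; all must be present in `sequences`.
#' @param window Terminal window length (nt); must be >= `nchar(motif)`.
#' @param cleavage_pos Optional named integer vector giving the 1-based
#'   position of the cleavage site within each sequence (default: sequence
#'   end).
#' @param seed Integer seed.
#' @return Character vector of sequences with the motif planted.
#' @export
plant_motif <- function(sequences, motif, genes, window = 100,
                        cleavage_pos = NULL, seed = 1L) {
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(seqs)))
    stop_tailfrac("`sequences` must be named", "tailfrac_data_error")
  if (nchar(motif) > window)
    stop_tailfrac("`motif` longer than `window`", "tailfrac_domain_error")
  missing <- setdiff(genes, names(seqs))
  if (length(missing) > 0)
    stop_tailfrac(paste0("genes absent from sequence set: ",
                         paste(missing, collapse = ", ")),
                  "tailfrac_data_error")
  for (g in genes) {
    set.seed(gene_seed(seed, match(g, names(seqs))))
    cp <- if (is.null(cleavage_pos)) nchar(seqs[[g]]) else cleavage_pos[[g]]
    win <- min(window, cp)
    lo <- cp - win + 1L
    off <- sample.int(win - nchar(motif) + 1L, 1L)
    at <- lo + off - 1L
    substr(seqs[[g]], at, at + nchar(motif) - 1L) <- motif
  }
  seqs
}

# writes planted windows back into the per-gene contigs (simulation only;
# contig layout is one gene per contig as built by sim_gene_contigs)
replace_terminal_window <- function(annotation, genome, windows) {
  seqs <- stats::setNames(as.character(genome), names(genome))
  for (g in names(windows)) {
    a <- annotation[annotation$gene == g, ]
    cs <- distal_site(a$cleavage_sites[[1]], a$strand)
    w <- nchar(windows[[g]])
    if (a$strand == "+") {
      substr(seqs[[a$chrom]], cs - w + 1L, cs) <- windows[[g]]
    } else {
      rc <- as.character(reverseComplement(DNAStringSet(windows[[g]])))
      substr(seqs[[a$chrom]], cs + 1L, cs + w) <- rc
    }
  }
  DNAStringSet(seqs)
}

#' Simulate ePAT and control electropherogram traces
#'
#' Produces synthetic Bioanalyzer-style traces for an extension poly(A) test:
#' the (dT)-anchored control product forms a peak at the tail-less product
#' size `utr_length`, while the ePAT product is that peak smeared to larger
#' sizes by the poly(A)-tail length distribution (gamma with the given mean).
#' Replicate noise is multiplicative log-normal, so intensities stay
#' non-negative.
#'
#' @param mean_tail_by_group Named numeric vector: mean tail length (nt) per
#'   genotype/group.
#' @param utr_length Size (bp) of the tail-less PCR product.
#' @param size_grid Increasing numeric vector of product sizes (bp).
#' @param n_replicates Replicates per group and assay.
#' @param peak_sd Electrophoretic peak width (bp).
#' @param tail_shape Gamma shape of the tail-length distribution.
#' @param noise_sd Log-scale replicate noise.
#' @param seed Integer seed.
#' @return Long tibble with columns `sample`, `assay` (`ePAT`/`control`),
#'   `genotype`, `replicate`, `size`, `intensity`.
#' @export
generate_epat_traces <- function(mean_tail_by_group, utr_length, size_grid,
                                 n_replicates = 3, peak_sd = 8,
                                 tail_shape = 8, noise_sd = 0.05, seed = 1L) {
  if (is.unsorted(size_grid, strictly = TRUE))
    stop_tailfrac("`size_grid` must be strictly increasing", "tailfrac_domain_error")
  set.seed(seed)
  out <- list()
  for (g in names(mean_tail_by_group)) {
    mt <- mean_tail_by_group[[g]]
    control <- dnorm(size_grid, mean = utr_length, sd = peak_sd)
    if (mt > 0) {
      tails <- seq(0, max(3 * mt, 50), length.out = 121L)
      wt <- dgamma(tails, shape = tail_shape, rate = tail_shape / mt)
      wt <- wt / sum(wt)
      epat <- colSums(wt * t(vapply(tails, function(t0)
        dnorm(size_grid, mean = utr_length + t0, sd = peak_sd),
        numeric(length(size_grid)))))
    } else {
      epat <- control
    }
    for (r in seq_len(n_replicates)) {
      for (assay in c("ePAT", "control")) {
        base <- if (assay == "ePAT") epat else control
        noisy <- base * exp(rnorm(length(size_grid), 0, noise_sd))
        out[[length(out) + 1L]] <- tibble(
          sample = paste(g, assay, r, sep = "_"), assay = assay,
          genotype = g, replicate = r, size = size_grid, intensity = noisy)
      }
    }
  }
  bind_rows(out)
}
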