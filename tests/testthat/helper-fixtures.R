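# Small deterministic fixtures shared across test files.

# hand-built 4-gene, 16-sample count object (2 genotypes x 4 reps x 2 fractions)
tiny_fc <- function(counts = NULL) {
  samples <- tidyr::expand_grid(genotype = c("wt", "mut"),
                                replicate = 1:4,
                                fraction = c("short", "long"))
  samples$sample <- with(samples, paste(genotype, replicate, fraction, sep = "_"))
  if (is.null(counts)) {
    set.seed(99)
    counts <- matrix(rpois(4 * 16, 50), 4, 16,
                     dimnames = list(paste0("g", 1:4), samples$sample))
  }
  fraction_counts(counts, samples)
}

# cached mid-size simulation reused by several files (built once per run)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_experiment(sim_config(
      n_genes = 400, seed = 42, planted_motif = "AAGAAA",
      mean_expression = c(meanlog = log(300), sdlog = 0.7)))
  }
  .sim_cache$sim
}

expect_tsv_roundtrip <- function(tbl, write_fn, read_fn) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fn(tbl, path)
  back <- read_fn(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), tolerance = 1e-9)
}
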