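#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> normalize -> infer -> groups -> seqfeat
#' with one configuration, writing each stage's outputs as TSV before the
#' next stage starts and returning a run manifest with per-output checksums.
#'
#' The configuration is a named list (or path to a YAML file) with top-level
#' keys:
#' \describe{
#'   \item{seed}{integer; required when simulating.}
#'   \item{out_dir}{output directory.}
#'   \item{stages}{character subset of `c("simulate", "normalize", "infer",
#'     "groups", "seqfeat")`; defaults to all.}
#'   \item{sim}{list of [sim_config()] arguments.}
#'   \item{input}{list with `counts`, `meta` (and optionally `categories`,
#'     `modules`, `fasta`, `utr`, `spike`) paths, used instead of
#'     simulation.}
#'   \item{normalize}{list: `trim_m`, `trim_a`, `min_count`, `prior`.}
#'   \item{infer}{list: `reference`.}
#'   \item{groups}{list: `min_size`.}
#'   \item{seqfeat}{list: `window`, `flank`, `run_sweep`.}
#' }
#' Unknown keys raise a configuration error (fail-fast).
#'
#' @param config Named list or path to a YAML file.
#' @return List of class `tailfrac_manifest`: `config_hash`, `stages`
#'   (tibble with stage timings), `outputs` (tibble with file checksums),
#'   and in-memory `results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "stages", "sim", "input", "normalize",
             "infer", "groups", "seqfeat")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop_tailfrac(paste("unknown config keys:", paste(unknown, collapse = ", ")),
                  "tailfrac_config_error")
  stages <- config$stages %||% c("simulate", "normalize", "infer", "groups",
                                 "seqfeat")
  out_dir <- config$out_dir %||% tempfile("tailfrac_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if ("simulate" %in% stages && is.null(config$seed))
    stop_tailfrac("`seed` must be set when simulation is enabled",
                  "tailfrac_config_error")

  results <- list()
  stage_times <- list()
  outputs <- list()
  note <- function(stage, files) {
    outputs[[stage]] <<- tibble(stage = stage, path = unname(files),
                                md5 = unname(tools::md5sum(files)))
  }
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop_tailfrac(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                    "tailfrac_stage_error"))
    stage_times[[stage]] <<- tibble(stage = stage,
                                    seconds = proc.time()[["elapsed"]] - t0)
    val
  }

  ## inputs
  if ("simulate" %in% stages) {
    sim <- tick("simulate", {
      cfg <- do.call(sim_config, c(config$sim %||% list(),
                                   list(seed = config$seed)))
      simulate_experiment(cfg)
    })
    sim_dir <- file.path(out_dir, "inputs")
    paths <- write_experiment(sim, sim_dir)
    note("simulate", paths)
    results$sim <- sim
    fc <- sim$counts
    categories <- sim$categories
    modules <- sim$modules
    genome <- sim$genome
    annotation <- sim$annotation
    features <- sim$features
  } else {
    inp <- config$input
    if (is.null(inp$counts) || is.null(inp$meta))
      stop_tailfrac("`input$counts` and `input$meta` are required without simulation",
                    "tailfrac_config_error")
    fc <- read_fraction_counts(inp$counts, inp$meta,
                               spike = inp$spike %||% character())
    categories <- if (!is.null(inp$categories))
      readr::read_tsv(inp$categories, show_col_types = FALSE) else NULL
    modules <- if (!is.null(inp$modules))
      readr::read_tsv(inp$modules, show_col_types = FALSE) else NULL
    genome <- if (!is.null(inp$fasta)) readDNAStringSet(inp$fasta) else NULL
    if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
    annotation <- if (!is.null(inp$utr)) read_utr_annotation(inp$utr) else NULL
    features <- if (!is.null(inp$features))
      readr::read_tsv(inp$features, show_col_types = FALSE) else NULL
  }

  ## normalize
  ncfg <- config$normalize %||% list()
  if ("normalize" %in% stages) {
    norm <- tick("normalize", {
      filt <- filter_low_counts(fc, min_count = ncfg$min_count %||% 6L)
      list(fc = filt,
           state = tmm_factors(filt, trim_m = ncfg$trim_m %||% 0.30,
                               trim_a = ncfg$trim_a %||% 0.05))
    })
    fc <- norm$fc
    state <- norm$state
    p <- file.path(out_dir, "normalization.tsv")
    readr::write_tsv(state, p)
    note("normalize", p)
    results$norm <- state
  } else state <- NULL

  ## infer
  if ("infer" %in% stages) {
    icfg <- config$infer %||% list()
    reference <- icfg$reference %||% fc$samples$genotype[1]
    tail_res <- tick("infer", test_tail_change(fc, state, reference = reference))
    ab_res <- test_abundance_change(fc, state, reference = reference)
    p1 <- file.path(out_dir, "tailchange.tsv")
    p2 <- file.path(out_dir, "abundance.tsv")
    write_results(tail_res, p1)
    readr::write_tsv(dplyr::mutate(ab_res, across(dplyr::where(is.numeric),
                                                  ~signif(.x, 10))),
                     p2, na = "NA")
    note("infer", c(p1, p2))
    results$tail <- tail_res
    results$abundance <- ab_res
  }

  ## groups
  if ("groups" %in% stages && !is.null(results$tail)) {
    gcfg <- config$groups %||% list()
    vals <- tibble(gene = results$tail$gene, value = results$tail$log2FC_ratio)
    vals <- vals[!is.na(vals$value), ]
    grp <- tick("groups", {
      out <- list()
      if (!is.null(categories))
        out$categories <- category_sweep(vals, categories,
                                         min_size = gcfg$min_size %||% 5)
      if (!is.null(modules))
        out$modules <- module_cdf_compare(vals, modules,
                                          min_size = gcfg$min_size %||% 5)
      out
    })
    files <- character()
    if (!is.null(grp$categories)) {
      p <- file.path(out_dir, "category_sweep.tsv")
      readr::write_tsv(grp$categories, p, na = "NA"); files <- c(files, p)
    }
    if (!is.null(grp$modules)) {
      p <- file.path(out_dir, "module_compare.tsv")
      readr::write_tsv(grp$modules$result, p, na = "NA"); files <- c(files, p)
    }
    if (length(files) > 0) note("groups", files)
    results$groups <- grp
  }

  ## seqfeat
  if ("seqfeat" %in% stages && !is.null(genome) && !is.null(annotation) &&
      !is.null(results$tail)) {
    scfg <- config$seqfeat %||% list()
    vals <- tibble(gene = results$tail$gene, value = results$tail$log2FC_ratio)
    vals <- vals[!is.na(vals$value), ]
    sf <- tick("seqfeat", {
      wins <- extract_terminal_window(annotation, genome,
                                      window = scfg$window %||% 100)
      out <- list(
        variants = variant_signal_test(wins, vals),
        profile = base_composition_profile(annotation, genome,
                                           flank = scfg$flank %||% 200))
      if (isTRUE(scfg$run_sweep %||% TRUE))
        out$hexamers <- hexamer_sweep(wins, vals)
      if (!is.null(features))
        out$correlations <- feature_correlations(vals, features)
      out
    })
    files <- character()
    if (!is.null(sf$hexamers)) {
      p <- file.path(out_dir, "hexamers.tsv")
      readr::write_tsv(sf$hexamers, p, na = "NA"); files <- c(files, p)
    }
    p <- file.path(out_dir, "composition.tsv")
    readr::write_tsv(sf$profile, p, na = "NA"); files <- c(files, p)
    p <- file.path(out_dir, "variant_signals.tsv")
    readr::write_tsv(sf$variants$result, p, na = "NA"); files <- c(files, p)
    if (!is.null(sf$correlations)) {
      p <- file.path(out_dir, "feature_correlations.tsv")
      readr::write_tsv(sf$correlations, p, na = "NA"); files <- c(files, p)
    }
    note("seqfeat", files)
    results$seqfeat <- sf
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    out_dir = out_dir,
    stages = bind_rows(stage_times),
    outputs = bind_rows(outputs),
    results = results), class = "tailfrac_manifest")
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tailfrac_manifest <- function(x, ...) {
  cat("<tailfrac_manifest>\n  out_dir:", x$out_dir, "\n")
  cat("  stages run:", paste(x$stages$stage, collapse = ", "), "\n")
  cat("  outputs:", nrow(x$outputs), "files\n")
  invisible(x)
}

#' Summarize a pipeline run
#'
#' Builds the standard diagnostic plots (tail-change MA plot, module ECDFs,
#' base-composition profile, spike-in summary where available) and a text
#' summary of the top categories and motifs from an in-memory manifest.
#'
#' @param manifest A [run_pipeline()] manifest.
#' @param top_n Rows to show per result table in the text summary.
#' @return List with `plots` (named list of ggplot objects) and `summary`
#'   (character vector of summary lines).
#' @export
pipeline_report <- function(manifest, top_n = 10) {
  stopifnot(inherits(manifest, "tailfrac_manifest"))
  res <- manifest$results
  plots <- list()
  lines <- character()
  if (!is.null(res$tail)) {
    plots$ma <- plot_tail_ma(res$tail)
    n_sig <- sum(res$tail$BH_p_value < 0.05, na.rm = TRUE)
    lines <- c(lines, sprintf("tail change: %d genes tested, %d at BH < 0.05",
                              nrow(res$tail), n_sig))
  }
  if (!is.null(res$groups$categories) && nrow(res$groups$categories) > 0) {
    top <- head(res$groups$categories, top_n)
    lines <- c(lines, "top categories:",
               sprintf("  %s (n=%d) median %.3f BH p %.3g",
                       top$category_id, top$n, top$median_log2FC,
                       top$BH_p_value))
  }
  if (!is.null(res$groups$modules)) {
    plots$ecdf <- plot_module_ecdf(res$groups$modules,
                                   modules = head(res$groups$modules$result$module, 2))
  }
  if (!is.null(res$seqfeat$hexamers) && nrow(res$seqfeat$hexamers) > 0) {
    top <- head(res$seqfeat$hexamers, top_n)
    lines <- c(lines, "top hexamers:",
               sprintf("  %s (with=%d) effect %.3f BH p %.3g",
                       top$motif, top$n_with, top$effect_diff, top$BH_p_value))
  }
  if (!is.null(res$seqfeat$profile))
    plots$composition <- plot_composition_profile(res$seqfeat$profile)
  if (!is.null(res$sim)) {
    sp <- spike_proxy_table(res$sim$counts, res$sim$gene_lengths)
    plots$spikes <- plot_spike_summary(sp)
    lines <- c(lines, "spike-in short/long proxy ratios (median per spike):",
               {
                 med <- sp |> group_by(.data$spike) |>
                   summarise(m = median(.data$ratio_short_long), .groups = "drop")
                 sprintf("  %s: %.2f", med$spike, med$m)
               })
  }
  list(plots = plots, summary = lines)
}
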