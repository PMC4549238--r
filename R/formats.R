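#' Fraction-level count matrix with sample metadata
#'
#' Container pairing an integer gene-by-sample count matrix with per-sample
#' metadata. Validation enforces the pipeline's contracts: non-negative
#' integral counts, unique gene ids, and exactly one `short` and one `long`
#' library per (genotype, replicate) pair.
#'
#' @param counts Integer matrix, rownames = gene ids, colnames = sample ids.
#' @param samples Data frame with columns `sample`, `genotype`, `replicate`,
#'   `fraction` (one of `"short"`, `"long"`); optional `lib_size`,
#'   `rna_concentration`, `mapped_nonrrna_fraction`.
#' @param spike Character vector of spike-in gene ids (may be empty).
#' @return Object of class `fraction_counts`: list with elements `counts`,
#'   `samples` (tibble) and `spike`.
#' @export
fraction_counts <- function(counts, samples, spike = character()) {
  counts <- as.matrix(counts)
  samples <- as_tibble(samples)
  if (nrow(counts) > 0 &&
      (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
    stop_tailfrac("gene ids must be present and unique", "tailfrac_data_error")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_tailfrac(sprintf(
      "counts must be non-negative integers; first offender at gene '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
      "tailfrac_data_error")
  storage.mode(counts) <- "integer"
  need <- c("sample", "genotype", "replicate", "fraction")
  if (!all(need %in% names(samples)))
    stop_tailfrac(paste("sample metadata needs columns:", paste(need, collapse = ", ")),
                  "tailfrac_data_error")
  if (!setequal(colnames(counts), samples$sample) ||
      ncol(counts) != nrow(samples))
    stop_tailfrac("metadata must cover exactly the count columns", "tailfrac_data_error")
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (!all(samples$fraction %in% c("short", "long")))
    stop_tailfrac("`fraction` must be 'short' or 'long'", "tailfrac_data_error")
  pairing <- samples |>
    dplyr::count(.data$genotype, .data$replicate, .data$fraction) |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "n",
                       values_fill = 0L)
  if (!"short" %in% names(pairing)) pairing$short <- 0L
  if (!"long" %in% names(pairing)) pairing$long <- 0L
  off <- pairing[pairing$short != 1L | pairing$long != 1L, ]
  if (nrow(off) > 0)
    stop_tailfrac(sprintf(
      "unpaired sample: genotype '%s' replicate %s lacks a short/long pair",
      off$genotype[1], off$replicate[1]), "tailfrac_data_error")
  if (!"lib_size" %in% names(samples)) samples$lib_size <- colSums(counts)
  structure(list(counts = counts, samples = samples,
                 spike = intersect(spike, rownames(counts))),
            class = "fraction_counts")
}

#' @export
print.fraction_counts <- function(x, ...) {
  cat(sprintf("<fraction_counts> %d genes x %d samples (%d spike-ins)\n",
              nrow(x$counts), ncol(x$counts), length(x$spike)))
  cat(sprintf("  genotypes: %s; replicates: %s\n",
              paste(unique(x$samples$genotype), collapse = ", "),
              paste(range(x$samples$replicate), collapse = "-")))
  invisible(x)
}

#' @export
dim.fraction_counts <- function(x) dim(x$counts)

#' Read a fraction count matrix and its sample metadata
#'
#' Reads a tab-delimited gene-by-sample count table (first column = gene id)
#' and a sample-metadata TSV, validates them, and returns a
#' [fraction_counts()] object. Fails loudly on duplicate gene ids,
#' non-integer counts, and (genotype, replicate) pairs missing one fraction.
#'
#' @param counts_path,meta_path Paths to tab-delimited files; `'#'` starts a
#'   comment line, missing values are written `NA`.
#' @param spike Spike-in gene ids to flag.
#' @return A `fraction_counts` object.
#' @export
read_fraction_counts <- function(counts_path, meta_path, spike = character()) {
  ct <- readr::read_tsv(counts_path, comment = "#", show_col_types = FALSE,
                        na = c("NA", ""))
  genes <- as.character(ct[[1]])
  m <- as.matrix(ct[, -1, drop = FALSE])
  if (anyNA(m))
    stop_tailfrac("missing values in count matrix", "tailfrac_data_error")
  rownames(m) <- genes
  meta <- readr::read_tsv(meta_path, comment = "#", show_col_types = FALSE,
                          na = c("NA", ""))
  fraction_counts(m, meta, spike = spike)
}

#' @rdname read_fraction_counts
#' @param fc A `fraction_counts` object.
#' @export
write_fraction_counts <- function(fc, counts_path, meta_path) {
  ct <- bind_cols(tibble(gene = rownames(fc$counts)),
                  as_tibble(fc$counts))
  readr::write_tsv(ct, counts_path)
  readr::write_tsv(fc$samples, meta_path)
  invisible(c(counts_path, meta_path))
}

## ---- 3'-UTR annotation ----------------------------------------------------
## Internal convention: 0-based half-open. For a plus-strand UTR interval
## [start0, end0), the stop codon boundary is start0 and the cleavage site is
## end0; mirrored on the minus strand.

#' Construct / validate a 3'-UTR annotation table
#'
#' @param tbl Tibble with columns `gene`, `chrom`, `strand` (`+`/`-`),
#'   `stop_pos` (0-based), `cleavage_sites` (list column of 0-based
#'   positions).
#' @return Tibble of class `utr_annotation` with derived columns `n_utrs`
#'   and `max_utr_length` (maximum stop-to-cleavage distance, bp).
#' @export
utr_annotation <- function(tbl) {
  tbl <- as_tibble(tbl)
  if (!all(tbl$strand %in% c("+", "-")))
    stop_tailfrac("strand must be '+' or '-'", "tailfrac_data_error")
  ok <- purrr::map2_lgl(tbl$cleavage_sites, seq_len(nrow(tbl)), function(cs, i) {
    length(cs) >= 1 &&
      if (tbl$strand[i] == "+") all(cs >= tbl$stop_pos[i]) else all(cs <= tbl$stop_pos[i])
  })
  if (!all(ok))
    stop_tailfrac("cleavage sites must lie 3' of the stop codon", "tailfrac_data_error")
  tbl$cleavage_sites <- purrr::map(tbl$cleavage_sites,
                                   function(cs) sort(unique(as.integer(cs))))
  tbl$n_utrs <- purrr::map_int(tbl$cleavage_sites, length)
  tbl$max_utr_length <- purrr::map2_dbl(tbl$cleavage_sites, tbl$stop_pos,
                                        function(cs, s) max(abs(cs - s)))
  class(tbl) <- c("utr_annotation", class(tbl))
  tbl
}

# most distal cleavage site: largest coordinate on +, smallest on -
distal_site <- function(sites, strand) {
  if (strand == "+") max(sites) else min(sites)
}

#' Read 3'-UTR annotation from GFF3 or BED
#'
#' Parses 3'-UTR intervals and normalizes both dialects to the internal
#' 0-based half-open convention (GFF3 is 1-based closed: start is shifted by
#' -1; BED is already 0-based half-open). For each gene, the stop-codon
#' boundary is taken from the first file in which the gene appears
#' (authoritative source); cleavage sites from all files are merged by union,
#' so alternative polyadenylation sites accumulate across annotation sources.
#'
#' @param paths One or more annotation files, processed in order.
#' @param dialect `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param collapse_nt Collapse cleavage sites closer than this many nt to the
#'   more distal one; 0 (default) keeps all distinct sites.
#' @return A [utr_annotation()] tibble.
#' @export
read_utr_annotation <- function(paths, dialect = c("auto", "gff3", "bed"),
                                collapse_nt = 0) {
  dialect <- match.arg(dialect)
  per_file <- purrr::map(paths, function(p) {
    d <- if (dialect == "auto") {
      if (grepl("\\.bed$", p, ignore.case = TRUE)) "bed" else "gff3"
    } else dialect
    iv <- if (d == "bed") parse_bed(p) else parse_gff3_utr(p)
    # per gene within one file: stop = 5'-most boundary, cleavage = 3' ends
    iv |>
      group_by(.data$gene) |>
      summarise(
        chrom = .data$chrom[1],
        strand = .data$strand[1],
        stop_pos = if (.data$strand[1] == "+") min(.data$start0) else max(.data$end0),
        cleavage_sites = list(
          if (.data$strand[1] == "+") unique(.data$end0) else unique(.data$start0)),
        .groups = "drop")
  })
  merged <- bind_rows(per_file, .id = "file_rank") |>
    group_by(.data$gene) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      stop_pos = .data$stop_pos[1],      # first file is authoritative
      cleavage_sites = list(sort(unique(unlist(.data$cleavage_sites)))),
      .groups = "drop")
  if (collapse_nt > 0) {
    merged$cleavage_sites <- purrr::map2(
      merged$cleavage_sites, merged$strand,
      function(cs, st) collapse_sites(cs, st, collapse_nt))
  }
  utr_annotation(merged)
}

# keep the more distal of any pair of sites within `nt` of each other
collapse_sites <- function(cs, strand, nt) {
  cs <- sort(cs, decreasing = (strand == "+"))
  kept <- cs[1]
  for (s in cs[-1]) if (min(abs(kept - s)) > nt) kept <- c(kept, s)
  sort(kept)
}

parse_bed <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        show_col_types = FALSE)
  if (ncol(tb) < 6)
    stop_tailfrac("BED input needs 6 columns (BED6)", "tailfrac_data_error")
  names(tb)[1:6] <- c("chrom", "start0", "end0", "gene", "score", "strand")
  check_strand(tb$strand, path)
  tb[, c("chrom", "start0", "end0", "gene", "strand")]
}

parse_gff3_utr <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (ncol(tb) < 9)
    stop_tailfrac("GFF3 input needs 9 columns", "tailfrac_data_error")
  names(tb) <- c("chrom", "source", "type", "start", "end", "score",
                 "strand", "phase", "attributes")
  tb <- tb[tb$type %in% c("three_prime_UTR", "3UTR"), ]
  check_strand(tb$strand, path)
  gene <- stringr::str_match(tb$attributes, "(?:Parent|ID)=([^;]+)")[, 2]
  gene <- sub("\\.\\d+$", "", gene)   # strip transcript suffix
  tibble(chrom = tb$chrom,
         start0 = as.integer(tb$start) - 1L,  # 1-based closed -> 0-based half-open
         end0 = as.integer(tb$end),
         gene = gene, strand = tb$strand)
}

check_strand <- function(strand, path) {
  bad <- setdiff(unique(strand), c("+", "-"))
  if (length(bad) > 0)
    stop_tailfrac(sprintf("invalid strand character(s) %s in %s",
                          paste(sQuote(bad), collapse = ", "), path),
                  "tailfrac_data_error")
}

#' @rdname read_utr_annotation
#' @param annotation A `utr_annotation` tibble.
#' @param path Output path.
#' @export
write_utr_bed <- function(annotation, path) {
  rows <- purrr::pmap(annotation, function(gene, chrom, strand, stop_pos,
                                           cleavage_sites, ...) {
    tibble(chrom = chrom,
           start0 = if (strand == "+") stop_pos else cleavage_sites,
           end0 = if (strand == "+") cleavage_sites else stop_pos,
           gene = gene, score = ".", strand = strand)
  })
  readr::write_tsv(bind_rows(rows), path, col_names = FALSE)
  invisible(path)
}

## ---- results tables -------------------------------------------------------

#' Write / read a tail-change result table
#'
#' Fixed-schema TSV round-trip for the per-gene tail-length-change results:
#' columns `gene`, `log2FC_ratio`, per-genotype long/short log2-ratio
#' columns, `logCPM`, `p_value`, `BH_p_value`. Missing values (e.g.
#' non-converged fits) serialize as `NA`; numbers keep 10 significant digits
#' so write-then-read is lossless for practical purposes.
#'
#' @param results Result tibble from [test_tail_change()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  fixed <- c("gene", "log2FC_ratio")
  tail_cols <- c("logCPM", "p_value", "BH_p_value")
  geno_cols <- setdiff(names(results), c(fixed, tail_cols))
  out <- results[, c(fixed, geno_cols, tail_cols)]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 10))
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, na = "NA")
}

#' Write all inputs of a simulated experiment to a directory
#'
#' Emits the standard pipeline inputs as plain-text files: `counts.tsv`,
#' `samples.tsv`, `regions.fasta` (per-gene contigs), `utr.bed`,
#' `categories.tsv`, `modules.tsv`, `features.tsv`, `truth.tsv`.
#'
#' @param sim A `tailfrac_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "tailfrac_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             fasta = file.path(dir, "regions.fasta"),
             bed = file.path(dir, "utr.bed"),
             categories = file.path(dir, "categories.tsv"),
             modules = file.path(dir, "modules.tsv"),
             features = file.path(dir, "features.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fraction_counts(sim$counts, paths["counts"], paths["samples"])
  writeXStringSet(sim$genome, paths["fasta"])
  write_utr_bed(sim$annotation, paths["bed"])
  readr::write_tsv(sim$categories, paths["categories"])
  readr::write_tsv(sim$modules, paths["modules"])
  readr::write_tsv(sim$features, paths["features"], na = "NA")
  truth_flat <- sim$truth
  readr::write_tsv(truth_flat, paths["truth"], na = "NA")
  invisible(paths)
}
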