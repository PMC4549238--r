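#' Extract the terminal 3'-UTR window of each gene
#'
#' Strand-aware extraction of the last `window` nucleotides of each gene's
#' 3' UTR, ending at its most distal cleavage site; minus-strand windows are
#' reverse-complemented so all returned sequences read 5' to 3' with the
#' cleavage site at their last base. UTRs shorter than the window return
#' their full length.
#'
#' @param annotation A [utr_annotation()] tibble.
#' @param genome Named `DNAStringSet` (or named character vector) covering
#'   the annotated contigs.
#' @param window Window length in nt.
#' @return Named character vector of terminal sequences.
#' @export
extract_terminal_window <- function(annotation, genome, window = 100) {
  seqs <- stats::setNames(as.character(genome), names(genome))
  out <- character(nrow(annotation))
  names(out) <- annotation$gene
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    if (!a$chrom %in% names(seqs))
      stop_tailfrac(sprintf("contig '%s' absent from genome", a$chrom),
                    "tailfrac_data_error")
    contig <- seqs[[a$chrom]]
    L <- nchar(contig)
    cs <- distal_site(a$cleavage_sites[[1]], a$strand)
    if (cs < 0 || cs > L)
      stop_tailfrac(sprintf("cleavage site of '%s' outside contig", a$gene),
                    "tailfrac_data_error")
    utr_len <- a$max_utr_length
    w <- min(window, utr_len)
    if (a$strand == "+") {
      # internal 0-based half-open: window is [cs - w, cs) -> 1-based (cs-w+1)..cs
      out[i] <- substr(contig, cs - w + 1L, cs)
    } else {
      frag <- substr(contig, cs + 1L, cs + w)
      out[i] <- as.character(reverseComplement(DNAStringSet(frag)))
    }
  }
  out
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  sort(apply(g, 1, paste, collapse = ""))
}

# presence matrix (genes x 4096 hexamers) from terminal windows
hexamer_presence <- function(windows) {
  freq <- oligonucleotideFrequency(DNAStringSet(windows), width = 6)
  rownames(freq) <- names(windows)
  freq > 0
}

#' Hexamer association sweep over terminal 3'-UTR windows
#'
#' For each of the 4096 hexamers, splits genes into those with and without
#' the motif anywhere in their terminal window (presence is boolean) and
#' compares their tail-length changes with [wilcoxon_rank_sum()]. Two effect
#' sizes are reported: the difference of mean log2 fold changes
#' (`effect_diff`, primary) and the log2 ratio of the group means of the
#' linearized fold changes 2^log2FC (`effect_log2_ratio`, secondary).
#' Motifs present in no gene or in every gene are skipped. BH adjustment is
#' across all tested motifs.
#'
#' @param windows Named character vector of terminal windows (from
#'   [extract_terminal_window()]).
#' @param tail_changes Tibble with columns `gene`, `value` (per-gene
#'   log2 fold change of the tail-length proxy).
#' @return Tibble of class `hexamer_result`, sorted by p: `motif`, `n_with`,
#'   `n_without`, `effect_diff`, `effect_log2_ratio`, `p_value`,
#'   `BH_p_value`.
#' @export
hexamer_sweep <- function(windows, tail_changes) {
  stopifnot(all(c("gene", "value") %in% names(tail_changes)))
  common <- intersect(names(windows), tail_changes$gene)
  v <- stats::setNames(tail_changes$value, tail_changes$gene)[common]
  pres <- hexamer_presence(windows[common])
  motif_test(pres, v, colnames(pres))
}

# shared worker for hexamer_sweep and variant_signal_test
motif_test <- function(pres, v, motifs) {
  rows <- purrr::map(motifs, function(mo) {
    with_idx <- pres[, mo]
    n_with <- sum(with_idx)
    if (n_with == 0 || n_with == length(v)) return(NULL)  # skipped
    a <- v[with_idx]; b <- v[!with_idx]
    w <- wilcoxon_rank_sum(a, b)
    tibble(motif = mo, n_with = n_with, n_without = length(v) - n_with,
           effect_diff = mean(a) - mean(b),
           effect_log2_ratio = log2(mean(2^a) / mean(2^b)),
           p_value = w$p_value)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(motif = character(), n_with = integer(),
                  n_without = integer(), effect_diff = double(),
                  effect_log2_ratio = double(), p_value = double(),
                  BH_p_value = double())
  } else {
    out$BH_p_value <- benjamini_hochberg(out$p_value)
    out <- arrange(out, .data$p_value)
  }
  class(out) <- c("hexamer_result", class(out))
  out
}

#' Test canonical polyadenylation-signal variants
#'
#' Runs the same with/without rank-sum association as [hexamer_sweep()], but
#' restricted to a supplied set of hexamer variants — by default the
#' canonical signal AATAAA and its 18 single-nucleotide substitution
#' variants. Additionally returns the positional occurrence profile of each
#' variant relative to the cleavage site (position 0 = cleavage site; a motif
#' whose 5' base sits 20 nt upstream is at position -20).
#'
#' @inheritParams hexamer_sweep
#' @param variants Character vector of 6-mers over ACGT.
#' @return List with `result` (a `hexamer_result` tibble) and `positions`
#'   (tibble: `motif`, `position`, `count`).
#' @export
variant_signal_test <- function(windows, tail_changes,
                                variants = aataaa_variants()) {
  if (!all(grepl("^[ACGT]{6}$", variants)))
    stop_tailfrac("variants must be 6-mers over ACGT", "tailfrac_domain_error")
  common <- intersect(names(windows), tail_changes$gene)
  v <- stats::setNames(tail_changes$value, tail_changes$gene)[common]
  win <- windows[common]
  pres <- vapply(variants, function(mo) stringr::str_detect(win, stringr::fixed(mo)),
                 logical(length(win)))
  if (length(win) == 1) pres <- matrix(pres, nrow = 1, dimnames = list(NULL, variants))
  colnames(pres) <- variants
  res <- motif_test(pres, v, variants)
  pos_rows <- purrr::map(variants, function(mo) {
    locs <- stringr::str_locate_all(win, stringr::fixed(mo))
    starts <- unlist(purrr::map2(locs, nchar(win), function(lc, L) {
      if (nrow(lc) == 0) integer() else lc[, "start"] - L - 1L
    }))
    if (length(starts) == 0) return(NULL)
    tb <- as_tibble(table(position = starts))
    tibble(motif = mo, position = as.integer(tb$position),
           count = as.integer(tb$n))
  })
  list(result = res, positions = bind_rows(pos_rows))
}

#' @rdname variant_signal_test
#' @export
aataaa_variants <- function() {
  canonical <- "AATAAA"
  bases <- c("A", "C", "G", "T")
  vars <- unlist(purrr::map(1:6, function(i) {
    purrr::map_chr(setdiff(bases, substr(canonical, i, i)), function(b) {
      s <- canonical
      substr(s, i, i) <- b
      s
    })
  }))
  c(canonical, vars)
}

#' Base composition around the cleavage site
#'
#' Per-position nucleotide frequencies in a window of `flank` nt on either
#' side of each gene's most distal cleavage site, strand-aware (position 0 is
#' the first base after the cleavage site; negative positions are inside the
#' 3' UTR). Positions truncated at contig edges are counted as missing and
#' excluded from that position's denominator.
#'
#' @inheritParams extract_terminal_window
#' @param flank Flank size in nt on each side.
#' @return Tibble of class `composition_profile`: `position`, `A`, `C`, `G`,
#'   `T`, `n` (genes contributing).
#' @export
base_composition_profile <- function(annotation, genome, flank = 200) {
  if (nrow(annotation) == 0)
    stop_tailfrac("empty gene set", "tailfrac_data_error")
  seqs <- stats::setNames(as.character(genome), names(genome))
  positions <- seq(-flank, flank - 1L)
  tallies <- matrix(0L, length(positions), 4,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
  n_at <- integer(length(positions))
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    contig <- seqs[[a$chrom]]
    L <- nchar(contig)
    cs <- distal_site(a$cleavage_sites[[1]], a$strand)
    if (a$strand == "+") {
      lo <- cs - flank; hi <- cs + flank - 1L        # 0-based positions
      take_lo <- max(lo, 0L); take_hi <- min(hi, L - 1L)
      if (take_hi < take_lo) next
      frag <- substr(contig, take_lo + 1L, take_hi + 1L)
      offset <- take_lo - lo
      chars <- strsplit(frag, "")[[1]]
    } else {
      # position p (relative, reading 5'->3' on minus strand) maps to
      # 0-based genomic coordinate cs - 1 - p, complemented
      lo_p <- -flank; hi_p <- flank - 1L
      gen_hi <- cs - 1L - lo_p; gen_lo <- cs - 1L - hi_p
      take_lo <- max(gen_lo, 0L); take_hi <- min(gen_hi, L - 1L)
      if (take_hi < take_lo) next
      frag <- substr(contig, take_lo + 1L, take_hi + 1L)
      rc <- as.character(reverseComplement(DNAStringSet(frag)))
      offset <- gen_hi - take_hi
      chars <- strsplit(rc, "")[[1]]
    }
    idx <- seq_along(chars) + offset
    keep <- chars %in% c("A", "C", "G", "T") & idx >= 1 & idx <= length(positions)
    chars <- chars[keep]; idx <- idx[keep]
    for (b in c("A", "C", "G", "T")) {
      hit <- idx[chars == b]
      if (length(hit) > 0) {
        tb <- tabulate(hit, nbins = length(positions))
        tallies[, b] <- tallies[, b] + tb
      }
    }
    n_at[idx] <- n_at[idx] + 1L
  }
  tot <- rowSums(tallies)
  freq <- tallies / ifelse(tot == 0, NA_real_, tot)
  out <- bind_cols(tibble(position = positions), as_tibble(freq),
                   tibble(n = n_at))
  class(out) <- c("composition_profile", class(out))
  out
}

#' Correlate a per-gene metric with transcript features
#'
#' Pearson correlation (via [stats::cor.test()]) of a per-gene metric — the
#' tail-length proxy or its change — with each numeric feature column
#' (half-life, 3'-UTR length, number of 3' UTRs, mean abundance, ...). Pairs
#' with missing values are dropped per feature; features with fewer than 3
#' complete pairs or zero variance yield `NA` with a warning.
#'
#' @param metric Tibble with columns `gene`, `value`.
#' @param features Tibble with a `gene` column and numeric feature columns.
#' @return Tibble of class `correlation_result`: `feature`, `n`, `r`,
#'   `t_statistic`, `p_value`.
#' @export
feature_correlations <- function(metric, features) {
  stopifnot(all(c("gene", "value") %in% names(metric)))
  joined <- dplyr::inner_join(metric, features, by = "gene")
  feats <- setdiff(names(features), "gene")
  rows <- purrr::map(feats, function(f) {
    ok <- !is.na(joined$value) & !is.na(joined[[f]])
    x <- joined$value[ok]; y <- joined[[f]][ok]
    if (length(x) < 3 || sd(y) == 0 || sd(x) == 0) {
      rlang::warn(sprintf("feature '%s': constant or too few complete pairs", f))
      return(tibble(feature = f, n = length(x), r = NA_real_,
                    t_statistic = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(feature = f, n = length(x), r = unname(ct$estimate),
           t_statistic = unname(ct$statistic), p_value = ct$p.value)
  })
  out <- bind_rows(rows)
  class(out) <- c("correlation_result", class(out))
  out
}
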