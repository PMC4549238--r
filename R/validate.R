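#' Normalize electropherogram traces to their region of interest
#'
#' Divides every intensity of each trace by the mean intensity of that trace
#' within the region of interest (ROI), so the ROI mean of every normalized
#' trace is 1. Traces are identified by the `sample` column. Idempotent and
#' invariant to rescaling a trace.
#'
#' @param traces Long tibble with columns `sample`, `assay`, `genotype`,
#'   `replicate`, `size`, `intensity` (e.g. from [generate_epat_traces()]).
#' @param roi Numeric length-2 interval of sizes (bp) defining the ROI;
#'   `NULL` uses the full grid.
#' @return The input with `intensity` normalized per trace.
#' @export
epat_normalize <- function(traces, roi = NULL) {
  stopifnot(all(c("sample", "size", "intensity") %in% names(traces)))
  if (any(traces$intensity < 0))
    stop_tailfrac("intensities must be non-negative", "tailfrac_data_error")
  traces$.in_roi <- if (is.null(roi)) TRUE else
    traces$size >= roi[1] & traces$size <= roi[2]
  out <- traces |>
    group_by(.data$sample) |>
    mutate(.roi_mean = mean(.data$intensity[.data$.in_roi])) |>
    ungroup()
  if (any(!is.finite(out$.roi_mean) | out$.roi_mean == 0))
    stop_tailfrac("ROI mean is zero or empty for a trace", "tailfrac_data_error")
  out |>
    mutate(intensity = .data$intensity / .data$.roi_mean) |>
    select(-".roi_mean", -".in_roi")
}

#' ePAT-minus-control difference curves
#'
#' Averages normalized trace intensities by (assay, genotype) over replicates
#' and subtracts the control product curve from the ePAT product curve per
#' genotype. The resulting difference curve carries the poly(A)-tail signal:
#' mass at sizes above the tail-less product length reflects tailed
#' molecules.
#'
#' @param traces Normalized long tibble (see [epat_normalize()]) containing
#'   both assays (`"ePAT"`, `"control"`) on a shared size grid.
#' @return Tibble: `genotype`, `size`, `difference`.
#' @export
epat_difference <- function(traces) {
  stopifnot(all(c("assay", "genotype", "size", "intensity") %in% names(traces)))
  grids <- traces |>
    group_by(.data$sample) |>
    summarise(g = paste(.data$size, collapse = ","), .groups = "drop")
  if (length(unique(grids$g)) != 1)
    stop_tailfrac("traces must share an identical size grid", "tailfrac_data_error")
  have <- traces |> distinct(.data$genotype, .data$assay)
  for (g in unique(have$genotype)) {
    if (!setequal(have$assay[have$genotype == g], c("ePAT", "control")))
      stop_tailfrac(sprintf("genotype '%s' needs both ePAT and control traces", g),
                    "tailfrac_data_error")
  }
  traces |>
    group_by(.data$genotype, .data$assay, .data$size) |>
    summarise(mean_int = mean(.data$intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "mean_int") |>
    mutate(difference = .data$ePAT - .data$control) |>
    select("genotype", "size", "difference") |>
    arrange(.data$genotype, .data$size)
}

#' Signed shift score between two difference curves
#'
#' Compares the intensity-weighted mean product size of the positive parts of
#' two ePAT difference curves. A positive score means curve A carries its
#' poly(A) signal at longer products than curve B — i.e. longer tails in A.
#' Antisymmetric by construction.
#'
#' @param diff_a,diff_b Tibbles with columns `size`, `difference` on the same
#'   grid.
#' @return Signed scalar (bp); `NA` with a warning if either curve has no
#'   positive part.
#' @export
epat_shift_statistic <- function(diff_a, diff_b) {
  if (!isTRUE(all.equal(diff_a$size, diff_b$size)))
    stop_tailfrac("difference curves must share the same grid",
                  "tailfrac_data_error")
  wm <- function(d) {
    pos <- d$difference > 0
    if (!any(pos)) return(NA_real_)
    weighted.mean(d$size[pos], d$difference[pos])
  }
  a <- wm(diff_a); b <- wm(diff_b)
  if (is.na(a) || is.na(b)) {
    rlang::warn("a difference curve has no positive part; shift score is NA")
    return(NA_real_)
  }
  a - b
}

#' Expected class counts under a segregation ratio
#'
#' @param n Total observed count (> 0).
#' @param ratio Positive class weights, e.g. `c(1, 2, 1)` for Mendelian
#'   segregation of a monohybrid cross.
#' @param round Round to nearest integer (for display parity with published
#'   tables)?
#' @return Numeric vector of expected counts, summing to `n` (before
#'   rounding).
#' @examples
#' expected_counts(178, c(1, 2, 1))            # 44.5 89 44.5
#' expected_counts(178, c(1, 2), round = TRUE) # 59 119
#' @export
expected_counts <- function(n, ratio, round = FALSE) {
  if (n <= 0) stop_tailfrac("`n` must be > 0", "tailfrac_domain_error")
  if (any(ratio <= 0))
    stop_tailfrac("ratio weights must be positive", "tailfrac_domain_error")
  e <- n * ratio / sum(ratio)
  if (round) round(e) else e
}

#' Chi-square goodness-of-fit test against a segregation ratio
#'
#' Pearson chi-square test of observed class counts against expectations
#' derived from class weights, with df = classes - 1 and upper-tail p from
#' the chi-square distribution. By default expectations are computed
#' unrounded; `table_parity = TRUE` rounds them to the nearest integer first,
#' reproducing published tables whose expectations are printed rounded.
#'
#' @param observed Observed class counts (sum > 0, at least 2 classes).
#' @param ratio Positive class weights (same length as `observed`).
#' @param table_parity Use nearest-integer expectations?
#' @return Object of class `tailfrac_chisq`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected`.
#' @examples
#' chi_square_gof(c(111, 67, 0), c(1, 2, 1))$p_value   # 3.77e-33
#' @export
chi_square_gof <- function(observed, ratio, table_parity = FALSE) {
  if (length(observed) < 2)
    stop_tailfrac("need at least 2 classes", "tailfrac_domain_error")
  if (length(observed) != length(ratio))
    stop_tailfrac("`observed` and `ratio` must have the same length",
                  "tailfrac_domain_error")
  if (sum(observed) <= 0)
    stop_tailfrac("total observed count must be > 0", "tailfrac_domain_error")
  e <- expected_counts(sum(observed), ratio, round = table_parity)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 observed = observed, expected = e),
            class = "tailfrac_chisq")
}

#' @export
print.tailfrac_chisq <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: X2 = %.4f, df = %d, p = %.6g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
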