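# TMT reporter-ratio quantification and the comparison arithmetic.

#' Roll peptide log2 ratios up to proteins
#'
#' Protein log2 ratio = median of its peptide log2 ratios (robust rollup).
#'
#' @param peptide_ratios Tibble with `protein_id`, `peptide_id`,
#'   `log2_ratio` columns (one row per peptide).
#' @return Tibble with `protein_id`, `n_peptides`, `log2_ratio` and a
#'   list-column `peptide_log2_ratios`.
#' @export
protein_ratio_rollup <- function(peptide_ratios) {
  peptide_ratios |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      log2_ratio = stats::median(.data$log2_ratio),
      peptide_log2_ratios = list(.data$log2_ratio),
      .groups = "drop"
    )
}

#' Reporter-ion ratio quantification from accepted PSMs
#'
#' Each accepted PSM yields a peptide-level log2(channel 126 / channel 127)
#' ratio equal to the parent protein's true log2 ratio plus Gaussian reporter
#' noise (sd `noise_sd`, applied in log2 space, i.e. multiplicative noise).
#' PSM ratios are collapsed to one ratio per peptide (median), and protein
#' ratios are the median over accepted peptides. Proteins with no accepted
#' peptide are absent from the output.
#'
#' @param psms PSM tibble with `peptide_id` and `accepted` columns (a
#'   campaign's combined PSMs, see [run_pie_campaign()]).
#' @param mixture The ground-truth `pie_mixture`.
#' @param noise_sd Reporter noise sd in log2 units (default 0.2).
#' @param seed Integer seed.
#' @return Protein quantification tibble as in [protein_ratio_rollup()].
#' @export
reporter_ratios <- function(psms, mixture, noise_sd = 0.2, seed = 1L) {
  stopifnot(noise_sd >= 0)
  acc <- psms[psms$accepted & !psms$is_decoy, , drop = FALSE]
  pep <- if (!is.data.frame(mixture) && is.list(mixture) &&
             "peptides" %in% names(mixture)) mixture$peptides else mixture
  d <- acc |>
    dplyr::inner_join(
      pep[, c("peptide_id", "protein_id", "channel_log2_ratio")],
      by = "peptide_id")
  noise <- with_seed(seed, stats::rnorm(nrow(d), 0, noise_sd))
  d$log2_ratio <- d$channel_log2_ratio + noise
  d |>
    dplyr::group_by(.data$protein_id, .data$peptide_id) |>
    dplyr::summarise(log2_ratio = stats::median(.data$log2_ratio),
                     .groups = "drop") |>
    protein_ratio_rollup()
}

#' Ordinary least-squares regression summary
#'
#' Slope, intercept and the squared Pearson correlation of `y` on `x`.
#'
#' @param x,y Numeric vectors of equal length (>= 2), `x` non-constant.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' regression_stats(c(1, 2, 3), c(2, 4, 5))
regression_stats <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    rlang::abort("`x` and `y` must have equal length >= 2")
  }
  if (stats::sd(x) == 0) {
    rlang::abort("`x` is constant; regression is degenerate")
  }
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = stats::cor(x, y)^2,
    n = length(x)
  )
}

#' Venn partition of two identifier sets
#'
#' @param set_a,set_b Vectors (duplicates ignored).
#' @return One-row tibble `only_a`, `both`, `only_b`; components sum to the
#'   union size.
#' @export
venn_counts <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- length(intersect(a, b))
  tibble::tibble(only_a = length(a) - both, both = both,
                 only_b = length(b) - both)
}

#' Percent increase of one count over a reference
#'
#' `100 * (n_new - n_ref) / n_ref`, reported raw and rounded to the nearest
#' integer.
#'
#' @param n_new,n_ref Counts; `n_ref` must be positive.
#' @return One-row tibble `percent` (raw) and `percent_rounded`.
#' @export
#' @examples
#' percent_increase(845, 347)
percent_increase <- function(n_new, n_ref) {
  if (!is.numeric(n_ref) || n_ref <= 0) {
    rlang::abort("`n_ref` must be positive; percent increase is undefined")
  }
  p <- 100 * (n_new - n_ref) / n_ref
  tibble::tibble(percent = p, percent_rounded = round(p))
}

#' Per-protein sequence-coverage comparison
#'
#' Over proteins quantified by both strategies, the fraction whose peptide
#' count is strictly greater in A than in B, plus the full count table.
#'
#' @param quant_a,quant_b Protein quantification tibbles (see
#'   [reporter_ratios()]).
#' @return List with `increased_coverage_fraction` (`NA` with a warning when
#'   the intersection is empty) and `table` (per-common-protein counts with
#'   an `increased` flag).
#' @export
coverage_comparison <- function(quant_a, quant_b) {
  common <- dplyr::inner_join(
    quant_a[, c("protein_id", "n_peptides")],
    quant_b[, c("protein_id", "n_peptides")],
    by = "protein_id", suffix = c("_a", "_b"))
  if (nrow(common) == 0) {
    rlang::warn("no common proteins; increased-coverage fraction undefined")
    return(list(increased_coverage_fraction = NA_real_, table = common))
  }
  common$increased <- common$n_peptides_a > common$n_peptides_b
  list(increased_coverage_fraction = mean(common$increased), table = common)
}
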