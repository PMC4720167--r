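# Strategy comparison: Venn counts, percent increase, ratio regression.

#' Compare two acquisition strategies
#'
#' Aggregates the accepted identifications of two campaigns (typically a PIE
#' iteration campaign vs DDA replicates of the same mixture), quantifies
#' both via [reporter_ratios()], and computes the comparison statistics:
#' identification counts, the Venn partition of quantified proteins, percent
#' increases, the OLS regression of strategy-A log2 ratios on strategy-B
#' log2 ratios over common proteins, and the increased-coverage fraction.
#'
#' @param campaign_a,campaign_b `pie_campaign` objects (strategy A is
#'   conventionally the PIE campaign, B the DDA reference).
#' @param mixture The ground-truth `pie_mixture` both campaigns sampled.
#' @param labels Length-2 character labels for the strategies.
#' @param noise_sd Reporter noise sd in log2 units.
#' @param seed Seed for reporter noise (strategy B uses a derived stream).
#' @return A `pie_comparison` object; see [tidy.pie_comparison()],
#'   [glance.pie_comparison()] and [autoplot.pie_comparison()].
#' @export
compare_strategies <- function(campaign_a, campaign_b, mixture,
                               labels = c("PIE", "DDA"), noise_sd = 0.2,
                               seed = 1L) {
  stopifnot(length(labels) == 2)
  quant_a <- reporter_ratios(campaign_psms(campaign_a), mixture,
                             noise_sd = noise_sd,
                             seed = derive_seed(seed, "quantA"))
  quant_b <- reporter_ratios(campaign_psms(campaign_b), mixture,
                             noise_sd = noise_sd,
                             seed = derive_seed(seed, "quantB"))
  pep_a <- campaign_accepted_peptides(campaign_a)
  pep_b <- campaign_accepted_peptides(campaign_b)
  counts <- tibble::tibble(
    strategy = labels,
    n_proteins = c(nrow(quant_a), nrow(quant_b)),
    n_peptides = c(length(pep_a), length(pep_b))
  )
  venn <- venn_counts(quant_a$protein_id, quant_b$protein_id)
  inc_prot <- percent_increase(nrow(quant_a), max(nrow(quant_b), 1))
  inc_pep <- percent_increase(length(pep_a), max(length(pep_b), 1))
  ratios <- dplyr::inner_join(
    quant_a[, c("protein_id", "log2_ratio", "n_peptides")],
    quant_b[, c("protein_id", "log2_ratio", "n_peptides")],
    by = "protein_id", suffix = c("_a", "_b")) |>
    dplyr::left_join(
      mixture$proteins[, c("protein_id", "channel_log2_ratio")],
      by = "protein_id")
  regression <- if (nrow(ratios) >= 2 && stats::sd(ratios$log2_ratio_b) > 0) {
    regression_stats(ratios$log2_ratio_b, ratios$log2_ratio_a)
  } else {
    tibble::tibble(slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_, n = nrow(ratios))
  }
  coverage <- coverage_comparison(quant_a, quant_b)
  structure(list(
    labels = labels, counts = counts, venn = venn,
    percent_increase_proteins = inc_prot,
    percent_increase_peptides = inc_pep,
    regression = regression, coverage = coverage,
    ratios = ratios, quant_a = quant_a, quant_b = quant_b,
    noise_sd = noise_sd, seed = seed
  ), class = "pie_comparison")
}

#' @export
print.pie_comparison <- function(x, ...) {
  cat(sprintf("<pie_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  print(x$counts)
  cat(sprintf("protein increase: %.1f%% (%d%% rounded); venn %d/%d/%d\n",
              x$percent_increase_proteins$percent,
              x$percent_increase_proteins$percent_rounded,
              x$venn$only_a, x$venn$both, x$venn$only_b))
  cat(sprintf("ratio regression: slope %.3f, R^2 %.3f (n = %d common)\n",
              x$regression$slope, x$regression$r_squared, x$regression$n))
  cat(sprintf("increased coverage fraction: %.3f\n",
              x$coverage$increased_coverage_fraction))
  invisible(x)
}

#' Tidy a strategy comparison
#'
#' One row per protein quantified by both strategies: peptide counts, log2
#' ratios under each strategy, and the true mixture log2 ratio.
#'
#' @param x A `pie_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pie_comparison
#' @export
tidy.pie_comparison <- function(x, ...) {
  x$ratios |>
    dplyr::transmute(
      protein_id = .data$protein_id,
      log2_ratio_a = .data$log2_ratio_a,
      log2_ratio_b = .data$log2_ratio_b,
      true_log2_ratio = .data$channel_log2_ratio,
      n_peptides_a = .data$n_peptides_a,
      n_peptides_b = .data$n_peptides_b,
      increased_coverage = .data$n_peptides_a > .data$n_peptides_b
    )
}

#' Glance at a strategy comparison
#'
#' @param x A `pie_comparison`.
#' @param ... Unused.
#' @return A one-row tibble of the headline statistics.
#' @method glance pie_comparison
#' @export
glance.pie_comparison <- function(x, ...) {
  tibble::tibble(
    n_proteins_a = x$counts$n_proteins[1],
    n_proteins_b = x$counts$n_proteins[2],
    n_peptides_a = x$counts$n_peptides[1],
    n_peptides_b = x$counts$n_peptides[2],
    venn_only_a = x$venn$only_a, venn_both = x$venn$both,
    venn_only_b = x$venn$only_b,
    percent_increase_proteins = x$percent_increase_proteins$percent,
    percent_increase_proteins_rounded =
      x$percent_increase_proteins$percent_rounded,
    percent_increase_peptides = x$percent_increase_peptides$percent,
    slope = x$regression$slope,
    intercept = x$regression$intercept,
    r_squared = x$regression$r_squared,
    n_common = x$regression$n,
    increased_coverage_fraction = x$coverage$increased_coverage_fraction
  )
}

#' Scatter plot of log2 ratios between strategies
#'
#' Common-protein log2 ratios of strategy A against strategy B with the
#' identity line and the fitted OLS line.
#'
#' @param object A `pie_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pie_comparison
#' @export
autoplot.pie_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_ratio_b,
                                  y = .data$log2_ratio_a)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$regression$slope,
                         intercept = object$regression$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("log2 ratio (%s)", object$labels[2]),
      y = sprintf("log2 ratio (%s)", object$labels[1]),
      title = sprintf("slope = %.2f, R² = %.2f",
                      object$regression$slope, object$regression$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Write a comparison report to disk
#'
#' Emits `comparison.json` (machine-readable: counts, Venn, percent
#' increases, regression, coverage) and `comparison.md` (human summary)
#' under `dir`, plus optionally `ratio_scatter.pdf`.
#'
#' @param comparison A `pie_comparison`.
#' @param dir Output directory (created if needed).
#' @param plot Write the scatter plot as well?
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(comparison, dir, plot = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- glance(comparison)
  jsonlite::write_json(as.list(g), file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_tsv(tidy(comparison), file.path(dir, "ratio_table.tsv"))
  md <- c(
    sprintf("# %s vs %s comparison", comparison$labels[1],
            comparison$labels[2]),
    "",
    sprintf("- proteins: %d vs %d (%.1f%% increase, %d%% rounded)",
            g$n_proteins_a, g$n_proteins_b, g$percent_increase_proteins,
            g$percent_increase_proteins_rounded),
    sprintf("- peptides: %d vs %d (%.1f%% increase)", g$n_peptides_a,
            g$n_peptides_b, g$percent_increase_peptides),
    sprintf("- Venn (only %s / both / only %s): %d / %d / %d",
            comparison$labels[1], comparison$labels[2], g$venn_only_a,
            g$venn_both, g$venn_only_b),
    sprintf("- log2-ratio regression: slope %.3f, intercept %.3f, R^2 %.3f (n = %d)",
            g$slope, g$intercept, g$r_squared, g$n_common),
    sprintf("- increased coverage fraction: %.3f",
            g$increased_coverage_fraction)
  )
  readr::write_lines(md, file.path(dir, "comparison.md"))
  if (plot) {
    p <- autoplot(comparison)
    ggplot2::ggsave(file.path(dir, "ratio_scatter.pdf"), p,
                    width = 5, height = 4)
  }
  invisible(dir)
}
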