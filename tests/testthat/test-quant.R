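test_that("protein rollup is the median of peptide log2 ratios", {
  d <- tibble::tibble(protein_id = "P1",
                      peptide_id = c("a", "b", "c"),
                      log2_ratio = log2(c(1, 2, 4)))
  out <- protein_ratio_rollup(d)
  expect_equal(out$log2_ratio, 1)  # median ratio 2 -> log2 = 1
  expect_equal(out$n_peptides, 3)
})

test_that("noise-free reporter ratios recover the truth exactly", {
  mixture <- list(
    proteins = tibble::tibble(protein_id = c("P1", "P2"),
                              channel_log2_ratio = c(0, 1)),
    peptides = tibble::tibble(
      peptide_id = c("p1", "p2", "p3", "p4"),
      protein_id = c("P1", "P1", "P2", "P3"),
      channel_log2_ratio = c(0, 0, 1, -1))
  )
  psms <- tibble::tibble(
    event_id = paste0("e", 1:3), peptide_id = c("p1", "p2", "p3"),
    score = 3, is_decoy = FALSE, accepted = TRUE)
  out <- reporter_ratios(psms, mixture, noise_sd = 0, seed = 1)
  expect_equal(out$log2_ratio[out$protein_id == "P1"], 0)
  expect_equal(out$log2_ratio[out$protein_id == "P2"], 1)
  # protein with no accepted peptide is absent
  expect_false("P3" %in% out$protein_id)
})

test_that("regression stats reproduce the closed-form least squares", {
  out <- regression_stats(1:10, 1:10)
  expect_equal(out$slope, 1)
  expect_equal(out$r_squared, 1)

  out <- regression_stats(1:10, 0.5 * (1:10))
  expect_equal(out$slope, 0.5)
  expect_equal(out$r_squared, 1)

  out <- regression_stats(c(1, 2, 3), c(2, 4, 5))
  expect_equal(out$slope, 1.5, tolerance = 1e-12)
  expect_equal(out$intercept, 2 / 3, tolerance = 1e-12)
  expect_equal(out$r_squared, 27 / 28, tolerance = 1e-12)

  expect_error(regression_stats(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(regression_stats(1, 1), "length")
})

test_that("regression agrees with the normal equations on random inputs", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    out <- regression_stats(x, y)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(out$slope, slope, tolerance = 1e-10)
    expect_equal(out$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
    expect_equal(out$r_squared, stats::cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("venn counts partition the union", {
  expect_equal(venn_counts(1:5, 1:5), tibble::tibble(only_a = 0L, both = 5L,
                                                     only_b = 0L))
  expect_equal(venn_counts(1:3, 4:5), tibble::tibble(only_a = 3L, both = 0L,
                                                     only_b = 2L))
  set.seed(71)
  for (i in 1:20) {
    a <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    v <- venn_counts(a, b)
    expect_true(all(unlist(v) >= 0))
    expect_equal(v$only_a + v$both + v$only_b, length(union(a, b)))
  }
})

test_that("percent increase matches the worked identification counts", {
  out <- percent_increase(845, 347)
  expect_equal(out$percent, 100 * (845 - 347) / 347)
  expect_equal(out$percent_rounded, 144)
  expect_equal(percent_increase(347, 347)$percent, 0)
  expect_equal(percent_increase(1401, 731)$percent, 91.65526,
               tolerance = 1e-6)
  expect_error(percent_increase(10, 0), "positive")
  # antisymmetry around n_new = n_ref
  for (d in c(5, 17, 100)) {
    expect_equal(percent_increase(347 + d, 347)$percent,
                 -percent_increase(347 - d, 347)$percent)
  }
})

test_that("coverage comparison counts strictly increased proteins", {
  qa <- tibble::tibble(protein_id = c("A", "B", "C", "D"),
                       n_peptides = c(5, 3, 2, 1))
  qb <- tibble::tibble(protein_id = c("A", "B", "C", "D"),
                       n_peptides = c(4, 2, 1, 1))
  out <- coverage_comparison(qa, qb)
  expect_equal(out$increased_coverage_fraction, 0.75)
  expect_equal(coverage_comparison(qa, qa)$increased_coverage_fraction, 0)
  qb2 <- dplyr::mutate(qb, n_peptides = n_peptides - 1)
  expect_equal(coverage_comparison(qa, qb2)$increased_coverage_fraction, 1)
  expect_warning(
    out <- coverage_comparison(qa, tibble::tibble(protein_id = "Z",
                                                  n_peptides = 1)),
    "undefined")
  expect_true(is.na(out$increased_coverage_fraction))
})

test_that("the comparison object exposes tidy, glance and a plot", {
  mx <- tiny_mixture(seed = 81, n_proteins = 20)
  cfg <- fast_config()
  pie <- run_pie_campaign(mx, cfg, n_iterations = 2, seed = 9)
  dda <- run_dda_replicates(mx, cfg, n_reps = 2, seed = 9)
  cmp <- compare_strategies(pie, dda, mx, noise_sd = 0.2, seed = 1)
  g <- glance(cmp)
  expect_equal(nrow(g), 1)
  expect_equal(g$venn_only_a + g$venn_both + g$venn_only_b,
               length(union(cmp$quant_a$protein_id,
                            cmp$quant_b$protein_id)))
  expect_true(is.na(g$r_squared) || (g$r_squared >= 0 && g$r_squared <= 1))
  td <- tidy(cmp)
  expect_equal(nrow(td), g$n_common)
  expect_true(all(c("log2_ratio_a", "log2_ratio_b", "true_log2_ratio")
                  %in% names(td)))
  expect_s3_class(autoplot(cmp), "ggplot")
  dir <- withr::local_tempdir()
  write_comparison_report(cmp, dir)
  expect_true(file.exists(file.path(dir, "comparison.json")))
  expect_true(file.exists(file.path(dir, "comparison.md")))
})
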