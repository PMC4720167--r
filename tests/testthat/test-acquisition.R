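test_that("elution intensity follows the Gaussian closed form", {
  p <- list(peak_amplitude = 1e6, rt_apex = 40, rt_sigma = 0.5)
  expect_equal(elution_intensity(p, 40), 1e6)
  expect_equal(elution_intensity(p, 40.5), 1e6 * exp(-0.5))
  expect_lt(elution_intensity(p, 40 + 6 * 0.5), 1e6 * exp(-17.9))
})

test_that("is_excluded applies the ppm window inside the RT interval", {
  lst <- exclusion_list(tibble::tibble(mz = 500.0000, rt_start = 30,
                                       rt_end = 40))
  expect_true(is_excluded(500.0040, 35, lst, ppm = 10))   # 8 ppm
  expect_false(is_excluded(500.0040, 45, lst, ppm = 10))  # outside RT
  expect_false(is_excluded(500.0100, 35, lst, ppm = 10))  # 20 ppm
  expect_false(is_excluded(500.0, 35, exclusion_list(), ppm = 10))
})

test_that("a precursor on the exclusion list is never selected", {
  pep <- make_peptides(mz = 500.0, rt_apex = 5, peak_amplitude = 1e7)
  cfg <- deterministic_config(run_length = 10)
  lst <- exclusion_list(tibble::tibble(mz = 500.0, rt_start = 0,
                                       rt_end = 10))
  run <- simulate_run(pep, cfg, exclusion = lst, seed = 1)
  expect_equal(nrow(run$events), 0)
  # and without the list it is selected
  run2 <- simulate_run(pep, cfg, exclusion = NULL, seed = 1)
  expect_gt(nrow(run2$events), 0)
})

test_that("top-N selection picks the most intense co-eluting precursors", {
  # single effective cycle: run_length just above one 3.4 s cycle
  pep <- make_peptides(mz = c(600, 500, 700, 800, 900),
                       rt_apex = rep(0, 5),
                       peak_amplitude = c(5e6, 4e6, 3e6, 2e6, 1e6),
                       rt_sigma = 5)
  cfg <- deterministic_config(run_length = 0.1)
  run <- simulate_run(pep, cfg, seed = 1)
  expect_equal(run$n_cycles, 1)
  expect_equal(nrow(run$events), 3)
  expect_setequal(run$events$peptide_id, c("pep01", "pep02", "pep03"))
  expect_equal(run$n_ms2_events, 6)
})

test_that("selection ties break toward lower m/z", {
  pep <- make_peptides(mz = c(900, 500), rt_apex = c(0, 0),
                       peak_amplitude = c(1e6, 1e6), rt_sigma = 5)
  cfg <- deterministic_config(run_length = 0.1, top_n = 1)
  run <- simulate_run(pep, cfg, seed = 1)
  expect_equal(run$events$mz[1], 500)
})

test_that("an empty mixture yields zero events and the full cycle count", {
  cfg <- acquisition_config(run_length = 10)
  run <- simulate_run(make_peptides(numeric(0), numeric(0), numeric(0)),
                      cfg, seed = 1)
  expect_equal(nrow(run$events), 0)
  expect_equal(run$n_cycles,
               floor(10 * 60 / (cfg$survey_time +
                                  2 * cfg$top_n * cfg$ms2_event_time)))
})

test_that("precursors outside the survey range or below threshold are
           invisible", {
  pep <- make_peptides(mz = c(200, 500, 2500), rt_apex = rep(5, 3),
                       peak_amplitude = c(1e7, 1e3, 1e7))
  cfg <- deterministic_config(run_length = 10)
  run <- simulate_run(pep, cfg, seed = 1)
  expect_equal(nrow(run$events), 0)  # out of range or below threshold
  pep2 <- make_peptides(mz = 500, rt_apex = 5, peak_amplitude = 1e7)
  expect_gt(nrow(simulate_run(pep2, cfg, seed = 1)$events), 0)
})

test_that("dynamic exclusion caps selections per 60 s window", {
  pep <- make_peptides(mz = 500, rt_apex = 5, peak_amplitude = 1e8,
                       rt_sigma = 3)
  cfg <- deterministic_config(run_length = 10, top_n = 1)
  run <- simulate_run(pep, cfg, seed = 1)
  times <- sort(run$events$time)
  expect_gt(length(times), 2)
  dur <- cfg$dyn_excl_duration / 60
  k <- cfg$dyn_excl_repeat
  for (i in seq_len(length(times) - k)) {
    expect_gte(times[i + k] - times[i], dur - 1e-9)
  }
})

test_that("MS2 duty-cycle accounting is conserved", {
  mx <- tiny_mixture(seed = 4)
  cfg <- fast_config()
  run <- simulate_run(mx, cfg, seed = 9)
  expect_equal(run$n_ms2_events, 2 * nrow(run$events))
  expect_lte(nrow(run$events), cfg$top_n * run$n_cycles)
})

test_that("fdr_filter implements the walk on the worked cases", {
  psms <- tibble::tibble(score = c(10, 9, 8, 7, 6, 5, 4),
                         is_decoy = c(F, F, F, F, T, F, F))
  out <- fdr_filter(psms, alpha = 0.01)
  expect_equal(sum(out$accepted), 4)
  expect_true(all(which(out$accepted) <= 4))

  # no decoys: all targets accepted
  out <- fdr_filter(tibble::tibble(score = rnorm(10), is_decoy = FALSE),
                    alpha = 0.01)
  expect_true(all(out$accepted))

  # top-scoring decoy empties the accepted set
  out <- fdr_filter(tibble::tibble(score = c(10, 9, 8),
                                   is_decoy = c(TRUE, FALSE, FALSE)),
                    alpha = 0.01)
  expect_false(any(out$accepted))

  # 99 targets, 1 decoy, 1 target: exactly 99 accepted
  psms <- tibble::tibble(score = seq(101, 1), is_decoy = FALSE)
  psms$is_decoy[100] <- TRUE
  out <- fdr_filter(psms, alpha = 0.01)
  expect_equal(sum(out$accepted), 99)

  expect_error(fdr_filter(psms, alpha = 0), "0, 1")
  expect_error(fdr_filter(psms, alpha = 1.5), "0, 1")
})

test_that("fdr_filter matches the brute-force walk oracle on random sets", {
  set.seed(303)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    psms <- tibble::tibble(score = round(rnorm(n), 2),
                           is_decoy = runif(n) < 0.3)
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    out <- fdr_filter(psms, alpha)
    expect_equal(out$accepted, oracle_fdr(psms$score, psms$is_decoy, alpha))
  }
})

test_that("identification success is forced by the degenerate logistic", {
  mx <- tiny_mixture(seed = 12)
  cfg <- deterministic_config(run_length = 12)
  run <- simulate_run(mx, cfg, seed = 2)
  psms <- identify_and_filter(run$events, cfg, seed = 3)
  expect_true(all(psms$accepted))
  expect_false(any(psms$is_decoy))
  expect_equal(nrow(psms), nrow(run$events))
})
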