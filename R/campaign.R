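# Campaign orchestration: DDA replicates and PIE iterations.

# Simulate + identify one run; attaches PSMs and accepted peptide/protein
# sets. Seed derivation is fixed so campaigns are reproducible stage by
# stage.
run_acquisition <- function(mixture, config, exclusion, seed, run_id) {
  run <- simulate_run(mixture, config, exclusion = exclusion, seed = seed,
                      run_id = run_id)
  run$psms <- identify_and_filter(run$events, config,
                                  seed = derive_seed(seed, "identify"))
  acc <- run$psms[run$psms$accepted & !run$psms$is_decoy, ]
  run$accepted_peptides <- unique(acc$peptide_id)
  pep <- if (inherits(mixture, "pie_mixture")) mixture$peptides else mixture
  run$accepted_proteins <- unique(
    pep$protein_id[match(run$accepted_peptides, pep$peptide_id)])
  run$exclusion_in_force <- exclusion
  run
}

#' Build an exclusion list from a run's accepted identifications
#'
#' One entry per accepted PSM's selection event: the event m/z with a
#' retention-time window of the event time +/- `rt_pad`, intensity recorded
#' and the run id as provenance; the entries are then clustered with
#' [cluster_merge()].
#'
#' @param result A `pie_run` with PSMs attached (from [run_pie_campaign()],
#'   [run_dda_replicates()] or the campaign internals).
#' @param rt_pad Half-window in minutes (default 2).
#' @param ppm Clustering tolerance in ppm (default 10).
#' @param rt_gap RT gap passed to [cluster_merge()].
#' @return An [exclusion_list()].
#' @export
build_exclusion_from_run <- function(result, rt_pad = 2, ppm = 10,
                                     rt_gap = 0) {
  stopifnot(inherits(result, "pie_run"), !is.null(result$psms))
  acc <- result$psms[result$psms$accepted & !result$psms$is_decoy, ]
  ev <- result$events[result$events$event_id %in% acc$event_id, ]
  entries <- tibble::tibble(
    mz = ev$mz,
    rt_start = ev$time - rt_pad,
    rt_end = ev$time + rt_pad,
    intensity = ev$intensity,
    source_run = result$run_id
  )
  out <- cluster_merge(exclusion_list(entries, ppm_tolerance = ppm,
                                      rt_pad = rt_pad,
                                      provenance = result$run_id),
                       rt_gap = rt_gap)
  out
}

new_campaign <- function(mode, runs, exclusion, seed, config) {
  structure(list(mode = mode, runs = runs, exclusion = exclusion,
                 seed = seed, config = config),
            class = "pie_campaign")
}

#' Run an iterative PIE campaign
#'
#' Iteration 1 is plain DDA. Before each subsequent iteration the exclusion
#' list built from the latest run ([build_exclusion_from_run()]) is merged
#' into the cumulative list ([merge_lists()]) and capped to instrument
#' capacity ([cap_list()]); the run then acquires with that list in force.
#'
#' @param mixture A `pie_mixture`.
#' @param config An [acquisition_config()].
#' @param n_iterations Number of iterations (>= 1).
#' @param seed Master seed; run `i` uses `seed + 1000 * (i - 1)`.
#' @return A `pie_campaign` with `runs` (each a `pie_run` carrying its PSMs,
#'   accepted sets and the exclusion list that was in force) and the final
#'   cumulative `exclusion` list.
#' @export
run_pie_campaign <- function(mixture, config = acquisition_config(),
                             n_iterations = 3, seed = 1L) {
  stopifnot(n_iterations >= 1)
  cumulative <- exclusion_list(ppm_tolerance = config$ppm_window,
                               rt_pad = config$rt_pad)
  runs <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    run_seed <- as.integer(seed + 1000 * (i - 1))
    excl <- if (i == 1) NULL else cumulative
    run <- run_acquisition(mixture, config, excl, run_seed,
                           run_id = sprintf("iter%d", i))
    runs[[i]] <- run
    latest <- build_exclusion_from_run(run, rt_pad = config$rt_pad,
                                       ppm = config$ppm_window,
                                       rt_gap = config$rt_gap)
    cumulative <- cap_list(merge_lists(cumulative, latest,
                                       rt_gap = config$rt_gap),
                           max_entries = config$max_entries)
  }
  new_campaign("pie", runs, cumulative, seed, config)
}

#' Run independent DDA replicates
#'
#' Seeded runs with empty exclusion lists; retention-time jitter differs by
#' replicate through the per-run seeds, which follow the same derivation as
#' [run_pie_campaign()] so a 1-replicate DDA campaign equals a 1-iteration
#' PIE campaign under the same seed.
#'
#' @inheritParams run_pie_campaign
#' @param n_reps Number of replicates (>= 1).
#' @return A `pie_campaign` (mode `"dda"`, `exclusion = NULL`).
#' @export
run_dda_replicates <- function(mixture, config = acquisition_config(),
                               n_reps = 3, seed = 1L) {
  stopifnot(n_reps >= 1)
  runs <- lapply(seq_len(n_reps), function(i) {
    run_acquisition(mixture, config, NULL, as.integer(seed + 1000 * (i - 1)),
                    run_id = sprintf("rep%d", i))
  })
  new_campaign("dda", runs, NULL, seed, config)
}

#' @export
print.pie_campaign <- function(x, ...) {
  acc <- length(campaign_accepted_peptides(x))
  cat(sprintf("<pie_campaign> mode=%s, %d runs, %d unique accepted peptides\n",
              x$mode, length(x$runs), acc))
  for (r in x$runs) print(r)
  invisible(x)
}

#' Cumulative accepted identifications of a campaign
#'
#' @param campaign A `pie_campaign`.
#' @return Character vector of unique accepted peptide (protein) ids across
#'   all runs.
#' @export
campaign_accepted_peptides <- function(campaign) {
  unique(unlist(lapply(campaign$runs, `[[`, "accepted_peptides")))
}

#' @rdname campaign_accepted_peptides
#' @export
campaign_accepted_proteins <- function(campaign) {
  unique(unlist(lapply(campaign$runs, `[[`, "accepted_proteins")))
}

# All accepted PSMs of a campaign in one tibble.
campaign_psms <- function(campaign) {
  dplyr::bind_rows(lapply(campaign$runs, `[[`, "psms"))
}

#' Split a mixture into per-fraction sub-mixtures
#'
#' Fractionated campaigns are simulated as separate runs over
#' fraction-restricted sub-mixtures with per-fraction exclusion lists.
#'
#' @param mixture A `pie_mixture`.
#' @param scheme `"hilic"` or `"scx"`.
#' @return Named list of `pie_mixture` objects, one per occupied fraction.
#' @export
split_by_fraction <- function(mixture, scheme = c("hilic", "scx")) {
  scheme <- match.arg(scheme)
  col <- paste0(scheme, "_fraction")
  labs <- sort(unique(mixture$peptides[[col]]))
  out <- lapply(labs, function(f) {
    sub <- mixture
    sub$peptides <- mixture$peptides[mixture$peptides[[col]] == f, ]
    sub
  })
  names(out) <- sprintf("%s%d", scheme, labs)
  out
}

#' Serialize / restore campaign run tables
#'
#' Writes per-run selection-event and PSM TSV tables plus a JSON summary
#' (cycle counts, seeds, accepted counts) under `dir`. `read_run_results()`
#' restores the per-run tables (events, PSMs, accepted sets) for reporting.
#'
#' @param campaign A `pie_campaign`.
#' @param dir Output (input) directory.
#' @return `write_run_results()` returns `dir` invisibly;
#'   `read_run_results()` a list with `runs` and `summary`.
#' @export
write_run_results <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in campaign$runs) {
    readr::write_tsv(r$events, file.path(dir, paste0(r$run_id, "_events.tsv")))
    readr::write_tsv(r$psms, file.path(dir, paste0(r$run_id, "_psms.tsv")))
  }
  summary <- list(
    mode = campaign$mode,
    seed = campaign$seed,
    runs = lapply(campaign$runs, function(r) {
      list(run_id = r$run_id, seed = r$seed, n_cycles = r$n_cycles,
           n_selections = nrow(r$events), n_ms2_events = r$n_ms2_events,
           n_accepted_peptides = length(r$accepted_peptides),
           n_accepted_proteins = length(r$accepted_proteins))
    })
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_run_results
#' @export
read_run_results <- function(dir) {
  summary <- jsonlite::read_json(file.path(dir, "summary.json"))
  runs <- lapply(summary$runs, function(s) {
    events <- readr::read_tsv(
      file.path(dir, paste0(s$run_id, "_events.tsv")),
      show_col_types = FALSE, progress = FALSE)
    psms <- readr::read_tsv(
      file.path(dir, paste0(s$run_id, "_psms.tsv")),
      show_col_types = FALSE, progress = FALSE)
    acc <- psms[psms$accepted & !psms$is_decoy, ]
    structure(list(run_id = s$run_id, seed = s$seed, n_cycles = s$n_cycles,
                   events = events, psms = psms,
                   n_ms2_events = s$n_ms2_events,
                   accepted_peptides = unique(acc$peptide_id)),
              class = "pie_run")
  })
  list(runs = runs, summary = summary)
}
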