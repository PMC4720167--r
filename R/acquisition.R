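# In-silico LC-MS/MS acquisition: survey cycles, top-N selection, dynamic
# exclusion, and precursor-ion-exclusion (PIE) list compliance.

#' Acquisition configuration
#'
#' Defaults model a top 3x2 method on a hybrid ion-trap/orbitrap instrument:
#' each survey scan is followed by three precursors fragmented twice (HCD for
#' reporter ions, CID for sequencing), giving a cycle time of
#' `survey_time + 2 * top_n * ms2_event_time` seconds (3.4 s at defaults).
#' Survey range m/z 350-2000; dynamic exclusion bans a precursor for 60 s
#' after its second selection within 60 s, matched at a 10 ppm window.
#' Identification is modeled statistically: the probability that an MS2 event
#' yields a correct peptide-spectrum match follows a logistic curve in log10
#' precursor intensity (`id_midpoint`, `id_steepness`); correct matches score
#' `N(id_score_mean, id_score_sd)` while incorrect matches and injected
#' decoys score `N(0, 1)`, and the 1% FDR walk does the filtering.
#'
#' @param mz_min,mz_max Survey scan m/z range (Th).
#' @param top_n Precursors selected per survey scan.
#' @param survey_time,ms2_event_time Seconds per survey scan and per single
#'   MS2 event (each precursor costs two events: HCD + CID).
#' @param dyn_excl_duration Dynamic exclusion duration, seconds.
#' @param dyn_excl_repeat Selections within `dyn_excl_duration` that trigger
#'   dynamic exclusion (2 = "selected more than once").
#' @param ppm_window Matching tolerance (ppm) for both dynamic and list-based
#'   exclusion.
#' @param detection_threshold Minimum precursor intensity visible to the
#'   instrument (arbitrary units, same scale as mixture amplitudes).
#' @param run_length Run length, minutes.
#' @param rt_jitter_sd Per-peptide Gaussian retention-time jitter applied per
#'   run (minutes) to model run-to-run variation.
#' @param id_midpoint,id_steepness Logistic identification-success model in
#'   log10 intensity. `id_midpoint = -Inf` forces success probability 1.
#' @param id_score_mean,id_score_sd Score distribution of correct matches.
#' @param decoy_fraction Decoy PSMs injected per target PSM.
#' @param fdr_alpha Target-decoy FDR threshold (default 0.01).
#' @param rt_pad Half-window (minutes) when building exclusion entries from
#'   selection events.
#' @param rt_gap RT gap (minutes) used when clustering exclusion entries.
#' @param max_entries Instrument exclusion-table capacity.
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(mz_min = 350, mz_max = 2000, top_n = 3,
                               survey_time = 1.0, ms2_event_time = 0.4,
                               dyn_excl_duration = 60, dyn_excl_repeat = 2,
                               ppm_window = 10, detection_threshold = 5e4,
                               run_length = 120, rt_jitter_sd = 0.3,
                               id_midpoint = 5.5, id_steepness = 1.2,
                               id_score_mean = 3.5, id_score_sd = 1,
                               decoy_fraction = 0.15, fdr_alpha = 0.01,
                               rt_pad = 2, rt_gap = 0, max_entries = 2000) {
  stopifnot(mz_min < mz_max, top_n >= 1, survey_time > 0,
            ms2_event_time > 0, dyn_excl_duration > 0, dyn_excl_repeat >= 1,
            ppm_window > 0, detection_threshold > 0, run_length > 0,
            rt_jitter_sd >= 0, decoy_fraction >= 0,
            fdr_alpha > 0, fdr_alpha <= 1, rt_pad >= 0, rt_gap >= 0,
            max_entries >= 0)
  structure(list(
    mz_min = mz_min, mz_max = mz_max, top_n = as.integer(top_n),
    survey_time = survey_time, ms2_event_time = ms2_event_time,
    dyn_excl_duration = dyn_excl_duration,
    dyn_excl_repeat = as.integer(dyn_excl_repeat),
    ppm_window = ppm_window, detection_threshold = detection_threshold,
    run_length = run_length, rt_jitter_sd = rt_jitter_sd,
    id_midpoint = id_midpoint, id_steepness = id_steepness,
    id_score_mean = id_score_mean, id_score_sd = id_score_sd,
    decoy_fraction = decoy_fraction, fdr_alpha = fdr_alpha,
    rt_pad = rt_pad, rt_gap = rt_gap, max_entries = as.integer(max_entries)
  ), class = "acquisition_config")
}

cycle_time_sec <- function(config) {
  config$survey_time + 2 * config$top_n * config$ms2_event_time
}

#' Gaussian elution intensity
#'
#' Instantaneous precursor intensity of a peptide at time `t`:
#' `peak_amplitude * exp(-(t - rt_apex)^2 / (2 rt_sigma^2))`.
#'
#' @param peptide One-row tibble (or list) with `peak_amplitude`, `rt_apex`,
#'   `rt_sigma`.
#' @param t Time in minutes (vectorised).
#' @return Intensity in the same units as `peak_amplitude`.
#' @export
#' @examples
#' p <- list(peak_amplitude = 1e6, rt_apex = 40, rt_sigma = 0.3)
#' elution_intensity(p, 40)
elution_intensity <- function(peptide, t) {
  peptide$peak_amplitude *
    exp(-((t - peptide$rt_apex)^2) / (2 * peptide$rt_sigma^2))
}

#' Is a precursor excluded by a list at a given time?
#'
#' `TRUE` iff some entry matches within `ppm` (relative to the entry m/z) and
#' its closed retention-time window contains `t`.
#'
#' @param mz Precursor m/z (scalar).
#' @param t Time in minutes (scalar).
#' @param list An [exclusion_list()] (or entry data frame).
#' @param ppm Matching tolerance in ppm; defaults to the list's own.
#' @return Logical scalar.
#' @export
is_excluded <- function(mz, t, list, ppm = NULL) {
  ppm <- ppm %||% attr(list, "ppm_tolerance") %||% 10
  d <- as_entries(list)
  if (nrow(d) == 0) return(FALSE)
  any(abs(mz - d$mz) / d$mz * 1e6 <= ppm &
        d$rt_start <= t & t <= d$rt_end)
}

# Map times (minutes) to the first/last survey-cycle index covering them.
# Cycle k surveys at t_k = (k-1) * dt.
first_cycle_at_or_after <- function(t, dt) ceiling(t / dt - 1e-9) + 1L
last_cycle_at_or_before <- function(t, dt) floor(t / dt + 1e-9) + 1L

#' Simulate one LC-MS/MS run
#'
#' Advances survey cycles of `survey_time + 2 * top_n * ms2_event_time`
#' seconds. At each cycle the candidate precursors are the peptides whose
#' elution intensity exceeds the detection threshold and whose m/z lies in
#' the survey range, minus dynamically excluded and PIE-excluded species; the
#' `top_n` most intense are selected (ties broken by lower m/z). A peptide
#' selected `dyn_excl_repeat` times within `dyn_excl_duration` enters dynamic
#' exclusion for `dyn_excl_duration`. Per-run Gaussian retention-time jitter
#' (sd `rt_jitter_sd`) shifts each peptide's apex.
#'
#' @param mixture A `pie_mixture` (or a peptide tibble).
#' @param config An [acquisition_config()].
#' @param exclusion Optional [exclusion_list()] in force for this run.
#' @param seed Integer seed for jitter.
#' @param run_id Run identifier recorded on events.
#' @return A `pie_run` with the selection `events` tibble, `n_cycles`,
#'   `n_ms2_events` (2 per selection), and bookkeeping fields.
#' @export
simulate_run <- function(mixture, config = acquisition_config(),
                         exclusion = NULL, seed = 1L, run_id = "run1") {
  stopifnot(inherits(config, "acquisition_config"))
  pep <- if (inherits(mixture, "pie_mixture")) mixture$peptides else
    tibble::as_tibble(mixture)
  n <- nrow(pep)
  dt <- cycle_time_sec(config) / 60
  n_cycles <- as.integer(floor(config$run_length / dt))
  dur_min <- config$dyn_excl_duration / 60

  apex <- with_seed(seed, pep$rt_apex + stats::rnorm(n, 0, config$rt_jitter_sd))
  amp <- pep$peak_amplitude
  sig <- pep$rt_sigma
  mz <- pep$mz
  thr <- config$detection_threshold

  # Detectable cycle range per peptide; k_lo > n_cycles marks "never".
  k_lo <- rep.int(n_cycles + 2L, n)
  k_hi <- rep.int(0L, n)
  vis <- which(amp >= thr & mz >= config$mz_min & mz <= config$mz_max)
  if (length(vis)) {
    half <- sig[vis] * sqrt(2 * log(amp[vis] / thr))
    t_lo <- pmax(apex[vis] - half, 0)
    t_hi <- pmin(apex[vis] + half, config$run_length)
    ok <- t_lo <= t_hi
    k_lo[vis[ok]] <- pmax(first_cycle_at_or_after(t_lo[ok], dt), 1L)
    k_hi[vis[ok]] <- pmin(last_cycle_at_or_before(t_hi[ok], dt), n_cycles)
  }

  # Static PIE exclusion per peptide: cycle ranges where any matching entry's
  # RT window is open, folded into an increment/decrement count per cycle.
  pie_add <- vector("list", n_cycles + 1L)
  pie_rem <- vector("list", n_cycles + 1L)
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    ex <- as_entries(exclusion)
    ex <- ex[order(ex$mz), ]
    ppm <- attr(exclusion, "ppm_tolerance") %||% config$ppm_window
    p <- ppm * 1e-6
    lo_idx <- findInterval(mz / (1 + p) - 1e-12, ex$mz) + 1L
    hi_idx <- findInterval(mz / (1 - p) + 1e-12, ex$mz)
    pi_pep <- integer(0); pi_ks <- integer(0); pi_ke <- integer(0)
    for (i in seq_len(n)) {
      if (lo_idx[i] > hi_idx[i]) next
      jj <- lo_idx[i]:hi_idx[i]
      ks <- pmax(first_cycle_at_or_after(ex$rt_start[jj], dt), 1L)
      ke <- pmin(last_cycle_at_or_before(ex$rt_end[jj], dt), n_cycles)
      keep <- ks <= ke
      if (any(keep)) {
        pi_pep <- c(pi_pep, rep.int(i, sum(keep)))
        pi_ks <- c(pi_ks, ks[keep])
        pi_ke <- c(pi_ke, ke[keep])
      }
    }
    if (length(pi_pep)) {
      sp <- split(pi_pep, pi_ks)
      pie_add[as.integer(names(sp))] <- sp
      sp <- split(pi_pep, pmin(pi_ke + 1L, n_cycles + 1L))
      pie_rem[as.integer(names(sp))] <- sp
    }
  }

  pie_cnt <- integer(n)
  dyn_until <- rep.int(-Inf, n)
  sel_hist <- vector("list", n)
  cap <- n_cycles * config$top_n
  ev_pep <- integer(cap); ev_cycle <- integer(cap)
  ev_t <- numeric(cap); ev_int <- numeric(cap)
  n_ev <- 0L

  for (k in seq_len(n_cycles)) {
    if (!is.null(pie_add[[k]])) {
      pie_cnt[pie_add[[k]]] <- pie_cnt[pie_add[[k]]] + 1L
    }
    if (!is.null(pie_rem[[k]])) {
      pie_cnt[pie_rem[[k]]] <- pie_cnt[pie_rem[[k]]] - 1L
    }
    t <- (k - 1L) * dt
    cand <- which(k_lo <= k & k <= k_hi & pie_cnt == 0L & dyn_until <= t)
    if (!length(cand)) next
    inten <- amp[cand] * exp(-((t - apex[cand])^2) / (2 * sig[cand]^2))
    keep <- inten >= thr
    if (!any(keep)) next
    cand <- cand[keep]; inten <- inten[keep]
    ord <- order(-inten, mz[cand])
    take <- ord[seq_len(min(config$top_n, length(ord)))]
    sel <- cand[take]; si <- inten[take]
    for (j in seq_along(sel)) {
      n_ev <- n_ev + 1L
      ev_pep[n_ev] <- sel[j]; ev_cycle[n_ev] <- k
      ev_t[n_ev] <- t; ev_int[n_ev] <- si[j]
      p <- sel[j]
      h <- c(sel_hist[[p]], t)
      h <- h[h > t - dur_min + 1e-9]
      if (length(h) >= config$dyn_excl_repeat) {
        dyn_until[p] <- t + dur_min
        sel_hist[[p]] <- numeric(0)
      } else {
        sel_hist[[p]] <- h
      }
    }
  }

  idx <- seq_len(n_ev)
  events <- tibble::tibble(
    event_id = sprintf("%s_e%05d", run_id, idx),
    cycle = ev_cycle[idx],
    time = ev_t[idx],
    mz = mz[ev_pep[idx]],
    intensity = ev_int[idx],
    peptide_id = pep$peptide_id[ev_pep[idx]],
    run_id = rep.int(run_id, n_ev)
  )
  structure(list(
    run_id = run_id, seed = seed, n_cycles = n_cycles,
    cycle_time = cycle_time_sec(config), events = events,
    n_ms2_events = 2L * n_ev,
    rt_apex_jittered = apex
  ), class = "pie_run")
}

#' @export
print.pie_run <- function(x, ...) {
  cat(sprintf(
    "<pie_run> %s: %d cycles, %d selections (%d MS2 events)%s\n",
    x$run_id, x$n_cycles, nrow(x$events), x$n_ms2_events,
    if (!is.null(x$psms)) {
      sprintf(", %d accepted peptides", length(x$accepted_peptides))
    } else ""
  ))
  invisible(x)
}
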