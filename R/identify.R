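# Stochastic identification model and target-decoy FDR filtering.

#' Target-decoy FDR filtering ("accept until the FDR rate is reached")
#'
#' PSMs are ranked by decreasing score (ties put decoys first, which is
#' conservative) and accepted from the top for as long as every prefix keeps
#' the decoy/target ratio at or below `alpha`; the walk stops at the first
#' violation, so there is no fixed score cutoff. Decoys are never marked
#' accepted.
#'
#' @param psms Tibble with numeric `score` and logical `is_decoy` columns.
#' @param alpha FDR threshold in (0, 1], default 0.01.
#' @return `psms` with a logical `accepted` column (original row order).
#' @export
#' @examples
#' fdr_filter(tibble::tibble(score = c(5, 4, 3), is_decoy = c(FALSE, TRUE, FALSE)))
fdr_filter <- function(psms, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    rlang::abort("`alpha` must lie in (0, 1]")
  }
  stopifnot(all(c("score", "is_decoy") %in% names(psms)))
  psms <- tibble::as_tibble(psms)
  n <- nrow(psms)
  if (n == 0) {
    psms$accepted <- logical(0)
    return(psms)
  }
  ord <- order(-psms$score, -as.integer(psms$is_decoy))
  dec <- psms$is_decoy[ord]
  cum_d <- cumsum(dec)
  cum_t <- cumsum(!dec)
  valid <- cum_d <= alpha * cum_t
  k <- if (all(valid)) n else which(!valid)[1] - 1L
  accepted <- logical(n)
  if (k > 0) accepted[ord[seq_len(k)]] <- !psms$is_decoy[ord[seq_len(k)]]
  psms$accepted <- accepted
  psms
}

#' Score selection events and filter at the FDR threshold
#'
#' Every selection event yields one target PSM. With probability given by
#' the logistic identification model in log10 intensity the match is correct
#' and scores `N(id_score_mean, id_score_sd)`; otherwise it scores from the
#' null `N(0, 1)`. `round(decoy_fraction * n_events)` decoy PSMs drawn from
#' the null are injected, and [fdr_filter()] is applied at `fdr_alpha`.
#'
#' @param events Selection-event tibble from [simulate_run()].
#' @param config An [acquisition_config()].
#' @param seed Integer seed.
#' @return PSM tibble: `event_id`, `peptide_id`, `score`, `is_decoy`,
#'   `accepted` (decoy rows have `NA` event and peptide ids).
#' @export
identify_and_filter <- function(events, config = acquisition_config(),
                                seed = 1L) {
  stopifnot(inherits(config, "acquisition_config"))
  n <- nrow(events)
  with_seed(seed, {
    p_correct <- stats::plogis(
      config$id_steepness * (log10(pmax(events$intensity, 1e-12)) -
                               config$id_midpoint))
    correct <- stats::runif(n) < p_correct
    score_hit <- stats::rnorm(n, config$id_score_mean, config$id_score_sd)
    score_null <- stats::rnorm(n, 0, 1)
    n_decoy <- round(config$decoy_fraction * n)
    decoy_score <- stats::rnorm(n_decoy, 0, 1)
  })
  targets <- tibble::tibble(
    event_id = events$event_id,
    peptide_id = events$peptide_id,
    score = ifelse(correct, score_hit, score_null),
    is_decoy = FALSE
  )
  decoys <- tibble::tibble(
    event_id = NA_character_, peptide_id = NA_character_,
    score = decoy_score, is_decoy = TRUE
  )
  fdr_filter(dplyr::bind_rows(targets, decoys), config$fdr_alpha)
}
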