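# Experiment configuration, validation, and end-to-end orchestration.

experiment_defaults <- function() {
  list(
    seed = 1L,
    mixture = unclass(mixture_config()),
    acquisition = unclass(acquisition_config()),
    campaign = list(mode = "compare", replicates = 3L, iterations = 3L,
                    fractions = "none"),
    report = list(plots = FALSE, noise_sd = 0.2)
  )
}

# Recursively apply defaults and reject unknown keys; returns the merged
# config plus a tibble of applied defaults.
merge_config <- function(user, defaults, path = character()) {
  stopifnot(is.list(user))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    rlang::abort(sprintf(
      "unknown config key%s: %s",
      if (length(unknown) > 1) "s" else "",
      paste(paste(c(path, ""), collapse = "."), unknown, sep = "",
            collapse = ", ")))
  }
  applied <- list()
  out <- defaults
  for (key in names(defaults)) {
    here <- c(path, key)
    if (!key %in% names(user)) {
      applied[[length(applied) + 1L]] <- tibble::tibble(
        key = paste(here, collapse = "."),
        value = paste(format(unlist(defaults[[key]])), collapse = ","),
        origin = "default")
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
               key %in% c("mixture", "acquisition", "campaign", "report")) {
      sub <- merge_config(user[[key]], defaults[[key]], here)
      out[[key]] <- sub$config
      applied <- c(applied, list(sub$applied))
    } else {
      val <- user[[key]]
      if (is.numeric(defaults[[key]])) val <- as.numeric(val)
      if (!is.null(names(defaults[[key]])) && is.numeric(defaults[[key]])) {
        nm <- names(val) %||% names(defaults[[key]])
        val <- stats::setNames(as.numeric(val), nm)
      }
      out[[key]] <- val
      applied[[length(applied) + 1L]] <- tibble::tibble(
        key = paste(here, collapse = "."),
        value = paste(format(unlist(val)), collapse = ","),
        origin = "config")
    }
  }
  list(config = out, applied = dplyr::bind_rows(applied))
}

config_constraints <- function(cfg) {
  checks <- list(
    c("acquisition.run_length > 0", cfg$acquisition$run_length > 0),
    c("acquisition.mz_min < acquisition.mz_max",
      cfg$acquisition$mz_min < cfg$acquisition$mz_max),
    c("acquisition.top_n >= 1", cfg$acquisition$top_n >= 1),
    c("acquisition.survey_time > 0", cfg$acquisition$survey_time > 0),
    c("acquisition.ms2_event_time > 0", cfg$acquisition$ms2_event_time > 0),
    c("mixture.n_proteins >= 0", cfg$mixture$n_proteins >= 0),
    c("mixture.dynamic_range_orders > 0",
      cfg$mixture$dynamic_range_orders > 0),
    c("campaign.mode in dda|pie|compare",
      cfg$campaign$mode %in% c("dda", "pie", "compare")),
    c("campaign.replicates >= 1", cfg$campaign$replicates >= 1),
    c("campaign.iterations >= 1", cfg$campaign$iterations >= 1),
    c("campaign.fractions in none|hilic|scx",
      cfg$campaign$fractions %in% c("none", "hilic", "scx"))
  )
  tibble::tibble(
    constraint = vapply(checks, `[[`, character(1), 1),
    ok = vapply(checks, function(x) isTRUE(as.logical(x[[2]])), logical(1))
  )
}

#' Validate an experiment configuration
#'
#' Reads a YAML (or JSON) experiment config, applies and lists every
#' default, rejects unknown keys, and checks the cross-field constraints.
#'
#' @param config Path to a YAML/JSON file, or a config list.
#' @return A `pie_config_validation` list: `config` (fully merged),
#'   `applied` (tibble of every key with its origin), `violations` (tibble
#'   of failed constraints) and `ok`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      rlang::abort(sprintf("cannot read config file '%s'", config))
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  merged <- merge_config(config %||% list(), experiment_defaults())
  constraints <- config_constraints(merged$config)
  structure(list(
    config = merged$config,
    applied = merged$applied,
    violations = constraints[!constraints$ok, ],
    ok = all(constraints$ok)
  ), class = "pie_config_validation")
}

#' @export
print.pie_config_validation <- function(x, ...) {
  cat(sprintf("<pie_config_validation> %s\n",
              if (x$ok) "valid" else "INVALID"))
  if (nrow(x$violations)) {
    cat("violated constraints:\n")
    for (v in x$violations$constraint) cat("  -", v, "\n")
  }
  n_def <- sum(x$applied$origin == "default")
  cat(sprintf("%d keys (%d defaults applied)\n", nrow(x$applied), n_def))
  invisible(x)
}

campaign_for_mode <- function(mixture, acq, mode, n, seed) {
  if (mode == "dda") {
    run_dda_replicates(mixture, acq, n_reps = n, seed = seed)
  } else {
    run_pie_campaign(mixture, acq, n_iterations = n, seed = seed)
  }
}

#' Run a full experiment from a configuration
#'
#' Generates (or reloads) the mixture, runs the configured campaign(s) —
#' `mode: compare` runs both a DDA-replicate campaign and a PIE-iteration
#' campaign on the same mixture and emits the comparison report — and writes
#' a deterministic directory layout: `mixture.tsv`, per-run event/PSM
#' tables, the final exclusion list (round-trip TSV + instrument CSV),
#' `report/`, and `manifest.json` recording the full config, its hash and
#' every derived seed. Identical config + seed reproduce the directory
#' byte for byte.
#'
#' @param config Path to a YAML/JSON config, or a config list (see
#'   [validate_config()]).
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty `out_dir`?
#' @return The validated config (invisibly), with the outputs on disk.
#' @export
run_experiment <- function(config, out_dir, force = FALSE) {
  val <- validate_config(config)
  if (!val$ok) {
    rlang::abort(paste0("invalid config; violated: ",
                        paste(val$violations$constraint, collapse = "; ")))
  }
  cfg <- val$config
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    rlang::abort(sprintf(
      "output directory '%s' is not empty (use force = TRUE)", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seeds <- list(
    mixture = derive_seed(cfg$seed, "mixture"),
    dda = derive_seed(cfg$seed, "dda"),
    pie = derive_seed(cfg$seed, "pie"),
    report = derive_seed(cfg$seed, "report")
  )
  mx_cfg <- do.call(mixture_config,
                    c(cfg$mixture[setdiff(names(cfg$mixture), "seed")],
                      list(seed = seeds$mixture)))
  mixture <- generate_mixture(mx_cfg)
  write_mixture_tsv(mixture, file.path(out_dir, "mixture.tsv"))
  acq <- do.call(acquisition_config, cfg$acquisition)

  run_campaigns <- function(mode, n, seed, subdir) {
    if (cfg$campaign$fractions == "none") {
      camp <- campaign_for_mode(mixture, acq, mode, n, seed)
      write_run_results(camp, file.path(out_dir, subdir))
      list(camp)
    } else {
      subs <- split_by_fraction(mixture, cfg$campaign$fractions)
      purrr::imap(subs, function(sub, nm) {
        camp <- campaign_for_mode(sub, acq, mode, n,
                                  derive_seed(seed, nm))
        write_run_results(camp, file.path(out_dir, subdir, nm))
        camp
      })
    }
  }

  dda <- pie <- NULL
  if (cfg$campaign$mode %in% c("dda", "compare")) {
    dda <- run_campaigns("dda", cfg$campaign$replicates, seeds$dda,
                         "runs/dda")
  }
  if (cfg$campaign$mode %in% c("pie", "compare")) {
    pie <- run_campaigns("pie", cfg$campaign$iterations, seeds$pie,
                         "runs/pie")
    final <- Reduce(merge_lists, lapply(pie, `[[`, "exclusion"))
    write_exclusion_tsv(final, file.path(out_dir, "exclusion_final.tsv"))
    export_instrument_table(final, file.path(out_dir, "exclusion_final.csv"))
  }
  if (cfg$campaign$mode == "compare") {
    pie_all <- new_campaign("pie", unlist(lapply(pie, `[[`, "runs"),
                                          recursive = FALSE),
                            NULL, seeds$pie, acq)
    dda_all <- new_campaign("dda", unlist(lapply(dda, `[[`, "runs"),
                                          recursive = FALSE),
                            NULL, seeds$dda, acq)
    comparison <- compare_strategies(pie_all, dda_all, mixture,
                                     noise_sd = cfg$report$noise_sd,
                                     seed = seeds$report)
    write_comparison_report(comparison, file.path(out_dir, "report"),
                            plot = isTRUE(cfg$report$plots))
  }

  manifest <- list(config = cfg, config_hash = rlang::hash(cfg),
                   seeds = seeds)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(val)
}
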