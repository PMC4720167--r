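# Synthetic two-channel TMT tryptic mixture generator.

# Kyte-Doolittle hydropathy, used for the HILIC descriptor.
kd_hydropathy <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Configuration for the synthetic mixture generator
#'
#' Defaults describe a two-channel TMT-labeled tryptic digest of a moderately
#' complex proteome: 90 proteins whose abundances span 4 orders of
#' magnitude (yielding on the order of 5,000 tryptic peptides), Gaussian
#' elution over a 95-minute gradient, and a 20% subset of proteins carrying a
#' true +/-1 log2 between-channel difference.
#'
#' @param n_proteins Number of proteins in the mixture.
#' @param dynamic_range_orders log10 span of protein abundances; with the
#'   default log-uniform law the realised max/min ratio equals
#'   `10^dynamic_range_orders` exactly (abundances are rescaled to the span).
#' @param gradient_length Usable gradient length in minutes; elution apexes
#'   are sampled uniformly over \[0.05, 1\] x this length.
#' @param rt_sigma_range Min/max Gaussian elution peak sigma, minutes.
#' @param charge_weights Named weights over charge states 1-4; normalised.
#' @param differential_fraction Proportion of proteins with a non-zero true
#'   log2 channel ratio.
#' @param effect_size_log2 Magnitude of the true log2 ratio for differential
#'   proteins (sign randomised).
#' @param seed Integer seed; identical configs generate identical mixtures.
#' @param abundance_law `"log-uniform"` (default) or `"log-normal"`.
#' @param base_abundance Abundance of the least-abundant protein (arbitrary
#'   intensity units).
#' @param ionization_sdlog sdlog of the multiplicative lognormal ionization
#'   efficiency applied per peptide.
#' @param protein_length_range Min/max protein length in residues.
#' @param max_missed,min_length Digestion filters (see [digest_protein()]).
#' @param no_cleave_before_proline Trypsin proline rule switch, default off.
#' @param n_hilic,n_scx Number of HILIC / SCX fractions.
#' @return A `mixture_config` list.
#' @export
mixture_config <- function(n_proteins = 90,
                           dynamic_range_orders = 4,
                           gradient_length = 95,
                           rt_sigma_range = c(0.15, 0.5),
                           charge_weights = c("1" = 0.05, "2" = 0.55,
                                              "3" = 0.30, "4" = 0.10),
                           differential_fraction = 0.2,
                           effect_size_log2 = 1,
                           seed = 1L,
                           abundance_law = c("log-uniform", "log-normal"),
                           base_abundance = 1e4,
                           ionization_sdlog = 1,
                           protein_length_range = c(80L, 350L),
                           max_missed = 2,
                           min_length = 6,
                           no_cleave_before_proline = FALSE,
                           n_hilic = 6,
                           n_scx = 6) {
  abundance_law <- match.arg(abundance_law)
  if (!is.numeric(n_proteins) || length(n_proteins) != 1 || n_proteins < 0) {
    rlang::abort("`n_proteins` must be a non-negative integer")
  }
  check_positive(dynamic_range_orders, "dynamic_range_orders")
  check_positive(gradient_length, "gradient_length")
  stopifnot(length(rt_sigma_range) == 2, all(rt_sigma_range > 0),
            rt_sigma_range[1] < rt_sigma_range[2])
  stopifnot(length(protein_length_range) == 2,
            protein_length_range[1] >= 10,
            protein_length_range[1] < protein_length_range[2])
  if (is.null(names(charge_weights)) || any(charge_weights < 0) ||
      sum(charge_weights) <= 0) {
    rlang::abort("`charge_weights` must be named non-negative weights")
  }
  charge_weights <- charge_weights / sum(charge_weights)
  stopifnot(differential_fraction >= 0, differential_fraction <= 1,
            max_missed >= 0, min_length >= 1, n_hilic >= 1, n_scx >= 1)
  structure(list(
    n_proteins = as.integer(n_proteins),
    dynamic_range_orders = dynamic_range_orders,
    gradient_length = gradient_length,
    rt_sigma_range = rt_sigma_range,
    charge_weights = charge_weights,
    differential_fraction = differential_fraction,
    effect_size_log2 = effect_size_log2,
    seed = as.integer(seed),
    abundance_law = abundance_law,
    base_abundance = base_abundance,
    ionization_sdlog = ionization_sdlog,
    protein_length_range = as.integer(protein_length_range),
    max_missed = max_missed,
    min_length = min_length,
    no_cleave_before_proline = no_cleave_before_proline,
    n_hilic = as.integer(n_hilic),
    n_scx = as.integer(n_scx)
  ), class = "mixture_config")
}

empty_proteins <- function() {
  tibble::tibble(protein_id = character(0), sequence = character(0),
                 abundance = numeric(0), channel_log2_ratio = numeric(0))
}

empty_peptides <- function() {
  tibble::tibble(
    peptide_id = character(0), protein_id = character(0),
    sequence = character(0), n_missed_cleavages = integer(0),
    charge = integer(0), monoisotopic_mass = numeric(0), mz = numeric(0),
    rt_apex = numeric(0), rt_sigma = numeric(0), peak_amplitude = numeric(0),
    protein_abundance = numeric(0), channel_log2_ratio = numeric(0),
    channel_frac_126 = numeric(0), channel_frac_127 = numeric(0),
    hilic_fraction = integer(0), scx_fraction = integer(0)
  )
}

#' Generate a synthetic TMT-labeled tryptic peptide mixture
#'
#' Draws protein sequences (or uses the ones supplied), digests them fully
#' tryptically, and equips every peptide with charge, TMT-labeled
#' monoisotopic mass, m/z, a Gaussian elution profile, an ionization-noise
#' amplitude proportional to the parent protein abundance, true two-channel
#' reporter fractions, and HILIC/SCX fraction labels. Deterministic given the
#' config seed.
#'
#' @param config A [mixture_config()].
#' @param proteins Optional tibble with `protein_id` and `sequence` columns
#'   (e.g. from [read_protein_fasta()]); when supplied, `n_proteins` draws
#'   from these sequences instead of simulating new ones.
#' @return A `pie_mixture` list with tibbles `proteins` and `peptides` and
#'   the `config` used.
#' @export
#' @examples
#' mx <- generate_mixture(mixture_config(n_proteins = 5, seed = 7))
#' nrow(mx$peptides)
generate_mixture <- function(config = mixture_config(), proteins = NULL) {
  stopifnot(inherits(config, "mixture_config"))
  n <- config$n_proteins
  if (n == 0) {
    return(structure(list(proteins = empty_proteins(),
                          peptides = empty_peptides(), config = config),
                     class = "pie_mixture"))
  }
  with_seed(config$seed, {
    if (is.null(proteins)) {
      lr <- config$protein_length_range
      lens <- sample(seq.int(lr[1], lr[2]), n, replace = TRUE)
      aa <- names(aa_background_freq)
      seqs <- vapply(lens, function(l) {
        paste0(sample(aa, l, replace = TRUE, prob = aa_background_freq),
               collapse = "")
      }, character(1))
      ids <- sprintf("P%04d", seq_len(n))
    } else {
      stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
      take <- if (nrow(proteins) >= n) sample.int(nrow(proteins), n)
              else rep_len(seq_len(nrow(proteins)), n)
      seqs <- proteins$sequence[take]
      ids <- make.unique(proteins$protein_id[take])
      for (s in seqs) check_sequence(s)
    }

    span <- config$dynamic_range_orders
    u <- stats::runif(n)
    log10_ab <- switch(config$abundance_law,
      "log-uniform" = {
        if (n >= 2) u <- (u - min(u)) / (max(u) - min(u))
        u * span
      },
      "log-normal" = stats::rnorm(n, mean = span / 2, sd = span / 4)
    )
    abundance <- config$base_abundance * 10^log10_ab

    ratio <- numeric(n)
    n_diff <- round(config$differential_fraction * n)
    if (n_diff > 0) {
      idx <- sample.int(n, n_diff)
      ratio[idx] <- sample(c(-1, 1), n_diff, replace = TRUE) *
        config$effect_size_log2
    }
    prot <- tibble::tibble(protein_id = ids, sequence = seqs,
                           abundance = abundance,
                           channel_log2_ratio = ratio)

    digs <- lapply(seq_len(n), function(i) {
      d <- digest_protein(seqs[i], config$max_missed, config$min_length,
                          config$no_cleave_before_proline)
      if (nrow(d) > 0) d$protein_id <- ids[i]
      d
    })
    pep <- dplyr::bind_rows(digs)
    if (nrow(pep) == 0) {
      return(structure(list(proteins = prot, peptides = empty_peptides(),
                            config = config), class = "pie_mixture"))
    }
    m <- nrow(pep)
    pep <- pep |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::mutate(peptide_id = sprintf("%s_p%03d", .data$protein_id,
                                         dplyr::row_number())) |>
      dplyr::ungroup()

    charge <- as.integer(sample(names(config$charge_weights), m,
                                replace = TRUE,
                                prob = config$charge_weights))
    mass <- vapply(pep$sequence, compute_peptide_mass, numeric(1),
                   USE.NAMES = FALSE)
    rt_apex <- stats::runif(m, 0.05 * config$gradient_length,
                            config$gradient_length)
    rt_sigma <- stats::runif(m, config$rt_sigma_range[1],
                             config$rt_sigma_range[2])
    ionize <- stats::rlnorm(m, meanlog = 0, sdlog = config$ionization_sdlog)

    pep <- pep |>
      dplyr::left_join(prot[, c("protein_id", "abundance",
                                "channel_log2_ratio")], by = "protein_id") |>
      dplyr::rename(protein_abundance = "abundance") |>
      dplyr::mutate(
        charge = charge,
        monoisotopic_mass = mass,
        mz = peptide_mz(mass, charge),
        rt_apex = rt_apex,
        rt_sigma = rt_sigma,
        peak_amplitude = .data$protein_abundance * ionize,
        channel_frac_126 = 2^.data$channel_log2_ratio /
          (1 + 2^.data$channel_log2_ratio),
        channel_frac_127 = 1 - .data$channel_frac_126
      )
    pep <- assign_fractions(pep, config$n_hilic, config$n_scx)
    pep <- pep[, names(empty_peptides())]

    structure(list(proteins = prot, peptides = pep, config = config),
              class = "pie_mixture")
  })
}

#' @export
print.pie_mixture <- function(x, ...) {
  cat(sprintf("<pie_mixture> %d proteins, %d peptides (seed %d)\n",
              nrow(x$proteins), nrow(x$peptides), x$config$seed))
  invisible(x)
}

#' Assign HILIC and SCX fraction labels to peptides
#'
#' Each peptide receives one HILIC bin (quantile bin of mean Kyte-Doolittle
#' hydrophilicity, i.e. negated hydropathy) and one SCX bin (quantile bin of
#' the basic-residue count K+R+H plus one). Both descriptors are pure
#' functions of the sequence, so identical sequences always co-fractionate
#' and the two partitions are approximately orthogonal.
#'
#' @param peptides Tibble with a `sequence` column.
#' @param n_hilic,n_scx Number of fractions per mode (default 6 each).
#' @return `peptides` with integer columns `hilic_fraction`, `scx_fraction`.
#' @export
assign_fractions <- function(peptides, n_hilic = 6, n_scx = 6) {
  stopifnot(n_hilic >= 1, n_scx >= 1, "sequence" %in% names(peptides))
  if (nrow(peptides) == 0) {
    peptides$hilic_fraction <- integer(0)
    peptides$scx_fraction <- integer(0)
    return(peptides)
  }
  chars <- strsplit(peptides$sequence, "", fixed = TRUE)
  hydrophilicity <- -vapply(chars, function(ch) mean(kd_hydropathy[ch]),
                            numeric(1))
  basicity <- vapply(chars, function(ch) {
    sum(ch == "K" | ch == "R" | ch == "H") + 1L
  }, numeric(1))
  peptides$hilic_fraction <- quantile_bin(hydrophilicity, n_hilic)
  peptides$scx_fraction <- quantile_bin(basicity, n_scx)
  peptides
}

#' Serialize / restore a mixture as a TSV table
#'
#' One row per peptide with parent-protein abundance and channel ratio
#' columns, preceded by `#`-prefixed header comments documenting the columns,
#' so simulator runs are replayable from the file alone. Protein sequences
#' are not round-tripped; `read_mixture_tsv()` reconstructs the protein table
#' from the distinct protein-level columns.
#'
#' @param mixture A `pie_mixture`.
#' @param path Output (input) file path.
#' @return `write_mixture_tsv()` returns `path` invisibly;
#'   `read_mixture_tsv()` returns a `pie_mixture` (with empty protein
#'   sequences and a `NULL` config).
#' @export
write_mixture_tsv <- function(mixture, path) {
  stopifnot(inherits(mixture, "pie_mixture"))
  header <- c(
    "# pieacq synthetic mixture: one row per peptide species",
    "# peptide_id/protein_id: identifiers; sequence: peptide residues",
    "# n_missed_cleavages: internal K/R sites; charge: precursor charge",
    "# monoisotopic_mass (Da, TMT-labeled); mz (Th)",
    "# rt_apex/rt_sigma (min): Gaussian elution profile",
    "# peak_amplitude: apex intensity; protein_abundance: parent abundance",
    "# channel_log2_ratio: true log2(126/127) of parent protein",
    "# channel_frac_126/127: per-channel signal fractions (sum to 1)",
    "# hilic_fraction/scx_fraction: offline fraction labels"
  )
  readr::write_lines(header, path)
  readr::write_tsv(mixture$peptides, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_mixture_tsv
#' @export
read_mixture_tsv <- function(path) {
  pep <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  pep <- dplyr::mutate(
    pep,
    dplyr::across(dplyr::any_of(c("n_missed_cleavages", "charge",
                                  "hilic_fraction", "scx_fraction")),
                  as.integer)
  )
  prot <- pep |>
    dplyr::distinct(.data$protein_id, .data$protein_abundance,
                    .data$channel_log2_ratio) |>
    dplyr::transmute(protein_id = .data$protein_id, sequence = NA_character_,
                     abundance = .data$protein_abundance,
                     channel_log2_ratio = .data$channel_log2_ratio)
  structure(list(proteins = prot, peptides = pep, config = NULL),
            class = "pie_mixture")
}
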