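# In-silico proteolysis and peptide mass arithmetic.

#' Monoisotopic residue masses and related constants
#'
#' Named vector of monoisotopic masses (Da) for the 20 standard amino acid
#' residues, plus the constants used for peptide mass arithmetic: the mass of
#' water added on hydrolysis, the proton mass used for m/z, and the TMT
#' 6-plex label mass (one label per peptide N-terminus and one per lysine).
#'
#' @format `aa_mono_mass` is a named numeric vector of length 20.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
aa_mono_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname mass-constants
#' @export
water_mono_mass <- 18.0105646863

#' @rdname mass-constants
#' @export
proton_mass <- 1.007276466879

#' @rdname mass-constants
#' @export
tmt6_label_mass <- 229.162932

# Approximate background amino-acid frequencies (vertebrate proteomes),
# normalised; K+R together ~11% so tryptic peptides average ~9 residues.
aa_background_freq <- local({
  f <- c(A = 0.082, R = 0.055, N = 0.040, D = 0.054, C = 0.014, E = 0.068,
         Q = 0.039, G = 0.070, H = 0.023, I = 0.059, L = 0.097, K = 0.058,
         M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.053, W = 0.011,
         Y = 0.029, V = 0.069)
  f / sum(f)
})

check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(sequence)) {
    rlang::abort(sprintf("`%s` must be a non-empty amino-acid string", arg))
  }
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", sequence)
  if (bad > 0) {
    rlang::abort(sprintf(
      "non-standard residue '%s' at position %d of `%s`",
      substr(sequence, bad, bad), bad, arg
    ))
  }
  invisible(sequence)
}

#' Fully tryptic in-silico digestion
#'
#' Cleaves a protein sequence C-terminal to K or R (the combined Lys-C +
#' trypsin specificity) and enumerates every fully tryptic peptide with up to
#' `max_missed` internal missed cleavage sites and at least `min_length`
#' residues. Each distinct (start, end) span appears once.
#'
#' @param sequence Protein sequence (20 standard one-letter codes).
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_length Minimum peptide length in residues (default 6).
#' @param no_cleave_before_proline If `TRUE`, suppress cleavage at K/R
#'   followed by proline. Off by default.
#' @return A tibble with columns `sequence`, `n_missed_cleavages`, `start`,
#'   `end` (1-based residue coordinates in the parent).
#' @export
#' @examples
#' digest_protein("AAAAAAKCCCCCCR")
digest_protein <- function(sequence, max_missed = 2, min_length = 6,
                           no_cleave_before_proline = FALSE) {
  check_sequence(sequence)
  stopifnot(max_missed >= 0, min_length >= 1)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- which(chars == "K" | chars == "R")
  if (no_cleave_before_proline) {
    blocked <- cut_after < n & chars[pmin(cut_after + 1L, n)] == "P"
    cut_after <- cut_after[!blocked]
  }
  bounds <- unique(c(0L, cut_after[cut_after < n], n))
  nf <- length(bounds) - 1L
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(nf)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nf) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      if (e - s + 1L >= min_length) {
        starts <- c(starts, s); ends <- c(ends, e); missed <- c(missed, m)
      }
    }
  }
  tibble::tibble(
    sequence = substring(sequence, starts, ends),
    n_missed_cleavages = missed,
    start = starts,
    end = ends
  )
}

#' Monoisotopic peptide mass with TMT labels
#'
#' Sum of residue monoisotopic masses plus water, plus `n_tmt_labels` times
#' the TMT 6-plex label mass. When `n_tmt_labels` is `NULL` the label count
#' is derived from the sequence as 1 (N-terminus) + number of lysines.
#'
#' @param sequence Peptide sequence.
#' @param n_tmt_labels Number of TMT labels, or `NULL` to derive from the
#'   sequence.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' compute_peptide_mass("PEPTIDE", n_tmt_labels = 0)
compute_peptide_mass <- function(sequence, n_tmt_labels = NULL) {
  check_sequence(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (is.null(n_tmt_labels)) {
    n_tmt_labels <- 1L + sum(chars == "K")
  }
  stopifnot(n_tmt_labels >= 0)
  sum(aa_mono_mass[chars]) + water_mono_mass + n_tmt_labels * tmt6_label_mass
}

#' Mass-to-charge ratio of a peptide ion
#'
#' @param mass Neutral monoisotopic mass in Da (vectorised).
#' @param charge Positive integer charge state (vectorised).
#' @return m/z in Thomson.
#' @export
#' @examples
#' peptide_mz(1000, 2)
peptide_mz <- function(mass, charge) {
  stopifnot(all(charge >= 1))
  (mass + charge * proton_mass) / charge
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around Biostrings for supplying real protein sequences to
#' [generate_mixture()]. The description line up to the first whitespace is
#' used as the protein identifier.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  rlang::check_installed("Biostrings")
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  tibble::tibble(protein_id = ids, sequence = as.character(aa))
}
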