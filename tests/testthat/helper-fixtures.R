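# Small programmatic fixtures for fast unit tests.

tiny_mixture <- function(seed = 1, n_proteins = 15, gradient_length = 10,
                         ...) {
  generate_mixture(mixture_config(n_proteins = n_proteins,
                                  gradient_length = gradient_length,
                                  seed = seed, ...))
}

fast_config <- function(run_length = 12, rt_jitter_sd = 0.1, ...) {
  acquisition_config(run_length = run_length, rt_jitter_sd = rt_jitter_sd,
                     ...)
}

# Deterministic acquisition: identification always succeeds, no decoys, no
# retention-time jitter.
deterministic_config <- function(...) {
  acquisition_config(rt_jitter_sd = 0, id_midpoint = -Inf,
                     decoy_fraction = 0, ...)
}

# Minimal hand-built peptide table for targeted simulator tests.
make_peptides <- function(mz, rt_apex, peak_amplitude, rt_sigma = 0.3) {
  k <- length(mz)
  tibble::tibble(
    peptide_id = sprintf("pep%02d", seq_len(k)),
    protein_id = sprintf("prot%02d", seq_len(k)),
    mz = mz, rt_apex = rt_apex, rt_sigma = rep_len(rt_sigma, k),
    peak_amplitude = peak_amplitude
  )
}
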