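---
title: "Precursor ion exclusion acquisition: model, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precursor ion exclusion acquisition: model, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pieacq)
```

## The problem

Data-dependent acquisition (DDA) in shotgun proteomics selects the most
intense precursor ions from each survey scan for fragmentation. On complex
mixtures this biases identification toward high-abundance peptides: the same
intense precursors are fragmented run after run while low-abundance species
are never sampled. Precursor ion exclusion (PIE) attacks the redundancy
directly: the precursors identified in earlier runs of the same sample are
written to an instrument exclusion list — m/z values with retention-time
windows — so subsequent runs must sample new ions.

`pieacq` provides the two halves of that workflow as reusable, testable
code:

1. **An exclusion-list engine** — parse tabular exclusion exports, cluster
   entries that describe the same precursor (ppm tolerance in m/z,
   overlapping retention-time windows), merge lists across iterations, cap
   to instrument capacity, and export the instrument-import CSV. This is the
   list-conversion step that otherwise costs hours of manual spreadsheet
   work per iteration.
2. **An in-silico acquisition simulator** — synthetic two-channel TMT
   tryptic mixtures with known ground truth, a survey-cycle state machine
   with top-N selection and dynamic exclusion, a stochastic identification
   model with target-decoy FDR filtering, reporter-ratio quantification,
   and the comparison statistics (Venn counts, percent increase, log2-ratio
   regression) between a PIE campaign and replicate DDA.

No fragment spectra are synthesized and no search engine is run: the
simulator is ground-truth-aware by design, and identification success is a
statistical model. That is what makes campaign-level properties testable in
seconds.

## The synthetic mixture

`generate_mixture()` emulates a two-channel TMT-labeled tryptic digest:

* **Proteins.** Random sequences (80–350 residues, background amino-acid
  frequencies with K+R ≈ 11%) or user-supplied FASTA sequences. The default
  90 proteins digest into roughly 5,000 tryptic peptides, a scale at which a
  2-hour run undersamples the mixture the way real instruments do.
* **Abundances.** Log-uniform across `dynamic_range_orders` (default 4
  orders of magnitude, base 1e4). The sampled log-abundances are rescaled so
  the configured span is realized exactly — the simplest law that guarantees
  the dynamic range is present in every mixture. A log-normal law is
  available behind `abundance_law = "log-normal"`. Real tear fluid spans far
  more than 4 orders; the default is chosen so that a meaningful fraction of
  the mixture sits below the detection threshold without making every run
  trivially empty.
* **Digestion.** Fully tryptic (cleavage C-terminal to K/R, the combined
  Lys-C + trypsin specificity), up to 2 missed cleavages, minimum 6
  residues. The no-cleavage-before-proline rule is a config switch, off by
  default, since fully tryptic enumeration is the documented behaviour.
* **Masses.** Residue monoisotopic masses + water + TMT 6-plex labels
  (229.162932 Da; one per N-terminus, one per lysine). m/z follows
  `(M + z·m_p)/z` with charge states drawn from a 1:11:6:2 distribution
  over z = 1–4.
* **Elution.** Gaussian profiles: apex uniform over the usable 95-minute
  gradient, peak sigma uniform in 0.15–0.5 min. Retention time is sampled,
  not predicted — chromatographic realism is out of scope; what matters for
  the acquisition comparison is co-elution pressure and run-to-run jitter.
* **Channels.** A configurable 20% of proteins carry a true ±1 log2
  between-channel difference; the rest are exactly 1:1. This provides exact
  ground truth for ratio-recovery tests.
* **Fractions.** Each peptide gets one HILIC bin (quantile bin of mean
  Kyte–Doolittle hydrophilicity) and one SCX bin (quantile bin of the
  basic-residue count K+R+H+1), six of each by default. Both descriptors
  are pure functions of the sequence, so the two partitions are
  approximately orthogonal and identical sequences always co-fractionate.
  The SCX descriptor is discrete, so fewer than six occupied SCX bins is
  expected and correct.

What the generator does **not** emulate: isotope envelopes, fragment
spectra, chimeric MS2, chromatographic tailing, missing-value structure of
real reporter ions, or the true tear-proteome composition. Passing tests
therefore demonstrate the correctness of the acquisition logic and
statistics under a controlled model, not instrument-level fidelity.

## The acquisition state machine

`simulate_run()` advances survey cycles of
`survey_time + 2 · top_n · ms2_event_time` seconds — 3.4 s at the default
top 3×2 configuration, where each selected precursor is fragmented twice
(HCD for reporter ions, CID for sequencing), which is precisely why duty
cycle is scarce and undersampling is severe in quantitative mode. Per
cycle:

1. Candidates = peptides with elution intensity ≥ `detection_threshold`
   (default 5e4) and m/z within the survey range 350–2000 Th.
2. Minus dynamically excluded species: a peptide selected
   `dyn_excl_repeat` (= 2) times within `dyn_excl_duration` (= 60 s) is
   banned for 60 s. The phrasing "selected more than once within 60 s"
   is ambiguous about whether the ban starts at the second selection or
   lasts 60 s from the first; both numbers are config-exposed and the
   implementation uses second-selection-triggers-60-s-ban.
3. Minus species covered by the in-force exclusion list (10 ppm window
   against the entry m/z, inside the entry's closed RT window).
4. The `top_n` most intense survivors are selected; ties break toward
   lower m/z so replays are deterministic.

Per-run retention-time jitter (Gaussian, sd 0.3 min) models run-to-run
variation; with jitter at 0 and identification forced deterministic, a
second PIE iteration provably identifies a disjoint peptide set, which the
test suite asserts.

Identification success for each MS2 event follows a logistic in log10
precursor intensity (midpoint 5.5, steepness 1.2): intense precursors
identify reliably, near-threshold ones rarely — the empirical behaviour
that makes DDA replicates redundant. Correct matches score N(3.5, 1);
incorrect matches and injected decoys (0.15 per target) score N(0, 1). The
FDR walk then accepts score-ranked PSMs for as long as every prefix keeps
decoys/targets ≤ 1%, stopping at the first violation — no fixed score
cutoff. Ties put decoys first (conservative), and decoys are never marked
accepted.

## The exclusion-list engine

Two entries merge when their m/z values agree within the ppm tolerance
(computed against the lower m/z of the pair — conservative and effectively
symmetric at 10 ppm) **and** their RT intervals overlap or lie within
`rt_gap` (default 0). Clustering is the transitive closure of pairwise
merges, iterated to a fixpoint so the output is canonical: sorted by
(m/z, rt_start) with no mergeable pair remaining.

Numerical choices worth knowing:

* **Merged m/z** is the arithmetic mean of the *original* cluster members.
  Entries carry an `n_members` weight so that property survives repeated
  `merge_lists()` calls; this is what makes cross-iteration merging
  associative up to canonical form. An intensity-weighted mean was
  considered and rejected: order-independence under transitive closure is
  the property the tests pin down, and plain means keep it trivially.
* **Matching is on m/z, not neutral mass**, and ignores charge: the 10 ppm
  dynamic-exclusion window on the instrument is an m/z criterion, and
  exclusion tables are m/z tables. Clustering on neutral mass would split
  charge states of the same peptide across incomparable scales.
* **Closure vs pairwise fixpoints.** With borderline ppm chains (A–B and
  B–C mergeable but A–C not), transitive closure and repeated pairwise
  merging can legitimately reach different fixpoints. The oracle tests
  generate lists whose cluster members sit well inside the tolerance and
  whose clusters are separated by > 5× the tolerance, where the two
  provably coincide; the RT substructure (overlaps, gaps, chains) does the
  discriminating work there.
* **Capping** keeps the highest-intensity entries (default capacity 2000,
  typical of instrument reject tables); entries without intensity rank
  below any entry that has one; ties break by earlier RT then lower m/z.
* **Export** rounds m/z to 4 decimals and RT to 2 — the instrument-import
  precision — and re-parsing reproduces the list exactly at those
  precisions.
* On a tolerance mismatch between merged lists the **stricter ppm wins**,
  so merging can never silently loosen an exclusion criterion.
* The exact column layout of vendor exclusion exports varies, so parsing
  goes through a configurable column dialect
  (defaults: `m/z`, `RT [min]`, `Charge`, `Intensity`); a single RT value
  becomes the window ± `rt_pad` (default 2 min — the original tool's window
  width is not documented anywhere, so it is config-exposed).

## Campaigns and the comparison

`run_pie_campaign()` runs iteration 1 as plain DDA, then before each
subsequent iteration merges the newest run's accepted identifications into
the cumulative exclusion list and caps it. `run_dda_replicates()` runs the
same per-run seed schedule with empty lists, so a 1-iteration campaign and
a 1-replicate campaign are identical by construction. Fraction mode
(`split_by_fraction()`) simulates each HILIC or SCX fraction as a separate
run with its own exclusion list; whether the original workflow kept one
cumulative list across fractions is not documented, and per-fraction lists
are the safer reading (a fraction never sees another fraction's ions
anyway).

`compare_strategies()` aggregates both campaigns: identification counts,
the Venn partition of quantified proteins, percent increases
(`100 · (n_new − n_ref)/n_ref`, reported raw and rounded), the OLS
regression of PIE log2 ratios on DDA log2 ratios over common proteins
(slope and R² = squared Pearson correlation), and the fraction of common
proteins with *strictly* more peptides under PIE. Strictly-greater is a
deliberate choice — the natural reading of "increased coverage" — and ties
therefore count against the fraction.

Reporter quantification applies Gaussian noise (sd 0.2 by default) to the
true log2 ratio in log2 space — a multiplicative noise model with symmetric
errors — per accepted PSM; PSMs collapse to peptides and peptides to
proteins by medians. The median rollup is robust and makes
ratio recovery analysable: with ≥ 50 peptides per protein the median's
sampling sd is ≈ 0.2 · 1.253/√50 ≈ 0.035, so ±0.1 recovery for ≥ 95% of
proteins has large margin, which the acceptance suite verifies.

## Problem sizes and determinism

The test suite and the acceptance script work at the default study scale —
90 proteins / ~5,000 peptides, 120-minute runs, 3 iterations vs 3
replicates, 20 paired seeds for campaign-level properties — chosen so the
full property suite completes in a few minutes while leaving the mixture
heavily undersampled per run (≈ 6,300 selection slots for ≈ 4,000
detectable peptides whose intense members are re-selected repeatedly).
Every random draw descends from explicit integer seeds;
`derive_seed(seed, stage)` gives each stage (mixture, each run,
identification, quantification) an independent reproducible stream, and
`run_experiment()` writes a manifest (config, hash, derived seeds) from
which any experiment reproduces byte for byte.

## Known limitations

* Identification is a statistical surrogate; search-engine idiosyncrasies
  (modification localisation, chimeric spectra, protein inference) are out
  of scope, and protein-level counts here equate "protein identified" with
  "any accepted peptide".
* The simulator cannot anchor per-iteration gains to real instrument
  numbers; only qualitative campaign properties (PIE > DDA in unique
  identifications, iteration 2 digging into lower abundances) are asserted,
  and their magnitudes are configuration-dependent.
* Exclusion matching ignores charge; two peptides within 10 ppm in m/z
  shadow each other, which also happens on the real instrument.
* Vendor binary method files are not read or written; delimited text only.
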