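# pieacq

Precursor-ion-exclusion (PIE) acquisition tools for shotgun proteomics: an
exclusion-list engine plus an in-silico LC-MS/MS acquisition simulator.

## The problem

Data-dependent acquisition (DDA) selects the most intense precursors from
each survey scan for MS2. On complex mixtures — especially in quantitative
TMT mode, where every precursor is fragmented twice (HCD for reporter ions,
CID for sequencing) and duty cycle is scarce — replicate runs redundantly
re-sequence the same high-abundance peptides while low-abundance species are
never sampled. PIE breaks the redundancy: precursors identified in earlier
runs are placed on an instrument exclusion list (m/z ± 10 ppm with a
retention-time window), forcing later runs of the same sample to fragment
new, less-abundant ions.

`pieacq` is for proteomics methods developers and instrument operators who
want to build, merge and export such exclusion lists, and to study the
DDA-vs-PIE trade-off quantitatively on synthetic mixtures with known ground
truth.

Core operations:

* **Exclusion-list engine** — `parse_exclusion_export()`,
  `cluster_merge()` (transitive closure of merges when |Δm/z| ≤ ppm·m/z·10⁻⁶
  and RT windows overlap; merged m/z is the arithmetic mean of the original
  members, RT the union interval), `merge_lists()` across iterations,
  `cap_list()` to instrument capacity, `export_instrument_table()` /
  `parse_instrument_table()` for the `Mass,Start (min),End (min)` CSV.
* **Mixture generator** — `generate_mixture()`: fully tryptic digestion
  (≤ 2 missed cleavages, ≥ 6 residues), TMT 6-plex masses, log-uniform
  protein abundances over 4 orders of magnitude, Gaussian elution, true
  two-channel log2 ratios, 6 HILIC + 6 SCX fraction labels.
* **Acquisition simulator** — `simulate_run()`: top 3×2 survey cycles,
  dynamic exclusion (2 selections within 60 s → 60 s ban, 10 ppm),
  PIE-list compliance; `identify_and_filter()`: logistic
  identification-success model in log10 intensity with target-decoy FDR
  filtering (`fdr_filter()`, accept until decoys/targets exceeds 1%).
* **Campaigns and statistics** — `run_pie_campaign()`,
  `run_dda_replicates()`, `compare_strategies()` with `tidy()`, `glance()`
  and `autoplot()`: Venn counts, percent increase
  `100·(n_new − n_ref)/n_ref`, OLS log2-ratio regression (slope, R²),
  increased-coverage fraction.
* **Orchestration** — `validate_config()` / `run_experiment()` for
  YAML-configured, fully seeded experiments, and a thin CLI at
  `inst/exec/pieacq` (`elc convert|merge`, `sim dda|pie`, `run`,
  `validate`).

## Worked example

```r
library(pieacq)

mx  <- generate_mixture(mixture_config(seed = 42))
cfg <- acquisition_config()
pie <- run_pie_campaign(mx, cfg, n_iterations = 3, seed = 7)
dda <- run_dda_replicates(mx, cfg, n_reps = 3, seed = 7)
pie
#> <pie_campaign> mode=pie, 3 runs, 3418 unique accepted peptides
#> <pie_run> iter1: 2117 cycles, 4877 selections (9754 MS2 events), 1667 accepted peptides
#> <pie_run> iter2: 2117 cycles, 4725 selections (9450 MS2 events), 1366 accepted peptides
#> <pie_run> iter3: 2117 cycles, 4476 selections (8952 MS2 events), 1203 accepted peptides

compare_strategies(pie, dda, mx, seed = 7)
#> <pie_comparison> PIE vs DDA
#> # A tibble: 2 × 3
#>   strategy n_proteins n_peptides
#>   <chr>         <int>      <int>
#> 1 PIE              89       3418
#> 2 DDA              61       1843
#> protein increase: 45.9% (46% rounded); venn 28/61/0
#> ratio regression: slope 1.012, R^2 0.985 (n = 61 common)
#> increased coverage fraction: 0.852
```

Reading the output: the three DDA replicates saturate at 1,843 unique
accepted peptides because each replicate re-selects largely the same
intense precursors, while the PIE campaign keeps digging (1667 → 1366 →
1203 *new-list-constrained* identifications per iteration) and reaches
3,418 unique peptides and 89 of the 90 proteins. The 28 proteins quantified
only by PIE are low-abundance species DDA never sampled. The log2-ratio
regression over the 61 common proteins shows the two strategies agree on
quantification (slope ≈ 1, high R²): deeper sampling did not distort the
ratios of peptides that both methods measured. `autoplot()` draws the
corresponding scatter plot.

The methods vignette (`vignettes/pie-acquisition.Rmd`) documents the
models, parameters, numerical choices and limitations.

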