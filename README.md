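# presynmorph

Quantitative EM morphometry of presynaptic terminals, for neuroscientists
analysing traced transmission-EM annotations of synapses — in particular
cerebellar parallel-fibre boutons, where glutamate is released both at the
active zone and ectopically onto ensheathing Bergmann-glial processes.

The package consumes coordinate traces (terminal perimeter, postsynaptic
density, glial membranes, vesicle centre points, with a nm-per-pixel
calibration) and computes:

* **membrane compartments** — the perimeter resampled at a fixed arc-length
  step and classified into active-zone / glial-facing / other membrane by
  proximity to the PSD and glial traces (thresholds τ_AZ = τ_glial = 30 nm
  by default), with contiguous runs collected into regions;
* **vesicle distance distributions** — for every vesicle centre *v*, the
  exact Euclidean distance min‖v − m‖ to the perimeter and to each
  compartment; pooled per condition into histograms and a Gaussian-kernel
  density estimate with Silverman's bandwidth
  h = 0.9·min(σ̂, IQR/1.34)·n^(−1/5), whose local maxima (with ≥5%
  prominence) are the vesicle pools — classically, a readily-releasable
  pool within ~50 nm of the active zone and a reserve pool near ~100 nm —
  each with its trapezoidal probability mass over one bin width;
* **near-membrane contingency analysis** — counts of vesicles strictly
  within 50 nm (one vesicle diameter) of each compartment, compared between
  conditions with a two-sided Fisher's exact test (sum-of-small-p
  convention, log-factorial arithmetic exact at 10^4-scale counts);
* **glial apposition morphometry** — fractional coverage of the perimeter
  by glial-facing membrane, and the terminal-to-glia gap at each
  apposition's arc-length midpoint;
* **group comparisons** — Kruskal–Wallis (tie-corrected) with Dunn's
  pairwise z and Bonferroni adjustment for per-terminal metrics;
* **a synthetic-annotation generator** — Fourier-perturbed terminal
  outlines with PSD and flanking glial traces and vesicles placed from a
  configurable mixture of active-zone-distance pools, with full ground
  truth, so the entire chain is testable without raw micrographs.

## Worked example

```r
library(presynmorph)

cfgs <- list(
  low_freq  = synthetic_config(n_terminals = 12, condition = "low_freq"),
  high_freq = synthetic_config(n_terminals = 12, condition = "high_freq",
                               gap_mean_nm = 6.26))
ds   <- generate_dataset(cfgs, seed = 42)
anns <- c(ds$annotations$low_freq, ds$annotations$high_freq)
anns[[1]]
#> <terminal_annotation 'low_freq_001' (low_freq): perimeter 2844 nm, 1 PSD, 3 glial, 56 vesicles>

rep <- condition_report(anns)
rep$pools[["low_freq.active_zone"]]
#> <pool_distribution: n = 684, bandwidth 13.39 nm, 2 peak(s)>
#>   peak at   35.0 nm  density 0.00744 /nm  probability 7.4%
#>   peak at  102.0 nm  density 0.00754 /nm  probability 7.5%

subset(rep$contingency, compartment == "active_zone")
#>   compartment condition_a condition_b within_a total_a within_b total_b
#> 1 active_zone    low_freq   high_freq      214     684      215     698
#>   fraction_a fraction_b odds_ratio p_two_sided
#> 1  0.3128655  0.3080229    1.02288   0.8616385
```

The two active-zone pool peaks (here 35 nm and 102 nm, within half a
bandwidth of the generator's default 32 nm and 97 nm pools at this sample
size)
are the readily-releasable and reserve pools; `within_a/total_a` are the
vesicles closer than 50 nm to the active zone out of all vesicles pooled
over that condition's terminals, and the Fisher p (0.86) correctly finds no
difference — the two configs differ only in their glial gap. Real tracings
enter the same way through `read_annotation_bundle()` (JSON bundles or
ImageJ "Save XY Coordinates" text files), and `write_condition_report()`
emits the full TSV table set.

The `analysis/` scripts are the same pipeline as a narrative workflow:
`01_simulate.R` → `02_morphometry.R` → `03_vesicle_pools.R` →
`04_group_comparisons.R` on a simulated three-condition study, and
`05_published_counts.R` re-analyses published near-membrane contingency
counts. They write their tables under `results/`.

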