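# condensatr

Transcription factors such as YAP concentrate at chromatin in part through
biomolecular condensates, and the specificity of those condensates is
written into the charge patterning of intrinsically disordered regions
(IDRs): blocks of negative charge on one partner pair with blocks of
positive charge on another, whereas the same residues dispersed along the
sequence interact far more weakly. condensatr is an R toolkit for testing
that idea quantitatively, end to end:

* **Sequence grammar** — sliding-window charge profiles; a kappa-style
  patterning statistic
  `delta = mean over windows g of mean_i (sigma_i - sigma_bar)^2` with
  `sigma_i = (fX_i - fY_i)^2 / (fX_i + fY_i)`, z-scored against shuffle
  nulls (compositionally identical random sequences) and against an IDRome
  background (`grammar_report()`).
* **Sequence design** — a deterministic algorithm that disperses charge
  blocks ("well-mixed charge" variant) while conserving composition,
  per-IDR net charge, fixed positions, and structured domains exactly
  (`design_well_mixed()`, `validate_variant()`).
* **Interaction maps** — mean-field window-by-window interaction strength
  `epsilon(i, j) = mean of w(a, b) over residue pairs` between two IDRs,
  with a pluggable 20×20 residue-pair potential; negative = attractive
  (`intermap()`, `summarize_interaction()`).
* **Single-molecule dwell times** — tracker-table ingestion, strict 1-CDF
  survival curves, constrained bi-exponential fits
  `S(t) = A exp(-t/tau_ns) + (1-A) exp(-t/tau_s)` separating non-specific
  from specific chromatin binding, population-bin fold changes with
  t-tests, and percentile-based expression gating (`fit_biexponential()`,
  `dwell_bin_fractions()`, `expression_gate()`).
* **Cluster quantification** — 2D Gaussian fits with offset, molecule
  counting against a single-molecule unitary intensity, cluster-size 1-CDF,
  and dense/dilute phase decomposition (`fit_gaussian2d()`,
  `phase_decomposition()`).
* **Recruitment kinetics** — track filtering with a rejection ledger,
  mono-exponential control correction for photobleaching and non-specific
  recruitment, recruitment gating, pooling, and treatment-difference curves
  (`filter_tracks()`, `fit_control_correction()`, `drb_difference()`).
* **Synthetic data** — seeded generators with machine-readable ground truth
  for every input the pipeline consumes (`sim_dwells()`,
  `sim_track_table()`, `sim_idr()`, `sim_idrome()`, `sim_cluster_scene()`,
  `sim_recruitment()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on the main result types.

## Worked example

Simulate 10,000 dwell times from the two-population binding mixture
(70% non-specific at 1.2 s, 30% specific at 7 s, 150 ms frames, 80 s
movie), fit the survival curve, and bin the populations:

```r
library(condensatr)

d   <- sim_dwells(1e4, A = 0.7, tau_fast = 1.2, tau_slow = 7, seed = 1)
fit <- fit_biexponential(d)
fit
#> Bi-exponential survival fit: A = 0.655, tau_ns = 1.036 s, tau_s = 6.530 s
#>   RSS 0.3557 on 222 curve points

dwell_bin_fractions(d)
#> # A tibble: 4 × 2
#>   bin   fraction
#>   <chr>    <dbl>
#> 1 <1.2    0.455
#> 2 >=1.2   0.545
#> 3 >=7     0.112
#> 4 >=10    0.0724
```

The fitted time constants land within ~15% of the generating values (the
frame round-up and 80 s censoring bias them slightly short); the `>=7 s`
fraction matches the mixture's closed-form tail probability. On the
sequence side, the well-mixed-charge design on a blocky toy:

```r
res <- design_well_mixed("GEEGGKKG", idr_regions = list(c(1, 8)))
res$variant_sequence
#> [1] "GEKGGEKG"
patterning_delta("GEEGGKKG", "neg", "pos", windows = 5) # blocky  0.0822
patterning_delta("GEKGGEKG", "neg", "pos", windows = 5) # mixed   0.0022
```

Charge alternation drops the patterning delta ~40-fold while net charge
(0) and composition are untouched — the de-blocked variant is what loses
its predicted interaction with an oppositely charged partner in
`summarize_interaction()`.

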