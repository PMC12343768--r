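---
title: "Charge grammar, dwell times, and condensate recruitment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge grammar, dwell times, and condensate recruitment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensatr)
library(dplyr)
```

condensatr links the charge patterning of intrinsically disordered regions
(IDRs) to the behaviour of transcriptional condensates, and quantifies that
behaviour from single-molecule tracking, cluster imaging, and condensate
recruitment time series. This vignette explains the models and procedures,
the parameters that matter, and the choices made where the design was
genuinely open. Every empirical statement here is one the package's test
suite or `scripts/acceptance.R` computes.

## Sequence grammar

### Charge profiles

`charge_profile()` slides a window of length $L$ over the sequence and
assigns each window its net charge per residue, $f_{pos} - f_{neg}$ with
$pos = \{K, R\}$ and $neg = \{D, E\}$. A residue's profile value is the mean
over all full windows containing it, so terminal residues average fewer
windows. $L = 5$ resolves individual charge blocks; $L = 31$ matches the
interaction-map window and gives the smoothed view. With $L$ equal to the
sequence length the profile collapses to the NCPR, which the tests use as a
closed-form limit.

### Patterning statistic

The blockiness of two disjoint residue groups X and Y is measured by a
kappa-style statistic. For window size $g$, each full window $i$ gets a
local asymmetry

$$\sigma_i = \frac{(f_{X,i} - f_{Y,i})^2}{f_{X,i} + f_{Y,i}},$$

zero when the window contains neither group; the same quantity computed from
whole-sequence fractions gives $\bar\sigma$; and
$\delta_g = \mathrm{mean}_i\,(\sigma_i - \bar\sigma)^2$. The reported
$\delta$ is the mean of $\delta_g$ over $g \in \{5, 6\}$ — the usual "blob"
sizes for charge-patterning statistics; the underlying feature definitions
in the literature do not pin a window size, so ours is a documented
approximation and `windows` is an argument. Significance comes from a
shuffle null: `patterning_zscore()` compares $\delta$ against its
distribution over uniform random permutations of the sequence (default
10,000, seeded), so $z > 0$ means blockier than composition alone predicts.
Homopolymer-like inputs make every shuffle identical; the null SD is 0 and
the z-score is reported as 0 with a `degenerate` flag rather than NaN.

### Grammar reports

`grammar_report()` combines composition z-scores against an IDRome
background (mean/SD of each feature over a background set of IDRs, e.g. from
`sim_idrome()` or a real proteome scan) with patterning z-scores for each
group against its complement and for every disjoint pair of groups. The
default feature set is 30 composition features (20 amino-acid fractions,
8 group fractions, FCR, NCPR) and up to 36 patterning features; the
conventional display rule marks features with $|z| \ge 1$ for at least one
IDR. Under the default groups, `ala` = {A} is a subset of `hyd` =
{A, I, L, M, V}; a patterning statistic between overlapping groups is
undefined, so that pair is skipped and reported as NA rather than silently
redefining the groups.

## Well-mixed-charge design

`design_well_mixed()` disperses charge blocks while conserving everything
else. Within each IDR region separately, negative (D, E) and positive
(K, R, H) residues — minus any fixed positions, which must hold a negative
residue in the input — are extracted N-to-C into two queues, and the same
charged positions are refilled N-to-C by alternating draws, negative first
by default. When one queue empties, the remainder of the other is placed in
extraction order. Three conventions deserve note:

* **Histidine** counts as positive during extraction/alternation (it
  balances the queue lengths) but contributes 0 to the net-charge
  conservation check (K/R = +1, D/E = −1). Both conventions are standard
  and used side by side.
* **Per-region processing** (rather than one pooled queue across regions)
  makes net charge conserved exactly within each IDR, which is what
  `validate_variant()` asserts; a pooled queue would only conserve the
  total.
* **The alternation phase** (negative-first) and leftover handling are
  explicit arguments because the verbal description of such procedures is
  ambiguous; the default is deterministic, so `seed` plays no role.

On the toy `"GEEGGKKG"` the rule gives `"GEKGGEKG"` by hand and by code.
`validate_variant()` checks composition identity, per-IDR net charge,
fixed-position identity, untouched non-IDR segments, and reports the
neg-vs-pos delta and z of both sequences.

## Interaction maps

`intermap()` computes a mean-field interaction strength between every pair
of length-$L$ windows (default 31, stride 1) of two sequences:
$\varepsilon(i, j)$ is the mean of the pair weight $w(a, b)$ over all
residue pairs of the two windows, so order inside a window does not matter,
and $\varepsilon$ of (A, B) is exactly the transpose of (B, A). Negative
values are attractive. The default `default_pair_matrix()` is a simplified
potential — opposite charges −1, like charges +1, aromatic–aromatic −0.7,
cation–$\pi$ −0.5, else 0 — because force-field-derived weights are not
printed anywhere reusable; any 20×20 symmetric matrix can be supplied via
`read_pair_matrix()`, and results with a real coarse-grained matrix will
differ in scale (our normalization is the per-pair mean). With the
pure-electrostatic matrix, $\varepsilon(i,j)$ factorizes into the product of
the two windows' net charges, which the tests exploit as an exact oracle:
attraction sits exactly where the charge patterns are sign-opposite. The
per-residue attractive vector is the mean of $\min(\varepsilon, 0)$ over all
map cells whose window contains the residue, hence always $\le 0$.

## Single-molecule dwell times

`extract_dwells()` converts tracker tables to dwell times as
$(\mathrm{last} - \mathrm{first} + 1) \times \Delta t$ with
$\Delta t = 0.15$ s: blink gaps up to 2 frames count toward the dwell (the
molecule is presumed bound across a gap-closed blink), tracks with fewer
than 2 detections are dropped as unlinked detections, and ingestion splits
tracks at gaps beyond the limit. The survival function `survival_curve()`
is the strict empirical 1-CDF ($S(t) = $ fraction of dwells $> t$, with
$(0, 1)$ prepended), and `fit_biexponential()` fits

$$S(t) = A e^{-t/\tau_{ns}} + (1 - A) e^{-t/\tau_s}$$

by least squares on $\log_{10} S$. Fitting the log gives the rare long-dwell
tail — the biologically interesting part — sensible weight; raw-S fitting is
available (`on_log = FALSE`). The parameterization (logit $A$, log
$\tau_{ns}$, log ratio) enforces $0 < A < 1$ and $\tau_{ns} < \tau_s$, so
label swaps cannot occur; effectively single-exponential data return with a
`degenerate` flag (ratio < 1.5). No photobleaching correction is applied to
dwell times — a caveat, since bleaching shortens apparent long dwells.

Population comparisons use `dwell_bin_fractions()` (default edges 1.2, 7,
10 s: one partition at 1.2 s plus nested upper tails) and
`fold_change_stats()` (mean-of-condition over mean-of-control per bin;
two-sided equal-variance Student's t-test across experiments, Welch by
flag). Expression gating takes the 1st/99th percentiles of wild-type
nuclear intensity as physiological bounds, maps fixed-stain intensities to
the live scale by `corr_fix = mean(live)/mean(fixed)`, and keeps nuclei
strictly inside the bounds.

```{r dwell-example}
d <- sim_dwells(1e4, A = 0.7, tau_fast = 1.2, tau_slow = 7, seed = 1)
fit <- fit_biexponential(d)
tidy(fit)
```

## Cluster quantification

`fit_gaussian2d()` fits amplitude, sub-pixel centre, per-axis sigma, and a
flat offset on an 11×11 patch. Sigma is bounded to
$[0.5, \sigma_{max} = 3]$ px inside the optimizer — the optical PSF scale —
because at low signal-to-noise an unbounded sigma absorbs background and
destabilizes the fit; fits whose sigma pins at the bound, or whose amplitude
is not positive (flat patch), are rejected with a reason. The cluster
integral is the model-minus-offset sum over the 2$\sigma$ ellipse
(~86.5% of the Gaussian mass; raw-pixel summation available by flag).
Molecule counts divide by a unitary intensity calibrated as the **median**
integral of isolated single molecules measured through the same fit path, so
the partial-mass factor cancels; the median is robust to occasional doublets
in the calibration sample.

Two quantitative caveats the tests encode explicitly:

* At per-pixel noise equal to the unitary intensity, a single fit of a
  15-molecule cluster is information-limited (the amplitude's Cramér–Rao
  bound alone is ~35%), so the ±15% recovery statement holds for the median
  over seeded replicates, not per fit.
* The dense/dilute decomposition excludes the 2$\sigma$ ellipse of every
  fitted cluster from the dilute pool; the ~13.5% of each cluster's mass
  outside that ellipse leaks into the dilute estimate. On synthetic nuclei
  this bias stays within 2% of the background level.

Dense phase = summed integrals of clusters with ≥ 10 molecules per nuclear
pixel; dilute phase = mean intensity of nuclear pixels outside all cluster
ellipses; total = mean over the nucleus. On generator scenes without
dense-phase buffering, dilute rises linearly with total — the saturation
diagnostic.

## Recruitment time series

The pipeline is: filter → correct → gate → pool → compare.

* **Filters** (`filter_rules()`): track starts at frame 0, lasts ≥ 10
  frames (18 min at 2-min sampling), mean area within [0.45, 1.55] a.u.
  (opaque tracker units; the cutoffs are taken as given), and nuclear
  localization. Rejections are counted per rule.
* **Correction**: the partner channel of fluorophore-only control tracks
  carries only non-specific recruitment plus photobleaching; its pooled
  mean is fit with $I(t) = a e^{-t/\tau} + c$ (the offset $c$ makes a flat
  control a well-posed special case) and subtracted pointwise from
  experimental tracks after background subtraction. The pipeline is linear:
  a constant added to all intensities cancels. Because the correction is
  subtractive, bleaching of the *specific* signal itself is attenuated, not
  restored — visible as the sustained scenario's final/max ratio sitting
  slightly below 1.
* **Gating**: tracks whose baseline-subtracted cargo signal at 16 min
  (nearest frame, 1-interval tolerance) misses the threshold (250 a.u. for
  a Halo cargo, 750 for SNAP) are dropped.
* **Pooling**: time grids are intersected, the mean ± SEM computed across
  tracks, and the mean re-zeroed at $t = 0$. `drb_difference()` subtracts
  two pooled curves on their shared grid (SEMs in quadrature).

## The generators

Every input the analysis consumes has a seeded generator with
machine-readable truth, and every analysis module has a round-trip test
against it.

* `sim_dwells()` draws from the two-exponential mixture (defaults
  $A = 0.7$, $\tau = 1.2$ and $7$ s — the canonical non-specific/specific
  residence times; the fast fraction is an assumption, as fitted fast
  fractions are rarely reported), rounds dwells *up* to whole 150 ms frames
  (a molecule present for any part of a frame is detected; bias
  $+\Delta t/2$, documented), and censors at 80 s, the longest dwell a movie
  of this length can contain.
* `sim_track_table()` lays dwells onto frame runs with optional 1–2-frame
  blinks (never exceeding the gap-closing limit, so the span — and hence the
  dwell — is blink-invariant) and single-frame noise detections that the
  `min_frames` filter removes.
* `sim_idr()`/`sim_idrome()` generate sequences at controlled composition;
  a target patterning delta is approached by seeded Monte-Carlo position
  swaps, with a best-effort flag when the target is outside the reachable
  range. The default IDRome sampler draws group fractions around
  disorder-promoting values (polar 0.30, negative 0.12, positive 0.10,
  hydrophobic 0.15, proline 0.08, aromatic 0.04, glycine remainder).
* `sim_cluster_scene()` renders Gaussian spots whose full integrated mass is
  molecules × unitary on a flat background with i.i.d. Gaussian noise, and
  warns when centres sit closer than 3$\sigma$.
* `sim_recruitment()` integrates a phenomenological ODE (cargo → Mediator
  partner with positive feedback; Mediator → polymerase partner under
  transcript-mediated negative feedback) on the 2-min grid, applies a
  per-track lognormal amplitude (SD 0.1), additive noise (SD 5 a.u.), and
  multiplicative bleaching ($\tau = 600$ min: ~18% signal loss over the
  2-h movie, typical of gentle spinning-disk acquisition). The rates are
  not measurements. They were chosen once, by steady-state analysis, so
  that the Mediator-like channel plateaus inside the movie (sustained) and
  the polymerase-like channel peaks near 30 min and falls below half its
  peak (adaptive) — the qualitative phenotypes the pipeline must separate;
  the near-integrator transcript feedback (`k_rna_decay` = 0.001/min)
  is what makes the adaptation deep. A transcription-inhibitor treatment
  (`drb_time`) zeroes transcript production from that time, breaking the
  feedback.

What the generators deliberately omit — and hence what passing tests do
*not* show about real data: camera noise statistics and pixelation beyond
Gaussian i.i.d. noise, chromatin motion and drift, detection/tracking errors
other than blinks, condensate fusion/fission, cell-to-cell rate variability
beyond a scalar amplitude, and any mechanistic realism of the recruitment
rates.

## Problem sizes and determinism

The test suite and acceptance script use sizes chosen to make the
statistical assertions sharp while staying desk-scale: 10^4 dwells × 20
seeds for parameter recovery (2 × 10^5 for tail probabilities), 96×96 px
scenes × 20–40 seeds for cluster recovery, 16 tracks per recruitment arm,
and shuffle nulls of 200–5000 in tests (default 10,000 for analyses). All
randomness flows through explicit integer seeds; every generator is
bit-reproducible given its seed.

## Known limitations

* Patterning windows {5, 6} and the feature list approximate, not
  reproduce, the published grammar-feature catalogues; z-scores are
  comparable within this package, not across tools.
* The default pair matrix is a caricature of real residue-residue
  energetics; use `read_pair_matrix()` for quantitative work.
* Dwell times are not bleach-corrected; long-dwell fractions are lower
  bounds under heavy bleaching.
* The subtractive bleach correction cannot restore bleached specific
  signal; ratios of late to early signal inherit a downward bias of order
  $1 - e^{-T/\tau_{bleach}}$.
* The recruitment ODE is phenomenological; its rates parameterize
  phenotypes, not molecules.
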