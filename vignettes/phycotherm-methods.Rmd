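---
title: "Models and methods behind phycotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phycotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycotherm)
```

phycotherm analyses long-term warming-adaptation experiments on a
phytoplankton host and its associated bacterial community: two selection
lines (ambient vs warming, "LA"/"LW"-style designs) assayed for thermal
performance, microbiome composition and host metabolites. This vignette
explains the models, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical choices.

## Thermal performance model

The growth-rate response to temperature is the Norberg curve, an Eppley
exponential envelope times a quadratic thermal niche:

$$f(T) = a\,e^{bT}\left[1 - \left(\frac{T - z}{w/2}\right)^2\right]$$

with $a$ (day$^{-1}$) and $b$ (°C$^{-1}$) the Eppley coefficient and
exponent, $z$ (°C) the centre of the quadratic term and $w$ (°C) the niche
width. Growth is positive exactly on $(z - w/2,\ z + w/2)$, so the
critical thermal limits are the exact roots
$CT_{min} = z - w/2$, $CT_{max} = z + w/2$ — computed analytically rather
than by root search, which is mathematically identical for this family and
numerically exact. The optimum satisfies
$T_{opt} = z + (\sqrt{1 + b^2 (w/2)^2} - 1)/b$ (limit $z$ as $b \to 0$);
`derive_traits()` maximises the curve numerically and cross-checks against
this closed form (tolerance $10^{-6}$ °C), then reports the analytic
value. $\mu_{max} = f(T_{opt})$, and the thermal breadth $B_{80}$ is the
width of the (contiguous, since the curve is unimodal) region where
$f \ge 0.8\,\mu_{max}$, endpoints by bisection to $10^{-6}$ °C. The
`fraction` parameter (default 0.8) generalises $B_{80}$; breadth is
non-increasing in it.

### Fitting

`fit_norberg()` minimises the residual sum of squares over a multi-start
grid: $z$ at the observed-temperature quartiles, $w$ at 0.8/1.2/1.6 times
the observed span, $b \in \{0, 0.063\}$ (0.063 °C$^{-1}$ is the canonical
Eppley exponent), and $a$ rescaled so each candidate curve touches the
observed maximum — 18 starts, each refined by Nelder–Mead then BFGS on
$(\log a, b, z, \log w)$, which enforces $a, w > 0$ while leaving $b$
free (a fitted $b \le 0$ is legitimate for symmetric or cold-skewed
curves). Lowest SSR wins; ties go to the smallest parameter norm.
Negative observed rates are retained — they carry the information that
locates the thermal limits. Fits are per replicate; group comparisons
(`compare_traits()`) use two-sided pooled-variance Student's t-tests,
matching the equal-variance convention of the designs in scope.

### Trait inversion

`params_from_traits()` maps $(\mu_{max}, T_{opt}, CT_{min}, CT_{max})$
back to $(a, b, z, w)$ in closed form. Only warm-skewed curves
($T_{opt}$ at or above the midpoint of the limits, i.e. $b \ge 0$) are
supported; every published trait row this package emulates is warm-skewed.
The forward/backward maps are exact inverses (round-trip identity to
$10^{-6}$, property-tested), which is what makes desk-scale
parameter-recovery experiments possible: invert a published trait row,
generate noise-free observations at the nine assay temperatures, fit, and
re-derive — $B_{80}$ then acts as an out-of-sample check because it is
not an inversion input.

## Growth kinetics

The specific growth rate is the OLS slope of $\ln(\text{cells})$ on day.
The exponential window is chosen by a deterministic rule the user can
override with an explicit window: among all contiguous windows of at
least `min_points` (default 3) observations with $R^2 \ge$
`r2_threshold` (default 0.95), take the one with the largest slope; if
none qualifies, the one with the largest $R^2$; ties go to the longer,
then earlier window. A window fitted exactly (e.g. perfectly flat) counts
as $R^2 = 1$, so a flat lag phase never outranks a genuine exponential
phase on slope. Lag time is defined by a fold-change threshold (default
2×) over the initial density — the underlying experiments report lags
descriptively, without a rule, so the threshold is exposed. Generation
counts use $\mu t / \ln 2$ only; no transfer-by-transfer accounting is
attempted. `two_way_anova()` implements the standard balanced-design
fixed-effects decomposition with interaction and refuses unbalanced or
unreplicated designs.

## Community diversity

All diversity operations consume an ASV count table (samples × ASVs) with
a taxonomy map and a sample-to-group map. Filtering reproduces the
table-level effect of upstream read QC: singleton ASVs (dataset-wide
total ≤ 1) and taxa matching configured labels (e.g. chloroplast,
mitochondrial) are dropped.

- Richness is the count of nonzero ASVs per sample, reported per
  replicate and averaged per group (fractional group means are expected).
- Shannon $H = -\sum p_i \ln p_i$ in nats.
- Evenness is Smith–Wilson
  $E_{var} = 1 - \tfrac{2}{\pi}\arctan V$ with $V$ the population
  variance of log abundances of the nonzero ASVs — the standard index
  with the name "Evar"; a perfectly even sample gives 1 and
  abundances $(1, e^2)$ give exactly 0.5.
- Presence of an ASV in a group means ≥ 1 read in ≥ 1 replicate, applied
  after filtering — the most literal reading of "below detection".
  Extinctions are reference-present, target-absent ASVs; shared-ASV
  accounting reports Venn-style exclusive counts for every group subset
  *and* per-replicate-pair mean shared counts, since pooled-group and
  per-replicate presence are both defensible conventions.
- Bray–Curtis $d(x,y) = \sum|x_i - y_i| / \sum(x_i + y_i)$ is computed on
  per-sample proportions by default (so depth differences are not read as
  community differences), with a raw-count mode.
- PERMANOVA is re-implemented from the squared-distance decomposition
  ($SS_{total} = \tfrac1n \sum_{i<j} d_{ij}^2$ etc.), permuting labels
  freely (no strata) and estimating $p$ as $(b+1)/(m+1)$ with 999
  permutations by default. The vegan implementation is used in the test
  suite as an independent oracle, never in the package code.
- Per-taxon group tests are pooled t-tests on percent relative
  abundances with no multiple-testing correction by default (mirroring
  per-taxon significance marks in this literature); Bonferroni is
  available behind a flag.

## Metabolite profile

Class fractions are computed per sample (class total / sample total ×
100) and then averaged per group, matching the mean ± SE form in which
such fractions are reported. Fold change is the ratio of group
*arithmetic means* per metabolite (the underlying reports do not state
mean vs median; means are the default choice), with `log2fc` alongside.
Zero denominator means are surfaced as flagged error rows rather than
dropped; an optional pseudocount added to both means is off by default so
zeros stay visible. The class-level group test is a one-way ANOVA on
per-sample class totals; for two groups its $F$ equals the square of the
pooled t statistic (property-tested).

## Synthetic data: what it emulates and what it does not

The generators are pure functions of (parameters, seed); identical inputs
give identical outputs, and the pipeline derives per-stream substream
seeds from one master seed so adding a stream never perturbs another.

- **Trajectories**: flat at `n0` until `lag_days`, then logistic to
  `carrying_capacity` — the minimal model exhibiting the lag /
  exponential / stationary phases the experiments describe (no equation
  is published for them). Defaults: `n0 = 3e5` cells/ml (the experiments'
  inoculation density), a ~3-day lag, multiplicative lognormal counting
  noise (`noise_sigma = 0.05`) because flow-cytometry error scales with
  magnitude and counts must stay positive.
- **Thermal observations**: curve value plus Gaussian noise
  (`noise_sd = 0.1` day⁻¹, the order of replicate scatter implied by the
  published trait SEs), 3 replicates at the nine assay temperatures.
- **ASV tables**: one dominant taxon (default 40–50% expected relative
  abundance) plus a geometric rank-abundance tail — the simplest
  one-parameter shape producing a dominant genus over a rare tail —
  drawn multinomially at fixed depth (default 10 000 reads), 13–22 ASVs
  over 3 replicates per group. All groups share one rank-ordered ASV
  pool, so groups with fewer ASVs lack the deepest tail ranks; that makes
  extinction accounting between synthetic groups meaningful.
- **Metabolites**: lognormal concentrations with class-level
  multiplicative group effects (defaults: amino acids up ~1.6×,
  carbohydrates down ~0.35×, other unchanged, cv = 0.1 — the direction
  of the published shifts).

Not emulated: read-level sequencing (no FASTQ, error model, chimera or
taxonomy assignment), spectra (no NMR/GC–MS peaks), transfer schedules of
the multi-year batch cultures (trajectory parameters for that regime are
user-set), and any covariance between the microbiome and metabolite
layers. A green test on synthetic data therefore establishes that the
*computational chain* is correct under the stated statistical structure —
not that real communities satisfy that structure.

## Numerical choices and edge cases

- Degenerate regressions: a window with zero log-variance has
  $R^2 := 1$ and standard error 0; a zero between-group difference gives
  $t := 0$, $p := 1$ even when the pooled variance is 0; zero effect SS
  gives $F := 0$, $p := 1$, and zero residual SS with positive effect SS
  gives $F = \infty$, $p = 0$.
- `fraction = 1` gives $B_{80} := 0$ without root search.
- PERMANOVA counts permuted $F \ge F_{obs} - 10^{-12}$ so fully
  exchangeable distances give $p = 1$ exactly.
- Significance letters in `make_report()` use a greedy compact letter
  display (descending means, reuse the first compatible letter), which is
  exact for the 2–4 group designs in scope.
- Configuration is JSON (`jsonlite`); all thresholds above
  (`r2_threshold`, `fold_threshold`, `fraction`, `n_permutations`,
  `pseudocount`, seeds) are config-exposed with the defaults stated here.

## Known limitations

- Only the Norberg family is fitted — no Sharpe–Schoolfield, Gaussian or
  quadratic alternatives, no bootstrap confidence intervals (replicate
  level SEs mirror the reporting convention of the target experiments).
- Trait estimates from noisy fits carry the usual small nonlinear
  least-squares bias: at Gaussian noise 0.1 day⁻¹ and 9 temperatures the
  measured biases are of order +0.006 day⁻¹ ($\mu_{max}$), −0.05 °C
  ($CT_{min}$), −0.02 °C ($B_{80}$) — well under 1% of the trait values
  and small against replicate scatter, but detectable by a
  200-simulation Monte Carlo, where the strict "mean within 2 Monte
  Carlo SE" recovery check can flag a trait (see the acceptance suite).
- `params_from_traits()` rejects cold-skewed ($b < 0$) trait sets.
- The two-way ANOVA supports balanced designs with replication only; no
  mixed-effects models (out of scope).
- No ordination (PCA/CAP), no rarefaction, no sequence processing.
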