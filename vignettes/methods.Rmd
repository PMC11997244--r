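---
title: "Methods: gene-set summaries, mixed models and thermal traits in thermoresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set summaries, mixed models and thermal traits in thermoresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermoresp` compares transcriptomic temperature-stress responses across
plant species that were each quantified against their own de novo assembly,
and relates those responses to photosystem II (PSII) thermal-tolerance
plasticity. This vignette documents the statistical model behind each stage,
the tunable parameters and their defaults, the numerical conventions, and
what the synthetic-data tests do and do not demonstrate about real data.

## Data model and filtering

The unit of observation is a sequencing *library* (one plant), tied to a
species, a treatment arm (`control`, `cold`, `hot`) and the species' biome
of origin (`arid`, `alpine`, `temperate`). Expression is TPM from RSEM
`.genes.results` files (one per library) or an equivalent gene × library
matrix; gene identifiers are opaque, species-specific strings.

Per species, genes are retained when their mean TPM across *all* of the
species' libraries (arms pooled) is at or above `tpm_threshold` (default
10 TPM, boundary inclusive). Pooling arms gives one retention decision per
species, so every downstream summary for a species draws on one fixed gene
universe. Setting the threshold to 0 disables filtering (accepted with a
warning).

Treatment contrasts are per-gene log2 fold changes of arm means against
control, with a symmetric pseudocount (default 0.5 TPM) in numerator and
denominator. Retained genes can still have a zero mean in one arm — single-
library arms exist in the design — so the pseudocount keeps contrasts
finite. With `pseudocount = 0`, infinite ratios are propagated as missing
and excluded from gene-set medians; the affected set's subset size is capped
at the number of usable members. The fold change is antisymmetric in its
arguments and converges to `log2(mean ratio)` as the pseudocount shrinks,
both of which are property-tested.

## Gene-set construction

Biological-process GO annotations are parsed from Trinotate-style reports,
taking the union over all GO-bearing columns and over transcripts of a gene;
only the `biological_process` branch is kept. A GO term is retained when
every species contributes at least `min_genes` (default 10) retained,
annotated members. We read the published rule "a minimum of N annotated
genes across all species" as *per species* rather than *in total*: the
subset-size rule below divides by the cross-species minimum, which is only
bounded when every species qualifies, and the per-species reading is what
controls for annotation-depth differences. The total-count reading remains
available (`go_scope = "total"`). Member counts are taken after the
expression filter, because the boot-strap operates on expressed genes.

Orthogroups pass a two-stage filter: present (≥ 1 gene, before the
expression filter) in at least `presence_min` species (default 15 of 20),
then expressed (≥ 1 retained gene) in at least `expressed_min` species
(default 12). Both counts are recorded; the defaults scale with the
20-species design and are parameters so other designs can use proportional
values.

## The boot-strapped median summarizer

For each retained GO term, the per-library (and, for fold changes,
per-species-contrast) summary is the mean over `n_resamples = 1000` random
subsets of the member values of the subset median. The subset size is

```
k = max(1, round_half_up(0.75 * min over species of member count))
```

Half-up rounding is our convention for "rounded to the nearest whole
integer" (7.5 → 8, 10.5 → 11); base R's banker's rounding would differ at
exact halves, so the choice is explicit and configurable. Subsets are drawn
*without* replacement: with a subset strictly smaller than the member set,
resampling subsets describes subsampling, and the statistic interpolates
between the full-set median (`k = |S|`, where it is exactly the sample
median) and an average of partial medians. A with-replacement mode exists
for sensitivity analysis. The even-size subset median is the mean of the two
central order statistics.

The estimator's expectation is computable exactly by enumerating all
`choose(n, k)` subsets (`exact_subset_median_mean()`); the test suite and
the acceptance script verify the Monte-Carlo implementation against that
oracle to within 3 Monte-Carlo standard errors across all small instances,
and the resample loop is implemented in C++ for throughput.

Reproducibility contract: every (gene set, species) pair consumes an RNG
substream derived deterministically from the master seed and the pair's
identifiers (`substream_seed()`), so estimates are independent of processing
order — shuffling terms or parallelizing leaves every estimate bit-identical.

Orthogroup expression is summarized by the member mean instead, because many
orthogroups hold a single gene in some species; medians would be both
undefined in spirit and noisier.

For presentation-style summaries, per-set values can be z-scaled (sample SD,
`n − 1`; the convention is stated because the population-SD alternative
changes nothing downstream — the mixed-model t statistics are scale
invariant, which is property-tested). Constant vectors are refused rather
than silently scaled to zero.

## Treatment mixed models

Per gene set, library-level summaries are modelled with a Gaussian linear
mixed model, `estimate ~ treatment + (1 | species)`, fit by REML with
control as the reference level. Reported per contrast: the estimate, its
standard error, `t = estimate/se`, a two-sided p value, and per model the
species and residual variance components, the ICC
`sigma2_sp / (sigma2_sp + sigma2_res)` and the treatment marginal R²
(fixed-effect fitted variance over fixed + random + residual variance).
The response is the raw boot-strapped median TPM, not log-transformed or
z-scaled: t statistics are invariant to affine rescaling, and scaling is a
presentation device only.

Degrees of freedom follow the residual convention

```
df = n_obs - n_species - (n_treatment_levels - 1)
```

which gives 166 for the full design (188 libraries, 20 species, 3 arms) and
correspondingly fewer for sets spanning fewer species. This integer-df
convention is an assumption — the alternative Satterthwaite approximation
(`df_mode = "satterthwaite"`, via lmerTest) yields non-integer, per-contrast
df — but it is calibrated: under a simulated null the 0.05-level rejection
rate of the treatment contrast is 5% (acceptance report). Singular fits
(species variance collapsing to zero) are reported with `icc = 0` and a
flag rather than dropped; with a single species the model refuses to fit,
since the ICC is undefined.

## Biome and acclimation models

Species-level fold-change summaries are regressed on biome with a one-way
fixed-effect linear model (multiple R², overall-F p value, per-biome mean ±
SE). Per-species observations — not biome means — enter the model; biomes
with a single species are flagged, and a single-biome table is refused.
Acclimation models regress a per-species thermal trait delta on the
corresponding gene-set fold change (hot traits against hot-vs-control FC,
cold traits against cold-vs-control FC), reporting the slope t and p, the
adjusted R², the minimum cross-species member count behind the summary, and
the FC median/min/max across species. Result tables are ordered by trait and
then descending adjusted R², with lexicographic set-id tie-breaks so output
is deterministic. BH-FDR adjustment is available but off by default: with 20
species the emphasis is on effect sizes and functional coherence rather than
corrected p values.

## Thermal trait extraction

Basal fluorescence F0 rises slowly with temperature until PSII begins to
fail, then rises steeply. Tcrit is the breakpoint of the continuous
two-segment model `F0 = b0 + b1*T + b2*(T - psi)+`, fit by least squares
with `psi` searched exhaustively on a `grid_step = 0.1` °C grid over the
central 80% of the (peak-truncated) temperature range. The exhaustive grid
is deterministic and free of starting-value sensitivity, unlike iterative
segmented-regression fitting; refining the grid can only lower the RSS at
the optimum (tested), and an optional finer grid can be layered on top.
Breakpoint acceptance requires an interior RSS minimum and a relative RSS
improvement over a single straight line (default 5%); otherwise "no
breakpoint detected" is raised. A fast-phase slope that does not exceed the
slow-phase slope is flagged but not fatal.

Traces are QC'd before fitting: non-finite points dropped, duplicate
temperatures averaged, at least 20 usable points required. Cooling ramps are
analyzed on the negated temperature axis so the rise-phase logic is shared,
and results are negated back. Because synthetic and real ramps continue past
the fluorescence peak, the trace is truncated at its smoothed-F0 maximum
before the two-segment fit — the slow/fast-rise breakpoint precedes the
peak by construction.

Tmax is the temperature of the rolling-median-smoothed (window 5 points) F0
maximum; exact ties resolve to the temperature nearest Tcrit's side of the
ramp, and a maximum at a trace endpoint is flagged as a possible truncated
ramp. This smoothed-argmax definition is a documented stand-in for
protocol-specific extraction conventions and is isolated in one operation so
it can be swapped.

Acclimation deltas are `treatment-arm mean − control mean` per species and
trait. Positive hot deltas mean gained heat tolerance; positive cold deltas
(critical temperatures moving toward 0 °C) mean *worsened* cold
performance — the delta is a plasticity metric, not necessarily an
improvement.

## The synthetic-data generator

`simulate_dataset()` produces a complete input bundle with known ground
truth. Its defaults are the study design the analysis targets:

* 20 species (7 alpine, 7 arid, 6 temperate) with the published per-arm
  library counts, totalling 188 libraries and including n = 1 arms, which
  exercise the single-library code paths;
* gene-level log2-TPM: `mu_g + u_s + beta[set, arm, biome] + e_l + eps_gl`,
  with species intercepts `u_s ~ N(0, 0.45)`, library-level residuals
  `e_l ~ N(0, 0.55)` — so the planted ICC is 0.45, matching a typical
  between-species differentiation level for such designs — and gene noise
  `eps ~ N(0, 0.3^2)`;
* planted GO terms with effects up to ±1 log2 unit, some uniform across
  biomes and some biome-differential (arid-weak heat response, alpine-weak
  cold response), plus null terms and a distractor with one species below
  the retention minimum;
* orthogroups planted to pass, fail the presence stage, or fail the
  expression stage exactly;
* two-segment fluorescence ramps (heating 20→65 °C at 30 °C/h, cooling
  20→−25 °C at 15 °C/h, 5-s logging) with planted per-species breakpoints,
  peaks, acclimation deltas (+2.5 °C Tcrit-hot by default) and Gaussian
  noise (SD 0.02).

Two structural choices make the ground truth identifiable. Effects are
planted on the log2-TPM scale, so a planted beta equals the expected log2
fold change and maps additively onto log2-transformed median summaries
(the median commutes with monotone transforms). And GO-member baseline
expression `mu_g` is shared across species — orthologous processes keep
comparable expression levels — so the species random intercept is the only
between-species component of a gene-set median; with species-specific
member baselines, the cross-species variance of the median baseline would
inflate the apparent species variance and make the planted ICC
unrecoverable by design rather than by estimation error. Gene-level noise
is kept modest (SD 0.3) relative to the library-level residual for the same
reason: it enters the median summary as a small extra variance component.

Defaults down-scale only the per-species gene count (2,000 genes, 25%
planted below the filter) relative to the ~12,000 retained genes a real
assembly yields; gene count must merely exceed the retention rules, while
species and library counts are what the models actually see. The generator
does not emulate read-level sampling noise, TPM compositional coupling
across genes, annotation errors, or phylogenetic correlation between
species' random intercepts — so passing tests demonstrate correctness of
the estimators under the stated model, not robustness to those real-data
features.

## Problem sizes and numerical conventions

The test suite and acceptance script run entirely on synthetic data:
mixed-model recovery uses 100 replicates of the full 188-library design
with a single planted gene set (1,000 resamples each), null calibration
uses 500 direct simulations from the model's generating process, breakpoint
recovery uses 100 noisy ramps, and end-to-end checks use a 6-species bundle
(300–400 genes/species) plus one full 20-species bundle. These sizes are
the package's choices for routine verification; all are parameters.

Other conventions worth stating: TPM values must be non-negative and gene
ids unique (hard errors otherwise); parsers either succeed or raise typed
format errors naming the offending entity — there are no silent partial
reads; malformed GO entries are skipped with a counted warning while a
report with no biological-process entries at all is an error; every
stochastic stage requires an explicit seed, and rerunning a pipeline with
the same inputs and seed reproduces every output table byte-for-byte.
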