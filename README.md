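# thermoresp

Comparative transcriptomics of temperature-stress responses for plant
species without a shared reference genome, paired with photosystem II (PSII)
thermal-tolerance trait extraction.

## The problem

When distantly related species are profiled with de novo transcriptome
assemblies, genes cannot be matched one-to-one across species. Responses can
still be compared at the level of *functional gene sets*: biological-process
GO terms annotated per species, and orthogroups inferred from sequence
similarity. `thermoresp` implements that workflow for a design in which
plants from contrasting biomes (arid, alpine, temperate) are exposed to hot,
cold and control temperature treatments and profiled by RNA-seq (TPM from
per-species assemblies), alongside chlorophyll-fluorescence temperature
ramps measuring PSII thermal tolerance.

## The core statistics

**Boot-strapped median gene-set expression.** For a gene set with members
$g \in S_s$ in species $s$, the summarizer is

$$\hat{m} = \frac{1}{B}\sum_{b=1}^{B} \operatorname{median}\{x_g : g \in S_s^{(b)}\},$$

where each $S_s^{(b)}$ is a random subset (without replacement) of fixed
size $k = \operatorname{round}(0.75 \cdot \min_s |S_s|)$ and $B = 1000$.
Fixing $k$ at 75% of the *smallest* cross-species member count controls for
unequal annotation depth between species. Gene sets are retained when every
species contributes at least 10 members (GO terms), or when an orthogroup is
present in ≥ 15 species and expressed (after a mean-TPM ≥ 10 filter) in
≥ 12 species.

**Treatment mixed models.** Per gene set, library-level summaries are
modelled as `estimate ~ treatment + (1 | species)` (REML), giving hot and
cold contrasts against control with
$t$ statistics on $n - n_{species} - 2$ degrees of freedom (166 for the
full 188-library, 20-species design), an ICC
$\sigma^2_{sp}/(\sigma^2_{sp}+\sigma^2_{res})$ quantifying between-species
differentiation, and the treatment marginal $R^2$.

**Biome and acclimation models.** Species-level log2 fold changes
(`log2((mean_treat + 0.5)/(mean_control + 0.5))`, summarized per gene set)
are regressed on biome (one-way fixed-effect model, multiple $R^2$ and
overall-F $p$), and on per-species PSII acclimation deltas
(`acclimation ~ FC`, adjusted $R^2$), where acclimation is the difference in
Tcrit/Tmax between a treatment arm and control.

**Tcrit extraction.** The critical temperature is the breakpoint between the
slow and fast rise phases of basal fluorescence, estimated by least squares
on the continuous two-segment model
$F_0 = \beta_0 + \beta_1 T + \beta_2 (T-\psi)_+$ with $\psi$ searched on a
0.1 °C grid; Tmax is the temperature of (smoothed) maximum $F_0$.

A fully ground-truthed synthetic data generator (`simulate_dataset()`)
reproduces the study design — 20 species, 188 libraries with unbalanced
arms, planted log2-scale treatment effects modulated by biome, distractor
gene sets that must fail retention, and two-segment fluorescence ramps —
so every stage is testable without downloading data.

## Worked example

```r
library(thermoresp)

sp <- simulation_config()$species[c(1, 2, 8, 9, 15, 16), ]   # 6 species
sp$biome <- rep(c("alpine", "arid", "temperate"), each = 2)
cfg <- simulation_config(species = sp, n_genes = 400, plants_per_combo = 2)
ds  <- simulate_dataset(cfg, seed = 42)
write_synthetic_bundle(ds, "bundle")

res <- run_pipeline(validate_config(list(
  input_dir = "bundle", output_dir = "out", seed = 1, n_resamples = 1000,
  presence_min = ds$truth$presence_min,
  expressed_min = ds$truth$expressed_min)))

boot <- res$go_expression_boot
fit_treatment_lmm(boot[boot$set_id == "GO:2000001", ], ds$metadata,
                  set_id = "GO:2000001")
#> Treatment mixed model [GO:2000001]: 47 libraries, 6 species
#>  contrast estimate    se       t df        p
#>      cold    2.147 73.87 0.02907 39 0.976961
#>       hot  249.389 71.62 3.48214 39 0.001242
#> ICC = 0.164  marginal R2 = 0.230  (sigma2_sp = 7967, sigma2_res = 4.076e+04)
```

`GO:2000001` carries a planted +1 log2 heat effect, and the hot contrast is
strongly positive (t = 3.48, p = 0.001) while the cold contrast is null; the
ICC says 16% of the remaining variance sits between species. The degrees of
freedom follow the residual convention (47 − 6 − 2 = 39).

```r
fit_tcrit(ds$traces[["sp01_heating_control_r1"]])
#> Tcrit = 46.00 C (slopes 0.002003 -> 0.08233, RSS 0.3235, n = 817)
```

The planted breakpoint for this trace was 46.0 °C (to grid resolution); the
slope pair shows the slow → fast rise transition that defines the onset of
PSII disruption.

The pipeline also writes `lmm_results.tsv`, `biome_results.tsv`,
`acclimation_results.tsv` (ordered by trait, then descending adjusted R²),
`thermal_traits.tsv`, a retention log with one line per gene set, and a JSON
manifest with parameters, seed and input checksums.

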