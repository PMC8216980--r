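# limnotte

Trophic transfer efficiency (TTE) of carbon, nutrients and omega-3 PUFA
in lake plankton food webs.

`limnotte` is for limnologists and food-web ecologists who want to turn a
snapshot lake survey — hydrochemistry, vertical chlorophyll/PAR/PSII
profiles, zooplankton counts with body lengths, and elemental +
fatty-acid composition of seston and zooplankton — into per-lake,
per-substance transfer efficiencies and class-level comparisons. A seeded
synthetic survey generator emulating a 30-lake summer survey in four
trophic classes (oligo-, meso-, eu- and dystrophic) makes the whole
pipeline testable without field data.

## The statistic at the core

For each lake and substance *s* ∈ {C, N, P, ω-3 PUFA}:

```
TTE_s = 100 × (SP × s-content of zooplankton) / (GPP × s-content of seston)   [%]
```

where GPP is depth-integrated gross primary production in carbon units
(a pluggable light-response model on chlorophyll, PSII activity and PAR,
O₂ → C by the 0.32 factor) and SP is crustacean secondary production from
the allometric regression

```
SP = 10^(−0.23·log10(M) − 0.73) · 1.12 · M · N      [µg DW L⁻¹ day⁻¹]
```

(M mean individual dry mass in µg, N abundance in ind/L; dry weight → C
by 1/2.3). Because production is measured in carbon, N and P enter via
element:carbon ratios and ω-3 as mass per unit carbon; efficiencies above
100 % are flagged as measurement artefacts and excluded from summaries.
Supporting layers: Carlson TSI + a hydrochemical dystrophy index for
classification; length–weight allometry for biomass; one-way ANOVA with
Fisher-LSD compact letters, Bray–Curtis clustering and (canonical)
correspondence analysis for the comparisons.

## Worked example

```r
library(limnotte)

cfg <- pipeline_config(
  generator = generator_config(seed = 2021),  # 5/7/8/10 lakes per class
  class_col = "true_class"
)
res <- run_pipeline(cfg)

dplyr::filter(res$tte_summary, trophic_class == "all")
#> # A tibble: 4 × 6
#>   trophic_class substance     n n_artefact  mean    sd
#>   <chr>         <chr>     <int>      <int> <dbl> <dbl>
#> 1 all           C            30          0  5.95  5.42
#> 2 all           N            30          0 10.6  10.7
#> 3 all           P            30          0 13.4  13.4
#> 4 all           omega3       30          3 18.5  18.2
```

Bulk carbon moves at ~6 % on average while phosphorus and ω-3 PUFA move
two to three times more efficiently — the stoichiometric/biochemical
mismatch the pipeline is built to quantify. (Three lakes drew the
generator's simulated ω-3 measurement failure; they are counted under
`n_artefact` and excluded from the ω-3 mean.) The class contrast and its
letter display:

```r
res$stats$C$anova
#> One-way ANOVA: tte_pct ~ cls
#>   F(3, 26) = 11.84, p = 4.488e-05
res$stats$C$lsd$letters
#> # A tibble: 4 × 2
#>   group        letters
#> 1 dystrophic   b
#> 2 eutrophic    b
#> 3 mesotrophic  a
#> 4 oligotrophic a

carbon <- dplyr::filter(res$tte, substance == "C", !artefact)
fold_range(carbon$tte_pct)
#> # A tibble: 1 × 4
#>     min   max  fold fold_rounded
#> 1 0.233  21.4  91.9           92
```

Carbon transfer is highest in the oligotrophic class, collapses in
eutrophic and dystrophic lakes (groups sharing no letter differ at
p < 0.05), and spans nearly two orders of magnitude between lakes.
`plot_tte_box()`, `plot_chl_profiles()` and `autoplot()` on a
`correspondence_analysis()` object give the standard figures;
`tidy()`/`glance()` methods return the fitted objects as tibbles.

Working from files instead: `write_survey()`/`read_survey()` define the
CSV schemas (`survey_schemas()`), `read_pipeline_config()` reads a YAML
run description, and `run_pipeline()` with an `output_dir` writes
`assessments.csv`, `biomass.csv`, `production.csv`, `tte.csv`,
`tte_summary.csv`, `stats/*.csv` and a reproducibility manifest.

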