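# coexar

Bottom-up species–area (SAR) and coexistence–area (CAR) relationships for
annual plant communities, built from neighborhood-scale interaction data.

Ecologists who census fecundity and neighborhood composition of focal
individuals across plots and years — the standard design for studying
competition among annual plants — can use `coexar` to go from those raw
observations to an answer to: *how much of the rise of species richness
with area is explained by local interactions, how much by environmental
heterogeneity, and which species are merely transient?*

## The model

Viable seed production of a focal individual of species *i* follows a
Ricker model with negative-binomial noise,

    F_i = lambda_i * exp( - sum_j alpha_ij * N_j ),

with `lambda_i` the intrinsic fecundity, `N_j` the neighbor counts, and
`alpha_ij` the per-capita effect of species *j* on *i* (positive =
competition, negative = facilitation). Fits are per focal species and
year, either pooled over all plots ("homogeneous") or with plot-level
partial pooling ("heterogeneous"). Vital rates of the seed bank
(germination `g`, seed survival `s`) convert fitted fecundities to
Lotka–Volterra growth rates,

    r_i = log(lambda_i) - log( (1 - (1 - g_i) * s_i) / g_i ),

and a species subset *coexists* (is feasible) when
`A' N* = r'` restricted to the subset has an all-positive solution.
Scanning every subset of each plot community assigns every species the
simplest configuration that lets it persist — `dominant`, `pair`,
`multispecies`, or `transient` — and CARs average the number of
persisting species over all combinations of plots for each area, just as
Type-B SARs average observed richness. Power laws `S = c * A^z`
summarize both; reshuffling null models test whether the identity of
pairwise interactions matters.

A full account of the model, the synthetic-data generator, and every
numerical choice is in `vignettes/coexistence-area.Rmd`.

## Worked example

A one-year, four-plot, eight-species world with known ground truth:

```r
library(coexar)

design <- study_design(n_years = 1, n_plots = 4,
                       species_names = default_species_codes()[1:8])
truth <- generate_ground_truth(design, scenario = "heterogeneous",
                               heterogeneity_sd = 0.4, seed = 42)
obs <- generate_observations(truth, design,
                             n_focal_per_species_plot = 25, seed = 43)

hom <- fit_homogeneous(obs, truth$g, truth$s, year = 2015)
het <- fit_heterogeneous(obs, truth$g, truth$s, year = 2015, pooled = hom)

presence <- presence_table(obs)
records <- dplyr::bind_rows(
  classify_year(hom, presence, "hom"),
  classify_year(het, presence, "het")
)
table(records$parameterization, records$category)
#>       dominant multispecies pair transient
#>   het        2            0   15         1
#>   hom        1            2   15         0
```

Most species persist through pairwise interactions — each plot-year
record says in which configuration a species can persist there. The
curves then average over plot combinations:

```r
curves <- build_curve_table(
  presence,
  dplyr::filter(records, parameterization == "hom"),
  dplyr::filter(records, parameterization == "het"),
  plots = 1:4
)
curves
#>    year     k area_m2 n_combinations sar_mean sar_se car_hom_mean ...
#>   2015     1    72.2              4     4.5   1.19          4.5
#>   2015     2   144.               6     6.83  0.401         6.83
#>   2015     3   217.               4     7.75  0.25          7.75
#>   2015     4   289                1     8     0             8

power_law_fit(curves$area_m2, curves$car_hom_mean)
#> Power law S = 0.9238 * A^0.3888 (RSS 0.548)
heterogeneity_contribution(curves)
#> [1] -2.095588
```

Richness climbs from 4.5 species in one plot to all 8 at the full area
(`sar_se = 0` at the largest scale, where only one combination exists);
here every observed species also persists under the homogeneous
parameterization, so the CAR tracks the SAR, the coexistence–area
exponent is z ≈ 0.39, and plot heterogeneity contributes essentially
nothing (−2%) to coexistence. `run_pipeline(pipeline_config(...))` runs
the same chain — plus parameter draws and null models — for all years
and writes `observations.csv`, per-year fits, `persistence.csv`,
`curves.csv`, `powerlaw.csv`, `nulls.csv` and a run manifest.

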