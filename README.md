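# reeftraits

Trait-based analysis of how **intraspecific trait variation (ITV)** and
**species turnover** jointly reshape coral assemblages along an inshore
gradient of rising temperature and falling pH.

Reef surveys that pair colony-level trait sampling (here: nine traits —
zooxanthellae density ZD, tissue biomass TB, protein biomass PB,
chlorophyll CH, surface-to-volume SV, branch density BD, branch width BW,
corallite width CW, skeletal density SD) with line-intercept abundance
transects can separate two routes of community change: replacement of
species by better-suited species, and within-species trait shifts of the
species that persist. `reeftraits` is for ecologists who have (or want to
simulate) such paired data and need the standard quantitative toolkit:

* **Standardized effect sizes** of a binary location contrast (inner vs
  outer reefs) on each trait: OLS per species, and linear mixed models with
  a species random intercept pooled across species, summarized as
  *E* = slope / residual SD.
* **Community-weighted means (CWM)** per transect,
  CWM<sub>t</sub> = Σ<sub>s</sub> p<sub>st</sub> ȳ<sub>s</sub>, under
  *fixed* (one study-wide mean per species; turnover signal only) versus
  *local* (site-specific species means; turnover + ITV) modes.
* **Sums-of-squares decomposition** of study-wide CWM variation,
  SS<sub>local</sub> = SS<sub>fixed</sub> + SS<sub>intra</sub> + SS<sub>cov</sub>,
  each reported as a proportion of SS<sub>local</sub> (the covariation term
  is negative when ITV opposes turnover).
* **Effect decomposition** across locations, E<sub>intra</sub> =
  E<sub>local</sub> − E<sub>fixed</sub>, with amplification
  (E<sub>local</sub>/E<sub>fixed</sub>) and percent reduction
  (100·(|E<sub>fixed</sub>| − |E<sub>local</sub>|)/|E<sub>fixed</sub>|) of the
  compositional shift.
* **Trait-space ordination** (PCA with a deterministic sign convention),
  per-species shift vectors between location classes, and the
  abundance-weighted trait-space shift contributed by site-restricted
  species alone.
* A **synthetic community generator** with known ground truth (16 species:
  7 generalists, 6 outer- and 3 inner-restricted specialists; 8 sites; 24
  transects) for parameter-recovery testing, plus an end-to-end pipeline
  with CSV outputs and a checksummed manifest.

See the methods vignette
(`vignettes/trait-variation-decomposition.Rmd`) for the models,
assumptions, generator design and known limitations.

## Worked example

```r
library(reeftraits)

run <- run_pipeline(out_dir = tempfile("reefrun"), seed = 1)
run$decomposition[, c("trait", "prop_fixed", "prop_intra", "prop_cov",
                      "amplification", "reduction")]
```

```
  trait prop_fixed prop_intra prop_cov amplification reduction
1    ZD      0.435     0.1237   0.4413         2.584   -158.36
2    TB      0.559     0.0750   0.3658         1.817    -81.71
3    PB      0.646     0.0485   0.3054         2.005   -100.49
4    CH      0.433     0.1283   0.4387         2.861   -186.08
5    SV      2.590     0.5561  -2.1464         0.475     52.53
6    BD      0.954     0.0179   0.0276         1.040     -3.97
7    BW      2.155     0.6305  -1.7858         0.395     60.51
8    CW      1.150     0.0356  -0.1857         0.810     18.95
9    SD      0.410     0.2038   0.3858         2.053   -105.30
```

Reading this: tissue traits (ZD…CH) split their assemblage variation
between composition (43–65%) and ITV-plus-positive-covariation, and ITV
*amplifies* the composition-driven inshore shift ~1.8–2.9-fold (negative
"reduction" means amplification). Morphological structure (SV, BW) is the
mirror image: composition alone would shift assemblages even further toward
low-complexity forms (prop_fixed > 1 with negative covariation), but
opposing intraspecific shifts cut the realized change by ~50–60%.

The hand-checkable standardized effect (two colonies per side, trait
values 1,3 outer vs 4,6 inner):

```r
species_effect_size(c(1, 3, 4, 6), c(0, 0, 1, 1))
#   slope residual_sd  effect p_value n converged
# 1     3     1.41421 2.12132 0.16795 4      TRUE
```

Diagnostics: `plot_decomposition(run$decomposition)` (stacked
compositional/intraspecific effect bars with net points) and
`plot_trait_space(run$pca)` (colonies plus trait loading vectors).

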