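# savcarbon

Whole-ecosystem carbon accounting for disturbance-prone savannas.

Dryland savannas store a large share of terrestrial carbon, but standard
forest-inventory protocols misestimate their stocks: woody plants carry
visible damage from elephants, other browsers, woodcutting and fire; heavily
damaged "gulliver" shrubs and large root systems hold substantial carbon;
and soil organic carbon varies strongly between vegetation patches and with
depth. `savcarbon` implements a carbon-accounting pipeline built for these
conditions, aimed at ecosystem ecologists and carbon-assessment
practitioners working with growth-form stratified plot inventories, plus
the statistical toolkit to relate the resulting stocks to disturbance
regimes.

## What it computes

**Aboveground carbon (AGC).** Individuals are converted to biomass with
growth-form specific allometries — adult trees via the pantropical model
*AGB = a (ρ D² H)ᵇ* (ρ = specific wood density g/cm³, D = DBH cm,
H = height m; defaults a = 0.0673, b = 0.976) and shrub-like forms via a
crown-area × height power law — then to carbon with species-wise carbon
fractions. Per-agent biomass-loss fractions recorded in the field let the
pipeline extrapolate each individual's pre-disturbance stock,
AGC_pre = AGC / (1 − loss).

**Belowground carbon (BGC).** Root:shoot ratios are size-dependent for
adult trees, RS = 1.89208 · DBH^−0.43491, and fixed at 2.16 for shrubs,
gullivers and subadults. Lightly damaged individuals (loss ≤ 30%) carry
RS · AGC_pre of root carbon; heavily damaged gullivers get the mean of the
pre-disturbance maximum and post-disturbance minimum, approximating partial
root dieback.

**Soil organic carbon (SOC).** Per depth layer,
SOC [t/ha] = C [g/kg] × bulk density [g/cm³] × depth [cm] / 10, summed into
topsoil (0–30 cm) and subsoil (30–100 cm), with hand-auger cores imputed
from full-depth neighbours and patch-type cores weighted by their relative
ground cover.

Stocks are expressed per hectare and assembled into six compartments (tree
AGC/BGC, shrub AGC/BGC, topsoil/subsoil SOC), pools (AGC, BGC, SOC) and
whole-ecosystem C_total per plot.

**Disturbance regime and drivers.** Ordinal disturbance scores (0–20 per
agent; browsing split by vegetation layer, 0–10 each), herbivore-guild
density indices, per-land-use damage shares, Games-Howell and
ANOVA/Tukey group comparisons, and Gaussian GAMMs with thin-plate smooths,
double-penalty (shrinkage) smoothness selection by REML, two
fire × browsing tensor interactions, vegetation type as parametric plus
random intercept, and hierarchical partitioning of explained deviance
across predictors.

**Synthetic data.** `generate_dataset()` emulates the underlying study: two
vegetation types × five land-use types (low/medium/high elephant density,
rangeland, agriculture; 10/10/10/6/6 plots each, 84 plots), land-use
specific disturbance-agent mixes, unimodal disturbance–carbon responses,
and depth-structured soil profiles — with a ground-truth record for
parameter-recovery testing.

## Worked example

```r
library(savcarbon)

run <- run_pipeline(run_config(seed = 42, fit_models = FALSE))
run
#> Savanna carbon pipeline run
#>   84 plots; mean C_total 45.7 t C/ha (AGC 6.2, BGC 9.0, SOC 30.5)
#>   manifest hash: 0010497b (seed 42)

landuse_means(run$compartments, "agc")$pooled
#>    A    H    L    M    R
#> 3.20 4.77 9.56 7.32 4.43
```

Aboveground carbon peaks on the low-disturbance reference plots (L,
9.56 t C/ha) and declines along both land-use change pathways — to
4.77 t C/ha under high elephant density (conservation pathway, −50%) and
3.20 t C/ha on agricultural fields (intensification pathway, −66%) —
while soil carbon, the largest pool, changes far less. Group differences
can be tested without assuming equal variances:

```r
gh <- games_howell(run$compartments$agc, run$compartments$landuse)
head(gh[order(gh$p.adj), ], 3)
#>   group1 group2      diff       se       df        q        p.adj
#> 5      H      L  4.791588 1.011506 35.81907 6.699250 0.0003101098
#> 2      A      L  6.355304 1.443711 20.52842 6.225454 0.0021664866
#> 9      L      R -5.131233 1.255906 24.47460 5.778029 0.0034387109
```

`fit_gamm()` then models AGC or C_total on the eight plot-level drivers;
`partial_effect()` and `peak_location()` extract the centred smooth curves
and their optima, and `deviance_partition()` attributes the explained
deviance to individual predictors.

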