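# chamoisdem

Demographic analysis of Alpine chamois (*Rupicapra rupicapra*) vital rates
from annual block-count data, as functions of density dependence, seasonal
precipitation and interspecific competition with red deer (*Cervus
elaphus*).

Long-term census programmes classify every visible animal once a year into
kid, yearling, adult female or adult male. From such series, wildlife
demographers want to know which forces drive each demographic component --
and whether a competitor depresses population growth indirectly through
specific vital rates. `chamoisdem` implements that analysis end to end,
for ecologists working with classified ungulate count series:

1. **Preprocessing** — proportional reassignment of partially classified
   ("unknown 1+", "unknown 2+") animals, and undercount adjustment
   (counts divided by 1 − c; c = 0.20 for chamois block counts, 0.35 for
   deer spotlight counts).
2. **State-space filtering** — each log-abundance series is modelled as a
   local level with drift, x_t = x_{t−1} + u + w_t, y_t = x_t + v_t,
   fitted by maximum likelihood (Kalman prediction-error decomposition,
   multi-start) and smoothed with the RTS recursion, separating
   observation from process error.
3. **Vital rates** — birth rate Br_t = kid_t/adultF_t; kid survival
   Ks_t = yearling_{t+1}/kid_t; female survival
   Fs_t = adultF_{t+1}/(adultF_t + yearling_t/2) (analogously male
   survival); log growth rate Y_t = ln(N_{t+1}/N_t), kids excluded.
4. **Regression inference** — for each rate, a 19-model candidate set of
   autoregressive Gaussian linear models over lagged own abundance, lagged
   deer abundance, winter (Jan–Mar) and spring–summer (Apr–Jul)
   precipitation, ranked by AICc and combined by Akaike-weight averaging
   (ΔAICc < 4, shrinkage averaging with unconditional SEs), with VIF,
   permutation Durbin–Watson, bootstrap optimism-corrected RMSE and a
   Huber M-estimation refit as diagnostics.
5. **Path analysis** — four recursive mediation models
   deer_{t−1} → vital rate → growth, each with 1 df, compared by AIC with
   χ²/RMSEA fit assessment and delta-method (or bootstrap) confidence
   intervals for the indirect effect a·b.
6. **Simulator** — a seeded age-structured population/observation
   generator with logistic-link vital rates, binomial demography,
   logistic competitor dynamics, binomial detection and two-stage
   misclassification, so every stage is testable against known truth.

## Worked example

Simulate a 28-year two-species census under the default conditions and run
the full pipeline:

```r
library(chamoisdem)

cfg <- pipeline_config(simulate = sim_config(seed = 1),
                       bootstrap_B = 200, seed = 1)
res <- run_pipeline(cfg)

res$selection$Fs$averaged
#>                 term estimate      se      lcl      ucl
#> 1        (Intercept)  0.85986 0.00533  0.84943  0.87030
#> 2                 ar -0.00933 0.00788 -0.02477  0.00611
#> 3           P_winter -0.01895 0.00611 -0.03094 -0.00697
#> 4          N_chamois  0.01177 0.00977 -0.00738  0.03093
#> 5             N_deer -0.03694 0.00931 -0.05519 -0.01869
#> 6 P_winter:N_chamois -0.05050 0.00563 -0.06153 -0.03947
```

The averaged standardized coefficients say: mean female survival is 0.86;
one standard deviation more red deer the year before lowers it by about
0.037 (95% CI −0.055, −0.019), and the winter-precipitation × chamois-
density interaction lowers it by 0.050 per SD of the product — the
generator's negative competition and winter-crowding effects, recovered
with correct signs. The model ranking and the mediation comparison:

```r
head(res$selection$Fs$ranking, 3)
#>      model delta   weight adj_r2   rmse
#> 1   m.1.fs   0.0 9.96e-01  0.866 0.0312
#> 13 m.13.fs  11.3 3.51e-03  0.771 0.0392
#> 5   m.5.fs  19.6 5.51e-05  0.685 0.0480

res$path$comparison[, c("mediator", "chisq", "p_value", "rmsea", "aic",
                        "indirect")]
#>   mediator  chisq  p_value rmsea aic indirect
#> 1       Fs  0.851 3.56e-01 0.000 168  -0.5590
#> 2       Ms  9.047 2.63e-03 0.567 220  -0.1491
#> 3       Br 14.307 1.55e-04 0.730 222  -0.0275
#> 4       Ks 16.588 4.64e-05 0.790 225   0.0416
```

Only the female-survival chain is consistent with the data (χ² p = 0.36,
RMSEA = 0): rising deer abundance relates to chamois growth indirectly
through female survival, with a standardized indirect effect of −0.56.

On real data, replace `simulate` with `counts`, `deer` and `climate` CSV
paths (wide `year,kid,...` or long `year,class,count`; `year,count`;
`year,month,precip_mm`); `run_pipeline()` also accepts a YAML/JSON
configuration file with the same keys.

## Package layout

- `R/sim-config.R`, `R/simulate.R` — simulator configuration and the
  generative chain.
- `R/counts-io.R` — CSV readers/validators, unknown reassignment,
  undercount adjustment.
- `R/state-space.R` — Kalman filter/smoother maximum likelihood.
- `R/demography.R` — vital rates, climate aggregation, standardization,
  lag-aligned design tables.
- `R/model-selection.R` — candidate set, OLS fits, AICc, weights,
  averaging, diagnostics.
- `R/path-analysis.R` — mediation path models and comparison.
- `R/pipeline.R` — configuration and orchestration.
- `vignettes/chamois-vital-rates.Rmd` — the methods account: model
  assumptions, numerical choices, simulator design and limitations.
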