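# limnocast

Comparative chlorophyll-a prediction for lake water-quality monitoring.

Chlorophyll-a is the standard proxy for algal biomass and hence for the
trophic state of a lake (ultra-oligotrophic through hypertrophic,
boundaries 1.0 / 2.5 / 8.0 / 25 µg/l). `limnocast` implements, side by
side, four model families used to forecast chlorophyll-a from routine
limnological measurements — water temperature, pH, dissolved oxygen,
Secchi depth, turbidity, conductivity, NH3-N, NO3-N, COD, TSS — and a
common three-criterion assessment:

| family | core |
|---|---|
| **MLR** | stepwise multiple linear regression (p-to-enter 0.05, p-to-remove 0.10, OLS) |
| **FL** | self-organizing-map clustering → triangular memberships anchored at cluster means → case-based rule induction → Mamdani min–max inference with centroid defuzzification |
| **RANN** | Elman recurrent net, tanh(0.7·x) activations, backpropagation through time with momentum `w(n+1) = w(n) + η δ x + α (w(n) − w(n−1))`, validation early stopping, sensitivity-based backward elimination of inputs |
| **HEA** | genetic programming over an `IF (cond) THEN chla = expr ELSE chla = expr` rule grammar with protected `÷` and `ln|·|`, plus genetic-algorithm optimization of the rule constants via non-convex multi-parent linear-combination crossover |

Every model is scored on a held-out test block by **RMSE** (µg/l),
**Pearson r** (reliability flag at r ≥ 0.5) and **AUC** of the ROC curve
obtained by dichotomizing observed chlorophyll-a at a trophic boundary
(default 8 µg/l; trapezoidal integration; grades acceptable / excellent /
outstanding at 0.7 / 0.8 / 0.9).

Because no lake record is publicly deposited for this study design, the
package ships a synthetic-data generator (`generate_series()`) that
emulates a tropical reservoir record — bounded Beta marginals matching
published min/mean/max summaries, Gaussian-copula cross-correlations,
AR(1) persistence — and plants a *known* chlorophyll mechanism (a published
regression line, a published evolved rule set, or any rule you write in
the grammar) plus Gaussian noise. Every pipeline stage is therefore a
testable recovery problem.

## Worked example

The rule interpreter evaluates the published evolved rule set exactly:

```r
library(limnocast)
rule <- mechanism_hea_printed()$ruleset
eval_rule(rule, data.frame(NO3N = 0.1, Secchi = 1.0, DO = 7.0, pH = 7.4))
#> [1] 13.797
eval_rule(rule, data.frame(NO3N = 0.0, Secchi = 1.0, DO = 7.0, pH = 7.4))
#> [1] 6.753034
```

(13.797 = 96.579/7.0 via the THEN branch; 6.753 = 7 − ln|61.273/7.4 − 7|
via the ELSE branch.)

Stepwise regression recovers a planted line exactly from noise-free
synthetic data:

```r
s <- generate_series(synth_config(n = 120, seed = 9,
                                  mechanism = mechanism_mlr_printed(),
                                  noise_sd = 0))
stepwise_fit(s, limno_variables())
#> <mlr_model> chla = -11.69 +2.732*DO
```

The full comparative study (several minutes; the evolutionary search
dominates the cost):

```r
res <- compare_models(study_config(synth = synth_config(n = 400, seed = 1),
                                   seed = 1))
print(res)
#> Comparative chlorophyll-a model assessment (test set B, n = 80)
#>  model rmse    r  auc  auc_grade
#>    MLR 2.87 0.44 0.73 acceptable
#>     FL 4.19 0.24 0.67       poor
#>   RANN 3.00 0.40 0.75 acceptable
#>    HEA 2.67 0.62 0.82  excellent
```

Here the planted mechanism is the published evolved rule plus 2 µg/l
noise: the rule-discovery model clearly beats the linear baseline in all
three criteria, while the recurrent net — whose context units find no
temporal signal in the independent-noise scenario — lands beside it. See
the methods vignette (`vignettes/chlorophyll-model-comparison.Rmd`) for
why, and for every modelling assumption and default.

The numbered drivers under `analysis/` replay the study as a narrative:

```sh
Rscript analysis/01_simulate.R            # synthetic record + summary table
Rscript analysis/02_select_variables.R    # stepwise + sensitivity/backward elimination
Rscript analysis/03_recovery_experiments.R# planted-line and planted-rule recovery
Rscript analysis/04_compare_models.R      # four-model comparison -> results/study/
```

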