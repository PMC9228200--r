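# medopt

Statistical optimization of a fermentation medium for a *Bacillus*-based
biocontrol agent active against aflatoxigenic *Aspergillus flavus*. The
package implements the full dual-modelling workflow such a study runs:

1. **Screening** — one-way ANOVA and Duncan's multiple range test select the
   carbon and nitrogen sources (cellulose and urea win on activity and cost).
2. **Design** — a 4-factor, 3-level Box–Behnken design (27 runs: 24
   edge-midpoint runs plus 3 center replicates) over cellulose (5–35), urea
   (0–5), ammonium sulfate (0–5) and dipotassium phosphate (0.5–4.5 g/L).
3. **Response-surface model** — ordinary least squares on the second-degree
   polynomial

   Y = b₀ + Σᵢ bᵢXᵢ + Σᵢ<ⱼ bᵢⱼXᵢXⱼ + Σᵢ bᵢᵢXᵢ²

   with full inference (coefficient t/p values, model ANOVA, R², adjusted R²),
   where Y is the inhibition-zone diameter (mm) and Xᵢ are the component
   concentrations (g/L).
4. **ANN branch** — an autoencoder (4-neuron embedding) trained on the
   normalized 27-run table generates 10,000 synthetic rows from uniform
   [−1, 2.5] embedding samples; a 3-hidden-layer MLP predictor is trained on
   the augmented rows only and validated on the 27 held-out original runs.
5. **Comparison and optimization** — models are ranked by adjusted R²
   (1 − (1−R²)(n−1)/(n−p)), and the winning quadratic models feed a
   Derringer–Suich desirability optimization: minimize cellulose and urea,
   keep both salts in range, maximize both predicted inhibition zones, all
   with weight 3; overall desirability D is the geometric mean of the
   per-goal scores, maximized over the design box by seeded multi-start
   bounded simplex search.

Because the study's raw run-level responses are unpublished, the package
ships a synthetic-data generator anchored to the published quadratic
coefficient sets (`reference_models()`): every stage is runnable and
testable end to end, and the published summary statistics (screening ANOVA
tables, Duncan letters, predicted optimum responses, optimized composition)
are reproduced exactly where they are reproducible.

## Worked example

```r
library(medopt)

# the two published quadratic models, natural units (g/L -> mm)
m <- reference_models()
predict_response(m$SA2BSS, c(5, 0, 3.77, 0.5))
#> [1] 30.66264
predict_response(m$PA2DSS, c(5, 0, 3.77, 0.5))
#> [1] 27.83557

# a synthetic 27-run experiment on those surfaces, and a fresh fit
d   <- bbd_design(default_medium_factors(), center_replicates = 3, seed = 2024)
d   <- simulate_bbd_responses(d, noise_sd = 0.5, seed = 2024)
fit <- fit_quadratic(d, "SA2BSS")
round(c(r2 = fit$diagnostics$r2, adj_r2 = fit$diagnostics$adj_r2), 3)
#>     r2 adj_r2
#>  0.954  0.901

# desirability optimization over both models
opt <- optimize_medium(m, default_goals(),
                       data = as.matrix(d$responses), seed = 2024)
opt
#> desirability optimum (D = 0.6398 )
#>   composition (g/L): cellulose=5.00, urea=0.00, ammonium_sulfate=3.83, dipotassium_phosphate=0.50
#>   predicted responses (mm): SA2BSS=30.59, PA2DSS=27.87
```

The optimum sits at the economical corner — cellulose at its 5 g/L floor, no
urea, phosphate at its 0.5 g/L floor — with ammonium sulfate at an interior
value trading off the two isolates' responses. The predicted zones of
about 30.6 mm (SA2BSS) and 27.9 mm (PA2DSS) say the cheap medium loses
nothing in activity.

The numbered scripts under `analysis/` run the complete study narrative
(screening → design → RSM → ANN → comparison → optimization) and write
their tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

## The methods vignette

`vignettes/medium-optimization.Rmd` documents the models and their
assumptions, the synthetic-data generator and what passing tests do and do
not establish about real data, the neural-network training scheme and its
numerical choices, and the known limitations.
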