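# esfrich

Spatial regression modelling of gridded tree species richness (TSR),
for ecologists working with plot-based forest inventories aggregated to
large-area grids. The package covers the complete workflow: estimating
grid richness from unequal plot samples by a fixed-size bootstrap,
deriving the standard bioclimatic predictor set from monthly climate
series, selecting predictors with a Poisson LASSO, and fitting Poisson
generalized linear models with and without **eigenvector spatial
filtering** (ESF) to account for spatial autocorrelation, together with
the usual diagnostics (Moran's *I* with z-scores, percent deviance
explained, VIFs, paired Wilcoxon signed-rank tests).

A synthetic-data generator produces masked lattices, spatially
autocorrelated environmental fields, and plot-level species occurrence
data with realistic richness structure, so the whole pipeline runs and
is tested without any raster or inventory downloads.

## The model

Richness counts (or bootstrap mean richness) in cell *i* follow a
Poisson log-link regression

```
y_i ~ Poisson(mu_i),   log mu_i = X_i beta_x + E_i beta_k
```

where `X` holds standardized environmental predictors and `E` holds a
selected subset of **Moran eigenvectors** — eigenvectors of the doubly
centered binary contiguity matrix `(I − 11'/n) W (I − 11'/n)`. Each
eigenvector is a map pattern whose Moran's *I* equals `(n/S0) λ`, so
high-eigenvalue vectors describe smooth regional structure and
negative-eigenvalue vectors fine-grained alternation. Adding selected
eigenvectors to the mean structure absorbs spatial autocorrelation that
would otherwise contaminate residuals and coefficient tests.

Supporting machinery, all exported:

* `bootstrap_richness()` — richness of a grid as the mean over 1000
  draws of 31 plots without replacement (grids with fewer than 31 plots
  are dropped by `filter_grids()`).
* `seasonality()`, `quarter_stat()`, `energy_water()`,
  `aggregate_mean()`, `aggregate_range()`, `derive_predictors()`,
  `standardize_predictors()` — the 18-variable bioclimatic predictor
  table (PSN, TSN, MTWQ, MTCQ, MPDQ, MFDF, FA, ...).
* `fit_lasso_path()`, `cv_select()`, `run_full_and_reduced()` — Poisson
  LASSO by coordinate descent, ten-fold cross-validation, 1-SE rule.
* `fit_glm()` — Poisson IRLS with deviance, AIC, standard errors.
* `build_weights()`, `eigen_basis()`, `stepwise_esf()` — queen/rook
  contiguity, the Moran eigenvector basis, stepwise AIC eigenvector
  selection with a significance gate.
* `moran_i()`, `wilcoxon_signed_rank()`, `compare_models()`,
  `vif()` — diagnostics and model comparison.
* `run_pipeline()` — the end-to-end analysis on a synthetic scenario;
  `inst/cli/esfrich` wraps it as a shell command with subcommands
  (`simulate`, `richness`, `predictors`, `select`, `fit`, `evaluate`,
  `run-all`).

## Worked example

```r
library(esfrich)

grid  <- gen_lattice(20, 20, seed = 1)        # 400 cells of 50 km
W     <- build_weights(grid)                  # queen contiguity
basis <- eigen_basis(W)                       # Moran eigenvectors

X <- gen_env_fields(grid, basis, k = 8, spatial_mix = 0.5,
                    seed = 2, n_fields = 2, names = c("x1", "x2"))
y <- gen_richness_surface(grid, X, beta = c(0.5, -0.3),
                          gamma = 0.35 * sqrt(400) * c(1, 1, 1),
                          basis = basis, gamma_idx = c(2, 5, 9), seed = 3)

esf <- stepwise_esf(X, y, basis)
esf
#> ESF Poisson fit: 3 eigenvector(s) selected; AIC 2572 (base GLM 1.13e+04)
#>   eigenvectors: 2, 9, 5

compare_models(list(glm = esf$glm_base, esf = esf), W = W)
#> Model comparison
#>  model       aic null_deviance residual_deviance pct_explained moran_i moran_z
#>    glm 11296.442      16836.62          9121.663        45.822   0.759  29.618
#>    esf  2571.561      16836.62           390.783        97.679  -0.019  -0.657
#>  n_eigenvectors
#>              NA
#>               3
```

The planted eigenvectors {2, 5, 9} are recovered exactly and nothing
else enters; filtering raises deviance explained from 46% to 98% and
drops the residual Moran z-score from 29.6 to −0.7.

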