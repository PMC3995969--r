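# geomoran

Bayesian geostatistical Moran-curve analysis of vector count surveys.

`geomoran` is for vector ecologists and control programmes that monitor an
insect population — the motivating case is tsetse flies (*Glossina* spp.)
caught on fixed fly-rounds in Zambia — with monthly counts at georeferenced
transect stops, and want more than a smoothed abundance map: a decomposition
of the population's **net change** into fertility, density-independent
losses driven by environmental covariates, and density-dependent losses that
engage only above a threshold abundance, resolved in space and season.

## The model in brief

With `y = log10(count + 1)` at stop *s* and month *t*, losses add as
k-values on the Moran curve (the log form of the Ricker stock-recruitment
curve):

```
y[t+1] = y[t] + b − di(s,t) − dd(y[t]) + Z(s,t) + ε
```

* `b` — constant monthly log10 fertility;
* `dd(y) = tan(α°) · max(0, y − a)` — density-dependent k-value above the
  threshold `a`, with slope angle `α` (30° ≈ under-compensation);
* `di = β₁ + Xβ₂` — density-independent k-value regressed on day/night land
  surface temperature and cattle density;
* `Z` — zero-mean Gaussian field with the non-separable space-time
  correlation `exp(−Δs/φ − Δt/ρ − δ·(Δs/φ)(Δt/ρ))`;
* `ε` — iid observation error.

Candidates `(b, a, α)` on a deterministic grid (the full design is
30×30×30 = 27,000) are each scored by DIC — covariance parameters
`(φ, ρ, δ, σ²z, σ²e)` sampled by adaptive MCMC under IG/uniform priors with
the total variance integrated out — and the lowest-DIC candidate drives the
maps: a mean net-change surface plus simple kriging of the spatio-temporal
residual, seasonal averages, and a source mask (cells non-negative in all
three Zambian seasons). Leave-site-out validation reports ME/MSE on the log
scale and as "equivalent flies" (`10^ME`).

A synthetic fly-round generator with known truth (`simulate_population()`)
makes the whole pipeline testable end to end; `recovery_experiment()` runs
replicate studies and reports what is — and provably is not — recoverable
(the likelihood is invariant to `b`, so fertility is an input, not an
estimate; see the methods vignette).

## Worked example

```r
library(geomoran)

# a synthetic study emulating a 4-site fly-round survey, truth known
cfg <- synthetic_config(n_stops = rep(30, 4), sigma2_z = 0.27, sigma2_e = 0.06,
                        immigration = 0.9, y0_mean = 1.9, y0_sd = 0.3)
sim <- simulate_population(cfg, seed = 1)
tr  <- build_transitions(sim$catches, sim$covariates)

fit <- fit_candidates(
  tr,
  grid    = make_candidate_grid(5, c(0.19, 0.27), 5, c(0.259, 0.659), 5, c(10, 50)),
  control = mcmc_control(n_adapt = 400, n_keep = 600, max_rounds = 3,
                         mc_error_target = Inf, site_blocks = TRUE),
  seed = 1, strict = FALSE)
fit
#> Bayesian geostatistical Moran-curve fit
#>   selected candidate: b = 0.19 (x1.55/month), a = 0.259 (1.82 flies), alpha = 30 deg
#>   DIC = 1006.6 over 125 candidate(s); chain converged: TRUE

tidy(fit$chain)
#> # A tibble: 6 x 6
#>   term     median   mean      sd hpd_lower hpd_upper
#>   <chr>     <dbl>  <dbl>   <dbl>     <dbl>     <dbl>
#> 1 phi      1.30   1.34   0.217      1.03      1.81
#> 2 rho      1.12   1.15   0.204      0.784     1.53
#> 3 delta    0.780  0.745  0.201      0.349     0.997
#> 4 sigma2_z 0.265  0.269  0.0407     0.197     0.347
#> 5 sigma2_e 0.0650 0.0652 0.00410    0.0571    0.0739
#> 6 kappa    0.802  0.802  0.0266     0.757     0.859
```

The generating values were φ = 1.5 km, ρ = 1 month, δ = 0.8, σ²z = 0.27,
σ²e = 0.06: each 95% HPD covers its truth. α = 30° is selected exactly;
`a` is only weakly identified in this high-abundance regime and `b` is not
identified at all (its DIC column is provably flat, so the reported 0.19 is
the grid's deterministic tie-break) — the vignette derives why.

Seasonal aggregation and mapping then follow the fitted object:

```r
aggregate_net_change(fit$decomposition)
#> # A tibble: 5 x 5
#>   site        rainy cold_dry hot_dry year_mean
#>   <chr>       <dbl>    <dbl>   <dbl>     <dbl>
#> 1 s1         0.128   -0.0892 -0.251   -0.0544
#> 2 s2         0.0496   0.0972  0.291    0.133
#> 3 s3        -0.250    0.359  -0.217   -0.0194
#> 4 s4        -0.227    0.0439  0.256    0.00327
#> 5 all sites -0.0747   0.103   0.0198   0.0156

grid_cells <- make_prediction_grid(fit$geometry, cell_km = 1)
cov_cells  <- generate_covariates(cfg, points = grid_cells)  # cell-month covariates
maps <- map_net_change(fit, cov_cells)
classify_sources(maps)                    # source = non-negative in all seasons
autoplot(maps)
```

Per-site seasonal means carry the realised spatio-temporal field of this
particular year (site 2 grows, sites 1 and 3 shrink), while the all-sites
year mean (0.016) sits near the small net change a population close to
equilibrium should show.

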