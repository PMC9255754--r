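# gridsecr

Spatially explicit capture–recapture (SECR) density estimation for
grid-based small-mammal live trapping, and tools for asking the question
field programs actually face: *how much trapping effort can be cut before
density estimates degrade?*

Long-term monitoring of species such as the salt marsh harvest mouse
(*Reithrodontomys raviventris*) typically runs a fixed trap grid for a few
consecutive nights every year. Classical capture–recapture gives abundance
over an ill-defined "effective area"; SECR instead models a latent activity
centre for every animal and a detection function that decays with the
distance between centre and trap, so density `D` (animals per hectare) is
estimated directly. `gridsecr` implements the full (Poisson-n) SECR
likelihood for multi-catch traps

```
L(theta) = exp(-Lambda) * prod_i [ D * a * sum_m pi_{u_i} Pr(omega_i | X_m, theta_{u_i}) ],
Lambda   = D * a * sum_m sum_u pi_u * pdot(X_m; theta_u)
```

with the activity centre integrated over a discretised habitat mask
`{X_m}` (cell area `a`), detection functions `g(d)` of half-normal
(`HN`), negative-exponential (`EX`) or hazard-rate (`HR`) form, per-trap
competing risks `p_k = (h_k / H)(1 - exp(-H))` with `h = -log(1 - g)`,
and optional time, behavioural ("trap happy"/"trap shy") and sex-mixture
effects on `g0` and `sigma`. Maximisation is over link-scale parameters
(`log D`, `logit g0`, `log sigma`, `logit pmix`), with delta-method
standard errors and AIC model selection. The likelihood kernel is
compiled C++ (via Rcpp), so Monte Carlo design studies with hundreds of
fits are practical.

On top of the estimator sit the two design-evaluation methods used in
long-term monitoring audits:

1. **Subsampling** — delete traps (smaller `n x n` grids, checkerboard
   half-density thinning) or occasions (3-night sessions) from observed
   capture histories, refit, and compare against the full design
   (differences, percent differences, within-1-SE replication rates).
2. **Monte Carlo** — simulate populations and captures at known density
   under a candidate design, refit each replicate, and summarise relative
   bias `RB = (Dhat - D) / D` and `RMSE = sqrt(mean((Dhat - D)^2))`.

The package also ships the published 18-year annual density tables from a
Suisun Marsh (California) monitoring grid (`crescent_densities()`,
`crescent_differences()`), and a calibrated 18-session synthetic-study
generator (`default_study_scenario()`, `synth_study()`) emulating that
program.

## Worked example

```r
library(gridsecr)

traps <- build_grid(10, 10, 9.43)          # 100 traps, 9.43 m spacing
mask  <- build_mask(traps, buffer = 50)    # ~3.42 ha buffered region

pop <- simulate_population(30, mask, seed = 1)   # true D = 30 / ha
ch  <- simulate_capthist(pop, traps, n_occasions = 4,
                         params = list(F = detection_params(0.32, 7, "EX"),
                                       M = detection_params(0.16, 9, "EX")),
                         seed = 2)

fit <- fit_secr(ch, traps, build_mask(traps, 50, 10),
                secr_model("EX", g0_effects = "sex", sigma_effects = "sex"))
fit
#> SECR fit (EX detection)
#>   n = 41 individuals, 86 records, 44 spatial recaptures, S = 4
#>   D = 30.45 / ha (SE 5.40)
#>   pmix(F) = 0.345 (SE 0.084)
#>   logLik = -375.049, k = 6, AIC = 762.098
#>   converged: TRUE
```

The density estimate (30.5 ± 5.4 mice/ha) brackets the simulated truth of
30/ha; `pmix` is the estimated proportion of females, and `glance(fit)`
/ `tidy(fit)` return the same numbers as tibbles. Evaluating a reduced
design takes one call per scenario:

```r
truth <- tibble::tibble(session = "demo", D = 30, g0_F = 0.32, g0_M = 0.16,
                        sigma_F = 7, sigma_M = 9, pmix = 0.5)
mc <- monte_carlo_eval(truth, design_scenario("9x9", "n_by_n", n = 9),
                       n_reps = 20, seed = 1)
glance(mc)
#> # A tibble: 1 x 7
#>   scenario true_D mean_RB  RMSE sd_RB n_used n_excluded
#>   <chr>     <dbl>   <dbl> <dbl> <dbl>  <int>      <int>
#> 1 9x9          30 -0.0513  5.62 0.185     20          0
```

Mean relative bias near zero says the 81-trap design still recovers the
true density; `RMSE` and `sd_RB` quantify the precision cost, and any
non-converged replicates are counted in `n_excluded`, never silently
dropped.

## Vignette

`vignettes/secr-design-evaluation.Rmd` documents the model, the
likelihood and its numerical choices, the calibration of the synthetic
study generator, and known limitations (notably buffer behaviour under
negative-exponential detection).
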