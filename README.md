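# snowsecr

Bayesian spatially explicit capture–recapture (SECR) for camera-trap
density estimation of rare, wide-ranging carnivores, built around the
snow-leopard survey design: a systematic trap grid sampled daily, few
individuals, and very few recaptures.  The package covers the full
workflow — capture-record filtering, capture-history construction, the
data-augmented SECR sampler, an estimator-evaluation simulation study,
and a density-surface covariate analysis (kriged sign indices +
negative-binomial regression with AIC model averaging) — plus a
synthetic-scenario generator so everything runs without field data.

## The model

Individual `i` has a latent activity centre `s_i` on a discrete state
space: a regular pixel grid (default 1.96 km² pixels) buffered around the
trap array (default 24 km) with unsuitable habitat masked out.  Its
encounter rate at trap `j` on one occasion is

    lambda_ij = lam0 * exp(-d_ij^2 / (2 sigma^2))     (half-normal)
    lambda_ij = lam0 * exp(-d_ij / sigma)             (negative exponential)

and capture is Bernoulli with the complementary-log-log link
`p_ij = 1 - exp(-lambda_ij)`.  Unknown population size is handled by
parameter-expanded data augmentation: `M = n + 200` pseudo-individuals
carry inclusion flags `z_i ~ Bernoulli(psi)`, so `N = sum(z)` and density
is `N / A` over the suitable area `A`.  Sampling is Metropolis-within-
Gibbs: `z` and `psi` (conjugate Beta) by Gibbs, activity centres by a
radius-restricted pixel walk, `lam0` and `sigma` by adaptive log-scale
random walks (adaptation frozen after burn-in).

Downstream, per-pixel posterior mean counts of activity centres are the
response in a negative-binomial (NB-2, log link) regression on
standardised covariates — prey-sign and livestock-sign indices kriged
from transect surveys, and slope SD from a DEM — ranked over all
covariate subsets by AIC with Akaike-weight model averaging.

## Worked example

```r
library(snowsecr)
scn <- generate_scenario(seed = 11)     # 60 traps, 93 occasions, paper-like truth
scn
#> scenario (seed 11): 60 traps, 93 occasions, 1688 suitable pixels (3308 km^2)
#>   N = 101, detected 20, captures 52

fit <- fit_secr(scn$history, scn$traps, scn$state_space,
                secr_config(iterations = 20000, burn_in = 5000, seed = 42))
summary_table(fit)
#>   parameter       mean        sd   hpd_lower   hpd_upper
#> 1   density    2.91      0.76       1.51        4.44
#> 2     sigma 4196.10    632.97    3141.34     5430.51
#> 3      lam0    0.0036    0.0009     0.0020      0.0053
#> 4       psi    0.44      0.12       0.22        0.68
#> 5         N   96.30     25.24      50         147

bayesian_p_value(fit)        # 0.46 -- no evidence of misfit
geweke(fit$chains$density)$z # 0.04 -- converged by the |z| < 1.64 rule
mmdm(scn$history, scn$traps)
#> movement_summary: MMDM 8.18 km (sd 3.51, se 1.06, n = 11); half-MMDM 4.09 km
```

The generating truth (density 3.31/100 km², sigma 4785 m, lam0 0.0036)
sits inside every 95% HPD interval: with 20 detected individuals the
data are weakly informative, which is exactly the sampling situation the
evaluation module quantifies (`run_simulation_study()` /
`summarize_study()` report RMSE of the posterior mean/mode/median and
95% HPD coverage for density and psi).

Density is reported per 100 km²; `density[t] * area / 100 = N[t]` holds
for every draw, and the pixel map from `pixel_density_map()` totals the
posterior mean of N exactly.

## Command line

```sh
Rscript -e 'snowsecr::secr_cli()' simulate --seed 7 --out run1
Rscript -e 'snowsecr::secr_cli()' fit --captures run1/captures.csv \
  --traps run1/trap_deployment.csv --statespace run1/state_space.csv \
  --iterations 60000 --burnin 10000 --out run1/fit
Rscript -e 'snowsecr::secr_cli()' report --out run1/fit
```

Every command writes a `manifest.json` with its effective settings.

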