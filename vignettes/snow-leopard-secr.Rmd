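---
title: "Camera-trap density estimation with data-augmented Bayesian SECR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-trap density estimation with data-augmented Bayesian SECR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the defaults and why they are what they are, what the
synthetic world does and does not emulate, and the numerical choices
that were genuinely open.

## The estimation problem

Large solitary carnivores occur at densities of a few animals per 100
km², range over areas far larger than any feasible camera grid, and are
recaptured rarely.  Naive (non-spatial) capture–recapture then needs an
ad hoc "effective trapping area" to convert abundance into density, and
the choice dominates the estimate.  Spatially explicit capture–recapture
(SECR) removes that arbitrariness by modelling *where* each individual
lives: a latent activity centre whose distance to each trap governs its
encounter rate.  Density follows directly as the number of activity
centres per unit of suitable habitat.

## Model and sampler

For individual `i` with activity centre `s_i` (a pixel of the state
space) and trap `j` at distance `d_ij`, per-occasion captures are
Bernoulli with

* encounter rate `lambda_ij = lam0 * k(d_ij)`, `k` half-normal
  `exp(-d^2/2sigma^2)` (default) or negative-exponential `exp(-d/sigma)`;
* capture probability `p_ij = 1 - exp(-lambda_ij)` (cloglog link).

Two consequences are used heavily in the implementation: the likelihood
depends on the data only through per-trap capture counts and per-trap
effort (occasions are exchangeable given `s_i`), and
`log(1 - p_ij) = -lambda_ij`, so the all-zero-history log-likelihood is
the linear form `-lam0 * H(s)` with `H(s)` the effort-weighted kernel
mass.  Each sampler update therefore touches only the pixels actually
occupied or proposed, never the full grid.

Unknown `N` is handled by data augmentation: `M = n_observed + 200`
histories, inclusion flags `z_i ~ Bernoulli(psi)`, `psi ~ Uniform(0,1)`.
The augmentation add-on of 200 reflects the reference configuration for
this survey scale; `psi * M` then matches the posterior mean of `N`
(e.g. 0.4986 x 220 = 109.7), which the tests assert as bookkeeping.

Updates per iteration:

1. activity centres: for excluded augmented individuals, an exact prior
   (uniform) Gibbs draw; for included ones, a Metropolis move uniform on
   suitable pixels within a 5-pixel radius, Hastings-corrected with the
   per-pixel neighbour counts so edge pixels are handled exactly;
2. `z`: Bernoulli full conditional (only augmented rows; observed rows
   are structurally `z = 1`);
3. `psi`: conjugate `Beta(1 + sum z, 1 + M - sum z)`;
4. `lam0`, `sigma`: log-scale random-walk Metropolis under uniform
   priors on `[0, lam0_max]` and `[0, sigma_max]` (defaults 5 and five
   times the array diagonal).  Proposal scales adapt toward a 0.44
   acceptance rate during burn-in only and are frozen afterwards, so the
   post-burn-in chain is a fixed, valid Markov chain.

A trap-specific behavioural response is deliberately absent from the
default model (the reference analysis fixed it at zero); the detection
kinds are the half-normal, negative-exponential and non-spatial family.

Correctness of the sampler is not taken on faith: on a one-trap,
one-pixel toy problem the test suite compares the MCMC posterior of
`lam0` against brute-force numerical integration of the augmented
likelihood over a `(lam0, psi)` grid, and the `psi` step is checked
against its closed-form Beta posterior on data that freeze `z`.

### Defaults that matter

| parameter | default | units | why |
|---|---|---|---|
| buffer | 24 | km | density stabilises before this width for ~5 km movement scales; larger buffers only add far pixels with negligible detection mass |
| pixel area | 1.96 | km² | fine relative to `sigma` (~4.8 km), coarse enough to keep the grid ~1,700 pixels |
| iterations / burn-in / thin | 60,000 / 10,000 / 1 | — | reference long-run configuration; the evaluation preset uses 8,000/2,000 |
| augmentation add-on | 200 | individuals | ceiling comfortably above plausible `N` (~110); `psi` near 0.5 keeps the ceiling non-binding |
| dedup window | 6 | h | "a few hours" is unspecified in field protocols; configurable, every discard logged |
| centre-proposal radius | 5 | pixels | local moves mix the ~100 included centres well at this grid resolution |

## State space

The pixel lattice is anchored on the trap-array centre, so enlarging the
buffer extends the grid without shifting existing pixel centres
(monotonicity is a tested invariant), and a pixel whose footprint
contains a trap is always kept, so the vanishing-buffer limit retains
exactly the trap pixels.  Habitat suitability is an input mask (the
field delineation of reserve boundaries, villages and roads is not
reproducible in code); `buffer_sensitivity()` refits over increasing
buffers to check stabilisation.

## The synthetic world

`generate_scenario()` is a stated world, not a tuning knob: 20 cells of
4x4 km with 3 traps each (>= 1 km spacing), 93 daily occasions, a 24 km
buffer with 1.96 km² pixels, half-normal detection with
`sigma = 4784.7` m and `lam0 = 0.0036`, density 3.3147 per 100 km², and
`psi = 0.4986` at `M = 220`.  Density and `psi` jointly imply a suitable
area of `100 * M * psi / density ~ 3310` km²; since the real habitat mask
is unpublished, the generator keeps the pixels nearest the trap array up
to that area — a synthetic stand-in that makes the two parameterisations
of abundance consistent.  Sign surveys are Bernoulli segment detections
driven through a logit link by Gaussian random fields with exponential
covariance (range 6 km), and the DEM is smoothed Gaussian noise at 90 m
resolution.

What the generator does **not** emulate: staggered camera deployment
(all 60 x 93 trap-days are active, against ~2,900 in the emulated
survey, so synthetic datasets detect somewhat more individuals),
topography-forced trap-spacing violations, unmodelled heterogeneity
(sex, behaviour), and non-closure.  A green end-to-end test therefore
establishes that the estimator recovers its own generating model at the
survey's scale — not that any particular field estimate is right.

## Evaluation study

`run_simulation_study()` simulates datasets at a known truth, refits
each, and tabulates the mean, RMSE and 95% HPD coverage of the posterior
mean, mode and median for density and `psi`.  Per-dataset seeds derive
from the master seed by a counter-based linear-congruential step, so
studies are reproducible and order-independent, and zero-detection
datasets are logged and skipped rather than silently dropped.  The
headline configuration is 100 datasets at 30,000 iterations (CPU-hours);
the shipped CI preset (10 datasets, 8,000 iterations, 7.84 km² pixels)
runs in ~2 minutes and is what the acceptance test asserts: coverage
within the binomial band around 95% for n = 10 and RMSE within twice the
reference values.

## Covariate analysis

The regression response is the per-pixel posterior mean count of
activity centres (`pixel_mean_abundance()`), a non-integer; the NB-2
likelihood extends continuously through its gamma-function form and
`MASS::glm.nb` is used as is (with a Poisson fallback at the
`theta -> Inf` boundary).  `K` counts intercept + slopes + `theta`, so a
2-covariate model has `K = 4`, matching the reference ranking table.
The model set is the 7 non-empty covariate subsets; the intercept-only
model can be added with a flag but is excluded by default to mirror the
reference set.  The chi-square goodness-of-fit takes its degrees of
freedom explicitly because `n - p` conventions differ in how they count
`theta`.

Kriging choices, since the original interpolation ran through a GIS
wizard whose settings are unknown: exponential variogram by default
(spherical available), weighted-least-squares fit to a 12-bin empirical
semivariogram, log transform as `log(x + c)` with `c` half the smallest
positive observation (zero-sign cells occur), and lognormal
bias-corrected back-transformation.  Exact interpolation at zero nugget
and the hand-solved 3-point system are test oracles; a constant field
predicting itself everywhere doubles as the weights-sum-to-one check.

## Numerical choices and edge cases

* **HPD**: shortest window over the sorted draws at 95%.  **Mode**: the
  midpoint of the fullest histogram bin with Freedman–Diaconis widths —
  continuous chains have no unique mode, and this matches how modal
  summaries are tabulated for such output.  Constant chains return the
  constant with zero-width intervals.
* **Geweke**: 10%/50% windows, variance via AR-fit spectral density at
  zero; zero-variance windows return a flagged NA rather than a number.
* **Posterior-predictive fit**: Freeman–Tukey discrepancy on individual
  encounter totals over all included individuals, computed inside the
  sampler every 20th saved draw; `p = Pr(T_rep >= T_obs)`, so a chain of
  exact ties gives `p = 1` by convention.
* **MMDM**: only individuals captured at >= 2 distinct traps contribute;
  with none, the result is flagged undefined rather than zero.  Both the
  SD and SD/sqrt(n) of the maxima are reported because "SE" is used for
  either in field reports.  `half_MMDM = MMDM/2` holds identically.
* **Non-spatial model**: the same augmentation machinery with constant
  per-trap-day `p`; it reports density only against a user-supplied
  effective area, since the model itself has none.
* Per-pixel occupancy is accumulated as a running sum over saved
  iterations (the full iterations x pixels matrix would be ~0.7 GB at
  reference settings); the stored mean still satisfies
  `sum(pixel_mean) = mean(N)` exactly.
* All stochastic entry points require an explicit seed; nothing consumes
  ambient RNG state.

## Known limitations

* The sampler is plain R (vectorised over pixels and individuals);
  ~60,000 iterations on the reference design take a couple of minutes.
  That is fine for single fits and the CI-scale study, but the full
  100-dataset study is an overnight job on one core.
* Covariates cannot enter the SECR intensity itself (as in the reference
  analysis, density-surface effects are explored post hoc); occupancy-
  style detection correction of the sign surveys is out of scope.
* Distances are Euclidean on projected coordinates — adequate for a
  ~500 km² study area, wrong for unprojected or continental extents.
* The habitat mask is an input; no GIS operations beyond point-in-mask
  flags are provided.
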