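# detection model, simulator, sampler, summaries, diagnostics

test_that("detection functions hit their analytic anchors", {
  hn <- detection_params(0.0036, 4784.72, "half_normal")
  ne <- detection_params(0.0127, 4138.54, "neg_exponential")
  ns <- detection_params(0.0005, kind = "non_spatial")
  expect_equal(detection_rate(0, hn), 0.0036)
  expect_equal(detection_rate(0, ne), 0.0127)
  expect_equal(detection_rate(hn$sigma, hn), 0.0036 * exp(-0.5))
  expect_equal(detection_rate(ne$sigma, ne), 0.0127 * exp(-1))
  expect_equal(detection_rate(c(0, 1e5), ns), c(0.0005, 0.0005))
  expect_error(detection_rate(-1, hn), ">= 0")
  expect_error(detection_params(-0.1, 100), "lam0")
  expect_error(detection_params(0.1, -5), "sigma")

  expect_equal(encounter_prob(0), 0)
  expect_equal(encounter_prob(1e9), 1)
  expect_equal(encounter_prob(0.0036), 1 - exp(-0.0036))
  expect_error(encounter_prob(-0.1))
})

test_that("posterior_summary: HPD, mode and degenerate chains", {
  # uniform order statistics: HPD width 0.95 within one sample step
  ch <- (1:1000) / 1000
  ps <- posterior_summary(ch)
  expect_lt(abs((ps$hpd_upper - ps$hpd_lower) - 0.95), 0.002)
  # constant chain: every summary equals the constant
  pc <- posterior_summary(rep(3.5, 200))
  expect_equal(unlist(pc), c(mean = 3.5, sd = 0, median = 3.5, mode = 3.5,
                             hpd_lower = 3.5, hpd_upper = 3.5))
  # standard normal: HPD approximates (-1.96, 1.96)
  set.seed(42)
  ps <- posterior_summary(rnorm(1e5))
  expect_lt(abs(ps$hpd_lower + 1.96), 0.05)
  expect_lt(abs(ps$hpd_upper - 1.96), 0.05)
  expect_lt(abs(ps$mode), 0.2)   # mode is binned, so coarser than mean
})

test_that("geweke flags trending chains and passes iid ones", {
  set.seed(1)
  flags <- replicate(40, abs(geweke(rnorm(2000))$z) < 1.64)
  expect_gte(mean(flags), 0.7)    # nominal ~90%
  # strong linear drift dominates the noise
  drift <- seq(0, 50, length.out = 2000) + rnorm(2000)
  expect_gt(abs(geweke(drift)$z), 1.64)
  # identical windows give z exactly 0
  x <- rep(c(1, 2), 500)
  expect_equal(geweke(c(x, x))$z, 0, tolerance = 1e-8)
  expect_error(geweke(rnorm(50)), "too short")
})

test_that("simulator limits: no signal, flat signal, determinism", {
  d <- small_design()
  truth0 <- list(params = detection_params(0, 2000), density = 3)
  s0 <- simulate_secr(truth0, d$traps, d$ss, seed = 1)
  expect_null(s0$history)
  expect_gt(s0$latent$N, 0)

  # same seed -> identical bundle; different seed -> different
  truth <- list(params = detection_params(0.05, 2500), density = 5)
  a <- simulate_secr(truth, d$traps, d$ss, seed = 9)
  b <- simulate_secr(truth, d$traps, d$ss, seed = 9)
  c <- simulate_secr(truth, d$traps, d$ss, seed = 10)
  expect_identical(a$history$y, b$history$y)
  expect_false(identical(a$history$y, c$history$y))
  expect_error(simulate_secr(truth, d$traps, d$ss), "seed")

  # inconsistent psi and density is a config error
  area <- suitable_area_km2(d$ss)
  bad <- list(params = detection_params(0.05, 2500), density = 5,
              psi = 0.9, M = 200)
  expect_error(simulate_secr(bad, d$traps, d$ss, seed = 1), "different")
})

test_that("simulated capture totals match the expectation oracle", {
  # E[total captures] by direct summation over the pixel grid: centres are
  # uniform on suitable pixels, so E = N * mean_g sum_j K_j p(d_gj)
  d <- small_design(n_occasions = 20)
  params <- detection_params(0.05, 2000)
  truth <- list(params = params, density = 8)
  area <- suitable_area_km2(d$ss)
  N <- round(8 * area / 100)
  Kj <- rowSums(d$traps$activity)
  D <- sqrt(outer(d$ss$x, d$traps$x, "-")^2 + outer(d$ss$y, d$traps$y, "-")^2)
  P <- matrix(encounter_prob(detection_rate(as.vector(D), params)), nrow(D))
  expected <- N * mean(drop(P %*% Kj))
  tot <- vapply(1:300, function(s) {
    sim <- simulate_secr(truth, d$traps, d$ss, seed = 1000 + s)
    if (is.null(sim$history)) 0 else sum(sim$history$y)
  }, numeric(1))
  # within 4 standard errors of the Monte-Carlo mean
  expect_lt(abs(mean(tot) - expected), 4 * sd(tot) / sqrt(length(tot)))
})

test_that("sampler is deterministic and respects augmentation algebra", {
  d <- small_design(n_occasions = 25)
  truth <- list(params = detection_params(0.06, 2200), density = 8)
  sim <- simulate_secr(truth, d$traps, d$ss, seed = 21)
  cfg <- secr_config(iterations = 1200, burn_in = 300, M_add = 60, seed = 5)
  f1 <- fit_secr(sim$history, d$traps, d$ss, cfg)
  f2 <- fit_secr(sim$history, d$traps, d$ss, cfg)
  expect_identical(f1$chains, f2$chains)       # same seed, same chains
  expect_error(fit_secr(sim$history, d$traps, d$ss,
                        secr_config(iterations = 200, burn_in = 50)),
               "seed")

  ch <- f1$chains
  M <- f1$settings$M
  area <- suitable_area_km2(d$ss)
  # exact algebra: density[t] * area / 100 = N[t] at every iteration
  expect_equal(ch$density * area / 100, ch$N, tolerance = 1e-12)
  # N is an integer in [n observed, M]
  expect_true(all(ch$N == round(ch$N)))
  expect_true(all(ch$N >= sim$history$n_individuals & ch$N <= M))
  # psi-Gibbs conjugacy: E[psi | N] = (1 + N)/(M + 2) draw by draw, so the
  # chain means must agree within Monte-Carlo error
  expect_lt(abs(mean(ch$psi) - (1 + mean(ch$N)) / (M + 2)),
            4 * sd(ch$psi) / sqrt(50))
  # pixel map totals the posterior mean of N to machine precision
  expect_equal(sum(f1$pixel_mean), mean(ch$N), tolerance = 1e-12)
  map <- pixel_density_map(f1)
  expect_equal(sum(map$value), mean(ch$N), tolerance = 1e-12)
  expect_true(all(map$value[!map$suitable] == 0))
})

test_that("psi Gibbs matches the closed-form Beta on fixed z", {
  # freeze the inclusion vector by making detection certain: every
  # included individual is seen, so N sticks at n observed + the posterior
  # over psi must be Beta(1 + N, 1 + M - N)
  tr <- trap_array("T1", 0, 0, n_occasions = 40)
  # one pixel exactly at the trap: distance 0, so p = 1 - exp(-lam0)
  ss0 <- structure(list(x = 0, y = 0, suitable = TRUE,
                        pixel_area_km2 = 0.01, buffer_m = 50,
                        spacing_m = 100), class = "state_space")
  truth <- list(params = detection_params(3, 50), psi = 0.5, M = 30)
  sim <- simulate_secr(truth, tr, ss0, seed = 2)
  cfg <- secr_config(iterations = 4000, burn_in = 500, M_add = 30, seed = 3)
  fit <- fit_secr(sim$history, tr, ss0, cfg)
  n <- sim$history$n_individuals
  M <- fit$settings$M
  expect_true(all(fit$chains$N == n))          # z frozen by the data
  a <- 1 + n; b <- 1 + M - n
  expect_lt(abs(mean(fit$chains$psi) - a / (a + b)), 0.02)
  expect_lt(abs(sd(fit$chains$psi) -
                  sqrt(a * b / ((a + b)^2 * (a + b + 1)))), 0.01)
})

test_that("toy posterior matches brute-force numerical integration", {
  # 1 trap, 1 suitable pixel at distance ~0: p = 1 - exp(-lam0).  The
  # marginal posterior of lam0 integrates over psi and the number of
  # included all-zero rows analytically on a grid -- an oracle fully
  # independent of the MCMC path.
  tr <- trap_array("T1", 0, 0, n_occasions = 15)
  ss0 <- structure(list(x = 0, y = 0, suitable = TRUE,
                        pixel_area_km2 = 0.01, buffer_m = 50,
                        spacing_m = 100), class = "state_space")
  expect_equal(length(ss0$x), 1)
  set.seed(8)
  K <- 15; n <- 4
  yv <- rbinom(n, K, 0.35)
  yv[yv == 0] <- 1
  y <- array(0L, dim = c(n, 1, K))
  for (i in seq_len(n)) y[i, 1, seq_len(yv[i])] <- 1L
  h <- structure(list(y = y, individual_id = paste0("i", 1:n),
                      n_individuals = n, n_traps = 1, n_occasions = K),
                 class = "capture_history")
  M_add <- 8; M <- n + M_add
  lam0_max <- 5

  # oracle: p(lam0 | y) on a grid; psi integrated by quadrature
  lgrid <- seq(1e-4, lam0_max, length.out = 400)
  pgrid <- seq(1e-4, 1 - 1e-4, length.out = 400)
  post <- vapply(lgrid, function(l0) {
    p <- 1 - exp(-l0)
    ll_obs <- sum(yv * log(p) + (K - yv) * log(1 - p))
    # each augmented row contributes psi*(1-p)^K + (1-psi)
    mean(exp(ll_obs + n * log(pgrid) +
               M_add * log(pgrid * (1 - p)^K + (1 - pgrid))))
  }, numeric(1))
  post <- post / sum(post)
  oracle_mean <- sum(lgrid * post)

  cfg <- secr_config(iterations = 20000, burn_in = 2000, M_add = M_add,
                     lam0_max = lam0_max, seed = 4)
  fit <- fit_secr(h, tr, ss0, cfg)
  expect_lt(abs(mean(fit$chains$lam0) - oracle_mean),
            0.05 * oracle_mean + 0.01)
})

test_that("posterior-predictive p-value honours the tie convention", {
  fake <- structure(list(pp = list(T_obs = c(1, 2, 3), T_rep = c(1, 2, 3))),
                    class = "secr_fit")
  expect_equal(bayesian_p_value(fake), 1)     # >= convention on exact ties
  fake$pp$T_rep <- c(0.5, 2.5, 10)
  expect_equal(bayesian_p_value(fake), 2 / 3)
})

test_that("non-spatial model: recovery, limits, and the shape contract", {
  # constant-p data: N recovered within the 95% HPD
  set.seed(12)
  N_true <- 40; K <- 10; J <- 6; p <- 0.1
  y <- array(rbinom(N_true * J * K, 1, p / J), dim = c(N_true, J, K))
  det <- which(apply(y, 1, sum) > 0)
  h <- structure(list(y = y[det, , , drop = FALSE],
                      individual_id = paste0("i", det),
                      n_individuals = length(det), n_traps = J,
                      n_occasions = K),
                 class = "capture_history")
  cfg <- secr_config(iterations = 6000, burn_in = 1000, M_add = 60, seed = 2)
  fit <- fit_nonspatial(h, cfg, effective_area_km2 = 100)
  ps <- posterior_summary(fit$chains$N)
  expect_gte(N_true, ps$hpd_lower * 0.9)
  expect_lte(N_true, ps$hpd_upper * 1.1)
  # shape contract: sigma absent, density present when an area is given
  expect_true(all(is.na(fit$chains$sigma)))
  expect_false(any(is.na(fit$chains$density)))
  expect_true(all(is.na(fit_nonspatial(h, cfg)$chains$density)))

  # near-certain detection concentrates N at the observed count
  y2 <- array(1L, dim = c(15, 2, 25))
  h2 <- structure(list(y = y2, individual_id = paste0("i", 1:15),
                       n_individuals = 15, n_traps = 2, n_occasions = 25),
                  class = "capture_history")
  f2 <- fit_nonspatial(h2, secr_config(iterations = 3000, burn_in = 500,
                                       M_add = 40, seed = 6))
  expect_equal(unname(stats::quantile(f2$chains$N, 0.95)), 15)
})
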