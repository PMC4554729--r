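# Data-augmented Bayesian SECR: detection models, simulator,
# Metropolis-within-Gibbs sampler, posterior summaries, diagnostics.
#
# Model: individual i has a latent activity centre s_i on the suitable
# pixels of the state space and a latent inclusion flag z_i ~ Bern(psi).
# Encounter rate at trap j is lambda_ij = lam0 * k(d_ij) with k the
# half-normal exp(-d^2/2sigma^2) or negative-exponential exp(-d/sigma)
# kernel; per-occasion capture is Bernoulli with the complementary-log-log
# link p = 1 - exp(-lambda).  Because p is constant over occasions the
# likelihood depends on the data only through per-trap capture counts and
# per-trap effort (active occasions), and log(1-p) = -lambda, which the
# sampler exploits throughout.

#' Detection-function parameters
#' @param lam0 baseline encounter rate per occasion (at distance 0).
#' @param sigma spatial scale in metres (ignored for `non_spatial`).
#' @param kind one of `"half_normal"`, `"neg_exponential"`, `"non_spatial"`.
#' @export
detection_params <- function(lam0, sigma = NULL,
                             kind = c("half_normal", "neg_exponential",
                                      "non_spatial")) {
  kind <- match.arg(kind)
  if (lam0 < 0) stop("lam0 must be >= 0")
  if (kind != "non_spatial") {
    if (is.null(sigma) || sigma <= 0) stop("sigma must be > 0 for spatial kinds")
  }
  structure(list(lam0 = lam0, sigma = sigma, kind = kind),
            class = "detection_params")
}

#' Expected encounter rate at distance d
#' @param d nonnegative distance(s), metres.
#' @param params a [detection_params].
#' @return expected encounter rate per occasion.
#' @export
detection_rate <- function(d, params) {
  if (any(d < 0)) stop("distance must be >= 0")
  switch(params$kind,
         half_normal = params$lam0 * exp(-d^2 / (2 * params$sigma^2)),
         neg_exponential = params$lam0 * exp(-d / params$sigma),
         non_spatial = rep(params$lam0, length(d)))
}

#' Per-occasion capture probability from an encounter rate
#'
#' Complementary-log-log link `p = 1 - exp(-rate)`.
#' @param rate nonnegative encounter rate(s).
#' @export
encounter_prob <- function(rate) {
  if (any(rate < 0)) stop("rate must be >= 0")
  -expm1(-rate)
}

#' MCMC settings for the SECR sampler
#'
#' Defaults follow the standard long-run configuration for this model
#' class: 60,000 iterations, burn-in 10,000, thinning 1, and augmentation
#' of 200 all-zero histories on top of the observed individuals.
#'
#' @param iterations total MCMC iterations (including burn-in).
#' @param burn_in discarded initial iterations.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param M_add number of all-zero augmented histories (M = n observed +
#'   `M_add`).
#' @param kind detection kind, `"half_normal"` or `"neg_exponential"`.
#' @param lam0_max,sigma_max upper bounds of the uniform priors; a NULL
#'   `sigma_max` defaults to 5 x the trap-array diagonal at fit time.
#' @param prop_lam0,prop_sigma initial log-scale random-walk SDs; adapted
#'   during burn-in only, frozen afterwards.
#' @param s_radius_pix activity-centre proposal radius in pixel widths.
#' @param pp_every compute the posterior-predictive discrepancy every this
#'   many saved iterations.
#' @param seed integer RNG seed (required: no global RNG state is used).
#' @export
secr_config <- function(iterations = 60000, burn_in = 10000, thin = 1,
                        M_add = 200, kind = c("half_normal",
                                              "neg_exponential"),
                        lam0_max = 5, sigma_max = NULL,
                        prop_lam0 = 0.2, prop_sigma = 0.2,
                        s_radius_pix = 5, pp_every = 20, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1, M_add > 0)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 M_add = M_add, kind = kind, lam0_max = lam0_max,
                 sigma_max = sigma_max, prop_lam0 = prop_lam0,
                 prop_sigma = prop_sigma, s_radius_pix = s_radius_pix,
                 pp_every = pp_every, seed = seed),
            class = "secr_config")
}

# kernel matrix rows for pixel indices `rows` (into the suitable set)
.kern_rows <- function(env, rows, sigma) {
  if (env$kind == "half_normal") {
    exp(env$D2[rows, , drop = FALSE] / (-2 * sigma^2))
  } else {
    exp(env$D[rows, , drop = FALSE] / (-sigma))
  }
}

# H(g) = sum_j K_j k(d_gj): the "effort-weighted kernel mass" whose
# product with lam0 is minus the all-zero-history log-likelihood
.H_at <- function(env, rows, sigma) {
  drop(.kern_rows(env, rows, sigma) %*% env$Kj)
}

# observed-individual cross terms sum_{j: y>0} y (log p + lambda),
# for the pixel of each observed individual
.cross_at <- function(env, pix_of_obs, lam0, sigma) {
  g <- pix_of_obs[env$obs_i]
  kv <- if (env$kind == "half_normal") {
    exp(env$D2[cbind(g, env$obs_j)] / (-2 * sigma^2))
  } else {
    exp(env$D[cbind(g, env$obs_j)] / (-sigma))
  }
  lam <- lam0 * kv
  term <- env$obs_y * (log(-expm1(-lam)) + lam)
  drop(rowsum(term, env$obs_i, reorder = TRUE))
}

# CSR neighbour structure for the activity-centre proposal
.build_neighbours <- function(sx, sy, spacing, radius_pix) {
  S <- length(sx)
  r2 <- (radius_pix * spacing * 1.0001)^2
  cx <- round((sx - min(sx)) / spacing)
  cy <- round((sy - min(sy)) / spacing)
  ord <- order(cy, cx)
  idx <- vector("list", S)
  for (g in seq_len(S)) {
    cand <- which(abs(cx - cx[g]) <= radius_pix & abs(cy - cy[g]) <= radius_pix)
    cand <- cand[cand != g]
    keep <- (sx[cand] - sx[g])^2 + (sy[cand] - sy[g])^2 <= r2
    idx[[g]] <- cand[keep]
  }
  nn <- lengths(idx)
  list(idx = unlist(idx, use.names = FALSE),
       ptr = c(0L, cumsum(nn)), n = nn)
}

#' Fit the data-augmented Bayesian SECR model
#'
#' Metropolis-within-Gibbs sampler: `z_i` from its Bernoulli full
#' conditional, `psi` from the conjugate Beta(1 + sum z, 1 + M - sum z),
#' activity centres by Metropolis over suitable pixels (uniform proposal
#' within a radius, Hastings-corrected at edges), and `lam0`, `sigma` by
#' log-scale random-walk Metropolis under uniform priors.  Proposal scales
#' adapt during burn-in only.
#'
#' @param history a `capture_history` (every individual has >= 1 capture).
#' @param traps the matching [trap_array].
#' @param state_space a `state_space` with >= 1 suitable pixel.
#' @param config a [secr_config()]; `config$seed` must be set.
#' @return object of class `secr_fit` with elements `chains` (data.frame
#'   `lam0`, `sigma`, `psi`, `N`, `density` per 100 km^2), `pixel_mean`
#'   (posterior mean count of activity centres per suitable pixel),
#'   `pp` (posterior-predictive Freeman-Tukey discrepancies), `accept`
#'   (acceptance rates), `settings`, and the inputs needed for maps.
#' @export
fit_secr <- function(history, traps, state_space, config = secr_config()) {
  stopifnot(inherits(history, "capture_history"),
            inherits(traps, "trap_array"),
            inherits(state_space, "state_space"))
  if (is.null(config$seed)) stop("config$seed must be set (no global RNG state)")
  set.seed(config$seed)

  y2 <- apply(history$y, c(1, 2), sum)     # individuals x traps counts
  n_obs <- nrow(y2)
  if (any(rowSums(y2) == 0)) stop("observed individual with zero captures")
  M <- n_obs + config$M_add
  Kj <- rowSums(traps$activity)

  suit <- which(state_space$suitable)
  S <- length(suit)
  if (S < 1) stop("state space has no suitable pixel")
  sx <- state_space$x[suit]; sy <- state_space$y[suit]
  area <- suitable_area_km2(state_space)

  env <- new.env(parent = emptyenv())
  env$kind <- config$kind
  env$Kj <- Kj
  env$D2 <- outer(sx, traps$x, "-")^2 + outer(sy, traps$y, "-")^2
  if (config$kind == "neg_exponential") env$D <- sqrt(env$D2)
  nz <- which(y2 > 0, arr.ind = TRUE)
  env$obs_i <- nz[, 1]; env$obs_j <- nz[, 2]; env$obs_y <- y2[nz]

  sigma_max <- config$sigma_max
  if (is.null(sigma_max)) {
    diag_t <- sqrt(diff(range(traps$x))^2 + diff(range(traps$y))^2)
    diag_s <- sqrt(diff(range(sx))^2 + diff(range(sy))^2)
    # single-trap/single-pixel designs have zero diagonals; fall back to
    # the grid spacing so the prior support stays non-degenerate
    sigma_max <- 5 * max(diag_t, diag_s, state_space$spacing_m)
  }

  nb <- .build_neighbours(sx, sy, state_space$spacing_m, config$s_radius_pix)

  # --- initialisation ---------------------------------------------------
  lam0 <- min(max(sum(y2) / (n_obs * sum(Kj)) * 2, 1e-4), config$lam0_max / 2)
  sigma <- min(state_space$spacing_m * 3, sigma_max / 2)
  psi <- 0.5
  # observed: nearest suitable pixel to the capture centroid
  s <- integer(M)
  for (i in seq_len(n_obs)) {
    js <- which(y2[i, ] > 0)
    cxy <- c(mean(traps$x[js]), mean(traps$y[js]))
    s[i] <- which.min((sx - cxy[1])^2 + (sy - cxy[2])^2)
  }
  s[(n_obs + 1):M] <- sample.int(S, M - n_obs, replace = TRUE)
  z <- c(rep(TRUE, n_obs), stats::runif(M - n_obs) < psi)

  ll_obs_init <- -lam0 * .H_at(env, s[1:n_obs], sigma) +
    .cross_at(env, s[1:n_obs], lam0, sigma)
  if (any(!is.finite(ll_obs_init)))
    stop("non-finite likelihood at initialization (check lam0/sigma bounds)")

  step_lam0 <- config$prop_lam0
  step_sigma <- config$prop_sigma
  acc <- c(s = 0, lam0 = 0, sigma = 0)
  try_n <- c(s = 0, lam0 = 0, sigma = 0)
  aug <- (n_obs + 1):M
  obs <- 1:n_obs

  n_save <- (config$iterations - config$burn_in) %/% config$thin
  chains <- matrix(NA_real_, n_save, 5,
                   dimnames = list(NULL, c("lam0", "sigma", "psi", "N",
                                           "density")))
  pixel_acc <- numeric(S)
  Tobs_v <- Trep_v <- numeric(0)
  save_i <- 0L
  adapt_batch <- 50L
  b_acc <- c(lam0 = 0, sigma = 0); b_try <- c(lam0 = 0, sigma = 0)

  for (it in seq_len(config$iterations)) {
    # --- (a) activity centres -------------------------------------------
    live <- which(z)
    dead_aug <- aug[!z[aug]]
    if (length(dead_aug))                       # prior Gibbs draw
      s[dead_aug] <- sample.int(S, length(dead_aug), replace = TRUE)
    movable <- live[nb$n[s[live]] > 0L]
    if (length(movable)) {
      cur <- s[movable]
      k <- floor(stats::runif(length(movable)) * nb$n[cur])
      prop <- nb$idx[nb$ptr[cur] + 1L + k]
      Hcur <- .H_at(env, cur, sigma)
      Hprop <- .H_at(env, prop, sigma)
      dll <- -lam0 * (Hprop - Hcur)
      is_o <- movable <= n_obs
      if (any(is_o)) {
        po <- s[obs]; po[match(movable[is_o], obs)] <- prop[is_o]
        dcross <- .cross_at(env, po, lam0, sigma) -
          .cross_at(env, s[obs], lam0, sigma)
        dll[is_o] <- dll[is_o] + dcross[match(movable[is_o], obs)]
      }
      logacc <- dll + log(nb$n[cur]) - log(nb$n[prop])
      ok <- log(stats::runif(length(movable))) < logacc
      s[movable[ok]] <- prop[ok]
      acc["s"] <- acc["s"] + sum(ok); try_n["s"] <- try_n["s"] + length(ok)
    }

    # --- (b) inclusion flags z (augmented rows only) --------------------
    A_aug <- -lam0 * .H_at(env, s[aug], sigma)
    pr1 <- psi * exp(A_aug)
    z[aug] <- stats::runif(length(aug)) < pr1 / (pr1 + 1 - psi)

    # --- (c) psi: conjugate Beta ----------------------------------------
    Nz <- n_obs + sum(z[aug])
    psi <- stats::rbeta(1, 1 + Nz, 1 + M - Nz)

    # --- (d,e) detection parameters -------------------------------------
    live <- which(z)
    H_live <- .H_at(env, s[live], sigma)
    sumH <- sum(H_live)
    cross_cur <- sum(.cross_at(env, s[obs], lam0, sigma))

    lam0p <- lam0 * exp(stats::rnorm(1, 0, step_lam0))
    try_n["lam0"] <- try_n["lam0"] + 1; b_try["lam0"] <- b_try["lam0"] + 1
    if (lam0p <= config$lam0_max) {
      crossp <- sum(.cross_at(env, s[obs], lam0p, sigma))
      logacc <- (-lam0p * sumH + crossp) - (-lam0 * sumH + cross_cur) +
        log(lam0p / lam0)                      # log-scale proposal Jacobian
      if (is.finite(logacc) && log(stats::runif(1)) < logacc) {
        lam0 <- lam0p; cross_cur <- crossp
        acc["lam0"] <- acc["lam0"] + 1; b_acc["lam0"] <- b_acc["lam0"] + 1
      }
    }

    sigmap <- sigma * exp(stats::rnorm(1, 0, step_sigma))
    try_n["sigma"] <- try_n["sigma"] + 1; b_try["sigma"] <- b_try["sigma"] + 1
    if (sigmap <= sigma_max) {
      sumHp <- sum(.H_at(env, s[live], sigmap))
      crossp <- sum(.cross_at(env, s[obs], lam0, sigmap))
      logacc <- (-lam0 * sumHp + crossp) - (-lam0 * sumH + cross_cur) +
        log(sigmap / sigma)
      if (is.finite(logacc) && log(stats::runif(1)) < logacc) {
        sigma <- sigmap
        acc["sigma"] <- acc["sigma"] + 1; b_acc["sigma"] <- b_acc["sigma"] + 1
      }
    }

    # adapt proposal scales during burn-in only
    if (it <= config$burn_in && it %% adapt_batch == 0L) {
      gain <- 1 / sqrt(it / adapt_batch)
      step_lam0 <- step_lam0 * exp(gain * (b_acc["lam0"] / b_try["lam0"] - 0.44))
      step_sigma <- step_sigma * exp(gain * (b_acc["sigma"] / b_try["sigma"] - 0.44))
      b_acc[] <- 0; b_try[] <- 0
    }

    # --- (f) save -------------------------------------------------------
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      save_i <- save_i + 1L
      Nn <- n_obs + sum(z[aug])
      chains[save_i, ] <- c(lam0, sigma, psi, Nn, Nn / area * 100)
      pixel_acc <- pixel_acc + tabulate(s[z], nbins = S)
      if (save_i %% config$pp_every == 0L) {
        live <- which(z)
        pm <- -expm1(-lam0 * .kern_rows(env, s[live], sigma))  # |live| x J
        e_i <- drop(pm %*% Kj)
        y_i <- numeric(length(live))
        o <- live <= n_obs
        y_i[o] <- rowSums(y2)[live[o]]
        Tobs <- sum((sqrt(y_i) - sqrt(e_i))^2)
        yrep <- matrix(stats::rbinom(length(pm), rep(Kj, each = nrow(pm)), pm),
                       nrow = nrow(pm))
        yr <- rowSums(yrep)
        Trep <- sum((sqrt(yr) - sqrt(e_i))^2)
        Tobs_v <- c(Tobs_v, Tobs); Trep_v <- c(Trep_v, Trep)
      }
    }
  }

  structure(list(
    chains = as.data.frame(chains),
    pixel_mean = pixel_acc / n_save,
    pp = list(T_obs = Tobs_v, T_rep = Trep_v),
    accept = acc / pmax(try_n, 1),
    settings = list(config = config, M = M, n_observed = n_obs,
                    suitable_area_km2 = area, seed = config$seed,
                    sigma_max = sigma_max),
    suit_index = suit, state_space = state_space, traps = traps),
    class = "secr_fit")
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("secr_fit (%s): %d saved draws, M = %d (%d observed)\n",
              x$settings$config$kind, nrow(x$chains), x$settings$M,
              x$settings$n_observed))
  print(summary_table(x))
  invisible(x)
}

#' Fit the non-spatial data-augmented abundance model
#'
#' Same augmentation machinery with a constant per-trap-day capture
#' probability `p = 1 - exp(-lam0)`; no activity centres, no sigma.
#' Density is reported only when an effective sampled area is supplied,
#' since a non-spatial model carries no notion of area.
#'
#' @param history a `capture_history`.
#' @param config a [secr_config()] (kind is ignored).
#' @param effective_area_km2 optional area (km^2) for the density chain.
#' @return object of class `secr_fit` with `sigma` NA in the chains.
#' @export
fit_nonspatial <- function(history, config = secr_config(),
                           effective_area_km2 = NULL) {
  stopifnot(inherits(history, "capture_history"))
  if (is.null(config$seed)) stop("config$seed must be set")
  set.seed(config$seed)
  y_i <- apply(history$y, 1, sum)
  n_obs <- length(y_i)
  # per-individual Bernoulli trials: every trap-occasion
  Tdays <- history$n_traps * history$n_occasions
  M <- n_obs + config$M_add
  lam0 <- max(sum(y_i) / (n_obs * Tdays), 1e-6)
  psi <- 0.5
  z <- c(rep(TRUE, n_obs), stats::runif(M - n_obs) < psi)
  step <- config$prop_lam0
  n_save <- (config$iterations - config$burn_in) %/% config$thin
  chains <- matrix(NA_real_, n_save, 5,
                   dimnames = list(NULL, c("lam0", "sigma", "psi", "N",
                                           "density")))
  save_i <- 0L
  acc <- 0; tries <- 0
  yz <- c(y_i, rep(0, M - n_obs))
  for (it in seq_len(config$iterations)) {
    p <- -expm1(-lam0)
    # z Gibbs (augmented rows all have zero histories)
    pr1 <- psi * (1 - p)^Tdays
    z[(n_obs + 1):M] <- stats::runif(M - n_obs) < pr1 / (pr1 + 1 - psi)
    Nz <- sum(z)
    psi <- stats::rbeta(1, 1 + Nz, 1 + M - Nz)
    # lam0 log-RW; loglik = sum_{z=1} y log p + (T - y) * (-lam0)
    sy <- sum(yz[z])
    lam0p <- lam0 * exp(stats::rnorm(1, 0, step))
    tries <- tries + 1
    if (lam0p <= config$lam0_max) {
      pp <- -expm1(-lam0p)
      logacc <- (sy * log(pp) - lam0p * (Nz * Tdays - sy)) -
        (sy * log(p) - lam0 * (Nz * Tdays - sy)) + log(lam0p / lam0)
      if (is.finite(logacc) && log(stats::runif(1)) < logacc) {
        lam0 <- lam0p; acc <- acc + 1
      }
    }
    if (it <= config$burn_in && it %% 50L == 0L)
      step <- step * exp((acc / tries - 0.44) / sqrt(it / 50))
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      save_i <- save_i + 1L
      dens <- if (is.null(effective_area_km2)) NA_real_ else
        Nz / effective_area_km2 * 100
      chains[save_i, ] <- c(lam0, NA_real_, psi, Nz, dens)
    }
  }
  structure(list(chains = as.data.frame(chains), pixel_mean = NULL,
                 pp = NULL, accept = c(lam0 = acc / tries),
                 settings = list(config = config, M = M, n_observed = n_obs,
                                 suitable_area_km2 = effective_area_km2,
                                 seed = config$seed, kind = "non_spatial")),
            class = "secr_fit")
}

#' Posterior summary of one chain
#'
#' Mean, SD, median, mode and the 95% highest-posterior-density interval.
#' The HPD interval is the shortest window containing 95% of the sorted
#' samples; the mode is the midpoint of the fullest histogram bin with
#' Freedman-Diaconis bin widths (continuous chains have no unique mode).
#'
#' @param chain numeric vector of >= 100 posterior draws (shorter chains
#'   are allowed only for degenerate/constant input).
#' @param prob interval mass, default 0.95.
#' @return list with `mean`, `sd`, `median`, `mode`, `hpd_lower`,
#'   `hpd_upper`.
#' @export
posterior_summary <- function(chain, prob = 0.95) {
  chain <- chain[is.finite(chain)]
  n <- length(chain)
  if (n == 0) stop("empty chain")
  if (stats::sd(chain) == 0 || n < 2) {
    c0 <- chain[1]
    return(list(mean = c0, sd = 0, median = c0, mode = c0,
                hpd_lower = c0, hpd_upper = c0))
  }
  if (n < 100) warning("chain shorter than 100 draws; summaries unstable")
  srt <- sort(chain)
  m <- ceiling(prob * n)
  if (m >= n) {
    hpd <- c(srt[1], srt[n])
  } else {
    w <- srt[(m + 1):n] - srt[1:(n - m)]
    i <- which.min(w)
    hpd <- c(srt[i], srt[i + m])
  }
  # Freedman-Diaconis mode
  iqr <- stats::IQR(chain)
  bw <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(range(chain)) / 30
  lo <- srt[1] - bw / 2
  nb <- ceiling((srt[n] - lo) / bw)
  counts <- tabulate(pmin(floor((chain - lo) / bw) + 1L, nb), nbins = nb)
  mode <- lo + (which.max(counts) - 0.5) * bw
  list(mean = mean(chain), sd = stats::sd(chain), median = stats::median(chain),
       mode = mode, hpd_lower = hpd[1], hpd_upper = hpd[2])
}

#' Posterior summary table for a fitted model
#'
#' One row per parameter with posterior mean, SD and 95% HPD bounds,
#' mirroring the standard SECR reporting layout.
#' @param fit a `secr_fit`.
#' @export
summary_table <- function(fit) {
  stopifnot(inherits(fit, "secr_fit"))
  pars <- c("density", "sigma", "lam0", "psi", "N")
  rows <- lapply(pars, function(p) {
    ch <- fit$chains[[p]]
    if (all(is.na(ch)))
      return(data.frame(parameter = p, mean = NA, sd = NA,
                        hpd_lower = NA, hpd_upper = NA))
    ps <- posterior_summary(ch)
    data.frame(parameter = p, mean = ps$mean, sd = ps$sd,
               hpd_lower = ps$hpd_lower, hpd_upper = ps$hpd_upper)
  })
  do.call(rbind, rows)
}

#' Pixel density surface from a fitted model
#'
#' Per-pixel posterior mean count of included activity centres; unsuitable
#' pixels are exactly zero.  The map total equals the posterior mean of N
#' by construction.
#'
#' @param fit a spatial `secr_fit`.
#' @param per_area divide by pixel area (individuals per km^2) if TRUE.
#' @return data.frame `x`, `y`, `suitable`, `value`.
#' @export
pixel_density_map <- function(fit, per_area = FALSE) {
  stopifnot(inherits(fit, "secr_fit"))
  if (is.null(fit$pixel_mean)) stop("fit has no per-pixel counts (non-spatial?)")
  ss <- fit$state_space
  v <- numeric(length(ss$x))
  v[fit$suit_index] <- fit$pixel_mean
  if (per_area) v <- v / ss$pixel_area_km2
  data.frame(x = ss$x, y = ss$y, suitable = ss$suitable, value = v)
}

#' Posterior-predictive (Bayesian) p-value
#'
#' Freeman-Tukey discrepancy on individual encounter totals,
#' `T = sum_i (sqrt(y_i.) - sqrt(E[y_i.]))^2`, compared between the
#' observed data and replicates drawn from the fitted model at each
#' retained posterior draw.  `p = Pr(T_rep >= T_obs)`; values near 0 or 1
#' indicate misfit.
#'
#' @param fit a `secr_fit` with stored discrepancies.
#' @export
bayesian_p_value <- function(fit) {
  stopifnot(inherits(fit, "secr_fit"))
  if (is.null(fit$pp) || length(fit$pp$T_obs) == 0)
    stop("fit carries no posterior-predictive discrepancies")
  mean(fit$pp$T_rep >= fit$pp$T_obs)
}

# spectral density at frequency zero via an AR fit (Geweke's variance)
.spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE), silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the means of the first `frac1` and last `frac2` of a
#' chain, standardised by spectral-density-at-zero variance estimates of
#' each window.  |z| < 1.64 is the conventional no-evidence-of-
#' nonconvergence bound.
#'
#' @param chain numeric chain of length >= 100.
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return list with `z` (NA when a window has zero variance) and
#'   `converged` (|z| < 1.64).
#' @export
geweke <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for the Geweke diagnostic")
  x1 <- chain[1:floor(frac1 * n)]
  x2 <- chain[(n - floor(frac2 * n) + 1):n]
  s1 <- .spectrum0_ar(x1); s2 <- .spectrum0_ar(x2)
  if (s1 == 0 && s2 == 0) {
    z <- if (mean(x1) == mean(x2)) 0 else NA_real_
    return(list(z = z, converged = !is.na(z) && abs(z) < 1.64))
  }
  if (s1 == 0 || s2 == 0)
    return(list(z = NA_real_, converged = NA))
  z <- (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
  list(z = z, converged = abs(z) < 1.64)
}

#' Simulate an SECR dataset
#'
#' Draws a population of activity centres uniformly on the suitable pixels
#' of the state space, then per-occasion Bernoulli captures at each active
#' trap-occasion under the detection model.  Individuals never captured
#' are dropped from the returned capture history but kept in the latent
#' truth record.
#'
#' @param truth list with `params` (a [detection_params]), and either
#'   `psi` + `M` (N ~ Binomial(M, psi)) or `density` per 100 km^2
#'   (N fixed at round(density x area / 100)).  Supplying both is an
#'   error unless they agree to within one individual in expectation.
#' @param traps a [trap_array] (its activity matrix defines effort).
#' @param state_space a `state_space`.
#' @param seed integer RNG seed (required).
#' @return list with `history` (a `capture_history`, possibly with zero
#'   individuals as NULL), `latent` (centres, inclusion, N, detected
#'   flags), and `truth`.
#' @export
simulate_secr <- function(truth, traps, state_space, seed) {
  stopifnot(inherits(traps, "trap_array"), inherits(state_space, "state_space"))
  if (missing(seed) || is.null(seed)) stop("seed must be supplied")
  set.seed(seed)
  suit <- which(state_space$suitable)
  if (length(suit) < 1) stop("state space has no suitable pixel")
  area <- suitable_area_km2(state_space)
  has_psi <- !is.null(truth$psi) && !is.null(truth$M)
  has_dens <- !is.null(truth$density)
  if (has_psi && has_dens) {
    EN_psi <- truth$psi * truth$M
    EN_dens <- truth$density * area / 100
    if (abs(EN_psi - EN_dens) > 1)
      stop(sprintf("psi and density imply different populations (%.1f vs %.1f)",
                   EN_psi, EN_dens))
  }
  if (has_psi) {
    N <- stats::rbinom(1, truth$M, truth$psi)
  } else if (has_dens) {
    N <- as.integer(round(truth$density * area / 100))
  } else stop("truth must supply psi+M or density")

  params <- truth$params
  K <- ncol(traps$activity)
  J <- length(traps$x)
  latent <- list(N = N, area_km2 = area, params = params)
  if (N == 0) return(list(history = NULL, latent = latent, truth = truth))

  ctr <- suit[sample.int(length(suit), N, replace = TRUE)]
  cx <- state_space$x[ctr]; cy <- state_space$y[ctr]
  d <- sqrt(outer(cx, traps$x, "-")^2 + outer(cy, traps$y, "-")^2)
  p <- encounter_prob(detection_rate(as.vector(d), params))
  p <- matrix(p, N, J)
  y <- array(0L, dim = c(N, J, K))
  act <- traps$activity
  for (k in seq_len(K)) {
    aj <- which(act[, k] == 1L)
    if (!length(aj)) next
    y[, aj, k] <- stats::rbinom(N * length(aj), 1L,
                                p[, aj, drop = FALSE])
  }
  det <- which(apply(y, 1, sum) > 0)
  latent$centres <- data.frame(pixel = ctr, x = cx, y = cy)
  latent$detected <- seq_len(N) %in% det
  if (length(det) == 0) return(list(history = NULL, latent = latent, truth = truth))
  ids <- sprintf("SIM%03d", det)
  hist_y <- y[det, , , drop = FALSE]
  dimnames(hist_y) <- list(ids, traps$trap_id, NULL)
  history <- structure(list(y = hist_y, individual_id = ids,
                            n_individuals = length(det), n_traps = J,
                            n_occasions = K),
                       class = "capture_history")
  list(history = history, latent = latent, truth = truth)
}
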