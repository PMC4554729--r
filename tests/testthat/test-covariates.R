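# sign indices, kriging, slope surfaces, NB regression, AIC inference

test_that("sign indices are per-cell proportions with missing flags", {
  sv <- data.frame(cell_id = c("a", "b", "c", "d"),
                   x = 1:4, y = 1:4,
                   n_segments = c(12, 16, 20, 0),
                   prey_pos = c(3, 0, 20, 0),
                   grazing_pos = c(6, 16, 0, 0))
  out <- sign_index(sv)
  expect_equal(out$prey_index, c(0.25, 0, 1, NA))
  expect_equal(out$grazing_index, c(0.5, 1, 0, NA))
  sv$prey_pos[1] <- 13
  expect_error(sign_index(sv), "exceed")
})

test_that("variogram fitting: pure nugget, white noise, recovery", {
  set.seed(2)
  pts <- cbind(runif(200, 0, 1e4), runif(200, 0, 1e4))
  # constant field -> pure nugget flag
  vf <- fit_variogram(pts, rep(2.5, 200))
  expect_true(vf$pure_nugget)
  # white noise: flat semivariogram at the variance; negligible structure
  z <- rnorm(200, 0, 3)
  vw <- fit_variogram(pts, z)
  total_sill <- vw$nugget + vw$psill
  expect_lt(abs(total_sill - var(z)) / var(z), 0.35)
  gamma_first <- vw$nugget + vw$psill *
    (1 - exp(-vw$bins$h[1] / vw$range))
  expect_gt(gamma_first, 0.5 * var(z))        # no spurious deep structure
  # exponential-field recovery within 50% at n = 200
  f <- gaussian_random_field(pts, range_m = 2000, sill = 4, seed = 30)
  vr <- fit_variogram(pts, f)
  expect_lt(abs(vr$range - 2000) / 2000, 0.5)
  expect_error(fit_variogram(pts[1:3, ], z[1:3]), ">= 5")
})

test_that("ordinary kriging: exactness, constancy, hand-solved system", {
  vg <- structure(list(nugget = 0, psill = 2, range = 1500,
                       model = "exponential", pure_nugget = FALSE),
                  class = "variogram_fit")
  pts <- cbind(c(0, 1000, 2000, 500), c(0, 800, 100, 1500))
  z <- c(4, 7, 5, 6)
  # zero nugget: prediction at a data point returns that datum exactly
  at_data <- ordinary_kriging(pts, z, pts, vg)
  expect_equal(at_data$pred, z, tolerance = 1e-8)
  # constant field -> constant prediction everywhere (weights sum to 1)
  trg <- cbind(runif(20, -500, 2500), runif(20, -500, 2500))
  const <- ordinary_kriging(pts, rep(3.3, 4), trg, vg)
  expect_equal(const$pred, rep(3.3, 20), tolerance = 1e-8)

  # 3-point 1D toy against the explicitly assembled kriging system
  p3 <- cbind(c(0, 1000, 2000), c(0, 0, 0))
  z3 <- c(2, 5, 3)
  target <- cbind(500, 0)
  gm <- function(h) ifelse(h == 0, 0, 0.5 + 2 * (1 - exp(-h / 1000)))
  vg3 <- structure(list(nugget = 0.5, psill = 2, range = 1000,
                        model = "exponential", pure_nugget = FALSE),
                   class = "variogram_fit")
  A <- rbind(c(gm(0), gm(1000), gm(2000), 1),
             c(gm(1000), gm(0), gm(1000), 1),
             c(gm(2000), gm(1000), gm(0), 1),
             c(1, 1, 1, 0))
  b <- c(gm(500), gm(500), gm(1500), 1)
  w <- solve(A, b)
  expect_equal(ordinary_kriging(p3, z3, target, vg3)$pred,
               sum(w[1:3] * z3), tolerance = 1e-10)

  # duplicated locations are averaged rather than crashing the solve
  dup <- ordinary_kriging(rbind(p3, p3[1, ]), c(z3, 4), target, vg3)
  expect_true(is.finite(dup$pred))
})

test_that("log-transform kriging back-transforms with bias correction", {
  set.seed(6)
  pts <- cbind(runif(40, 0, 8000), runif(40, 0, 8000))
  v <- exp(gaussian_random_field(pts, 3000, 0.4, seed = 7))
  out <- ordinary_kriging(pts, v, pts, log_transform = TRUE)
  # exact interpolation survives the log round-trip when nugget ~ 0
  expect_equal(cor(out$pred, v), 1, tolerance = 0.05)
  expect_true(all(is.finite(out$pred)))
})

test_that("slope surfaces: flat, inclined plane, naive-loop oracle", {
  gx <- seq(50, 1950, by = 100)
  mkpix <- function() {
    px <- expand.grid(x = c(500, 1500), y = c(500, 1500))
    attr(px, "spacing_m") <- 1000
    px
  }
  flat <- list(x = gx, y = gx, z = matrix(1000, 20, 20))
  s <- slope_sd_surface(flat, mkpix())
  expect_equal(s$slope_sd, rep(0, 4))
  # uniform inclined plane: constant slope, zero SD
  incl <- list(x = gx, y = gx, z = outer(gx, gx, function(a, b) 0.2 * a))
  s2 <- slope_sd_surface(incl, mkpix())
  expect_equal(s2$slope_sd, rep(0, 4), tolerance = 1e-10)

  # random ridged surface vs brute-force per-cell recomputation
  set.seed(9)
  z <- matrix(rnorm(400, 1000, 30), 20, 20)
  dem <- list(x = gx, y = gx, z = z)
  got <- slope_sd_surface(dem, mkpix())
  h <- 100
  slope <- matrix(NA_real_, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    ia <- min(i + 1, 20); ib <- max(i - 1, 1)
    ja <- min(j + 1, 20); jb <- max(j - 1, 1)
    gxv <- (z[ia, j] - z[ib, j]) / ((ia - ib) * h)
    gyv <- (z[i, ja] - z[i, jb]) / ((ja - jb) * h)
    slope[i, j] <- atan(sqrt(gxv^2 + gyv^2)) * 180 / pi
  }
  px <- mkpix()
  for (p in 1:4) {
    sel <- abs(rep(gx, 20) - px$x[p]) <= 500 &
      abs(rep(gx, each = 20) - px$y[p]) <= 500
    expect_equal(got$slope_sd[p], sd(as.vector(slope)[sel]))
  }
})

test_that("negative-binomial regression anchors and Poisson nesting", {
  d0 <- data.frame(y = rep(7, 40))
  f0 <- fit_negbin(y ~ 1, d0)
  expect_equal(unname(f0$coefficients[1]), log(7), tolerance = 1e-6)
  expect_equal(f0$K, 2)                        # intercept + theta
  expect_equal(f0$AIC, -2 * f0$logLik + 2 * f0$K)

  set.seed(14)
  dp <- data.frame(x = rnorm(2000))
  dp$y <- rpois(2000, exp(1.5 + 0.3 * dp$x))
  fnb <- fit_negbin(y ~ x, dp)
  fpo <- glm(y ~ x, poisson, dp)
  expect_gt(fnb$theta, 100)                    # effectively Poisson
  # nesting: the NB likelihood dominates the Poisson one by a margin
  # that is negligible on the scale of the log-likelihood (~ -4300)
  expect_gte(fnb$logLik + 1e-8, as.numeric(logLik(fpo)))
  expect_lt(fnb$logLik - as.numeric(logLik(fpo)), 1)
})

test_that("akaike weights: closed form, equal models, delta = 2", {
  expect_equal(akaike_weights(rep(100, 4)), rep(0.25, 4))
  expect_equal(akaike_weights(c(10, 12)),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(akaike_weights(c(3585.51, 3585.57, 3592.78, 3593.62,
                                    3615.45, 3616.15, 3617.03))), 1)
  expect_error(akaike_weights(c(1, Inf)))
})

test_that("model selection ranks all 7 subsets order-independently", {
  set.seed(15)
  n <- 252
  dat <- data.frame(prey = rnorm(n), grazing = rnorm(n), slope = rnorm(n))
  mu <- exp(0.9 - 0.4 * dat$prey - 0.5 * dat$grazing)
  dat$abundance <- rnbinom(n, size = 20, mu = mu)
  sel <- model_selection(dat, "abundance", c("prey", "grazing", "slope"))
  tab <- sel$table
  expect_equal(nrow(tab), 7)
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$delta_AIC[1], 0)
  expect_true(all(diff(tab$cum_weight) >= 0))
  expect_true(all(sel$importance >= 0 & sel$importance <= 1))
  # the two informative covariates dominate
  expect_gt(sel$importance[["prey"]], 0.9)
  expect_gt(sel$importance[["grazing"]], 0.9)
  # permuting covariate order leaves the ranking invariant
  sel2 <- model_selection(dat, "abundance", c("slope", "grazing", "prey"))
  expect_equal(sel2$table$AIC, tab$AIC)
  expect_equal(sel2$importance[names(sel$importance)], sel$importance)
  # a covariate present in every model has importance 1
  sel1 <- model_selection(dat, "abundance", "prey")
  expect_equal(unname(sel1$importance), 1)
})

test_that("goodness of fit and collinearity checks", {
  expect_equal(gof_chi2(0, 10), 1)
  expect_equal(round(gof_chi2(3.84, 1), 3), 0.050)
  expect_error(gof_chi2(5, 0))
  X <- data.frame(a = rnorm(50))
  X$b <- X$a
  X$c <- -X$a + rnorm(50, 0, 1e-8)
  cl <- collinearity(X)
  expect_equal(cl$correlations["a", "b"], 1)
  expect_lt(cl$correlations["a", "c"], -0.99)
  expect_gte(nrow(cl$flagged), 2)
  X$z <- 0
  expect_equal(collinearity(X)$degenerate, "z")
  expect_error(collinearity(X["a"]), ">= 2")
})

test_that("standardize/unstandardize is an exact inverse", {
  set.seed(16)
  X <- data.frame(a = rnorm(30, 5, 2), b = runif(30, 0, 9))
  Z <- standardize(X)
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unstandardize(Z), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(standardize(data.frame(a = rep(1, 5))), "zero-variance")
})

test_that("NB regression on Poisson data seldom rejects goodness of fit", {
  set.seed(17)
  rejects <- replicate(60, {
    d <- data.frame(x = rnorm(120))
    d$y <- rpois(120, exp(1 + 0.3 * d$x))
    f <- fit_negbin(y ~ x, d)
    gof_chi2(f$deviance, f$df_residual) < 0.05
  })
  expect_lte(mean(rejects), 0.15)             # nominal ~5%
})
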