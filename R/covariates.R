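# Density-surface covariate analysis: sign-survey indices, variogram
# fitting and ordinary kriging, slope variability, pixel-level abundance
# extraction, negative-binomial regression, and AIC multimodel inference.

#' Sign-survey indices
#'
#' The field index for each surveyed cell is the proportion of 250 m
#' transect segments in which sign (prey tracks/carcasses, or livestock
#' grazing) was recorded.  A cell with zero surveyed segments has no
#' information and is flagged missing, never zero.
#'
#' @param survey data.frame with columns `cell_id`, `x`, `y`,
#'   `n_segments`, `prey_pos`, `grazing_pos`.
#' @return the survey with added columns `prey_index`, `grazing_index`
#'   (NA where `n_segments == 0`).
#' @export
sign_index <- function(survey) {
  need <- c("cell_id", "x", "y", "n_segments", "prey_pos", "grazing_pos")
  miss <- setdiff(need, names(survey))
  if (length(miss)) stop("survey missing column(s): ", paste(miss, collapse = ", "))
  if (any(survey$prey_pos > survey$n_segments |
          survey$grazing_pos > survey$n_segments))
    stop("positives exceed surveyed segments")
  ok <- survey$n_segments > 0
  survey$prey_index <- ifelse(ok, survey$prey_pos / survey$n_segments, NA_real_)
  survey$grazing_index <- ifelse(ok, survey$grazing_pos / survey$n_segments,
                                 NA_real_)
  survey
}

# theoretical semivariogram
.vgm_curve <- function(h, nugget, psill, range, model) {
  s <- switch(model,
              exponential = 1 - exp(-h / range),
              spherical = ifelse(h >= range, 1,
                                 1.5 * h / range - 0.5 * (h / range)^3))
  ifelse(h == 0, 0, nugget + psill * s)
}

#' Fit a variogram to point data
#'
#' Bins the empirical semivariogram by distance and fits a nugget +
#' partial-sill model by weighted least squares (weights = pair counts),
#' the standard geostatistical workflow when no variogram is given.
#'
#' @param points two-column matrix/data.frame of coordinates (metres).
#' @param values numeric vector of observations.
#' @param model `"exponential"` (default) or `"spherical"`.
#' @param n_bins number of distance bins (default 12) up to half the
#'   maximum pairwise distance.
#' @return object of class `variogram_fit`: `nugget`, `psill`, `range`,
#'   `model`, `pure_nugget` flag, and the empirical bins.
#' @export
fit_variogram <- function(points, values, model = c("exponential",
                                                    "spherical"),
                          n_bins = 12) {
  model <- match.arg(model)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5) stop("need >= 5 points to fit a variogram")
  v <- stats::var(values)
  d <- as.vector(stats::dist(points))
  g <- as.vector(stats::dist(values))^2 / 2
  if (v < .Machine$double.eps * max(1, mean(values)^2)) {
    return(structure(list(nugget = 0, psill = 0, range = max(d) / 3,
                          model = model, pure_nugget = TRUE,
                          bins = NULL),
                     class = "variogram_fit"))
  }
  dmax <- max(d) / 2
  brk <- seq(0, dmax, length.out = n_bins + 1)
  bin <- cut(d, brk, labels = FALSE, include.lowest = TRUE)
  keep <- !is.na(bin)
  gm <- tapply(g[keep], bin[keep], mean)
  ct <- tapply(g[keep], bin[keep], length)
  hm <- tapply(d[keep], bin[keep], mean)
  bins <- data.frame(h = as.numeric(hm), gamma = as.numeric(gm),
                     n = as.numeric(ct))
  obj <- function(par) {
    nug <- exp(par[1]); ps <- exp(par[2]); rg <- exp(par[3])
    fit <- .vgm_curve(bins$h, nug, ps, rg, model)
    sum(bins$n * (bins$gamma - fit)^2)
  }
  init <- c(log(max(v * 0.1, 1e-8)), log(max(v * 0.9, 1e-8)),
            log(dmax / 3))
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  nug <- exp(opt$par[1]); ps <- exp(opt$par[2]); rg <- exp(opt$par[3])
  structure(list(nugget = nug, psill = ps, range = rg, model = model,
                 pure_nugget = ps < 1e-6 * (nug + ps), bins = bins),
            class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("variogram_fit (%s): nugget %.4g, partial sill %.4g, range %.4g%s\n",
              x$model, x$nugget, x$psill, x$range,
              if (x$pure_nugget) " [pure nugget]" else ""))
  invisible(x)
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system (weights constrained to sum to one
#' through a Lagrange multiplier) for every target location.  With
#' `log_transform`, the model is fitted to `log(value + c)` with `c` half
#' the smallest positive observation and predictions are back-transformed
#' with the lognormal bias correction `exp(pred + var/2) - c`.
#'
#' @param points two-column coordinates of the data (metres).
#' @param values observations at `points`.
#' @param targets two-column coordinates to predict at.
#' @param variogram a `variogram_fit`, or NULL to fit one here.
#' @param log_transform krige on the log scale (default FALSE).
#' @param dedup drop exactly duplicated locations (keeping the mean value)
#'   instead of failing on a singular system.
#' @return data.frame `x`, `y`, `pred`, `var` (kriging variance).
#' @export
ordinary_kriging <- function(points, values, targets, variogram = NULL,
                             log_transform = FALSE, dedup = TRUE) {
  points <- as.matrix(points); targets <- as.matrix(targets)
  if (nrow(targets) == 0) stop("no target locations")
  key <- paste(points[, 1], points[, 2])
  if (anyDuplicated(key)) {
    if (!dedup) stop("duplicate point locations make the kriging system singular")
    agg <- tapply(values, key, mean)
    first <- !duplicated(key)
    points <- points[first, , drop = FALSE]
    values <- as.numeric(agg[match(key[first], names(agg))])
  }
  offset <- 0
  obs <- values
  if (log_transform) {
    pos <- values[values > 0]
    if (!length(pos)) stop("log transform needs at least one positive value")
    offset <- min(pos) / 2
    obs <- log(values + offset)
  }
  if (is.null(variogram)) variogram <- fit_variogram(points, obs)
  n <- nrow(points)
  if (variogram$pure_nugget || (variogram$nugget + variogram$psill) == 0) {
    # no spatial structure: BLUP is the mean everywhere
    pred <- rep(mean(obs), nrow(targets))
    vr <- rep(stats::var(obs) * (1 + 1 / n), nrow(targets))
  } else {
    G <- matrix(0, n + 1, n + 1)
    dm <- as.matrix(stats::dist(points))
    G[1:n, 1:n] <- .vgm_curve(dm, variogram$nugget, variogram$psill,
                              variogram$range, variogram$model)
    G[n + 1, 1:n] <- 1; G[1:n, n + 1] <- 1
    d0 <- sqrt(outer(targets[, 1], points[, 1], "-")^2 +
                 outer(targets[, 2], points[, 2], "-")^2)
    g0 <- .vgm_curve(d0, variogram$nugget, variogram$psill,
                     variogram$range, variogram$model)
    rhs <- rbind(t(g0), 1)                      # (n+1) x T
    sol <- solve(G, rhs)
    w <- sol[1:n, , drop = FALSE]
    pred <- drop(crossprod(w, obs))
    vr <- colSums(sol * rhs)                    # sum w*gamma + mu
    vr <- pmax(vr, 0)
  }
  if (log_transform) pred <- exp(pred + vr / 2) - offset
  data.frame(x = targets[, 1], y = targets[, 2], pred = pred, var = vr)
}

#' Slope-variability surface from a DEM
#'
#' Slope in degrees from central-difference gradients on the elevation
#' grid, then the standard deviation of slope over the DEM cells enclosed
#' by each state-space pixel.  Pixels enclosing fewer than two DEM cells
#' are flagged missing.
#'
#' @param dem list with `z` (elevation matrix, rows = x index, cols = y
#'   index), `x`, `y` (cell-centre coordinate vectors, metres).
#' @param pixels data.frame with pixel centres `x`, `y` and attribute
#'   `spacing_m` (or a `state_space`).
#' @return data.frame `x`, `y`, `slope_sd` (NA where undefined).
#' @export
slope_sd_surface <- function(dem, pixels) {
  if (inherits(pixels, "state_space")) {
    px <- data.frame(x = pixels$x, y = pixels$y)
    spacing <- pixels$spacing_m
  } else {
    px <- pixels
    spacing <- attr(pixels, "spacing_m")
    if (is.null(spacing)) stop("pixels need a spacing_m attribute")
  }
  z <- dem$z
  hx <- mean(diff(dem$x)); hy <- mean(diff(dem$y))
  nx <- nrow(z); ny <- ncol(z)
  # central differences in the interior, one-sided at the boundary
  denx <- c(hx, rep(2 * hx, max(nx - 2, 0)), hx)[seq_len(nx)]
  deny <- c(hy, rep(2 * hy, max(ny - 2, 0)), hy)[seq_len(ny)]
  gx <- (z[c(2:nx, nx), , drop = FALSE] - z[c(1, 1:(nx - 1)), , drop = FALSE]) / denx
  gy <- sweep(z[, c(2:ny, ny), drop = FALSE] - z[, c(1, 1:(ny - 1)), drop = FALSE],
              2, deny, "/")
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  # assign each DEM cell to the pixel whose square footprint contains it
  cx <- rep(dem$x, times = ny); cy <- rep(dem$y, each = nx)
  out <- px
  out$slope_sd <- NA_real_
  half <- spacing / 2
  sv <- as.vector(slope)
  for (p in seq_len(nrow(px))) {
    in_p <- abs(cx - px$x[p]) <= half & abs(cy - px$y[p]) <= half
    if (sum(in_p) >= 2) out$slope_sd[p] <- stats::sd(sv[in_p])
  }
  out
}

#' Per-pixel posterior mean abundance
#'
#' The arithmetic mean over MCMC iterations of the number of included
#' activity centres in each pixel; the response variable for the
#' covariate regression.  The map total equals the posterior mean of N.
#'
#' @param fit a spatial `secr_fit`.
#' @return data.frame `x`, `y`, `mean_count` for the suitable pixels.
#' @export
pixel_mean_abundance <- function(fit) {
  stopifnot(inherits(fit, "secr_fit"))
  if (is.null(fit$pixel_mean)) stop("fit has no per-pixel counts")
  ss <- fit$state_space
  data.frame(x = ss$x[fit$suit_index], y = ss$y[fit$suit_index],
             mean_count = fit$pixel_mean)
}

#' Centre and scale covariate columns
#'
#' @param x data.frame or matrix of covariates.
#' @return same shape with each column standardised to mean 0, sd 1;
#'   the means/sds are kept as attributes `center`/`scale` so
#'   [unstandardize()] is an exact inverse.
#' @export
standardize <- function(x) {
  m <- as.matrix(x)
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance column cannot be standardised")
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  out <- as.data.frame(out)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert [standardize()]
#' @param x a standardised data.frame with `center`/`scale` attributes.
#' @export
unstandardize <- function(x) {
  ctr <- attr(x, "center"); scl <- attr(x, "scale")
  if (is.null(ctr)) stop("x was not produced by standardize()")
  out <- sweep(sweep(as.matrix(x), 2, scl, "*"), 2, ctr, "+")
  as.data.frame(out)
}

#' Negative-binomial regression (log link, NB-2)
#'
#' Wrapper around maximum-likelihood NB regression with the dispersion
#' parameter theta estimated alongside the coefficients.  The response
#' may be a non-integer posterior-mean count: the NB likelihood is
#' evaluated through its gamma-function form, which extends continuously.
#'
#' @param formula model formula.
#' @param data data.frame with response and covariates.
#' @return object of class `nb_fit`: coefficients, SEs, p-values, `theta`
#'   and its SE, `logLik`, `AIC`, `K` (slopes + intercept + theta),
#'   `deviance`, `df_residual`, and the underlying `glm` object.
#' @export
fit_negbin <- function(formula, data) {
  fit <- tryCatch(suppressWarnings(MASS::glm.nb(formula, data = data)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    # theta diverged: the data carry no overdispersion, so the NB limit
    # is exactly the Poisson model (theta = Inf)
    fit <- suppressWarnings(stats::glm(formula, stats::poisson, data))
    fit$theta <- Inf
    fit$SE.theta <- NA_real_
  } else if (!fit$converged) {
    stop("negative-binomial fit did not converge (iterations: ",
         fit$iter, ")")
  }
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  K <- nrow(co) + 1L                            # + theta
  pcol <- grep("^Pr", colnames(co), value = TRUE)[1]
  structure(list(coefficients = co[, "Estimate"], se = co[, "Std. Error"],
                 p_values = co[, pcol], theta = fit$theta,
                 theta_se = fit$SE.theta, logLik = as.numeric(stats::logLik(fit)),
                 AIC = -2 * as.numeric(stats::logLik(fit)) + 2 * K, K = K,
                 deviance = stats::deviance(fit),
                 df_residual = stats::df.residual(fit),
                 formula = formula, glm = fit),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("nb_fit:", deparse(x$formula), "\n")
  print(round(cbind(coef = x$coefficients, se = x$se, p = x$p_values), 4))
  cat(sprintf("theta %.1f (SE %.1f), AIC %.2f (K = %d)\n",
              x$theta, x$theta_se, x$AIC, x$K))
  invisible(x)
}

#' Akaike weights
#'
#' `w_m = exp(-Delta_m/2) / sum exp(-Delta/2)` with
#' `Delta_m = AIC_m - min(AIC)`.
#'
#' @param aic_values finite AIC values.
#' @return weights summing to 1, in input order.
#' @export
akaike_weights <- function(aic_values) {
  if (!length(aic_values) || any(!is.finite(aic_values)))
    stop("aic_values must be non-empty and finite")
  d <- aic_values - min(aic_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' All-subsets negative-binomial model selection
#'
#' Fits one NB model per non-empty subset of the covariates (7 models for
#' 3 covariates; the intercept-only model is excluded by default), ranks
#' by AIC, and computes Akaike weights, cumulative weights, and the
#' per-covariate summed weight ("relative importance").
#'
#' @param data data.frame containing the response and covariates.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names.
#' @param include_null also fit the intercept-only model (default FALSE).
#' @return object of class `model_rank_table`: data.frame `table` (model,
#'   K, AIC, delta_AIC, weight, cum_weight, one 0/1 column per covariate),
#'   `importance` (named summed weights), `fits` (the `nb_fit` objects).
#' @export
model_selection <- function(data, response, covariates,
                            include_null = FALSE) {
  if (length(covariates) < 1) stop("need at least one covariate")
  subsets <- list()
  for (k in seq_along(covariates))
    subsets <- c(subsets, utils::combn(covariates, k, simplify = FALSE))
  if (include_null) subsets <- c(list(character(0)), subsets)
  fits <- list(); rows <- list(); failed <- character(0)
  for (ss in subsets) {
    rhs <- if (length(ss)) paste(ss, collapse = " + ") else "1"
    f <- stats::as.formula(paste(response, "~", rhs))
    label <- paste(response, "~", rhs)
    fit <- try(fit_negbin(f, data), silent = TRUE)
    if (inherits(fit, "try-error")) {
      failed <- c(failed, label)
      next
    }
    fits[[label]] <- fit
    row <- data.frame(model = label, K = fit$K, AIC = fit$AIC)
    for (cv in covariates) row[[cv]] <- as.integer(cv %in% ss)
    rows[[label]] <- row
  }
  if (length(failed))
    warning("non-convergent model(s) excluded: ", paste(failed, collapse = "; "))
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$weight <- akaike_weights(tab$AIC)
  tab$cum_weight <- cumsum(tab$weight)
  tab <- tab[, c("model", "K", "AIC", "delta_AIC", "weight", "cum_weight",
                 covariates)]
  rownames(tab) <- NULL
  importance <- vapply(covariates,
                       function(cv) sum(tab$weight[tab[[cv]] == 1]),
                       numeric(1))
  structure(list(table = tab, importance = importance, fits = fits,
                 failed = failed),
            class = "model_rank_table")
}

#' @export
print.model_rank_table <- function(x, ...) {
  tab <- x$table
  tab$AIC <- round(tab$AIC, 2)
  tab$delta_AIC <- round(tab$delta_AIC, 2)
  tab$weight <- round(tab$weight, 2)
  tab$cum_weight <- round(tab$cum_weight, 2)
  print(tab, row.names = FALSE)
  cat("summed AIC-weight importance:\n")
  print(round(x$importance, 2))
  invisible(x)
}

#' Chi-square goodness of fit from residual deviance
#'
#' Upper-tail probability of the chi-square distribution with `df`
#' degrees of freedom evaluated at the residual deviance; p > 0.05 is the
#' conventional acceptable-fit bound.
#'
#' @param residual_deviance nonnegative deviance.
#' @param df degrees of freedom (>= 1), supplied explicitly so either
#'   parameter-counting convention can be reproduced.
#' @export
gof_chi2 <- function(residual_deviance, df) {
  if (df < 1) stop("df must be >= 1")
  if (residual_deviance < 0) stop("deviance must be >= 0")
  stats::pchisq(residual_deviance, df, lower.tail = FALSE)
}

#' Pairwise collinearity check
#'
#' Pearson correlations between covariate columns, flagging any pair with
#' |r| above the threshold.  Zero-variance columns give NA entries and
#' are flagged.
#'
#' @param X matrix/data.frame with >= 2 columns.
#' @param threshold flag bound (default 0.7; a conservative rule of thumb).
#' @return list with `correlations`, `flagged` (data.frame of offending
#'   pairs), `degenerate` (zero-variance column names).
#' @export
collinearity <- function(X, threshold = 0.7) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need >= 2 columns")
  sds <- vapply(X, stats::sd, numeric(1))
  degenerate <- names(sds)[sds == 0]
  r <- suppressWarnings(stats::cor(as.matrix(X)))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  bad <- ut[!is.na(r[ut]) & abs(r[ut]) >= threshold, , drop = FALSE]
  flagged <- data.frame(var1 = colnames(r)[bad[, 1]],
                        var2 = colnames(r)[bad[, 2]],
                        r = r[bad])
  list(correlations = r, flagged = flagged, degenerate = degenerate)
}
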