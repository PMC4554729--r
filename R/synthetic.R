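# Synthetic study scenarios: trap grids, latent populations, capture
# histories, sign surveys and elevation grids with the statistical
# structure the analysis assumes, so the whole pipeline runs with no
# field data.

#' Generate a systematic trap grid
#'
#' Divides a rectangular study area into cells and places traps uniformly
#' at random within each cell, rejection-sampling until all pairwise
#' distances meet the minimum spacing.  The default preset is the 5 x 4
#' cell, 4 km, 3-traps-per-cell design (60 traps over 480 km^2, >= 1 km
#' apart) with daily occasions.
#'
#' @param n_cells_x,n_cells_y cell grid dimensions.
#' @param cell_km cell side, km.
#' @param traps_per_cell stations per cell.
#' @param min_spacing_m minimum between-trap distance, metres.
#' @param n_occasions daily occasions for the (all-active) activity matrix.
#' @param seed integer RNG seed (required).
#' @param max_tries rejection-sampling budget per cell.
#' @return a [trap_array].
#' @export
generate_trap_grid <- function(n_cells_x = 5, n_cells_y = 4, cell_km = 4,
                               traps_per_cell = 3, min_spacing_m = 1000,
                               n_occasions = 93, seed, max_tries = 5000) {
  if (missing(seed)) stop("seed must be supplied")
  set.seed(seed)
  cell_m <- cell_km * 1000
  xs <- ys <- numeric(0)
  for (cx in seq_len(n_cells_x)) for (cy in seq_len(n_cells_y)) {
    x0 <- (cx - 1) * cell_m; y0 <- (cy - 1) * cell_m
    for (t in seq_len(max_tries)) {
      px <- x0 + stats::runif(traps_per_cell) * cell_m
      py <- y0 + stats::runif(traps_per_cell) * cell_m
      # spacing against traps in this cell and all already-placed ones
      ok <- TRUE
      if (traps_per_cell > 1 &&
          min(stats::dist(cbind(px, py))) < min_spacing_m) ok <- FALSE
      if (ok && length(xs)) {
        d2 <- outer(px, xs, "-")^2 + outer(py, ys, "-")^2
        if (min(d2) < min_spacing_m^2) ok <- FALSE
      }
      if (ok) break
      if (t == max_tries)
        stop("could not place ", traps_per_cell, " traps at spacing >= ",
             min_spacing_m, " m in a ", cell_km, " km cell")
    }
    xs <- c(xs, px); ys <- c(ys, py)
  }
  trap_array(sprintf("T%03d", seq_along(xs)), xs, ys,
             n_occasions = n_occasions)
}

#' Gaussian random field on a point set
#'
#' Zero-mean field with exponential covariance
#' `sill * exp(-d / range_m)`, generated by Cholesky factorisation of the
#' covariance matrix (with jitter retries if the factorisation fails
#' numerically).
#'
#' @param points two-column matrix/data.frame of coordinates (metres).
#' @param range_m correlation range, metres.
#' @param sill marginal variance (0 gives the zero field).
#' @param seed integer RNG seed (required).
#' @export
gaussian_random_field <- function(points, range_m, sill, seed) {
  if (missing(seed)) stop("seed must be supplied")
  if (range_m <= 0) stop("range_m must be > 0")
  if (sill < 0) stop("sill must be >= 0")
  points <- as.matrix(points)
  n <- nrow(points)
  if (sill == 0) return(rep(0, n))
  set.seed(seed)
  d <- as.matrix(stats::dist(points))
  C <- sill * exp(-d / range_m)
  jitter <- 0
  for (t in 1:5) {
    L <- try(chol(C + diag(jitter, n)), silent = TRUE)
    if (!inherits(L, "try-error")) break
    jitter <- max(jitter * 10, 1e-8 * sill)
    message("covariance factorisation failed; retrying with jitter ", jitter)
  }
  if (inherits(L, "try-error")) stop("covariance matrix not factorisable")
  drop(crossprod(L, stats::rnorm(n)))
}

#' Generate sign surveys over survey cells
#'
#' One survey per cell: `segments_per_cell[i]` 250 m transect segments,
#' each with a Bernoulli sign detection whose probability is the
#' inverse-logit of `link_scale` times the latent field value at the cell
#' centroid.  Between 12 and 36 segments per cell corresponds to the 3-9
#' km of transect walked per 16 km^2 cell in the emulated design.
#'
#' @param prey_field,grazing_field latent field values, one per cell.
#' @param cells data.frame with `cell_id`, `x`, `y` centroids.
#' @param segments_per_cell integer vector (or scalar) in 12..36.
#' @param link_scale logit slope on the latent field.
#' @param seed integer RNG seed (required).
#' @return a sign-survey data.frame as consumed by [sign_index()].
#' @export
generate_sign_survey <- function(prey_field, grazing_field, cells,
                                 segments_per_cell, link_scale = 1.5,
                                 seed) {
  if (missing(seed)) stop("seed must be supplied")
  set.seed(seed)
  n <- nrow(cells)
  segs <- rep_len(segments_per_cell, n)
  if (any(segs < 12 | segs > 36))
    stop("segments_per_cell must be between 12 and 36 (3-9 km of transect)")
  p_prey <- stats::plogis(link_scale * prey_field)
  p_grz <- stats::plogis(link_scale * grazing_field)
  data.frame(cell_id = cells$cell_id, x = cells$x, y = cells$y,
             n_segments = segs,
             prey_pos = stats::rbinom(n, segs, p_prey),
             grazing_pos = stats::rbinom(n, segs, p_grz))
}

#' Generate a synthetic elevation grid
#'
#' Smoothed Gaussian noise at a fixed resolution (90 m by default,
#' matching SRTM granularity), giving mountainous relief with tunable
#' roughness.
#'
#' @param xlim,ylim extent in metres.
#' @param res_m grid resolution, metres.
#' @param base_elev_m,relief_m mean elevation and relief amplitude.
#' @param smooth_cells half-width of the moving-average smoother, cells.
#' @param seed integer RNG seed (required).
#' @return list `x`, `y`, `z` as consumed by [slope_sd_surface()].
#' @export
generate_dem <- function(xlim, ylim, res_m = 90, base_elev_m = 3500,
                         relief_m = 600, smooth_cells = 5, seed) {
  if (missing(seed)) stop("seed must be supplied")
  set.seed(seed)
  x <- seq(xlim[1] + res_m / 2, xlim[2], by = res_m)
  y <- seq(ylim[1] + res_m / 2, ylim[2], by = res_m)
  z <- matrix(stats::rnorm(length(x) * length(y)), length(x), length(y))
  k <- 2 * smooth_cells + 1
  # separable moving-average smoother (reflect at edges via running means)
  sm <- function(m) {
    cs <- apply(m, 2, function(col) {
      stats::filter(c(rev(col[1:smooth_cells]), col,
                      rev(col[(length(col) - smooth_cells + 1):length(col)])),
                    rep(1 / k, k))[(smooth_cells + 1):(smooth_cells + length(col))]
    })
    cs
  }
  z <- sm(z); z <- t(sm(t(z)))
  z <- base_elev_m + relief_m * z / stats::sd(z)
  list(x = x, y = y, z = z)
}

#' Default generating parameters of the synthetic scenario
#'
#' The stated world of the emulated study: a 60-trap systematic grid over
#' 480 km^2 sampled for 93 daily occasions, half-normal detection with
#' `sigma = 4784.7 m` and `lam0 = 0.0036`, a state space with a 24 km
#' buffer and 1.96 km^2 pixels, density 3.3147 per 100 km^2, and
#' augmentation psi = 0.4986 at M = 220.  Suitable habitat is trimmed to
#' the area (~3310 km^2) at which that density and psi describe the same
#' expected population.
#' @export
scenario_defaults <- function() {
  list(n_cells_x = 5, n_cells_y = 4, cell_km = 4, traps_per_cell = 3,
       min_spacing_m = 1000, n_occasions = 93,
       buffer_km = 24, pixel_km2 = 1.96,
       density = 3.3147, psi = 0.4986, M = 220,
       lam0 = 0.0036, sigma = 4784.7201, kind = "half_normal",
       sign_range_m = 6000, sign_sill = 1, link_scale = 1.5,
       dem_res_m = 90)
}

#' Generate a complete synthetic study scenario
#'
#' Composes a trap grid, buffered state space with a habitat mask, latent
#' population and capture history, sign surveys on the survey cells, and
#' an elevation grid, all from one master seed.  The habitat mask keeps
#' the pixels nearest the trap array up to the suitable area implied by
#' the density/psi pair (a synthetic stand-in for the field habitat
#' delineation).  Regenerating with the same seed is bitwise identical.
#'
#' @param overrides named list overriding [scenario_defaults()].
#' @param seed master integer seed (required).
#' @param dem generate the elevation grid too (default TRUE; it is the
#'   slowest component).
#' @return object of class `scenario`: list with `traps`, `state_space`,
#'   `history`, `latent`, `survey`, `dem`, `cells`, `params`, `seed`.
#' @export
generate_scenario <- function(overrides = list(), seed, dem = TRUE) {
  if (missing(seed)) stop("seed must be supplied")
  prm <- utils::modifyList(scenario_defaults(), overrides)
  traps <- generate_trap_grid(prm$n_cells_x, prm$n_cells_y, prm$cell_km,
                              prm$traps_per_cell, prm$min_spacing_m,
                              prm$n_occasions, seed = seed)
  ss <- build_state_space(traps, prm$buffer_km * 1000, prm$pixel_km2)
  # habitat mask: keep pixels nearest the trap array up to the area that
  # makes density and psi consistent (area = 100 * M * psi / density)
  if (!is.null(prm$psi) && !is.null(prm$density)) {
    target_km2 <- 100 * prm$M * prm$psi / prm$density
    n_keep <- min(round(target_km2 / prm$pixel_km2), length(ss$x))
    d2min <- rep(Inf, length(ss$x))
    for (j in seq_along(traps$x))
      d2min <- pmin(d2min, (ss$x - traps$x[j])^2 + (ss$y - traps$y[j])^2)
    mask <- rank(d2min, ties.method = "first") <= n_keep
    ss <- apply_habitat_mask(ss, mask)
  }
  params <- detection_params(prm$lam0, prm$sigma, prm$kind)
  truth <- list(params = params, psi = prm$psi, M = prm$M)
  if (is.null(prm$psi)) truth$density <- prm$density
  sim <- simulate_secr(truth, traps, ss, seed = seed + 1L)

  cell_m <- prm$cell_km * 1000
  cells <- expand.grid(cx = seq_len(prm$n_cells_x), cy = seq_len(prm$n_cells_y))
  cells <- data.frame(cell_id = sprintf("C%02d", seq_len(nrow(cells))),
                      x = (cells$cx - 0.5) * cell_m,
                      y = (cells$cy - 0.5) * cell_m)
  prey_f <- gaussian_random_field(cells[, c("x", "y")], prm$sign_range_m,
                                  prm$sign_sill, seed = seed + 2L)
  grz_f <- gaussian_random_field(cells[, c("x", "y")], prm$sign_range_m,
                                 prm$sign_sill, seed = seed + 3L)
  set.seed(seed + 4L)
  segs <- sample(12:36, nrow(cells), replace = TRUE)
  survey <- generate_sign_survey(prey_f, grz_f, cells, segs,
                                 prm$link_scale, seed = seed + 5L)
  dem_grid <- NULL
  if (dem)
    dem_grid <- generate_dem(c(0, prm$n_cells_x * cell_m),
                             c(0, prm$n_cells_y * cell_m),
                             res_m = prm$dem_res_m, seed = seed + 6L)
  structure(list(traps = traps, state_space = ss, history = sim$history,
                 latent = sim$latent, survey = survey, dem = dem_grid,
                 cells = cells,
                 fields = data.frame(cell_id = cells$cell_id,
                                     prey = prey_f, grazing = grz_f),
                 params = prm, seed = seed),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario (seed %d): %d traps, %d occasions, %d suitable pixels (%.0f km^2)\n",
              x$seed, length(x$traps$trap_id), ncol(x$traps$activity),
              sum(x$state_space$suitable), suitable_area_km2(x$state_space)))
  if (is.null(x$history)) cat("  no individuals detected\n") else
    cat(sprintf("  N = %d, detected %d, captures %d\n", x$latent$N,
                x$history$n_individuals, sum(x$history$y)))
  invisible(x)
}

#' Write every scenario artefact as CSV
#'
#' Emits the capture, deployment, state-space and sign-survey dialects
#' plus a JSON manifest of the generating parameters and seed.
#'
#' @param scn a `scenario`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_scenario <- function(scn, dir) {
  stopifnot(inherits(scn, "scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(captures = file.path(dir, "captures.csv"),
             traps = file.path(dir, "trap_deployment.csv"),
             state_space = file.path(dir, "state_space.csv"),
             survey = file.path(dir, "sign_survey.csv"),
             manifest = file.path(dir, "manifest.json"))
  if (!is.null(scn$history)) {
    idx <- which(scn$history$y == 1L, arr.ind = TRUE)
    rec <- data.frame(trap_id = scn$traps$trap_id[idx[, 2]],
                      individual_id = scn$history$individual_id[idx[, 1]],
                      occasion = idx[, 3])
    rec <- rec[order(rec$individual_id, rec$occasion, rec$trap_id), ]
    write_capture_records(rec, paths["captures"])
  }
  write_trap_deployment(scn$traps, paths["traps"])
  write_state_space(scn$state_space, paths["state_space"])
  utils::write.csv(data.frame(CELL_ID = scn$survey$cell_id,
                              X = scn$survey$x, Y = scn$survey$y,
                              N_SEGMENTS = scn$survey$n_segments,
                              PREY_POS = scn$survey$prey_pos,
                              GRAZING_POS = scn$survey$grazing_pos),
                   paths["survey"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(scn$params, list(seed = scn$seed)),
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a sign-survey CSV (CELL_ID, X, Y, N_SEGMENTS, PREY_POS, GRAZING_POS)
#' @param path CSV file path.
#' @export
read_sign_survey <- function(path) {
  df <- utils::read.csv(path)
  need <- c("CELL_ID", "X", "Y", "N_SEGMENTS", "PREY_POS", "GRAZING_POS")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sign-survey file missing column(s): ",
                         paste(miss, collapse = ", "))
  data.frame(cell_id = df$CELL_ID, x = df$X, y = df$Y,
             n_segments = df$N_SEGMENTS, prey_pos = df$PREY_POS,
             grazing_pos = df$GRAZING_POS)
}
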