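# Estimator-evaluation study: simulate many datasets at a known truth,
# refit each, and tabulate bias, RMSE and 95% HPD coverage for density
# and psi.

#' Root-mean-squared error
#' @param estimates numeric vector of point estimates.
#' @param truth the generating value.
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) == 0) stop("rmse of an empty vector is undefined")
  sqrt(mean((estimates - truth)^2))
}

#' HPD interval coverage, percent
#' @param intervals two-column matrix/data.frame (lower, upper).
#' @param truth the generating value.
#' @export
hpd_coverage <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  if (nrow(intervals) == 0) stop("no intervals")
  if (any(intervals[, 1] > intervals[, 2]))
    stop("interval with lower > upper")
  100 * mean(intervals[, 1] <= truth & truth <= intervals[, 2])
}

# deterministic, order-independent per-dataset seed (counter-based; kept
# below 2^31 so it is a valid R integer)
.dataset_seed <- function(master, d) {
  as.integer((as.double(master) * 48271 + d * 9973) %% 2147483647) + 1L
}

#' Run a simulation study of the SECR estimator
#'
#' Simulates `n_datasets` capture histories at a known truth, refits each
#' with [fit_secr()], and records the posterior mean/mode/median and 95%
#' HPD bounds for density and psi.  Datasets with zero detected
#' individuals are logged and skipped, never silently dropped.
#'
#' @param truth truth spec as in [simulate_secr()] (needs `psi` + `M` or
#'   `density`, plus `params`).
#' @param traps,state_space the sampling design.
#' @param n_datasets number of replicate datasets (>= 1).
#' @param fit_config a [secr_config()] used for every refit; its seed is
#'   overridden per dataset.
#' @param seed master seed; per-dataset seeds derive deterministically
#'   from (seed, dataset index) so reruns are bitwise identical.
#' @return object of class `sim_study`: list with `results` (one row per
#'   fitted dataset), `skipped` (log of unusable datasets), `truth`
#'   (including the density/psi values implied by the design), and the
#'   configs.
#' @export
run_simulation_study <- function(truth, traps, state_space, n_datasets,
                                 fit_config = secr_config(), seed) {
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  if (missing(seed)) stop("a master seed is required")
  area <- suitable_area_km2(state_space)
  truth_density <- if (!is.null(truth$density)) truth$density else
    truth$psi * truth$M / area * 100
  truth_psi <- if (!is.null(truth$psi)) truth$psi else NA_real_
  rows <- list()
  skipped <- list()
  for (d in seq_len(n_datasets)) {
    sd_d <- .dataset_seed(seed, d)
    sim <- simulate_secr(truth, traps, state_space, seed = sd_d)
    if (is.null(sim$history)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(dataset = d, seed = sd_d, reason = "zero detected individuals")
      next
    }
    cfg <- fit_config
    cfg$seed <- .dataset_seed(sd_d, 1L)
    fit <- fit_secr(sim$history, traps, state_space, cfg)
    sd_dens <- posterior_summary(fit$chains$density)
    sd_psi <- posterior_summary(fit$chains$psi)
    rows[[length(rows) + 1]] <- data.frame(
      dataset = d, seed = sd_d, n_detected = sim$history$n_individuals,
      N_true = sim$latent$N,
      density_mean = sd_dens$mean, density_mode = sd_dens$mode,
      density_median = sd_dens$median,
      density_hpd_lower = sd_dens$hpd_lower,
      density_hpd_upper = sd_dens$hpd_upper,
      psi_mean = sd_psi$mean, psi_mode = sd_psi$mode,
      psi_median = sd_psi$median,
      psi_hpd_lower = sd_psi$hpd_lower, psi_hpd_upper = sd_psi$hpd_upper)
  }
  structure(list(
    results = if (length(rows)) do.call(rbind, rows) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    truth = list(density = truth_density, psi = truth_psi, spec = truth),
    n_datasets = n_datasets, fit_config = fit_config, seed = seed),
    class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d requested, %d fitted, %d skipped\n",
              x$n_datasets,
              if (is.null(x$results)) 0L else nrow(x$results),
              if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  invisible(x)
}

#' Summarise a simulation study
#'
#' For density and psi: the mean of each point estimator (posterior mean,
#' mode, median), its RMSE against the truth, and the 95% HPD coverage.
#'
#' @param study a `sim_study`.
#' @return data.frame with one row per parameter and columns `truth`,
#'   `mean`, `rmse_mean`, `mode`, `rmse_mode`, `median`, `rmse_median`,
#'   `coverage`.
#' @export
summarize_study <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  res <- study$results
  if (is.null(res) || nrow(res) == 0) stop("no fitted datasets to summarise")
  one <- function(par, truth) {
    est <- function(w) res[[paste0(par, "_", w)]]
    data.frame(
      parameter = par, truth = truth, n = nrow(res),
      mean = mean(est("mean")), rmse_mean = rmse(est("mean"), truth),
      mode = mean(est("mode")), rmse_mode = rmse(est("mode"), truth),
      median = mean(est("median")), rmse_median = rmse(est("median"), truth),
      coverage = hpd_coverage(
        cbind(est("hpd_lower"), est("hpd_upper")), truth))
  }
  rbind(one("density", study$truth$density),
        one("psi", study$truth$psi))
}

#' Write study results and summary to CSV
#' @param study a `sim_study`.
#' @param results_path,summary_path output CSV paths (NULL to skip one).
#' @export
write_study <- function(study, results_path = NULL, summary_path = NULL) {
  if (!is.null(results_path))
    utils::write.csv(study$results, results_path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(summarize_study(study), summary_path, row.names = FALSE)
  invisible(study)
}
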