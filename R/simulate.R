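#' Parameters of the pacemaker simulation
#'
#' The generator draws chronological ages, site rates and start levels,
#' perturbs each individual's age multiplicatively by its pacemaker tick
#' (t_j' = t_j (1 + e_j), e_j ~ N(0, sigma_t2)), builds noiseless
#' trajectories s_ij = s_i0 + r_i t_j', and adds iid Gaussian observation
#' noise with variance sigma_s2.
#'
#' Defaults emulate an adult human methylation-array cohort: ages uniform
#' on 10-100 years; per-site rates uniform on +/-0.03 methylation units per
#' year with |r| >= 0.005 (age-associated CpGs drift by at most a few
#' percent of the beta scale per year, and near-zero rates make a site
#' uninformative about time); start levels uniform on the beta scale [0, 1].
#' The model itself is unbounded — no clamping to [0, 1] is applied, since
#' the noise is Gaussian by assumption.
#'
#' @param n_sites,n_individuals Matrix dimensions.
#' @param sigma_t2 Pacemaker variance (variance of the multiplicative age
#'   perturbation; unitless).
#' @param sigma_s2 Observation-noise variance on methylation levels.
#' @param age_range,rate_range,start_range Ranges (min, max) for the uniform
#'   draws of ages (years), site rates (units/year) and start levels.
#' @param min_abs_rate Resample rates with |r| below this.
#' @param seed Integer seed; identical parameters and seed give a
#'   bitwise-identical dataset.
#' @return A list of class \code{simulation_params}.
#' @export
simulation_params <- function(n_sites, n_individuals, sigma_t2, sigma_s2,
                              age_range = c(10, 100),
                              rate_range = c(-0.03, 0.03),
                              min_abs_rate = 0.005,
                              start_range = c(0, 1),
                              seed = 1L) {
  stopifnot(n_sites >= 1, n_individuals >= 1, sigma_t2 >= 0, sigma_s2 >= 0)
  for (rg in list(age_range, rate_range, start_range))
    if (length(rg) != 2 || rg[1] > rg[2])
      rlang::abort("Ranges must be (lo, hi) with lo <= hi.",
                   class = "upmclock_error_validation")
  if (age_range[1] <= 0)
    rlang::abort("Ages must be strictly positive.", class = "upmclock_error_validation")
  if (min_abs_rate < 0 || min_abs_rate >= max(abs(rate_range)))
    rlang::abort("min_abs_rate must be nonnegative and below max |rate_range|.",
                 class = "upmclock_error_validation")
  structure(list(n_sites = as.integer(n_sites),
                 n_individuals = as.integer(n_individuals),
                 sigma_t2 = sigma_t2, sigma_s2 = sigma_s2,
                 age_range = age_range, rate_range = rate_range,
                 min_abs_rate = min_abs_rate, start_range = start_range,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

resample_until <- function(n, draw, keep) {
  x <- draw(n)
  bad <- !keep(x)
  while (any(bad)) {
    x[bad] <- draw(sum(bad))
    bad <- !keep(x)
  }
  x
}

#' Generate a pacemaker-perturbed synthetic methylation dataset
#'
#' @param params A [simulation_params()] object.
#' @return A list of class \code{synthetic_dataset}: \code{dataset} (a
#'   [methylation_dataset()] holding the noisy matrix and the UNperturbed
#'   chronological ages), \code{true_rates}, \code{true_starts},
#'   \code{true_perturbed_times} (the pacemaker times t_j'),
#'   \code{noiseless} (matrix before observation noise) and \code{params}.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_params(5, 4, sigma_t2 = 0.1, sigma_s2 = 1, seed = 7))
#' sim$dataset
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_sites; m <- params$n_individuals
  withr::with_seed(params$seed, {
    ages <- stats::runif(m, params$age_range[1], params$age_range[2])
    rates <- resample_until(
      n,
      function(k) stats::runif(k, params$rate_range[1], params$rate_range[2]),
      function(x) abs(x) >= params$min_abs_rate
    )
    starts <- stats::runif(n, params$start_range[1], params$start_range[2])
    # multiplicative pacemaker tick per individual; resample the rare
    # perturbations that would send a time nonpositive
    eps <- resample_until(
      m,
      function(k) stats::rnorm(k, 0, sqrt(params$sigma_t2)),
      function(x) x > -1
    )
    perturbed <- ages * (1 + eps)
    noiseless <- outer(rates, perturbed) + starts
    observed <- noiseless +
      matrix(stats::rnorm(n * m, 0, sqrt(params$sigma_s2)), n, m)
  })
  site_ids <- sprintf("site_%03d", seq_len(n))
  ind_ids <- sprintf("ind_%03d", seq_len(m))
  dimnames(observed) <- list(site_ids, ind_ids)
  ds <- methylation_dataset(observed, ages = ages)
  structure(list(dataset = ds,
                 true_rates = stats::setNames(rates, site_ids),
                 true_starts = stats::setNames(starts, site_ids),
                 true_perturbed_times = stats::setNames(perturbed, ind_ids),
                 noiseless = noiseless,
                 params = params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_dataset> %d sites x %d individuals (sigma_t2 = %g, sigma_s2 = %g, seed = %d)\n",
              p$n_sites, p$n_individuals, p$sigma_t2, p$sigma_s2, p$seed))
  invisible(x)
}

#' Write a synthetic dataset to matrix/ages/truth files
#'
#' @param sim A \code{synthetic_dataset}.
#' @param prefix Output path prefix; writes \code{<prefix>.matrix.tsv},
#'   \code{<prefix>.ages.tsv}, \code{<prefix>.truth.tsv}.
#' @return Invisibly, the three paths.
#' @export
write_synthetic_dataset <- function(sim, prefix) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  ds <- sim$dataset
  mat <- tibble::as_tibble(ds$values, rownames = "site_id")
  paths <- paste0(prefix, c(".matrix.tsv", ".ages.tsv", ".truth.tsv"))
  write_table(mat, paths[1])
  write_table(tibble::tibble(individual_id = ds$individual_ids,
                             age = unname(ds$ages)), paths[2])
  write_table(tibble::tibble(individual_id = ds$individual_ids,
                             perturbed_time = unname(sim$true_perturbed_times)),
              paths[3])
  invisible(paths)
}
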