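#' Search options for the pacemaker fit
#'
#' @param n_starts Number of random restarts (>= 1). The first start always
#'   uses the chronological ages unjittered, which guarantees the returned
#'   RSS never exceeds the clock-model RSS; later starts multiply the ages
#'   by iid lognormal jitter (sdlog 0.2).
#' @param max_outer_iters Cap on outer iterations per start.
#' @param rel_tol Convergence tolerance on the relative RSS improvement.
#' @param time_lower_bound Lower bound on epigenetic times in years;
#'   negative or zero times are biologically meaningless and break the
#'   average-rate definition.
#' @param seed Integer seed controlling the restart jitter.
#' @param strategy \code{"alternating"} (block coordinate descent on the
#'   bilinear RSS; default, fast) or \code{"direct-search"} (bounded
#'   quasi-Newton search over the m-vector of times with the closed-form
#'   site fit inside, mirroring the sequential least-squares approach).
#' @return A list of class \code{upm_options}.
#' @export
upm_options <- function(n_starts = 10, max_outer_iters = 500, rel_tol = 1e-9,
                        time_lower_bound = 1e-3, seed = 1L,
                        strategy = c("alternating", "direct-search")) {
  strategy <- match.arg(strategy)
  stopifnot(n_starts >= 1, rel_tol > 0, time_lower_bound > 0, max_outer_iters >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 max_outer_iters = as.integer(max_outer_iters),
                 rel_tol = rel_tol, time_lower_bound = time_lower_bound,
                 seed = as.integer(seed), strategy = strategy),
            class = "upm_options")
}

#' Site parameters conditional on a candidate time vector
#'
#' Given candidate epigenetic times, the RSS is again linear in the site
#' parameters, so rates and start levels have the same closed-form solution
#' as the clock fit with times replaced by the candidate vector.
#'
#' @param ds A [methylation_dataset()].
#' @param candidate_times Strictly positive vector, length m, at least two
#'   distinct values.
#' @return A list: rates, starts, rss (as from [fit_mc()]).
#' @export
conditional_site_fit <- function(ds, candidate_times) {
  fit <- fit_mc(ds, times = candidate_times)
  list(rates = fit$rates, starts = fit$starts, rss = fit$rss)
}

#' Times conditional on fixed site parameters
#'
#' With rates and start levels fixed, the RSS separates over individuals and
#' each time has the closed-form minimiser
#' t_j = sum_i rates_i (s_ij - starts_i) / sum_i rates_i^2, clipped below at
#' \code{lower_bound}.
#'
#' @param ds A [methylation_dataset()].
#' @param rates,starts Site parameter vectors of length n.
#' @param lower_bound Positive lower bound applied elementwise.
#' @return Length-m vector of times.
#' @export
conditional_times_fit <- function(ds, rates, starts, lower_bound = 1e-3) {
  rates <- as.numeric(rates); starts <- as.numeric(starts)
  if (length(rates) != ds$n || length(starts) != ds$n)
    rlang::abort("rates/starts must have one entry per site.",
                 class = "upmclock_error_validation")
  denom <- sum(rates^2)
  if (denom == 0)
    rlang::abort("All rates are zero: times are unidentifiable.",
                 class = "upmclock_error_singular")
  t_hat <- as.vector(crossprod(ds$values - starts, rates)) / denom
  pmax(t_hat, lower_bound)
}

upm_one_start <- function(ds, start_times, opts) {
  # below this, the rss is floating-point dust relative to the data scale:
  # treat the fit as exact rather than chase relative "improvements" in dust
  rss_floor <- 1e-20 * sum(ds$values^2)
  if (identical(opts$strategy, "alternating")) {
    times <- start_times
    rss_prev <- Inf
    sf <- NULL
    for (iter in seq_len(opts$max_outer_iters)) {
      sf <- tryCatch(conditional_site_fit(ds, times), error = function(e) NULL)
      if (is.null(sf)) {
        # degenerate candidate times (e.g. all clipped to the bound)
        return(list(ok = FALSE))
      }
      if (sf$rss <= rss_floor ||
          (is.finite(rss_prev) &&
           rss_prev - sf$rss <= opts$rel_tol * max(rss_prev, .Machine$double.eps))) break
      rss_prev <- sf$rss
      times <- conditional_times_fit(ds, sf$rates, sf$starts, opts$time_lower_bound)
    }
    list(times = times, rates = sf$rates, starts = sf$starts, rss = sf$rss,
         iters = iter, ok = TRUE)
  } else {
    obj <- function(tt) conditional_site_fit(ds, tt)$rss
    res <- tryCatch(
      stats::optim(start_times, obj, method = "L-BFGS-B",
                   lower = rep(opts$time_lower_bound, ds$m),
                   control = list(maxit = opts$max_outer_iters, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(res)) return(list(ok = FALSE))
    sf <- conditional_site_fit(ds, res$par)
    list(times = res$par, rates = sf$rates, starts = sf$starts, rss = sf$rss,
         iters = res$counts[[1]], ok = TRUE)
  }
}

#' Fit the universal pacemaker model
#'
#' Jointly estimates site rates, start levels and one epigenetic time per
#' individual by minimising the RSS (the maximum-likelihood solution under
#' Gaussian noise). The search runs only over the m-dimensional space of
#' times: for every candidate time vector the remaining parameters have a
#' closed-form least-squares solution. Multiple restarts guard against local
#' optima; the fit is reported in a fixed gauge with
#' mean(epigenetic times) = mean(chronological ages) (see
#' [normalize_scale()]).
#'
#' @param ds A validated [methylation_dataset()] with ages attached
#'   (n >= 2 sites, m >= 3 individuals).
#' @param opts An [upm_options()] object.
#' @return An object of class \code{upm_fit}: rates, starts,
#'   epigenetic_times, rss, n_starts, converged_rss_per_start,
#'   normalization, plus the chronological ages used.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_params(n_sites = 10, n_individuals = 8,
#'                                           sigma_t2 = 0.1, sigma_s2 = 0, seed = 1))
#' fit <- fit_upm(sim$dataset, upm_options(n_starts = 2, seed = 1))
#' fit$rss
fit_upm <- function(ds, opts = upm_options()) {
  stopifnot(inherits(ds, "methylation_dataset"), inherits(opts, "upm_options"))
  ds <- attach_ages(ds)
  if (all(ds$values == ds$values[, 1]))
    rlang::abort("Degenerate data: all individuals identical.",
                 class = "upmclock_error_singular")
  ages <- unname(ds$ages)
  jitter_seeds <- derive_seeds(opts$seed, opts$n_starts)
  results <- vector("list", opts$n_starts)
  for (k in seq_len(opts$n_starts)) {
    start_times <- if (k == 1L) ages else {
      withr::with_seed(jitter_seeds[k],
                       pmax(ages * stats::rlnorm(ds$m, 0, 0.2), opts$time_lower_bound))
    }
    results[[k]] <- upm_one_start(ds, start_times, opts)
  }
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok))
    rlang::abort("Optimizer failed on every start.", class = "upmclock_error_optim")
  results <- results[ok]
  rss_per_start <- vapply(results, `[[`, numeric(1), "rss")
  best <- results[[which.min(rss_per_start)]]
  fit <- structure(
    list(rates = best$rates, starts = best$starts,
         epigenetic_times = stats::setNames(best$times, ds$individual_ids),
         rss = best$rss,
         n_starts = opts$n_starts,
         converged_rss_per_start = rss_per_start,
         normalization = "none",
         chronological_ages = stats::setNames(ages, ds$individual_ids),
         strategy = opts$strategy, time_lower_bound = opts$time_lower_bound,
         n = ds$n, m = ds$m,
         site_ids = ds$site_ids, individual_ids = ds$individual_ids),
    class = "upm_fit"
  )
  normalize_scale(fit, ages)
}

#' Fix the scale gauge of a pacemaker fit
#'
#' The pacemaker likelihood is invariant to scaling all epigenetic times by
#' c > 0 and all rates by 1/c. This anchors the fit by
#' c = mean(chronological ages) / mean(epigenetic times), so epigenetic and
#' chronological ages live on the same scale and their ratio is directly
#' interpretable as age acceleration/deceleration.
#'
#' @param fit A \code{upm_fit}.
#' @param chronological_ages Length-m positive vector.
#' @return The rescaled fit (RSS unchanged); \code{normalization} records
#'   the convention. Idempotent.
#' @export
normalize_scale <- function(fit, chronological_ages = fit$chronological_ages) {
  stopifnot(inherits(fit, "upm_fit"))
  mt <- mean(fit$epigenetic_times)
  if (!is.finite(mt) || mt <= 0)
    rlang::abort("Mean epigenetic time must be positive to fix the scale.",
                 class = "upmclock_error_singular")
  c_scale <- mean(chronological_ages) / mt
  fit$epigenetic_times <- fit$epigenetic_times * c_scale
  fit$rates <- fit$rates / c_scale
  fit$normalization <- "mean_epigenetic_time_equals_mean_age"
  fit
}

#' Average (measurable) per-cell methylation rates
#'
#' r_ij = (s_ij - starts_i) / times_j, the average rate of site i in
#' individual j over that individual's lifetime. Under an exact pacemaker
#' the ratio r_ij / r_i'j is the same for every individual.
#'
#' @param ds A [methylation_dataset()].
#' @param starts Length-n start levels.
#' @param times Length-m strictly positive times.
#' @return An n x m matrix.
#' @export
average_rates <- function(ds, starts, times) {
  times <- as.numeric(times)
  if (any(times == 0))
    rlang::abort("Times must be nonzero.", class = "upmclock_error_validation")
  if (length(starts) != ds$n || length(times) != ds$m)
    rlang::abort("Dimension mismatch.", class = "upmclock_error_validation")
  sweep(ds$values - as.numeric(starts), 2, times, "/")
}

#' @export
print.upm_fit <- function(x, ...) {
  cat(sprintf("<upm_fit> %d sites x %d individuals (%s, %d starts)\n",
              x$n, x$m, x$strategy, x$n_starts))
  cat(sprintf("  rss = %.6g   rms error per entry = %.6g\n",
              x$rss, sqrt(x$rss / (x$n * x$m))))
  cat(sprintf("  gauge: %s\n", x$normalization))
  invisible(x)
}

#' Tidy per-site coefficients of a pacemaker fit
#'
#' @param x A \code{upm_fit}.
#' @param ... Unused.
#' @return A tibble with columns site_id, rate, start.
#' @method tidy upm_fit
#' @export
tidy.upm_fit <- function(x, ...) {
  tibble::tibble(site_id = x$site_ids, rate = unname(x$rates),
                 start = unname(x$starts))
}

#' One-row summary of a pacemaker fit
#'
#' @param x A \code{upm_fit}.
#' @param ... Unused.
#' @return A one-row tibble: n_sites, n_individuals, rss, rms_error,
#'   n_starts, n_converged, normalization.
#' @method glance upm_fit
#' @export
glance.upm_fit <- function(x, ...) {
  tibble::tibble(n_sites = x$n, n_individuals = x$m, rss = x$rss,
                 rms_error = sqrt(x$rss / (x$n * x$m)),
                 n_starts = x$n_starts,
                 n_converged = length(x$converged_rss_per_start),
                 normalization = x$normalization)
}

#' Per-individual epigenetic ages of a pacemaker fit
#'
#' @param x A \code{upm_fit}.
#' @return A tibble with columns individual_id, age, epigenetic_age, ratio
#'   (epigenetic over chronological), sorted by chronological age.
#' @export
epigenetic_ages <- function(x) {
  stopifnot(inherits(x, "upm_fit"))
  tibble::tibble(
    individual_id = x$individual_ids,
    age = unname(x$chronological_ages),
    epigenetic_age = unname(x$epigenetic_times),
    ratio = unname(x$epigenetic_times / x$chronological_ages)
  ) |> dplyr::arrange(.data$age)
}

# Deterministic stream of sub-seeds below 2^31, splitmix-style.
derive_seeds <- function(master, k) {
  x <- as.double(master %% 2147483646L) + 1
  out <- numeric(k)
  for (i in seq_len(k)) {
    x <- (x * 48271) %% 2147483647
    out[i] <- x
  }
  as.integer(out)
}
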