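#' Fit the molecular-clock model by closed-form least squares
#'
#' Under the molecular clock every site i drifts linearly in chronological
#' time: s_ij = s_i0 + r_i * t_j + e_ij with iid Gaussian noise. With times
#' fixed the residual sum of squares decouples across sites, so the maximum
#' likelihood fit is n independent simple linear regressions, computed here
#' in closed form (no iteration).
#'
#' @param ds A validated [methylation_dataset()] with ages attached (or see
#'   \code{times}).
#' @param times Optional explicit time vector overriding \code{ds$ages};
#'   strictly positive with at least two distinct values.
#' @return An object of class \code{mc_fit}: rates (r_i, methylation units
#'   per year), starts (s_i0), rss (total residual sum of squares),
#'   residuals (n x m matrix), site_rss, and the times used.
#' @export
#' @examples
#' ds <- methylation_dataset(matrix(c(3, 5), 1, 2), ages = c(1, 2))
#' fit <- fit_mc(ds)
#' fit$rates   # 2
#' fit$starts  # 1
fit_mc <- function(ds, times = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  times <- times %||% ds$ages
  if (is.null(times))
    rlang::abort("No times: attach ages or pass `times`.", class = "upmclock_error_validation")
  times <- as.numeric(times)
  if (length(times) != ds$m)
    rlang::abort("`times` length must equal the number of individuals.",
                 class = "upmclock_error_validation")
  if (any(!is.finite(times)) || any(times <= 0))
    rlang::abort("Times must be finite and strictly positive.",
                 class = "upmclock_error_validation")
  if (ds$n < 1 || ds$m < 2)
    rlang::abort("Need at least 1 site and 2 individuals.", class = "upmclock_error_insufficient")
  if (diff(range(times)) == 0)
    rlang::abort("All times equal: rate and start level are confounded (singular design).",
                 class = "upmclock_error_singular")

  S <- ds$values
  tc <- times - mean(times)
  sxx <- sum(tc^2)
  # slope_i = sum_j (t_j - tbar) s_ij / sxx ; intercept from the means
  rates <- as.vector(S %*% tc) / sxx
  starts <- rowMeans(S) - rates * mean(times)
  residuals <- S - outer(rates, times) - starts
  site_rss <- rowSums(residuals^2)
  structure(
    list(rates = stats::setNames(rates, ds$site_ids),
         starts = stats::setNames(starts, ds$site_ids),
         rss = sum(site_rss),
         site_rss = stats::setNames(site_rss, ds$site_ids),
         residuals = residuals,
         times = times,
         n = ds$n, m = ds$m,
         site_ids = ds$site_ids, individual_ids = ds$individual_ids),
    class = "mc_fit"
  )
}

#' Assemble the full design-matrix formulation of the clock fit
#'
#' Builds the mn x 2n system whose least-squares solution stacks all site
#' rates then all start levels: the row for cell (i, j) has times_j in
#' column i, 1 in column n + i, zeros elsewhere, and y entry s_ij. Solving
#' the normal equations of this system reproduces [fit_mc()]; it is exposed
#' as a cross-checking oracle (O((2n)^3)) rather than the production path
#' (O(nm)).
#'
#' @inheritParams fit_mc
#' @return A list with the design matrix \code{X} (mn x 2n) and response
#'   \code{y} (length mn), rows ordered site-major: row (i-1)*m + j is cell
#'   (i, j).
#' @export
build_design_matrix <- function(ds, times = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  times <- as.numeric(times %||% ds$ages)
  n <- ds$n; m <- ds$m
  X <- matrix(0, n * m, 2 * n)
  y <- numeric(n * m)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * m + seq_len(m)
    X[rows, i] <- times
    X[rows, n + i] <- 1
    y[rows] <- ds$values[i, ]
  }
  list(X = X, y = y)
}

#' Residual sum of squares of a parameterisation
#'
#' RSS = sum_ij (s_ij - rates_i * times_j - starts_i)^2, the quantity both
#' model fits minimise; minimising it is the maximum-likelihood solution
#' under iid Gaussian noise with a common variance.
#'
#' @inheritParams fit_mc
#' @param rates,starts Numeric vectors of length n.
#' @return Nonnegative scalar.
#' @export
rss_of <- function(ds, times, rates, starts) {
  stopifnot(inherits(ds, "methylation_dataset"))
  times <- as.numeric(times)
  if (length(times) != ds$m || length(rates) != ds$n || length(starts) != ds$n)
    rlang::abort("Dimension mismatch between dataset, times, rates, starts.",
                 class = "upmclock_error_validation")
  sum((ds$values - outer(as.numeric(rates), times) - as.numeric(starts))^2)
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("<mc_fit> %d sites x %d individuals\n", x$n, x$m))
  cat(sprintf("  rss = %.6g   rms error per entry = %.6g\n",
              x$rss, sqrt(x$rss / (x$n * x$m))))
  invisible(x)
}

#' Tidy per-site coefficients of a clock fit
#'
#' @param x An \code{mc_fit}.
#' @param ... Unused.
#' @return A tibble with columns site_id, rate, start, site_rss.
#' @method tidy mc_fit
#' @export
tidy.mc_fit <- function(x, ...) {
  tibble::tibble(site_id = x$site_ids, rate = unname(x$rates),
                 start = unname(x$starts), site_rss = unname(x$site_rss))
}

#' One-row summary of a clock fit
#'
#' \code{rms_error} is the root-mean-square residual per matrix entry,
#' sqrt(rss / (n m)).
#'
#' @param x An \code{mc_fit}.
#' @param ... Unused.
#' @return A one-row tibble: n_sites, n_individuals, rss, rms_error.
#' @method glance mc_fit
#' @export
glance.mc_fit <- function(x, ...) {
  tibble::tibble(n_sites = x$n, n_individuals = x$m, rss = x$rss,
                 rms_error = sqrt(x$rss / (x$n * x$m)))
}
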