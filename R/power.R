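#' One simulation trial of the pacemaker detection pipeline
#'
#' Simulates a dataset, fits the clock model on the chronological ages and
#' the pacemaker model on the matrix alone, and returns the p-value of the
#' likelihood-ratio test (df = number of individuals).
#'
#' @param params A [simulation_params()].
#' @param opts An [upm_options()].
#' @return The LRT p-value (scalar).
#' @export
run_single_trial <- function(params, opts = upm_options()) {
  sim <- simulate_dataset(params)
  res <- compare_models(sim$dataset, opts)
  res$p_value
}

#' Replicate-based power grid for pacemaker detection
#'
#' For each cell of a simulation grid, runs \code{n_replicates} independent
#' trials and records the detection frequency (fraction of replicates with
#' p < alpha) and the mean p-value. Per-replicate seeds are derived
#' deterministically from \code{seed}, so the whole grid is reproducible.
#'
#' @param grid A list of [simulation_params()] (their own seeds are
#'   overridden by the derived per-replicate seeds), or a data frame with
#'   columns sigma_t2, sigma_s2, n_sites, n_individuals (other generator
#'   settings at their defaults).
#' @param n_replicates Replicates per cell (>= 1).
#' @param alpha Significance threshold defining "detection".
#' @param opts [upm_options()] for the pacemaker fits; its seed is also
#'   re-derived per replicate.
#' @param seed Master seed.
#' @return A tibble of class \code{power_grid} with one row per cell:
#'   sigma_t2, sigma_s2, n_sites, n_individuals, n_replicates, alpha,
#'   detection_frequency, mean_p_value.
#' @export
#' @examples
#' grid <- expand.grid(sigma_t2 = 0.15, sigma_s2 = c(1, 5),
#'                     n_sites = 10, n_individuals = 15)
#' run_power_grid(grid, n_replicates = 3, seed = 42,
#'                opts = upm_options(n_starts = 2))
run_power_grid <- function(grid, n_replicates = 30, alpha = 0.05,
                           opts = upm_options(), seed = 1L) {
  stopifnot(n_replicates >= 1, alpha > 0, alpha <= 1)
  if (is.data.frame(grid)) {
    grid <- purrr::pmap(
      grid[c("sigma_t2", "sigma_s2", "n_sites", "n_individuals")],
      function(sigma_t2, sigma_s2, n_sites, n_individuals)
        simulation_params(n_sites = n_sites, n_individuals = n_individuals,
                          sigma_t2 = sigma_t2, sigma_s2 = sigma_s2)
    )
  }
  n_cells <- length(grid)
  seeds <- matrix(derive_seeds(seed, 2L * n_cells * n_replicates),
                  nrow = n_cells)
  rows <- purrr::imap(grid, function(params, cell) {
    pvals <- vapply(seq_len(n_replicates), function(rep) {
      params$seed <- seeds[cell, 2L * rep - 1L]
      opts$seed <- seeds[cell, 2L * rep]
      run_single_trial(params, opts)
    }, numeric(1))
    tibble::tibble(sigma_t2 = params$sigma_t2, sigma_s2 = params$sigma_s2,
                   n_sites = params$n_sites,
                   n_individuals = params$n_individuals,
                   n_replicates = n_replicates, alpha = alpha,
                   detection_frequency = mean(pvals < alpha),
                   mean_p_value = mean(pvals))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("power_grid", class(out))
  out
}

#' Plot detection frequency against observation noise
#'
#' @param object A \code{power_grid} from [run_power_grid()].
#' @param ... Unused.
#' @return A ggplot: detection frequency vs sigma_s2, one curve per site
#'   count, faceted by individuals when several are present.
#' @method autoplot power_grid
#' @export
autoplot.power_grid <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$sigma_s2,
                                    y = .data$detection_frequency,
                                    colour = factor(.data$n_sites))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = expression(sigma[s]^2 ~ "(site noise variance)"),
                  y = "Detection frequency",
                  colour = "Sites") +
    ggplot2::theme_minimal()
  if (length(unique(object$n_individuals)) > 1)
    p <- p + ggplot2::facet_wrap(~n_individuals, labeller = ggplot2::label_both)
  p
}
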