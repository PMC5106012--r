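#' Likelihood-ratio statistic comparing clock and pacemaker fits
#'
#' Under iid Gaussian noise with profiled variance, the maximised
#' log-likelihood of either model is -(nm/2) log(RSS) plus a shared
#' constant, so the log likelihood ratio of the nested pair is
#' log Lambda = -(nm/2) log(RSS_MC / RSS_UPM) and the test statistic is
#' chi2 = n m log(RSS_MC / RSS_UPM) (natural log), referred to a
#' chi-squared distribution with one degree of freedom per inferred
#' epigenetic time (df = m by default).
#'
#' @param rss_mc,rss_upm Positive residual sums of squares of the clock
#'   (null) and pacemaker (alternative) fits on the same data. rss_upm must
#'   not exceed rss_mc beyond floating-point noise (1e-8 relative, mapped to
#'   chi2 = 0); a larger excess signals an optimizer failure upstream and is
#'   an error, never clipped silently.
#' @param n,m Numbers of sites and individuals.
#' @param df Degrees of freedom; defaults to m.
#' @return An object of class \code{upm_lrt} with chi2, df, log_lambda,
#'   rss_mc, rss_upm and (after [lrt_pvalue()]) p_value.
#' @export
#' @examples
#' lrt_statistic(2, 1, n = 10, m = 5)$chi2  # 50 * log(2)
lrt_statistic <- function(rss_mc, rss_upm, n, m, df = m) {
  stopifnot(n >= 1, m >= 1, df >= 1)
  if (!is.finite(rss_mc) || !is.finite(rss_upm) || rss_mc <= 0)
    rlang::abort("RSS values must be finite and rss_mc > 0.",
                 class = "upmclock_error_validation")
  if (rss_upm <= 0)
    rlang::abort(paste("rss_upm is zero: the pacemaker model fits exactly and the",
                       "likelihood ratio is unbounded. This happens on noise-free",
                       "data; the test is not meaningful there."),
                 class = "upmclock_error_degenerate")
  if (rss_upm > rss_mc) {
    if ((rss_upm - rss_mc) / rss_mc <= 1e-8) {
      rss_upm <- rss_mc  # floating-point noise on identical optima
    } else {
      rlang::abort("rss_upm exceeds rss_mc: the pacemaker optimizer failed upstream (UPM nests MC).",
                   class = "upmclock_error_optim")
    }
  }
  chi2 <- n * m * log(rss_mc / rss_upm)
  structure(list(chi2 = chi2, df = as.integer(df), p_value = NA_real_,
                 rss_mc = rss_mc, rss_upm = rss_upm, log_lambda = -chi2 / 2,
                 n = n, m = m),
            class = "upm_lrt")
}

#' Attach the chi-squared p-value to a likelihood-ratio result
#'
#' @param result A \code{upm_lrt} from [lrt_statistic()].
#' @return The result with \code{p_value}, the upper-tail chi-squared
#'   probability at chi2 with df degrees of freedom.
#' @export
lrt_pvalue <- function(result) {
  stopifnot(inherits(result, "upm_lrt"), result$chi2 >= 0, result$df >= 1)
  result$p_value <- stats::pchisq(result$chi2, df = result$df, lower.tail = FALSE)
  result
}

#' Critical value of the chi-squared reference distribution
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Upper-tail probability in (0, 1).
#' @return The value x with P(Chi2_df > x) = alpha.
#' @export
#' @examples
#' round(chi2_critical(300, 0.01))  # 360
chi2_critical <- function(df, alpha) {
  stopifnot(df >= 1)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    rlang::abort("`alpha` must lie strictly between 0 and 1.",
                 class = "upmclock_error_validation")
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Run the full clock-versus-pacemaker comparison on a dataset
#'
#' Fits both models and returns the completed likelihood-ratio test.
#'
#' @param ds A validated [methylation_dataset()] with ages.
#' @param opts [upm_options()] controlling the pacemaker search.
#' @param df Degrees of freedom; defaults to the number of individuals.
#' @return A \code{upm_lrt} with p_value set, carrying the two fits as
#'   attributes \code{mc_fit} and \code{upm_fit}.
#' @export
compare_models <- function(ds, opts = upm_options(), df = NULL) {
  ds <- attach_ages(ds)
  mc <- fit_mc(ds)
  upm <- fit_upm(ds, opts)
  if (mc$rss <= 1e-20 * sum(ds$values^2)) {
    # both models fit exactly; the RSS ratio is floating-point dust, so the
    # comparison carries no evidence against the clock model
    res <- lrt_statistic(1, 1, n = ds$n, m = ds$m, df = df %||% ds$m)
    res$rss_mc <- mc$rss
    res$rss_upm <- upm$rss
  } else {
    res <- lrt_statistic(mc$rss, upm$rss, n = ds$n, m = ds$m, df = df %||% ds$m)
  }
  res <- lrt_pvalue(res)
  attr(res, "mc_fit") <- mc
  attr(res, "upm_fit") <- upm
  res
}

#' @export
print.upm_lrt <- function(x, ...) {
  cat("<upm_lrt> molecular clock (null) vs universal pacemaker\n")
  cat(sprintf("  rss_mc = %.6g  rss_upm = %.6g\n", x$rss_mc, x$rss_upm))
  cat(sprintf("  chi2 = %.4f  df = %d  p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' One-row summary of a likelihood-ratio comparison
#'
#' @param x A \code{upm_lrt}.
#' @param ... Unused.
#' @return A one-row tibble: rss_mc, rss_upm, chi2, df, log_lambda, p_value.
#' @method glance upm_lrt
#' @export
glance.upm_lrt <- function(x, ...) {
  tibble::tibble(rss_mc = x$rss_mc, rss_upm = x$rss_upm, chi2 = x$chi2,
                 df = x$df, log_lambda = x$log_lambda, p_value = x$p_value)
}
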