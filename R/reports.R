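#' Keep the k sites with the largest across-individual variance
#'
#' The standard pre-filter before model fitting on array data: sites whose
#' methylation barely varies across the cohort carry no age signal. Sample
#' variance uses the unbiased divisor m - 1. The default k = 300 matches
#' common epigenetic-clock practice.
#'
#' @param ds A [methylation_dataset()].
#' @param k Number of sites to keep, 1 <= k <= n.
#' @return A dataset of the k most variable sites ordered by descending
#'   variance (ties broken by original site order); ages preserved.
#' @export
select_top_variance_sites <- function(ds, k = 300) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (k < 1 || k > ds$n)
    rlang::abort(sprintf("`k` must be in [1, %d].", ds$n),
                 class = "upmclock_error_validation")
  v <- apply(ds$values, 1, stats::var)
  ord <- order(-v, seq_along(v))[seq_len(k)]
  out <- methylation_dataset(ds$values[ord, , drop = FALSE],
                             site_ids = ds$site_ids[ord],
                             individual_ids = ds$individual_ids)
  if (!is.null(ds$ages)) out <- set_ages(out, unname(ds$ages))
  out
}

#' Per-site clock/pacemaker rate-ratio report
#'
#' For each site, the ratio between its clock-model rate and its pacemaker
#' rate (MC/PM orientation). Sites are sorted ascending by ratio; the
#' \code{trim_fraction} most extreme rows at each end are flagged as
#' outliers for plotting (flagged, never deleted). A site with pacemaker
#' rate exactly zero gets an NA ratio and is excluded from the extremes
#' flagging.
#'
#' @param mc An \code{mc_fit}.
#' @param upm A \code{upm_fit} from the same dataset.
#' @param trim_fraction Fraction flagged at each end, in [0, 0.5).
#' @return A tibble of class \code{rate_ratio_report}: site_id, mc_rate,
#'   upm_rate, ratio, same_sign, decelerating (ratio <= 1 among same-sign
#'   sites), outlier.
#' @export
rate_ratio_report <- function(mc, upm, trim_fraction = 0.025) {
  stopifnot(inherits(mc, "mc_fit"), inherits(upm, "upm_fit"))
  if (!identical(mc$site_ids, upm$site_ids))
    rlang::abort("Fits come from different datasets (site ids differ).",
                 class = "upmclock_error_validation")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    rlang::abort("`trim_fraction` must lie in [0, 0.5).",
                 class = "upmclock_error_validation")
  out <- tibble::tibble(
    site_id = mc$site_ids,
    mc_rate = unname(mc$rates),
    upm_rate = unname(upm$rates),
    ratio = ifelse(upm_rate == 0, NA_real_, mc_rate / upm_rate),
    same_sign = sign(mc_rate) == sign(upm_rate)
  ) |>
    dplyr::mutate(decelerating = .data$same_sign & !is.na(.data$ratio) & .data$ratio <= 1) |>
    dplyr::arrange(is.na(.data$ratio), .data$ratio)
  n_def <- sum(!is.na(out$ratio))
  n_trim <- floor(trim_fraction * n_def)
  rank_def <- rank(out$ratio, na.last = "keep", ties.method = "first")
  out$outlier <- !is.na(rank_def) & (rank_def <= n_trim | rank_def > n_def - n_trim)
  class(out) <- c("rate_ratio_report", class(out))
  out
}

#' Per-individual epigenetic/chronological age-ratio report
#'
#' Ratio of the pacemaker-inferred epigenetic age to chronological age
#' (PM over chronological), one row per individual, sorted ascending by
#' chronological age. A ratio below 1 is age deceleration, above 1 age
#' acceleration.
#'
#' @param chronological Length-m positive vector of chronological ages, or
#'   NULL to use the ages stored in the fit.
#' @param upm A gauge-normalized \code{upm_fit}.
#' @return A tibble of class \code{age_ratio_report}: individual_id, age,
#'   epigenetic_age, ratio. Attribute \code{tercile_variance} holds the
#'   variance of the ratio within the youngest and oldest age terciles.
#' @export
age_ratio_report <- function(chronological = NULL, upm) {
  stopifnot(inherits(upm, "upm_fit"))
  chronological <- chronological %||% unname(upm$chronological_ages)
  if (length(chronological) != upm$m || any(chronological <= 0))
    rlang::abort("`chronological` must be length m and strictly positive.",
                 class = "upmclock_error_validation")
  out <- tibble::tibble(
    individual_id = upm$individual_ids,
    age = as.numeric(chronological),
    epigenetic_age = unname(upm$epigenetic_times),
    ratio = epigenetic_age / age
  ) |> dplyr::arrange(.data$age)
  terc <- cut(rank(out$age, ties.method = "first"),
              breaks = 3, labels = c("young", "mid", "old"))
  attr(out, "tercile_variance") <- c(
    young = stats::var(out$ratio[terc == "young"]),
    old = stats::var(out$ratio[terc == "old"])
  )
  class(out) <- c("age_ratio_report", class(out))
  out
}

#' Plot the sorted clock/pacemaker rate ratios
#'
#' @param object A \code{rate_ratio_report}.
#' @param hide_outliers Drop flagged extreme sites from the panel (they stay
#'   in the table).
#' @param ... Unused.
#' @return A ggplot of the sorted MC/PM rate ratio per site.
#' @method autoplot rate_ratio_report
#' @export
autoplot.rate_ratio_report <- function(object, hide_outliers = TRUE, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$ratio))
  if (hide_outliers) dat <- dplyr::filter(dat, !.data$outlier)
  dat$rank <- seq_len(nrow(dat))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Site (sorted by ratio)", y = "MC / PM rate ratio") +
    ggplot2::theme_minimal()
}

#' Plot epigenetic/chronological age ratios against age
#'
#' @param object An \code{age_ratio_report}.
#' @param ... Unused.
#' @return A ggplot of the PM/chronological age ratio vs chronological age.
#' @method autoplot age_ratio_report
#' @export
autoplot.age_ratio_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$age, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Epigenetic / chronological age") +
    ggplot2::theme_minimal()
}
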