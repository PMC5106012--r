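test_that("conditional_site_fit at chronological ages reproduces the clock fit", {
  d <- make_dataset(n = 4, m = 6, seed = 2, noise = 0.2)
  mc <- fit_mc(d$ds)
  cf <- conditional_site_fit(d$ds, d$ages)
  expect_equal(cf$rates, mc$rates)
  expect_equal(cf$starts, mc$starts)
  expect_equal(cf$rss, mc$rss)

  ds1 <- methylation_dataset(matrix(c(3, 5), 1, 2), ages = c(1, 2))
  cf1 <- conditional_site_fit(ds1, c(1, 2))
  expect_equal(unname(cf1$rates), 2)
  expect_equal(unname(cf1$starts), 1)
})

test_that("scaling candidate times scales rates inversely and leaves rss fixed", {
  d <- make_dataset(n = 4, m = 4, seed = 21, noise = 0.3)
  base <- conditional_site_fit(d$ds, d$ages)
  for (c_scale in c(0.5, 2, 7.3)) {
    scaled <- conditional_site_fit(d$ds, d$ages * c_scale)
    expect_equal(scaled$rates, base$rates / c_scale, tolerance = 1e-10)
    expect_equal(scaled$starts, base$starts, tolerance = 1e-10)
    expect_equal(scaled$rss, base$rss, tolerance = 1e-10)
  }
})

test_that("conditional_times_fit matches the closed form and a scalar-minimizer oracle", {
  # single site: t_j = (s_1j - s0)/r
  vals <- matrix(c(1.2, 2.4, 4.8), 1, 3)
  ds <- methylation_dataset(vals)
  t_hat <- conditional_times_fit(ds, rates = 0.6, starts = 0.3, lower_bound = 1e-3)
  expect_equal(t_hat, (vals[1, ] - 0.3) / 0.6)

  # gauge: scaling rates by c scales times by 1/c
  d <- make_dataset(n = 5, m = 3, seed = 4, noise = 0.5)
  t1 <- conditional_times_fit(d$ds, d$rates, d$starts, 1e-9)
  t2 <- conditional_times_fit(d$ds, d$rates * 3, d$starts, 1e-9)
  expect_equal(t2, t1 / 3, tolerance = 1e-12)

  # each t_j agrees with a 1-D numeric minimization of its column RSS
  # (stationarity located by root-finding on the derivative, which is
  # sharper than golden-section search)
  for (j in seq_len(3)) {
    col_rss <- function(t) sum((d$ds$values[, j] - d$rates * t - d$starts)^2)
    dcol <- function(t) (col_rss(t + 1e-4) - col_rss(t - 1e-4)) / 2e-4
    root <- uniroot(dcol, c(-500, 500), tol = 1e-12)$root
    expect_lt(abs(t1[j] - root), 1e-8 * max(1, abs(t1[j])))
  }

  expect_error(conditional_times_fit(d$ds, rep(0, 5), d$starts),
               class = "upmclock_error_singular")
})

test_that("pacemaker truth with zero noise is recovered exactly", {
  sim <- simulate_dataset(simulation_params(8, 6, sigma_t2 = 0, sigma_s2 = 0, seed = 31))
  fit <- fit_upm(sim$dataset, upm_options(n_starts = 3, seed = 1))
  expect_lt(fit$rss, 1e-12 * sum(sim$dataset$values^2))
  expect_equal(unname(fit$epigenetic_times), unname(sim$dataset$ages),
               tolerance = 1e-6)
})

test_that("the pacemaker rss never exceeds the clock rss", {
  for (seed in 1:8) {
    nm <- withr::with_seed(seed, sample(3:15, 2))
    sim <- simulate_dataset(simulation_params(nm[1], max(nm[2], 3),
                                              sigma_t2 = 0.1, sigma_s2 = 2,
                                              seed = seed))
    mc <- fit_mc(sim$dataset)
    upm <- fit_upm(sim$dataset, upm_options(n_starts = 3, seed = seed))
    expect_lte(upm$rss, mc$rss + 1e-8)
    expect_equal(upm$rss, min(upm$converged_rss_per_start))
    expect_true(all(upm$epigenetic_times > 0))
  }
})

test_that("the reported rss is reproducible from the returned parameters", {
  sim <- simulate_dataset(simulation_params(6, 8, 0.15, 1, seed = 12))
  fit <- fit_upm(sim$dataset, upm_options(n_starts = 2, seed = 5))
  expect_equal(rss_of(sim$dataset, fit$epigenetic_times, fit$rates, fit$starts),
               fit$rss, tolerance = 1e-10)
})

test_that("a tiny instance matches a brute-force search over time space", {
  sim <- simulate_dataset(simulation_params(3, 3, 0.2, 0.5, seed = 77))
  fit <- fit_upm(sim$dataset, upm_options(n_starts = 10, seed = 3))
  oracle <- brute_force_upm_rss(sim$dataset$values, unname(sim$dataset$ages))
  expect_equal(fit$rss, oracle$rss, tolerance = 1e-6)
})

test_that("alternating and direct-search strategies agree", {
  for (seed in c(1, 2)) {
    sim <- simulate_dataset(simulation_params(10, 10, 0.1, 2, seed = seed))
    alt <- fit_upm(sim$dataset, upm_options(n_starts = 10, seed = 9))
    direct <- fit_upm(sim$dataset,
                      upm_options(n_starts = 10, seed = 9, strategy = "direct-search"))
    expect_equal(alt$rss, direct$rss, tolerance = 1e-4)
  }
})

test_that("gauge rescaling leaves the rss unchanged and normalization collapses the orbit", {
  sim <- simulate_dataset(simulation_params(5, 6, 0.1, 1, seed = 8))
  fit <- fit_upm(sim$dataset, upm_options(n_starts = 2, seed = 2))
  rss0 <- rss_of(sim$dataset, fit$epigenetic_times, fit$rates, fit$starts)
  for (c_scale in c(0.25, 4)) {
    expect_equal(rss_of(sim$dataset, fit$epigenetic_times * c_scale,
                        fit$rates / c_scale, fit$starts),
                 rss0, tolerance = 1e-12)
  }
  # push the fit along its gauge orbit, re-anchor, recover the original
  shifted <- fit
  shifted$epigenetic_times <- fit$epigenetic_times * 2
  shifted$rates <- fit$rates / 2
  back <- normalize_scale(shifted)
  expect_equal(back$epigenetic_times, fit$epigenetic_times, tolerance = 1e-12)
  expect_equal(back$rates, fit$rates, tolerance = 1e-12)
  # idempotence
  again <- normalize_scale(fit)
  expect_equal(again$epigenetic_times, fit$epigenetic_times)
})

test_that("normalized times track the true perturbed times closely", {
  sim <- simulate_dataset(simulation_params(100, 100, sigma_t2 = 0.15,
                                            sigma_s2 = 0.5, seed = 424))
  fit <- fit_upm(sim$dataset, upm_options(n_starts = 3, seed = 17))
  r <- cor(unname(fit$epigenetic_times), unname(sim$true_perturbed_times))
  expect_gte(r, 0.95)
})

test_that("average rates obey the constant-ratio pacemaker property on noiseless data", {
  sim <- simulate_dataset(simulation_params(6, 5, sigma_t2 = 0.2, sigma_s2 = 0, seed = 55))
  ds <- sim$dataset
  # hand example first
  ds1 <- methylation_dataset(matrix(5, 1, 1), individual_ids = "a")
  expect_equal(average_rates(ds1, starts = 1, times = 2)[1, 1], 2)

  # measured average rates at chronological times: r_ij = r_i * t'_j / t_j,
  # so cross-site ratios are constant over individuals and equal r_i / r_i'
  rr <- average_rates(ds, sim$true_starts, unname(ds$ages))
  for (i in 2:6) {
    ratio <- rr[i, ] / rr[1, ]
    expect_lt(diff(range(ratio)), 1e-10)
    expect_equal(ratio[[1]], sim$true_rates[[i]] / sim$true_rates[[1]],
                 tolerance = 1e-10)
  }
  # at the true perturbed times the average rate IS the characteristic rate
  rr2 <- average_rates(ds, sim$true_starts, sim$true_perturbed_times)
  expect_equal(unname(rr2), matrix(rep(unname(sim$true_rates), 5), 6, 5),
               tolerance = 1e-10)
})

test_that("the fitted optimum factors residual rates into site x individual stretch", {
  sim <- simulate_dataset(simulation_params(40, 20, sigma_t2 = 0.15,
                                            sigma_s2 = 0.001, seed = 9))
  fit <- fit_upm(sim$dataset, upm_options(n_starts = 3, seed = 3))
  # implied stretch per individual
  delta <- unname(fit$epigenetic_times) / unname(sim$dataset$ages)
  rr <- average_rates(sim$dataset, fit$starts, unname(sim$dataset$ages))
  # r*_ij should be ~ rate_i * delta_j: compare against the outer product
  pred <- outer(unname(fit$rates), delta)
  expect_gt(cor(as.vector(rr), as.vector(pred)), 0.99)
})

test_that("degenerate inputs error cleanly", {
  vals <- matrix(rep(c(1, 2, 3), 3), 3, 3)  # identical columns
  ds <- methylation_dataset(vals, ages = c(10, 20, 30))
  expect_error(fit_upm(ds, upm_options(n_starts = 1)),
               class = "upmclock_error_singular")
})
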