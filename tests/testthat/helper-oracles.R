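# Independent reference implementations used as oracles. These deliberately
# avoid the package's production code paths: plain loops, lm(), optim().

# Elementwise-loop RSS
rss_loop <- function(values, times, rates, starts) {
  total <- 0
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      total <- total + (values[i, j] - rates[i] * times[j] - starts[i])^2
    }
  }
  total
}

# Total RSS of per-site simple regressions via lm()
rss_lm <- function(values, times) {
  sum(vapply(seq_len(nrow(values)), function(i) {
    sum(stats::resid(stats::lm(values[i, ] ~ times))^2)
  }, numeric(1)))
}

# Brute-force pacemaker search on a tiny instance: coarse grid over time
# vectors (gauge fixed to the mean of the chronological ages) followed by
# Nelder-Mead refinement of the best grid points. Site parameters come from
# lm(), not from the package's closed form.
brute_force_upm_rss <- function(values, ages, grid_mult = seq(0.3, 2.5, length.out = 7)) {
  m <- length(ages)
  obj <- function(tt) {
    if (any(tt <= 0) || diff(range(tt)) == 0) return(Inf)
    rss_lm(values, tt)
  }
  combos <- expand.grid(rep(list(grid_mult), m))
  best <- Inf; best_t <- NULL
  scores <- apply(combos, 1, function(mult) obj(ages * mult))
  keep <- order(scores)[seq_len(min(5, length(scores)))]
  for (k in keep) {
    res <- stats::optim(ages * as.numeric(combos[k, ]), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    res <- stats::optim(res$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (res$value < best) { best <- res$value; best_t <- res$par }
  }
  list(rss = best, times = best_t)
}

# Simple linear dataset builder
make_dataset <- function(n = 4, m = 6, seed = 1, ages = NULL, noise = 0.1) {
  withr::with_seed(seed, {
    ages <- ages %||% runif(m, 10, 100)
    rates <- runif(n, -0.05, 0.05)
    starts <- runif(n, 0, 1)
    values <- outer(rates, ages) + starts + matrix(rnorm(n * m, 0, noise), n, m)
  })
  list(ds = methylation_dataset(values, ages = ages),
       rates = rates, starts = starts, ages = ages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
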