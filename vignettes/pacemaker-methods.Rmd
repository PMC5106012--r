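---
title: "Clock versus pacemaker models of epigenetic aging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clock versus pacemaker models of epigenetic aging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upmclock)
```

## The two models

`upmclock` compares two generative accounts of how CpG methylation drifts
with age across a cohort of $m$ individuals measured at $n$ sites.

Under the **molecular clock (MC)**, each site $i$ has a characteristic rate
$r_i$ (methylation units per year) and a start level $s_i^0$, and the
observed level of site $i$ in individual $j$ of chronological age $t_j$ is

$$\hat{s}_{ij} = s_i^0 + r_i\,t_j + \varepsilon_{ij}, \qquad
\varepsilon_{ij} \sim N(0, \sigma^2) \text{ iid.}$$

Under the **universal pacemaker (UPM)**, all of an individual's sites may
speed up or slow down *together*: pairwise rate ratios between sites are
preserved, but each individual $j$ effectively lives on its own epigenetic
time $t_j'$, so the mean structure becomes $s_i^0 + r_i\,t_j'$ with $t_j'$
a free parameter per individual. The deviation of $t_j'$ from $t_j$ is age
acceleration (above) or deceleration (below).

With iid Gaussian noise and the variance profiled out, maximising the
likelihood of either model is exactly minimising the residual sum of
squares
$\mathrm{RSS} = \sum_{ij} (\hat{s}_{ij} - r_i t_j - s_i^0)^2$;
the maximised log-likelihood is $-\frac{nm}{2}\log \mathrm{RSS}$ plus a
constant shared by both models. This identity is what makes the
likelihood-ratio test below a pure function of the two RSS values.

## Fitting

**MC.** With times fixed the RSS decouples across sites, so `fit_mc()` runs
$n$ independent simple linear regressions in closed form, $O(nm)$ total.
The equivalent single least-squares system — an $mn \times 2n$ design
matrix whose row for cell $(i,j)$ carries $t_j$ in column $i$ and $1$ in
column $n+i$ — is kept in `build_design_matrix()` purely as a
cross-checking oracle for tests; solving its normal equations costs
$O((2n)^3)$ and must agree with the per-site path to $10^{-8}$.

**UPM.** The joint problem is bilinear in (rates, times). The key
structural fact is that the search only needs to run over the
$m$-dimensional space of candidate time vectors: for any fixed times the
site parameters have the same closed-form solution as the clock fit
(`conditional_site_fit()`). Two interchangeable optimizers are exposed:

* `"alternating"` (default): block coordinate descent. Given site
  parameters, each time has its own closed-form minimiser
  $t_j = \sum_i r_i(\hat{s}_{ij} - s_i^0) / \sum_i r_i^2$
  (`conditional_times_fit()`), clipped below at `time_lower_bound`.
  Alternating the two closed forms decreases the RSS monotonically; we stop
  when the relative improvement drops below `rel_tol` (default $10^{-9}$)
  or after `max_outer_iters` (default 500).
* `"direct-search"`: a bounded quasi-Newton search (L-BFGS-B) over the time
  vector with the closed-form site fit inside the objective — the
  sequential least-squares shape of the original procedure. Slower; the two
  strategies agree to $10^{-4}$ relative RSS in the test suite.

**Restarts.** The bilinear surface has local optima, so `fit_upm()` runs
`n_starts` restarts (default 10). The first start is always the
chronological ages unjittered — this guarantees the returned RSS never
exceeds the MC RSS, because the first alternation step reproduces the MC
fit and every later step only improves it. Remaining starts multiply the
ages by iid lognormal jitter (sdlog 0.2). All restart seeds derive
deterministically from `seed`.

**Gauge.** Scaling all times by $c > 0$ and all rates by $1/c$ leaves the
RSS unchanged, so one scale must be fixed by convention. We anchor
$\operatorname{mean}(t') = \operatorname{mean}(t)$ (`normalize_scale()`)
rather than pinning a single site's rate: the anchor is symmetric in
individuals, robust to any one site being atypical, and makes the
epigenetic/chronological age ratio directly readable from the fit. The
convention is recorded in the fit object.

**Numerical choices.** Epigenetic times are constrained to at least
`time_lower_bound` (default $10^{-3}$ years): nonpositive times are
biologically meaningless and break the average-rate definition
$r_{ij} = (\hat{s}_{ij} - s_i^0)/t_j$. When a fit is exact (RSS below
$10^{-20} \sum \hat{s}_{ij}^2$, i.e. floating-point dust), the alternation
stops rather than chasing relative improvements in dust, and
`compare_models()` reports $\chi^2 = 0$ — an exact clock fit carries no
evidence for a pacemaker. A site with zero variance is fit with $r_i = 0$
without error, since flat probes are common on real arrays; degenerate
*designs* (all ages equal, all individuals identical) are errors.

## The likelihood-ratio test

MC is UPM restricted to $t_j' = t_j$, so the models are nested and

$$\chi^2 = -2\log\Lambda = nm\,\log\frac{\mathrm{RSS}_{MC}}{\mathrm{RSS}_{UPM}}$$

(natural log throughout) is referred to a $\chi^2$ distribution with
$df = m$, one per inferred epigenetic time. The scale gauge arguably
removes one effective parameter; we keep $df = m$ as the convention and
expose `df` as an argument. `rss_upm` exceeding `rss_mc` by more than
$10^{-8}$ relative is reported as an upstream optimizer failure, never
silently clipped; within that tolerance $\chi^2$ is set to 0.

### How trustworthy is the $\chi^2_m$ reference?

Less than the asymptotics suggest, and users should know this. With no
pacemaker in the data at all, the multi-start bilinear fit absorbs more
noise than one unit per fitted time: at 50 sites and 20 individuals the
measured null rejection rate at $\alpha = 0.05$ is roughly 0.2 when the
linear age structure dominates the noise, and it climbs toward 1 as noise
swamps that structure (the fitted rank-one direction is then free to chase
the largest noise component; the effect also grows with the number of
restarts, because deeper local optima absorb more noise). Two practical
consequences:

* a significant $\chi^2$ at desk scales is evidence of *either* a
  pacemaker *or* finite-size overfitting — corroborate with the size of
  the relative RSS improvement and with the structure of the inferred age
  ratios;
* detection frequency against noise is not monotone: in the
  signal-dominated regime more noise weakens the test, but at extreme
  noise the spurious-rejection mechanism takes over. The power-study
  helpers report mean p-values alongside detection frequencies so both
  regimes are visible.

At the scale of the human cohorts this method targets (hundreds of sites
and individuals, strong age signal) the approximation is far better
behaved; the landmark value is that $p = 0.01$ at $df = 300$ requires
$\chi^2 \approx 360$.

## The synthetic-data generator

`simulate_dataset()` draws, per `simulation_params()`:

| Parameter | Default | Meaning |
|---|---|---|
| `age_range` | (10, 100) years | chronological ages $t_j \sim$ Uniform |
| `rate_range` | (−0.03, 0.03) per year | site rates $r_i \sim$ Uniform |
| `min_abs_rate` | 0.005 | resample rates with $\lvert r_i\rvert$ below |
| `start_range` | (0, 1) | start levels $s_i^0 \sim$ Uniform (beta scale) |
| `sigma_t2` | — | pacemaker variance of $\epsilon_j$ in $t_j' = t_j(1+\epsilon_j)$ |
| `sigma_s2` | — | observation-noise variance added to $s_i^0 + r_i t_j'$ |

The pacemaker perturbation is per-individual and shared by all of that
individual's sites — the defining UPM property — and the stored
chronological ages are the *unperturbed* $t_j$, so a fit sees exactly what
an investigator would. Perturbations that would make a time nonpositive
(a $>5\sigma$ event at the variances studied) are resampled.

The age and rate scales deserve a note, because only their product
matters to the test: the pacemaker signal per matrix entry scales as
$E[r^2]\,E[t^2]\,\sigma_t^2$ against noise $\sigma_s^2$. The defaults put
ages on an adult human cohort range and rates at a few percent of the
methylation beta scale per year — the magnitude at which age-associated
CpGs actually drift — which places the study's $\sigma_s^2 = 1\ldots10$
noise grid exactly in the regime where noise materially degrades the
evidence. Much larger rate scales would make every grid point trivially
detectable; much smaller ones would make every point hopeless.

What the generator does *not* emulate: bounded $[0,1]$ beta values (the
model is Gaussian and unbounded, so neither simulation nor fit clamps),
probe-specific noise variances, missing values, or batch structure.
Passing tests therefore demonstrate correctness of the estimators and the
test under the model's own assumptions — not robustness to array
artefacts.

## The power study

`run_single_trial()` is the full pipeline (simulate → fit both models →
LRT with $df = m$); `run_power_grid()` repeats it over a parameter grid
with per-replicate seeds derived from one master seed, reporting the
detection frequency at `alpha` (default 0.05 — the headline claims are
stated at the conventional level) and the mean p-value per cell. Thirty
replicates per cell (binomial SE ≈ 0.09 at 50% detection) keep the default
grids inside a few minutes on one CPU; both knobs are configurable upward.
At 50 sites × 50 individuals with strong pacemaker variance
($\sigma_t^2 = 0.15$) detection is essentially certain at every noise
level on the 1–10 grid. The published degradation of detection below one
half under a weak pacemaker ($\sigma_t^2 = 0.1$) and heavy noise is *not*
reproduced by this implementation at $\alpha = 0.05$: the null rejection
rate alone exceeds one half at those settings (previous section), so a
fully converged maximum-likelihood fit cannot fall below it — a weaker
search or a stricter threshold ($\alpha \approx 10^{-3}$) would be needed
to trace that curve.

## Reports

* `select_top_variance_sites()` keeps the $k$ (default 300) most variable
  sites (unbiased variance, divisor $m-1$; ties broken by original order)
  — the standard pre-filter for arrays where most probes carry no age
  signal.
* `rate_ratio_report()` tabulates per-site MC/PM rate ratios, sorted
  ascending; a configurable fraction of extreme sites (default 2.5% per
  end) is *flagged* for plotting, never deleted, and zero pacemaker rates
  become NA sentinels excluded from the extremes.
* `age_ratio_report()` tabulates per-individual epigenetic/chronological
  age ratios sorted by age, and attaches the ratio variance in the
  youngest and oldest age terciles (reported, not asserted — it is a
  dataset property).

Both ratio orientations (MC/PM for rates, PM/chronological for ages)
follow the reporting convention of the source analyses, despite the
asymmetry.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(
  simulation_params(n_sites = 50, n_individuals = 50,
                    sigma_t2 = 0.15, sigma_s2 = 2, seed = 11))

res <- compare_models(sim$dataset, upm_options(seed = 1))
glance(res)

ages <- age_ratio_report(upm = attr(res, "upm_fit"))
autoplot(ages)
```

## Known limitations

* The $\chi^2_m$ reference is anticonservative at small-to-moderate size
  (quantified above); treat borderline p-values with suspicion and
  consider the relative RSS improvement directly.
* One global noise variance: no per-site heteroscedasticity, no robust or
  weighted variants.
* The UPM here is genome-wide by definition; per-site pacemakers and
  time-resolved instantaneous rates are outside the model.
* Missing values are rejected at validation, not imputed: the likelihood
  has no missing-data mechanism, and silent imputation would bias both
  fits.
* Real beta values live in $[0,1]$; the Gaussian model does not, and no
  clamping is applied anywhere.
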