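---
title: "Random-walk models for disease surveillance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk models for disease surveillance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Surveillance time series — case counts $y_t$ with populations at risk
$P_t$ over evenly spaced periods $t = 1, \dots, n$ — are routinely
summarized with trend models. `ratetrends` implements a Bayesian
first-difference specification. For rare outcomes the counts are
Poisson,

$$y_t \sim \mathrm{Pois}\!\left(P_t\, e^{\eta_t}\right),$$

with $\eta_t$ the latent log rate; for non-rare outcomes a binomial
family with logit link is available, $y_t \sim \mathrm{Binom}(P_t,
\mathrm{logit}^{-1}(\eta_t))$ (the Poisson family is intended for rates
below roughly 4 per 100). The trend prior is a Gaussian random walk on
the latent scale,

$$\eta_t \sim \mathrm{N}(\eta_{t-1}, \tau^2), \qquad t > 1,$$

which imposes no functional form: the posterior smooths the observed
rates exactly as much as the data warrant, and uncertainty propagates
into every derived quantity. Two hyperpriors complete the model:

* $\eta_1 \sim \mathrm{N}(m_0, s_0^2)$, default $\mathrm{N}(-5, 5^2)$.
  The center corresponds to a rate of $e^{-5}$, about 674 per 100,000,
  and the scale is diffuse for any rare disease. Users studying common
  outcomes should move $m_0$.
* $\tau \sim \mathrm{N}^+(0, 1)$ (half-normal, scale default 1).
  Log-rate increments in routine surveillance are small (a 10% annual
  change is $|\Delta\eta| \approx 0.1$), so scale 1 is diffuse.

With $k$ related demographic groups, `joint = TRUE` replaces the scalar
increments by a multivariate normal, $\boldsymbol\eta_t \sim
\mathrm{N}(\boldsymbol\eta_{t-1}, \Sigma)$, with $\Sigma =
\mathrm{diag}(\boldsymbol\tau)\, C\, \mathrm{diag}(\boldsymbol\tau)$
and an LKJ$(2)$ prior on the correlation matrix $C$. Shape 2 places
mild mass toward independence, the common weakly informative choice.
Groups share the time index; each age stratum gets its own
$\boldsymbol\tau$ and $C$, since there is no reason to force the
correlation structure of, say, the 50–54 band onto the 75–79 band.

## Sampling

The posterior is explored with an adaptive Hamiltonian Monte Carlo
kernel written in C++ (via Rcpp):

* **Non-centered parameterization.** The walk is expressed through
  standardized increments, $\eta_t = \eta_1 + \tau \sum_{s \le t} z_s$
  with $z_s \sim \mathrm{N}(0,1)$ a priori, which removes the funnel
  between $\tau$ and the path when the data only weakly identify
  $\tau$. $\tau$ is sampled as $\log\tau$ with the Jacobian absorbed
  into the target.
* **Adaptation.** Step size is tuned by dual averaging toward an
  acceptance rate of 0.9 (configurable via `target_accept`); a
  diagonal mass matrix is estimated from two warmup windows
  (regularized toward a small constant, skipped when warmup is under
  60 iterations). Trajectories use a nominal integration time of 6
  units, jittered ±30%, capped at 100 leapfrog steps; the relatively
  long trajectories are what keeps the slowest coordinate ($\log\tau$
  on near-constant-risk data) mixing well. Windowed adaptation can
  occasionally lock in a step size that the far tail of the posterior
  cannot tolerate; if more than 5% of a series' post-warmup
  trajectories diverge, the series is refit once with the target
  raised to 0.99 — the standard remedy for divergences — before the
  divergence error is raised.
* **Correlation update (joint mode).** $C$ is parameterized by its
  Cholesky factor through tanh-transformed canonical partial
  correlations and updated with a random-walk Metropolis step whose
  scale adapts toward 35% acceptance during warmup, interleaved with
  the HMC updates. For $k = 2$ the induced prior reduces to the known
  $\frac{\rho+1}{2} \sim \mathrm{Beta}(\eta, \eta)$ form, which is how
  the transform's Jacobian was verified.
* **Determinism.** One user seed is expanded deterministically into
  per-series, per-chain streams; identical seed, spec and data
  reproduce draws bit-exactly on a given build.
* **Divergences.** A leapfrog trajectory whose Hamiltonian error
  exceeds 1000 counts as divergent and is rejected; a post-warmup
  divergence rate above 5% in any chain aborts the fit with an error
  carrying the diagnostics, since rates that high indicate geometry
  the integrator cannot traverse.

The default protocol is 4 chains × 6000 draws with the first 3000
discarded as warmup. Convergence is gated on the classic (not
rank-normalized) split-$\hat R$ at $< 1.01$ and on the Monte Carlo
standard error of each posterior mean at $< 10\%$ of the posterior
standard deviation; "sufficiently small MCMC error" is not a
universally quantified convention, and the 10% gate is this package's.
Failures raise a classed warning with the full diagnostics table
attached rather than an error: borderline mixing is the analyst's call.
The package's posterior was validated against an independent Gibbs
sampler (JAGS) on fixture data; the test suite keeps that cross-check.

## Derived quantities

All reported quantities are computed **per posterior draw and then
summarized** — never from summarized rates — because the posterior
mean of a nonlinear function is not the function of the posterior
means. Summaries are the posterior mean with an equal-tailed 95%
interval. Interval endpoints are order statistics (quantile type 1),
so intervals commute exactly with monotone transforms such as
exp or log.

* **Percent change.** Annual: $\mathrm{APC}_t = 100\,(R_t/R_{t-1}-1)$;
  cumulative: $\mathrm{CPC}_t = 100\,(R_t/R_1-1)$; these telescope,
  $\prod_t (1+\mathrm{APC}_t/100) = 1+\mathrm{CPC}_n/100$, per draw.
  The average annual percent change (AAPC) over a window is the
  arithmetic mean of the per-transition APCs, read literally from
  "average annual percent change"; a geometric (compound-annualized)
  variant is available via `method = "geometric"`. Four-year windows
  are the conventional stabilizing choice and the default in the
  workflow driver. When percent changes are compared against published
  tables, values are rounded half-away-from-zero to integers, the
  convention such tables use.
* **Direct age standardization.** $SR_t = \sum_i w_i R_{it}$ with
  weights normalized to sum to 1; the 2000 US standard million weights
  for the 50–79 five-year bands ship as a packaged table
  (`us_standard_2000()`), and any weight table is accepted. Strata are
  matched by label and any mismatch is an error — silently dropping a
  stratum is a classic standardization bug.
* **Pairwise inequality.** With a *declared* disadvantaged group $d$
  and advantaged group $a$: $\mathrm{RR} = R_d/R_a$, $\mathrm{RD} =
  R_d - R_a$, $\mathrm{PAR} = \mathrm{RD}/R_d$ (so $\mathrm{PAR} =
  1 - 1/\mathrm{RR}$ per draw, and `par_to_rr()` inverts it),
  $\mathrm{EC} = \mathrm{RD} \times P_d$, with cumulative forms
  $\sum_t \mathrm{EC}_t$ and $\sum_t \mathrm{EC}_t / \sum_t R_{dt}
  P_{dt}$. The advantaged group is never auto-selected by rate
  ranking: rankings can flip between draws and silent flips would
  corrupt the intervals. EC uses model-estimated rates times
  population — expected cases — so it carries posterior uncertainty.
  For age-standardized comparisons, relative measures come from the
  standardized rates, but EC must be computed within strata and then
  summed, $\mathrm{EC}_t = \sum_i (R_{dit}-R_{ait}) P_{dit}$, because
  standard-population weights do not reflect the disadvantaged group's
  actual age structure.
* **Theil index.** With expected burdens $b_j = R_j P_j$, burden
  shares $\omega_j$ and population shares $p_j$: $T = \sum_j \omega_j
  \ln(\omega_j/p_j)$ (natural log), with per-group components
  returned. Across nested units, $T = T_{between} + \sum_u \Omega_u
  T_{within,u}$ holds per draw to numerical precision
  (`theil_decomposition()`), which is what makes the index usable for
  geographically nested populations.

## The synthetic-data generator

`simulate_caseseries()` runs the generative model forward: a Gaussian
(optionally correlated across groups) random walk on the latent scale
and Poisson or binomial count draws, with optional deterministic
population growth so that excess cases can grow under a persistent
rate gap. Each series draws from its own seed-derived RNG stream.

The generator emulates exactly what the model assumes — and nothing a
real registry adds: no reporting delay, no small-count suppression, no
coding changes, no population interpolation error, and no
age-structure drift. Passing recovery and calibration tests therefore
demonstrates the correctness of the inference machinery under the
model, not robustness to registry artifacts.

Study conditions used by the checks (and the acceptance script):
recovery uses $n = 20$ periods with about $10^3$ cases per period
($\eta_1 = \log 10^{-3}$, $P = 10^6$) at $\tau \in \{0.02, 0.05,
0.1\}$, 25 replicates each, requiring 95% CI coverage of $\tau$ of at
least 80%. Interval calibration uses 100 datasets of $n = 10$ periods
at fixed $\tau = 0.05$ with $\eta_1 \sim \mathrm{N}(-5, 1)$ and the
matching fitting prior, requiring pooled 95% CI coverage of the rate
path in $[0.88, 0.99]$. The $\eta_1$ simulation scale is 1, not the
diffuse default 5: a $\mathrm{N}(-5,25)$ draw routinely implies rates
near or above one case per person, which no surveillance system
produces and which overflows count generation; scale 1 spans roughly
50 to 5000 per 100,000, the realistic range. These scaled-down fits
use 2 chains of 1200–1500 draws, enough for stable coverage counting;
single fits elsewhere use the full 4 × 6000 protocol.

## Numerical and interface choices

* Counts reported as `Suppressed`/`Missing`/empty are hard errors with
  row numbers: the model has no missing-data pathway, and imputing
  suppressed small counts silently would be worse than stopping.
* Integer time labels are calendar years and must advance by exactly
  one — `1999, 2001` is a gap, not biennial data. Non-integer numeric
  labels need a constant step; opaque labels are accepted with a
  warning that spacing cannot be checked.
* Zero populations are rejected (`P_t > 0` invariant) rather than
  dropped.
* Delimiters are fixed per dialect (tab for CDC-Wonder-style exports,
  comma for plain tables); auto-detection invites silent misparses.
* The workflow driver (`run_surveillance()`, or the
  `inst/cli/ratetrends.R` wrapper) removes partial outputs on failure
  and exits nonzero when any diagnostic gate fails.

## Limitations

The package models aggregated, evenly spaced, fully observed series;
it has no spatial structure, no covariates, and no missing-period
imputation. The Poisson family is for rare events. The joint model's
Metropolis correlation update mixes more slowly than the HMC
coordinates (roughly 5–10× fewer effective draws for $C$ than for the
rate path at the default protocol), which is adequate for the small
$k$ typical of demographic comparisons but would need a smarter
update for large $k$. Published-table comparisons inherit the tables'
integer rounding; agreement is assessed after applying the same
rounding.
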