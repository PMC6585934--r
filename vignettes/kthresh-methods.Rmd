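---
title: "Methods: estimating a supply-side cost-effectiveness threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating a supply-side cost-effectiveness threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A *k*-threshold expresses the opportunity cost of health-care spending: the
incremental cost at which spending at the margin produces (or, under a fixed
budget, displaces) one QALY. `kthresh` estimates it in two stages — a
Bayesian panel regression of cause-specific mortality on hospital spending,
and a life-table translation of the resulting spending elasticity into
discounted euros per QALY — and propagates the posterior uncertainty of the
elasticity through to the threshold.

# Stage 1: the panel model

The unit of observation is a stratum (5-year age group × gender) in a
calendar year. With `m` the CVD mortality rate (deaths per person-year) and
`c` per-capita CVD hospital spending, the model for year-over-year changes
in log mortality is

$$\Delta\log m_i \sim N(\mu + \alpha\,\Delta\log c_{it}
  + \beta\,\Delta\log c_{it-1} + \gamma_{t[i]} + \tau_{a[i]},\ \sigma_m),$$
$$\gamma_t \sim N(0, \sigma_\gamma), \qquad \tau_a \sim N(0, \sigma_\tau).$$

First-differencing removes time-invariant stratum effects; $\gamma_t$
absorbs shocks common to all strata in a year (e.g. a smoking ban);
$\tau_a$ absorbs stratum-specific linear mortality trends (lifestyle
trends). Logs make $\alpha$ and $\beta$ elasticities; their sum is the
elasticity of mortality with respect to spending, the quantity the second
stage consumes. The identifying assumption is that, conditional on the
differencing and both intercept sets, remaining variation in spending
changes is exogenous to mortality changes.

The lagged term uses $\Delta\log c_{it-1} = \log c_{t-1} - \log c_{t-2}$,
computed within the stratum. This is the only reading of a "lagged
first-differenced" covariate consistent with differencing the level
equation; it costs a second leading year, so a stratum observed over $T$
years contributes $T-2$ design rows.

## Priors

* Base case ("vague"): $\mu,\alpha,\beta \sim N(0, \text{variance } 10)$ —
  variance, not SD, so sd $=\sqrt{10}$ — and $\sigma_m, \sigma_\gamma,
  \sigma_\tau \sim U(0,1)$. A uniform upper bound of 1 is enormous for
  changes in log mortality (a residual SD of 1 means ±170% year-over-year
  swings), but if a posterior σ nonetheless piles up against the bound the
  fit warns that the prior truncation is binding rather than silently
  reporting a truncated posterior.
* Informative evidence on the instantaneous elasticity enters as
  $\alpha \sim N(\text{point}, \text{sd} = (hi-lo)/(2 \times 1.959964))$
  from a published point estimate and 95% interval, everything else vague.
  Two canned versions are exposed in the scenario battery: a meta-analytic
  total-spending estimate (−0.13, interval −0.20/−0.06, implied sd 0.0357)
  and an English circulatory-care estimate (−1.43, interval −1.86/−1.00,
  implied sd 0.2194).
* A degenerate uniform (`lo == hi`) pins a σ at a fixed value. This mildly
  extends the "uniform with `hi > lo`" contract because the closed-form
  conjugate checks need fixed variance components; it is the natural
  degenerate limit and validated as such.

## Sampler

All conditionals are available in closed form, so the sampler is a blocked
Gibbs scheme with no tuning parameters:

* $(\mu, \alpha, \beta)$ jointly from the conjugate multivariate normal;
* each $\gamma_t$ and $\tau_a$ from univariate normals (random intercepts
  are *sampled*, not marginalized, and kept centred at zero by their
  zero-mean hierarchical prior — no post-hoc sweeping);
* each σ exactly, by inverse-CDF sampling of the precision: given a sum of
  squares over $n$ terms, $\sigma^2$ has an inverse-gamma
  (shape $(n-1)/2$, rate $SS/2$) conditional truncated to the uniform
  support, which can be drawn exactly via `pgamma`/`qgamma`.

A slice sampler for the σs was considered and rejected: the truncated
conjugate draw is exact, faster, and has no step-size state, which also
makes runs bit-reproducible under a seed. Chains start overdispersed:
chain $c$ starts the regression block at the prior mean plus a symmetric
chain-dependent offset (scaled by `init_scale`, capped at one prior SD) and
the σs at staggered points inside their supports. Default protocol settings
are 3 chains × 75,000 iterations, 25,000 burn-in, thinning by 4 — retaining
exactly 37,500 draws per parameter. Convergence is monitored by split-chain
potential scale reduction, effective sample size (Geyer initial-monotone
pairwise autocorrelation sums on split chains, capped at the retained
count), and a lag-1..10 autocorrelation table. With a single chain the
scale-reduction statistic is reported as `NA`; a numerically constant chain
is flagged with ESS 1.

If the spending covariates carry no variation the sampler still runs (the
elasticity posterior equals its prior) but the fit is flagged: the data
carry no information on the elasticity.

## Frequentist and reduced variants

OLS of $\Delta\log m$ on the spending covariates with full year and stratum
dummy blocks (treatment coding) replaces the random intercepts by fixed
effects; the coefficient covariance feeds a 10,000-draw multivariate-normal
coefficient sample so the translation step can treat it like a posterior.
The no-lag variant simply omits $\beta$; its elasticity is $\alpha$ alone.

Random-versus-fixed effects is not a vacuous distinction: shrinkage of
$\gamma_t$ and $\tau_a$ toward zero moves the Bayesian $\alpha, \beta$ away
from the OLS estimates by an amount that grows as $\sigma_\gamma,
\sigma_\tau$ shrink relative to $\sigma_m$. In the synthetic world below the
gap is a modest fraction of a posterior SD; the acceptance check therefore
asserts agreement at the scale of the statistical uncertainty (half an OLS
standard error, plus Monte-Carlo allowance, and interval widths within
25%) rather than coincidence to more decimal places than the data could
support.

# Stage 2: the life-table translation

For each starting cohort (age group × gender, population-weighted), an
annual-cycle life table runs from the first age of the group to a closure
age. Conventions (each an explicit argument or input, since published
appendix conventions vary):

* additive cause-specific hazards: the probability of dying in a year is
  $1-\exp(-(\text{CVD rate} + \text{other rate}))$;
* a person lives the **full year** in which they die — so one guaranteed
  year of life, QALYs and costs even under certain immediate death;
* closure age (default 105): everyone still alive dies there, which forces
  the death-year distribution to sum to one;
* 5-year age groups are expanded to single years by assigning the group
  rate to each constituent age (no interpolation is claimed by the sources
  this emulates);
* quality of life $q(\text{age}, \text{ttd})$ and unrelated hospital cost
  $u(\text{age}, \text{ttd})$ depend on current age and time to death,
  truncated at a horizon $H$ (default 5): $H$ or more years from death
  takes the background column. This is what makes postponing death also
  postpone terminal utility losses and terminal costs;
* discounting: costs at 4%/year and effects at 1.5%/year by default; year 0
  is undiscounted.

QALYs are $\sum_y d_e(y) \sum_{d\ge y} P(D=d)\, q(\text{age}_y, d-y)$, life
years the same with $q \equiv 1$, CVD costs accrue per year lived, and
unrelated costs use the (age, time-to-death) surface — so future unrelated
medical costs in gained life years are part of the incremental cost. The
implementation is vectorized over (year-lived, death-year) pairs; the test
suite pins it, cell for cell, to a brute-force enumeration over all death
years.

The alternative scenario raises CVD spending by 10% and multiplies CVD
mortality by $1.1^{\alpha+\beta}$. The phrase "decrease mortality by the
product of 0.9 and the elasticity" admits a literal linear reading
($1 + 0.9(\alpha+\beta)(1.1-1)$), but only the constant-elasticity
multiplier is consistent with a log-log regression, so the power form is
the default and the linear form a selectable mode (it errors if it would
drive a rate negative). `compare_states()` generalizes the same delta
computation to two arbitrary observed states (e.g. first-versus-last
observation year), which supports the historical average-returns
calculation.

## Threshold conventions

The point estimate is mean incremental cost over mean incremental QALYs
across elasticity draws. The reported 95% interval evaluates the ratio at
the 0.025/0.975 quantiles of $\alpha+\beta$ — reproducing the source
table's convention — not a percentile interval of per-draw ratios; the
percentile alternative is computed and returned alongside because it is the
standard PSA summary. Draws with non-positive incremental QALYs make the
per-draw ratio meaningless: they are flagged, excluded from the
ratio-percentile interval, and never count as "below x" in the
probability-below-value curve, so that curve saturates below 1 when a
material fraction of draws shows no health gain (the no-lag scenario's
signature). If the *mean* QALY gain is non-positive the point estimate
itself is `NA` with a flag rather than a sign-flipped number. Formatted
reports round currency to the nearest 100; raw values are kept internally.

The life-expectancy attribution compares, at a reference age (65), the gain
in *undiscounted* life expectancy from scaling first-year CVD mortality by
the spending-attributable factor $(c_{last}/c_{first})^{\alpha+\beta}$
against the gain from the full observed mortality change, aggregating
gender-specific gains with population weights before taking the ratio.
Whether the source used discounted or undiscounted life expectancy is
unstated; undiscounted is the natural demographic reading and is what the
package uses.

# The synthetic world

`generate_panel()` draws from exactly the model above, with an exogenous
log-random-walk spending path (deterministic trend plus noise) — no
feedback from mortality to spending, matching the identifying assumption.
One pre-sample spending year is simulated internally so the lagged term is
defined for every transition. Defaults describe the world the estimation
stage expects:

* 8 age groups (60-64 … 95+) × 2 genders × 1994-2010 (16 strata, 17 years);
* true elasticities $\alpha = -0.065$, $\beta = -0.124$ (the recovery
  studies' truth);
* $\mu = -0.04$/year: CVD mortality in high-income countries fell by
  roughly 3–5% a year over this period;
* spending trend 0.044/year on the log scale (a doubling over 16 years,
  as observed for Dutch CVD hospital spending) with stratum-level increment
  noise of SD 0.10 — year-to-year idiosyncratic variation in attributed
  spending of ~10%, which is what gives the design enough identifying
  variation for posterior SDs of the elasticities of a few hundredths,
  comparable to the precision the real panel delivered;
* $\sigma_m = 0.05$, $\sigma_\gamma = 0.02$, $\sigma_\tau = 0.01$: residual
  mortality-change noise of 5%, common year shocks of 2%, stratum trend
  heterogeneity of 1% per year;
* baseline mortality Gompertz in age (≈0.003 at 60 to ≈0.09 at 95+,
  men above women), baseline spending a bump peaking near age 80.

Realized year and stratum intercepts are returned in a sidecar truth table
(and written to a separate file) so recovery tests can see the truth while
the fitting path never reads it.

`generate_life_inputs()` tabulates Gompertz other-cause and CVD mortality,
a quality-of-life surface declining linearly in age with additive
decrements in the last five years of life, an unrelated-cost surface
growing log-linearly in age with a terminal-year multiplier (default 6 —
last-year-of-life hospital costs are several times background), and a
population thinning with age. Values are parametric stand-ins with the
right *structure*; no published surface values are reproduced.

What a green test establishes, therefore, is that the machinery is correct
*for data generated by the assumed model*: correct posterior computation
(against conjugate closed forms), nominal credible-interval coverage,
exact life-table arithmetic (against enumeration), and the documented
qualitative behaviours (prior shift/shrinkage, curve saturation). It does
not establish that the model is right for any real panel: no reverse
causality, no omitted confounders, no measurement error, and no calibration
to the real Dutch series are simulated.

# Numerical choices and degenerate inputs

* σ updates with a numerically zero sum of squares (probability-zero under
  continuous dynamics) return the lower support bound instead of a failing
  `qgamma` call; σ fixed at 0 pins the corresponding effects at zero.
* Retained draws per chain are `floor((n_iter - burn_in) / thin)`; chains
  are stored separately with chain and iteration labels.
* Equal-tailed quantile intervals (type-7 quantiles) everywhere.
* Rates of `Inf` are tolerated in the life table (death probability 1).
* All tabular I/O is headered CSV with "." decimal, UTF-8; metadata rides
  as `# key: value` comment lines or sidecar key-value files, avoiding
  locale drift on European-formatted numbers.
* Reproducibility: chain $c$ seeds `set.seed(seed + 7919 c)`; the pipeline
  writes a manifest with the seed, settings and MD5 digests, and identical
  configurations regenerate byte-identical artifacts.

# Test-budget choices

The credible-interval coverage study (100 replicates at the full panel
dimensions) runs a single chain of 10,000 iterations (2,000 burn-in) per
replicate — the protocol's reduced-MCMC regime; multiple chains would only
slow the loop without changing the coverage question. The conjugate-oracle
and prior-shift checks use 2-3 chains at reduced lengths. Full protocol
settings are exercised arithmetically (the 37,500 retained-draw identity)
rather than by a quarter-hour production run inside the test suite.

# Known limitations

* The sampler assumes the linear-Gaussian structure above; it is not a
  general-purpose engine.
* Mortality is the only channel: quality-of-life effects of spending are
  not modelled (gained years inherit the (age, ttd) utility surface).
* The frequentist translation treats the OLS sampling distribution as a
  posterior, which is a convenience, not a calibrated Bayesian object.
* The year-window scenario interprets its label literally (calendar years
  2001-2010) and errors when the panel does not reach the window.
* Spending units are whatever the user supplies; no deflation to constant
  prices is applied or assumed.
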