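# kthresh

Estimation of a **supply-side cost-effectiveness threshold** (a
*k*-threshold): the incremental cost at which marginal hospital spending
buys — or, under a fixed budget, displaces — one quality-adjusted life year
(QALY). The package is aimed at health economists who want to estimate
marginal returns to disease-specific hospital care from routinely collected
panels of spending and cause-specific mortality, and to translate those
returns into euros per QALY with full uncertainty propagation.

## The model

**Step 1 — spending elasticity of mortality.** For a panel of per-capita
cardiovascular (CVD) hospital spending `c` and CVD mortality rates `m` by
5-year age group × gender stratum `a` and calendar year `t`, a Bayesian
first-difference regression is fitted:

    Δlog m_i ~ Normal(μ + α·Δlog c_it + β·Δlog c_it−1 + γ_t[i] + τ_a[i], σ_m)
    γ_t ~ Normal(0, σ_γ)        (year random intercepts)
    τ_a ~ Normal(0, σ_τ)        (stratum random intercepts)

First-differencing removes time-invariant stratum confounders; the year and
stratum intercepts absorb common shocks and stratum-specific trends. The sum
`α + β` (instantaneous plus one-year-lagged effect) is the elasticity of CVD
mortality with respect to CVD spending. Priors: normal(0, variance 10) on
(μ, α, β) and uniform(0, 1) on the standard deviations; informative normal
priors on α can be built from published point estimates and 95% intervals.
Estimation is by a blocked Gibbs sampler with exact conjugate updates
(default protocol: 3 chains × 75,000 iterations, 25,000 burn-in, thinning by
4 → 37,500 retained draws), with split-chain scale-reduction and effective
sample size diagnostics. A frequentist variant (OLS with year and stratum
dummies) and a no-lag variant are included.

**Step 2 — life-table translation.** A cohort life table with additive
cause-specific hazards projects every starting age group × gender cohort
under baseline inputs and under a 10% CVD spending increase with CVD
mortality multiplied by `1.1^(α+β)`. Quality of life and unrelated hospital
costs depend on age *and time to death*, so postponing death also postpones
terminal health losses and terminal costs (future unrelated medical costs in
gained years are included). Costs are discounted at 4%, effects at 1.5%. Per
posterior draw of `α + β`, incremental discounted costs and QALYs give the
threshold:

    k = mean(Δcost) / mean(ΔQALY)

with 95% intervals obtained by evaluating the ratio at the 0.025/0.975
quantiles of `α + β`, plus probability-below-value curves across draws.

Because the registry data behind such analyses are typically not
redistributable, the package ships a **synthetic-data module** that draws
panels from exactly the model above with known truth (and parametric
life-table surfaces), so every stage is testable offline, including full
parameter-recovery studies.

## Worked example

```r
library(kthresh)

# a synthetic world: 16 strata (60-64 ... 95+, both genders), 1994-2010,
# true alpha = -0.065, beta = -0.124
sim   <- generate_panel(true_panel_params(seed = 42))
frame <- build_model_frame(sim$panel)
fit   <- fit_mcmc(frame, make_prior("vague"),
                  mcmc_config(n_chains = 2, n_iter = 6000, burn_in = 1000,
                              thin = 4, seed = 42))

life <- generate_life_inputs(life_surface_params())
ts   <- summarize_threshold(elasticity_draws(fit), life)
ts
#> k-threshold summary (2500 draws)
#>   cost per QALY: 24,200 (19,000/33,800)
#>   cost per life year: 18,900 (14,900/26,400)
#>   share of draws with non-positive incremental QALYs: 0

attribute_le_gain(sim$panel, life, mean(elasticity_draws(fit)), 65)
#> life-expectancy gain at age 65, 1994-2010: 0.441 of the gain attributable
#> to spending growth (0.299 / 0.679 years)

probability_below(elasticity_draws(fit), life, grid = c(2e4, 4e4, 8e4))
#>   value probability
#> 1 20000      0.0692
#> 2 40000      0.9972
#> 3 80000      1.0000
```

Reading the output: a 10% increase in CVD hospital spending in this
synthetic world costs about €24,200 per QALY gained (interval from the
elasticity quantiles); life years are cheaper than QALYs because gained
years are not lived in perfect health; the short MCMC run (posterior mean
elasticity −0.32 on one random panel) is for illustration — the protocol
settings are `mcmc_config()`'s defaults. The attribution line says 44% of
this world's life-expectancy gain at 65 is attributable to spending growth;
the curve gives the probability that the threshold lies below each monetary
value.

A full run (simulate → fit → diagnose → translate → report, all artifacts as
CSV/JSON plus a reproducibility manifest) is driven by a JSON configuration:

```r
cfg <- load_config("config.json")
run_pipeline(cfg, stages = "all")
```

or from the shell via `Rscript inst/cli/kthresh.R all --config config.json`.

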