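# ordval

Hierarchical Bayesian modeling of risk and ambiguity attitudes when choice
outcomes are ordinal rather than numeric.

## The problem

Classic models of decision-making under uncertainty score a lottery by a
power utility of its numeric payoff,

    SV = (P − β·A/2) · V^α

with winning probability `P`, ambiguity level `A` (the occluded fraction of
the probability display), payoff `V`, risk attitude `α` and ambiguity
attitude `β`. Many consequential decisions — which medical treatment to
take — have outcomes like "moderate improvement" that have no `V`. `ordval`
implements an estimated-value model for such ordinal outcomes: outcome
level `i` is worth the cumulative sum of nonnegative, subject-specific
increments ν₁…νᵢ,

    SV = (P − β·A/2) · Σ_{j≤i} ν_j

so the model *estimates* the values people assign to qualitative outcomes
while preserving their ordering, instead of assuming a utility curve. A
no-subjective-parameters baseline and a trembling-hand (lapse) choice rule
complete the model set. Everything is fitted by MCMC (the package's own
No-U-Turn sampler with hand-derived gradients in C++), with partial pooling
across subjects, rank-normalized split R-hat / bulk-ESS convergence
diagnostics, and PSIS-LOO model comparison with stacking weights.

The package is for researchers in behavioral economics and computational
psychiatry who want to quantify uncertainty attitudes from lottery-choice
tasks with qualitative outcomes, run model-recovery studies on simulated
agents, and compare ambiguity attitudes across outcome domains with a
robust (Student-t) Bayesian regression.

## Worked example

Simulate 30 classic-utility agents on the in-person task, apply the
exclusion rules, fit the estimated-value model, and inspect convergence:

```r
library(ordval)

design <- build_design("in_person", "monetary")   # 84 trials, 12 catch
agents <- draw_agents(30, noise_sd = 0.3, seed = 1)
raw    <- simulate_choices(agents, design, seed = 2)
ex     <- apply_exclusions(raw)

fit <- fit_model(model_spec("estimated_value"), ex$data,
                 sampler_settings(draws = 1000, tune = 1000, chains = 4,
                                  seed = 1))
fit
#> Hierarchical fit: estimated_value + logistic rule
#>  30 subjects, 2160 trials, 4 chains x 1000 draws
#>   max split R-hat 1.0026 | min bulk ESS 1324 | converged: TRUE
```

`max split R-hat` is the worst convergence ratio over all 190 sampled
parameters (values at or below 1.01 indicate the chains agree) and `min
bulk ESS` the smallest effective sample size (how many independent draws
the 4000 retained draws are worth for the hardest parameter). Compare
against the classic utility model:

```r
cu  <- fit_model(model_spec("classic_utility"), ex$data,
                 sampler_settings(seed = 1))
cmp <- compare_models(list(estimated_value = psis_loo(fit$log_lik),
                           classic_utility = psis_loo(cu$log_lik)))
cmp
#> Model comparison by PSIS-LOO (rank 0 = best):
#>            model rank elpd_loo p_loo d_loo  d_se weight    se
#>  estimated_value    0  -316.91 60.93  0.00  0.00      1 19.58
#>  classic_utility    1  -396.40 24.85 79.49 11.41      0 13.95
```

Higher `elpd_loo` is better; `d_loo` is the gap to the best model and
`p_loo` the effective parameter count — the flexible ordinal model pays a
larger complexity penalty yet still predicts these choices better, because
at this noise level the tight inverse-temperature prior keeps the utility
model from matching the sharpness of the simulated choices (the methods
vignette discusses exactly when this happens and what it implies for
recovery studies). `psis_loo()` also flags trials whose importance weights
have heavy tails (Pareto k > 0.7) so unreliable comparisons are visible.
`extract_subject_estimates(fit)` returns the per-subject posterior means
of β, γ and the four value increments; `robust_regression()` relates β
estimates across domains and reports the posterior mean slope with an 89%
highest-density interval.

A thin CLI wraps the same pipeline
(`inst/scripts/ordval simulate|fit|compare|crossdomain|recover|validate`).

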