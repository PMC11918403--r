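---
title: "Modeling risk and ambiguity attitudes with ordinal outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling risk and ambiguity attitudes with ordinal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Decision tasks that measure risk and ambiguity attitudes usually offer
numeric payoffs, because the standard models need a cardinal outcome value.
Many real decisions — choosing between medical treatments, say — offer only
ordinal outcomes ("slight improvement" < "moderate improvement" < "major
improvement" < "complete recovery"). `ordval` implements a family of
hierarchical Bayesian choice models that estimate the subjective values of
such ordinal outcomes jointly with each person's uncertainty attitudes, and
the machinery needed to compare those models honestly: PSIS-LOO
cross-validation, convergence diagnostics, a task/choice simulator for
recovery studies, and a robust regression for comparing attitudes across
outcome domains.

## The task

Each trial offers a certain outcome (always the lowest level, e.g. $5 or
"slight improvement") against a lottery over a better outcome. Lotteries are
*risky* (winning probability fully displayed: 25, 50 or 75%) or *ambiguous*
(probability display partially occluded; the occluded fraction A is 24, 50
or 74%, and the nominal probability is centered at 50%). `build_design()`
generates the full trial table: in the in-person variant each of the 3
outcome levels × 6 uncertainty conditions repeats 4 times (72 trials), plus
12 catch trials in which the lottery's prize equals the certain outcome —
a dominated option used as an attention check — for 84 trials per domain.
The online variant halves the repetitions and adds a fully occluded
(A = 1) condition.

Two design details are underdetermined by the printed totals and fixed here
as conventions: the 12 catch trials repeat each of the 6 uncertainty
conditions twice, and the online variant presents one catch trial per
uncertainty condition (7), giving 49 trials. Trial order is a seeded uniform
shuffle when requested and enumeration order otherwise.

## The models

All models score a trial by a subjective value (SV) for each option and map
the SV difference to a choice probability.

**Classic utility** (power utility with a linear ambiguity penalty on
probability):

$$SV = \left(P - \beta \frac{A}{2}\right) V^{\alpha}$$

with risk attitude $\alpha \in (0, 2)$ (< 1 risk averse) and ambiguity
attitude $\beta \in [-1.5, 1.5]$ (> 0 ambiguity averse). The certain option
is $V_{certain}^{\alpha}$.

**Estimated value** (the ordinal model): outcome level $i$ has value
$\sum_{j \le i} \nu_j$ with nonnegative per-level increments $\nu_j$, so
values respect the ordinal structure by construction and no separate risk
parameter exists — curvature lives in the increments:

$$SV = \left(P - \beta \frac{A}{2}\right) \sum_{j=1}^{i} \nu_j .$$

**No-subjective-parameters baseline**: the category index is the value and
ambiguity is penalized at unit rate, $SV = (P - A/2)\, i$, with no
subject-level parameters. It anchors model comparisons from below.

**Choice rules.** The logistic rule
$P(\text{lottery}) = \text{logit}^{-1}\{\gamma (SV_{lottery} - SV_{safe})\}$
with inverse temperature $\gamma$; and the trembling-hand rule
$(1-\delta)\,\text{logit}^{-1}(SV_{lottery} - SV_{safe}) + \delta/2$, a
unit-temperature logistic with lapse rate $\delta$ that decouples the
asymptotes of the choice function from the value parameters. The
trembling-hand rule is paired only with the classic utility model, and the
package corrects an inverted sign sometimes seen in print for this rule so
that choice probability increases in the lottery's value, consistent with
the logistic rule.

**Hyperpriors.** Subject-level parameters are partially pooled:
$\alpha \sim 2\,\mathrm{Beta}(\alpha_1, \alpha_2)$ with
$\alpha_1 \sim N(4,1)$, $\alpha_2 \sim N(7,3)$ (both truncated at 0), which
puts the plug-in central prior mean of $\alpha$ at $2 \cdot 4/(4+7) = 8/11
\approx 0.73$ — slight risk aversion; $\beta \sim N(\mu_\beta,
\sigma_\beta)$ truncated to $[-1.5, 1.5]$ with $\mu_\beta \sim N(0.65, 1)$
(slight ambiguity aversion) and $\sigma_\beta \sim \mathrm{Gamma}(2,1)$;
$\gamma \sim \mathrm{LogNormal}(0, 0.25)$ per subject;
$\delta \sim \mathrm{Beta}(\delta_1, \delta_2)$ with $\delta_{1,2} \sim
N(2,1)$ truncated at 1; $\nu_i \sim N(\mu_{\nu_i}, \sigma_{\nu_i})$
truncated at 0 with $\mu_{\nu_i} \sim N(4, 2)$ truncated at 0 and
$\sigma_{\nu_i} \sim \mathrm{Gamma}(3, 1)$. All are configurable through
`hyperprior_settings()` and serializable as YAML; the defaults ship in
`inst/extdata/hyperpriors_default.yaml`. The plug-in reading of the prior
mean (locations into the Beta mean, rather than Monte Carlo over the
truncated hyperpriors) is a deliberate choice: it is the quantity a reader
can verify in closed form.

In the estimated-value model $\gamma$ and the overall scale of the $\nu$
increments are only softly identified against each other; the informative
$\mathrm{LogNormal}(0, 0.25)$ prior on $\gamma$ anchors the scale. This is
an identifiability caveat, not a bug: reported increments are meaningful on
the scale pinned down by that prior.

## Inference

Models are fitted by the package's own No-U-Turn sampler: Hamiltonian Monte
Carlo on the unconstrained scale (log transforms for positive parameters,
scaled-logit for interval-bounded ones, with the matching Jacobians and
truncation normalizers), dual-averaging step-size adaptation to a target
acceptance of 0.8, and a diagonal mass matrix estimated in expanding
windows during warmup. Defaults follow the printed sampler settings: 4
chains, 1000 tuning iterations, 1000 retained draws, no thinning. Gradients
are exact, hand-derived, implemented in C++, and verified against numerical
differentiation in the test suite.

The $\nu$ increments use a fully non-centered parameterization through the
truncated-normal inverse CDF: the sampled variable is $w \sim N(0,1)$ and
$\nu = \mu_\nu + \sigma_\nu\, \Phi^{-1}\!\left(\Phi(-r) + \Phi(w)\,
\Phi(r)\right)$ with $r = \mu_\nu/\sigma_\nu$ — the exact
$\mathrm{TruncNormal}(\mu_\nu, \sigma_\nu, 0, \infty)$ quantile evaluated
at the uniform variate $\Phi(w)$. This is the same model, reparameterized:
all dependence on the group-level location and scale moves into a smooth
deterministic map, which removes the funnel between $\sigma_{\nu_1}$ and
the subject-level increments that otherwise throttles mixing (the level-1
value is informed only weakly by each subject's choices; centered variants
of this model cost a several-fold larger autocorrelation time in the
group-scale block). $\beta$ remains centered: its truncation bounds are fixed and its
hierarchy shows no such pathology. $\gamma$ is per-subject but not hierarchical (its prior is fixed
rather than learned), matching the model definitions above.

The same posteriors are also expressible in JAGS, and `fit_model(...,
engine = "jags")` retains that formulation as an independent reference
implementation: the test suite checks that both samplers agree on small
problems. The Gibbs/slice reference mixes far less efficiently per draw on
the estimated-value model (the $\gamma$–$\nu$ ridge), which is why NUTS is
the default engine rather than an option.

Convergence is assessed with rank-normalized split R-hat and bulk effective
sample size, computed per parameter over all chains (thresholds: R-hat
$\le$ 1.01 and ESS $\ge$ 1000 under the default settings); divergent
transitions are counted and surfaced. The diagnostics implementation is
validated in tests against white-noise and AR(1) oracles with known
R-hat/ESS.

## Model comparison

Per-trial pointwise log-likelihoods are computed from the retained draws
(the LOO unit is the trial), and out-of-sample predictive fit is estimated
by PSIS-LOO: importance weights per held-out trial, with the upper tail of
the log-weights replaced by expected order statistics of a generalized
Pareto distribution fitted by the empirical-Bayes profile-likelihood method
(with the weakly informative shrinkage of the tail-shape estimate toward
0.5), truncated at the raw maximum. Trials with tail shape $k > 0.7$ are
flagged. `compare_models()` ranks by ELPD, reports the difference to the
best model with its pointwise standard error, and computes *stacking*
weights — the convex combination of models maximizing the summed log
pointwise predictive density. Stacking is used (rather than pseudo-BMA)
because it is the default of the tooling this workflow mirrors; ties break
by model name for stable output. The implementation is validated against
an exact quadrature-based leave-one-out oracle on a one-parameter logistic
model and a brute-force refit oracle on a small hierarchical dataset.

## The simulator and what passing tests mean

`draw_agents()` and `simulate_choices()` implement the model-recovery
generator: each synthetic agent has $\alpha \sim U[0.1, 1.6]$ and $\beta
\sim U[-1.4, 1.4]$ (independent uniforms over the stated identifiability
ranges; the generating distribution inside those ranges is otherwise
unconstrained, and uniform is the least-assuming choice), and chooses the
lottery when the classic-utility value difference plus a single zero-mean
Gaussian noise draw is positive. The noise is applied to the SV
*difference* — applying independent noise to each SV is equivalent up to a
$\sqrt{2}$ rescaling, so `noise_sd` is defined on the difference scale.
The default study grid crosses sample sizes and noise:
(30, 0.1), (30, 0.3), (30, 0.5), (60, 0.3), (60, 0.5), (120, 0.5),
(300, 0.5).

Two caveats this generator makes explicit. First, a strongly
ambiguity-seeking agent ($\beta < -1.35$) *rationally* prefers the
74%-ambiguous catch lottery to the certain option, because
$P - \beta A/2 > 1$; "catch failures are impossible at zero noise" holds
for $|\beta| \le 1$, and the tests state it that way. Second, simulated
agents use a deterministic threshold plus Gaussian noise (a probit-like
policy), not the logistic rule used in fitting; this mild mismatch is part
of the recovery study design, not an accident.

Passing recovery tests on these simulations shows that the pipeline can
tell the models apart and recover parameters *under this generator*; it
does not certify behavior on real participants, whose choices include
sequential effects, attention lapses and non-stationarity that the
generator deliberately omits.

## Preprocessing

`apply_exclusions()` implements the two participant-level rules, per
dataset (i.e. per domain, matching the convention that each domain is
preprocessed and fitted separately): subjects failing $\ge 6$ of the 12
attention checks are excluded ("failing" = choosing the dominated catch
lottery), and subjects choosing the lottery fewer than 2 times are excluded
because a constant choice pattern carries no gradient for the choice
models. Catch trials of retained subjects are then dropped from the fitting
data: under every model here the catch lottery's value information is
degenerate, so they contribute only to the attention rule. Both boundaries
are pinned by tests (5 vs 6 failures; 1 vs 2 lottery choices).

## Cross-domain association

Ambiguity attitudes are comparable across domains (risk attitudes are not:
in the estimated-value model, curvature is absorbed into the outcome values
themselves). `robust_regression()` regresses per-subject medical $\beta$
point estimates on monetary ones with a Student-t observation model —
$y_i \sim t_\nu(a + b x_i, \sigma)$ with weakly informative Normal(0, 10)
priors on $a, b$, a flat positive prior on $\sigma$ and
$\nu = 1 + \mathrm{Exponential}(1/29)$ — fitted via JAGS (a small, standard
model where the established Gibbs engine is the right tool). Using
posterior means as inputs is the usual two-stage shortcut; propagating full
posteriors is out of scope. Intervals are reported as highest-density
intervals (`hdi()`, default mass 0.89, the narrowest-window estimator on
sorted draws). An optional grouping column yields independent regressions
per group (e.g. by surgery history); no interaction model is fitted.

## Numerical choices and problem sizes

Tolerances and sizes that matter, all of them the package's own choices:
the GPD tail fit needs at least 5 positive exceedances, otherwise the
weights are left unsmoothed (degenerate tails arise with near-constant
likelihoods, where smoothing is unnecessary); HDI computation requires 100
draws except at full mass; the dominated-option guard in the trembling-hand
likelihood floors probabilities at `1e-300`; the NUTS tree depth is capped
at 10 and initial values are prior-typical points jittered with SD 0.15 on
the unconstrained scale. The convergence checks in the test suite run the
full printed sampler settings on a 30-subject simulated dataset; the
recovery and cross-engine tests use reduced chains (2 × 500 or smaller) on
5–60 subjects, sizes at which the checked properties are already stable.

## Known limitations

* The estimated-value scale is relative; increments are interpretable on
  the scale fixed by the $\gamma$ prior, not in dollars.
* PSIS-LOO tail estimates use the raw draws without an effective-sample-
  size correction of the tail length; with the ESS levels the sampler
  produces this is immaterial, but severely autocorrelated input would
  deserve the correction.
* The categorical (non-cumulative) model variant, prior-sensitivity
  sweeps beyond configurable hyperpriors, and fitting of real participant
  data are out of scope.
* In the package's own recovery study (classic-utility generator at the
  printed parameter ranges, noise on the dollar-scale value difference,
  printed hyperpriors), the estimated-value model outranks the classic
  utility model by LOO at *every* tested noise level, including 0.1. The
  mechanism is identifiable: at these noise levels the simulated choices
  are nearly deterministic relative to the value differences, and the
  tight LogNormal(0, 0.25) prior on the inverse temperature prevents the
  utility model from expressing that sharpness, while the ordinal model
  sharpens by scaling its free values at small prior cost. Relaxing the
  inverse-temperature prior, or rescaling the noise to the value-difference
  spread, makes the utility model win at every noise level instead; no
  tested convention produces a noise-driven ranking reversal. Treat
  low-noise recovery rankings from this generator accordingly.
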