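---
title: "Multilevel strategy models for reciprocity games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel strategy models for reciprocity games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopstrat)
```

## The scientific question

When people cooperate repeatedly, do they react only to what their partner
just did (tit-for-tat-like reciprocity), or also to what they themselves
just did (win-stay-lose-shift-like behavior)? coopstrat implements a
complete analysis pipeline for answering this question with repeated
binary cooperation decisions from two experimental protocols:

* **Direct reciprocity** — an iterated prisoner's dilemma. Participants
  are paired once and stay paired; in every round both members of a pair
  simultaneously decide whether to give their endowment (20 units, doubled
  to 40 for the receiver) to the partner or keep it, 42 rounds in total.
* **Generalized reciprocity** — a sequential gift-giving game on rings of
  five players. Each player in fixed order decides whether to give the
  endowment to the next player on the ring, conditioned on what the
  previous player last gave *them*. Each participant decides 42 times
  (2 decisions per rotation × 7 rotations × 3 chains).

In both games, the partner's previous action is shown with **perception
error**: with probability 0.25 the opposite of the actual decision is
displayed. The error creates the conditions under which win-stay-lose-shift
is theoretically advantageous and guarantees observations of reactions to
both cooperation and defection.

## The behavioral models

Every decision $y \in \{0,1\}$ (1 = cooperate) is Bernoulli with
probability $p$ given by an inverse-logit linear predictor. Writing
$O_{i,t-1}$ for participant $i$'s own previous action and $P_{i,t-1}$ for
the partner's *displayed* previous action (indicator coding, C = 1,
D = 0), the four candidate models are

* **PA** (partner's action): $\mathrm{logit}\, p = \alpha_{1,i} +
  \alpha_{2,i} P_{i,t-1}$,
* **OPA** (own and partner's action): $\mathrm{logit}\, p = \beta_{1,i} +
  \beta_{2,i} O_{i,t-1} + \beta_{3,i} P_{i,t-1} +
  \beta_{4,i} O_{i,t-1} P_{i,t-1}$,
* **OA** (own action): $\mathrm{logit}\, p = \gamma_{1,i} +
  \gamma_{2,i} O_{i,t-1}$,
* **Null**: $\mathrm{logit}\, p = \varepsilon_i$ (varying intercept only).

Whenever a model's conditioning information does not exist — the first
round of the direct game, or the opening donor of a chain — the linear
predictor is a single shared scalar $v$, the no-information cooperative
tendency. $v$ is shared by all participants in all models; a varying $v$
is poorly identified because each participant contributes at most a
handful of uninformed decisions.

All other coefficients are **varying effects**: $m_i = \mu + z_i \sigma$
with $z_i \sim \mathrm{Normal}(0,1)$, so each participant's coefficient is
drawn from a group-level normal distribution (partial pooling, written in
the non-centered form that samplers handle well). Two non-multilevel OPA
variants are included for comparison: `OPA_NONPOOL` gives every
participant independent coefficients with no shared distribution, and
`OPA_POOL` forces a single coefficient vector on everyone.

### Priors

$v \sim \mathrm{Normal}(0, 10)$ on the logit scale. The same
$\mathrm{Normal}(0, 10)$ is used for every group-level mean $\mu$ and for
the non-pooling/pooling coefficients, and
$\sigma \sim \mathrm{half\text{-}Normal}(0, 5)$ for the group-level
standard deviations. On the logit scale these are weakly informative:
$|\mathrm{logit}\, p| > 6$ already pins $p$ within $0.0025$ of 0 or 1.
All four scales can be overridden through `prior_spec()`.

## Sampling

`fit_model()` runs Hamiltonian Monte Carlo, implemented in C++ inside the
package: leapfrog integration with a diagonal mass matrix estimated from
the middle half of warm-up, dual-averaging step-size adaptation targeting
an acceptance statistic of 0.8, trajectory lengths of (nominal integration
time) / (step size) with ±10% step-size jitter, and group-level SDs
sampled as $\log \sigma$ with the Jacobian correction. A transition whose
Hamiltonian error exceeds 1000 counts as a divergence and is rejected.

Because the likelihood depends on an observation only through
(participant, conditioning state), the observations are aggregated into
binomial cells before sampling — at most four cells per participant plus
one shared no-information cell for the OPA design. This is an exact
rewriting of the likelihood, not an approximation, and makes a full fit of
40 participants × 42 decisions take on the order of a second.

Defaults follow the analysis protocol: 4 chains × 5,000 iterations with
2,000 discarded as warm-up, i.e. 12,000 retained draws. Convergence is
assessed with split-chain R-hat for every free parameter; values at or
above 1.05 mark the fit as unconverged (with a warning, never silently),
and values above 1.01 deserve inspection. Each chain's RNG seed is derived
deterministically from the master seed, so a fit is exactly reproducible.

A note on scale for routine checking: the package's own test-suite
experiments (parameter recovery, model discrimination, classification)
use 2 chains × 1,500 iterations with 500 warm-up on 40 × 42 data sets.
At that size the posterior quantiles used by the checks are stable; final
analyses should use the defaults.

## Model comparison

`waic(log_lik_matrix(fit))` computes the widely applicable information
criterion from the pointwise log-likelihood over draws:
$\mathrm{lppd} = \sum_n \log\left(\tfrac1S \sum_s \Pr(y_n \mid
\Theta_s)\right)$ (always through log-sum-exp; a naive mean of
exponentials underflows for realistic log-likelihoods),
$p_{\mathrm{WAIC}} = \sum_n \mathrm{Var}_s\left(\log \Pr(y_n \mid
\Theta_s)\right)$ with the $1/(S-1)$ divisor, and
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$.

`compare_models()` reports each model's WAIC, its difference from the
best model (dWAIC), and Akaike-type weights
$w_k = \exp(-\tfrac12 \mathrm{dWAIC}_k) / \sum_j \exp(-\tfrac12
\mathrm{dWAIC}_j)$. Standard errors are the usual pointwise-variance
estimators, $\mathrm{SE} = \sqrt{N \,\mathrm{Var}_n(\mathrm{pointwise}_n)}$
and, for dSE, the variance of the pointwise *differences* against the best
model; the best model's dSE is undefined. Tables are written at two
decimals for presentation while full precision is retained in the returned
object.

## Posterior summaries

`group_probs()` reports, per retained draw, the inverse logit of the
*hyper-mean* linear predictor for each conditioning state (for OPA:
CC, DC, CD, DD), summarized by the median and the equal-tailed 95%
compatibility interval. This describes the group-level mean participant.
A second definition — the cooperation probability of a hypothetical *new*
participant, which also carries the between-person spread — is available
with `marginal = TRUE`; it averages the inverse logit over the group
normal by Gauss–Hermite quadrature (the new participant's predictor is
exactly normal for any fixed design row, so a 21-node 1-D rule suffices
and keeps the summary a deterministic function of the draws). The
hyper-mean definition is the default because the quantity of interest is
the group-level behavioral tendency, not a prediction for an unseen
person.

Interval endpoints use inverse-ECDF (type 1) quantiles. Order statistics
commute with monotone transforms, so an interval of probabilities is
exactly the inverse logit of the corresponding interval of linear
predictors.

`prob_diffs()` subtracts per-draw probabilities for ordered condition
pairs and reports $P(\mathrm{diff} > 0)$ as the fraction of draws strictly
above zero — draws exactly at zero count as *not* greater.

## Behavioral typing

`classify_types()` assigns each participant one of four types from the
95% compatibility intervals of their own predicted
$\hat p(\mathrm{C|CC})_i$ and its differences from the other three
conditional probabilities, where "greater than $c$" means the interval's
lower bound exceeds $c$:

| Type | $\hat p(\mathrm{C|CC})_i$ | vs DC | vs CD | vs DD |
|------|--------------|-------|-------|-------|
| 1 (TFT-like) | > .50 | not > 0 | > 0 | > 0 |
| 2 (WSLS-like) | > .50 | > 0 | > 0 | — |
| 3 (other) | > .50 | any other pattern | | |
| 4 (non-cooperative) | not > .50 | any pattern | | |

Two reading decisions make the rule total (every interval configuration
maps to exactly one type). First, the "≤ 0" in the TFT row is read as
*not resolvably greater than zero* (lower bound ≤ 0) rather than *interval
entirely below zero*; the stricter reading leaves configurations with an
interval straddling zero unclassifiable. Second, a bound exactly at 0.5
or 0 counts as not-greater. The TFT rule is checked before the WSLS rule,
so a participant whose difference vs DC is unresolved but whose other
differences are clear is TFT-like even though they also satisfy two of the
three WSLS conditions. Type distributions across games are compared with
Fisher's exact test (`exact_type_test()`), the exact conditional test with
the probability-ordering two-sided criterion.

## The synthetic-data generator

No raw experimental data are distributed with the package, so
`simulate_direct()` and `simulate_generalized()` generate decision tables
with the full statistical and scheduling structure of the two protocols:
42 decisions per participant, fixed pairs or fixed five-player rings, the
25% display-error channel (applied once per display event, to the
partner's action only — a player's *own* previous action is always
conditioned on truthfully), endowment bookkeeping, and missing
conditioning information exactly where a participant has no prior
information. Agents are parametric: five conditional cooperation
probabilities (`agent_strategy()`), with presets for TFT, WSLS, ALLC and
ALLD, and `strategy_from_opa()` to build agents that realize any OPA
coefficient vector — simulating such a population *is* simulating from
the OPA generative model, which is what the recovery and discrimination
checks in the test suite do.

Two scheduling details of the generalized game are under-determined by a
verbal protocol description and were fixed as follows: a "rotation"
consists of two consecutive passes around the ring in fixed order (each
player donates twice per rotation), and ring membership and order are held
fixed across the three chains, which are simulated as independent. Only
the marginal conditioning structure — one displayed upstream action and
one own previous action per decision — matters for every model in the
package, and that structure is faithful under any resolution of the
ambiguity. A participant's own-action sequence runs across chains in
simulation order, so own information is missing only at the very first
decision.

The default simulated population (`build_population()`) is an equal
mixture of near-deterministic TFT, WSLS, ALLC and ALLD agents with
execution noise 0.05 and a 0.5 no-information cooperation rate: the four
classic strategy archetypes the typing step is designed to detect, soft
enough that every conditioning state is visited. Real participants are
messier — the generator produces stationary strategies with no learning,
no payoff sensitivity, no drift over rounds, and no session-level
effects. Passing recovery and classification checks on these populations
therefore demonstrates correctness of the estimator and classifier under
the assumed model class, not that human data satisfy those assumptions.

RNG discipline: one seeded generator per simulation; within each round the
display flips are drawn first (participant order), then the decisions
(participant order), so a seed fixes the byte stream of the output table.

## Numerical choices

* Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ before logs in
  the R-level `log_likelihood()`; the C++ path uses the numerically stable
  softplus form and needs no clipping.
* `inv_logit()` evaluates the two branches separately for positive and
  negative arguments, so it saturates cleanly at ±∞ without overflow.
* WAIC's lppd uses column-max-shifted log-sum-exp.
* Empirical conditional frequencies with a zero denominator are reported
  as undefined (`NA`) and excluded from group means, never imputed as 0.
  Group means weight participants equally regardless of their number of
  observations in a condition, and the group interval is
  mean ± 1.96 standard errors across participants.
* Degenerate R-hat (constant parameter) is `NA`, flagged but not an error.

## Known limitations

* The sampler is a fixed-trajectory HMC, not a dynamic-trajectory (NUTS)
  implementation; heavy funnel geometries would need smaller adaptation
  targets or reparameterization. The non-centered parameterization keeps
  the models in this package well behaved.
* WAIC is the only comparison criterion; cross-validation (LOO/PSIS) is
  out of scope.
* The generalized-game chain interleaving is simulated as independent
  chains, as discussed above.
* Strategies condition on exactly one lag; models with deeper memory are
  out of scope.
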