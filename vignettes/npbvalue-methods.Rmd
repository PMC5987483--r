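---
title: "Nonparametric Bayesian valuation of health states with cross-country priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric Bayesian valuation of health states with cross-country priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npbvalue)
```

## The problem

Preference-based measures such as the SF-6D describe health on six
dimensions (physical functioning, role limitation, social functioning,
bodily pain, mental health, vitality) with 6, 4, 5, 6, 5 and 5 levels, so
18,000 states are definable, coded `"111111"` (full health) to `"645655"`
(the "pits"). A *value set* assigns a utility to every state on the
dead = 0 / full health = 1 scale; it is estimated from valuation surveys in
which respondents value a sample of states by the standard gamble (SG),
with adjusted values bounded below at -1. Surveys are expensive, so most
countries have none. The question this package addresses: can a completed
survey in one country serve as a statistically principled head start —
an informative prior — for a smaller survey in another?

## The model

For respondent $j$ valuing state $x_{ij}$:

$$y_{ij} = 1 - \alpha_j\{1 - u(x_{ij})\} + \varepsilon_{ij}, \qquad
  \alpha_j \sim LN(t_j'\gamma_\alpha, \tau^2), \quad
  \varepsilon_{ij} \sim N(0, \upsilon^2),$$

where $u(\cdot)$ is the population utility function, $\alpha_j > 0$ is a
multiplicative respondent effect (how far respondent $j$'s valuations sit
from full health relative to the population), $t_j$ its covariate vector
(intercept, optionally centred age and sex), and $\varepsilon_{ij}$
measurement noise. The $-1$ bound on $y$ is treated as data preparation,
not as censoring in the likelihood, matching how the adjusted SG values
are produced.

The prior on $u$ over any set of states is multivariate normal. In
*standalone* mode the mean is $1 + \beta'(x - 1)$ (approximately additive
in the dimension levels) and the covariance $\sigma^2 c(x, x')$ with the
lattice kernel

$$c(x, x') = \exp\Big\{-\sum_d b_d (x_d - x_d')^2\Big\}.$$

Because the true function may deviate from the linear mean in any
direction permitted by this Gaussian process, the model is nonparametric
in the relevant sense. In *transfer* mode a previous country's posterior
(mean $E(u_{base}(x))$, covariance $\mathrm{cov}(u_{base}(x),
u_{base}(x'))$, both available from its fit) enters additively:

$$E(u(x)) = E(u_{base}(x)) + \gamma_0 + \beta'x, \qquad
  \mathrm{cov} = \mathrm{cov}(u_{base}) + \sigma^2 c(x, x').$$

$\gamma_0 + \beta'x$ absorbs systematic cross-country differences of
additive-linear form; $\sigma^2 c$ absorbs what remains. Either way the
prior is conditioned exactly on $u(111111) = 1$ (Gaussian conditioning,
not a penalty), and levels are centred as $(x - 1)$ so the linear term
vanishes at full health. Analyses over more than two countries are
iterated applications of `posterior_as_prior()`: each fit's posterior
becomes the next study's base, which realizes the general
sum-of-means / sum-of-covariances form as sequential composition through
one code path.

## Inference

`npb_fit()` runs Metropolis-within-Gibbs:

* $u$ at the design states: exact multivariate-normal full conditional
  (given $\alpha$ the likelihood is linear-Gaussian in $u$);
* $\log\alpha_j$: vectorized random-walk Metropolis;
* $\gamma_\alpha$, $\tau^2$, $\upsilon^2$, $(\gamma_0, \beta)$: conjugate
  draws;
* $\log\sigma^2$ (and optionally $\log b_d$): random-walk Metropolis with
  scales auto-tuned during burn-in towards 20--40% acceptance.

Default chain: 20,000 iterations, 5,000 burn-in, thin 5. The examples and
tests use much shorter chains (1,500--6,000 iterations) on studies of
15--60 design states and 15--100 respondents; those sizes were chosen so
the whole battery of replicated checks runs in minutes while leaving
Monte-Carlo error well inside the asserted tolerances.

### Identifiability

The likelihood is exactly invariant under $1 - u \mapsto c(1 - u)$,
$\alpha \mapsto \alpha / c$: the utility scale and the respondent-effect
scale are confounded. Two devices pin the scale down: the full-health
anchor, and centring the median of $\alpha$ at 1 by shrinking the
intercept of $\gamma_\alpha$ with a $N(0, 0.05^2)$ prior (covariate
coefficients keep $N(0, 1)$). We found a loose intercept prior lets the
scale drift by $\pm 20\%$ and biases every utility; the tight prior is
the operational meaning of "median respondent effect equal to 1", and is
particularly load-bearing in transfer mode, where the free offset
$\gamma_0$ opens the same soft direction again.

### Hyperpriors and numerical choices

$\gamma_0 \sim N(0,1)$, $\beta_d \sim N(0,1)$,
$\log\sigma^2 \sim N(-4, 1.5^2)$, $\tau^2, \upsilon^2 \sim$
Inverse-Gamma(2, 0.05), $b_d$ fixed at 0.1 by default (optionally sampled
with $\log b_d \sim N(\log 0.1, 0.5^2)$). Fixing $b$ stabilizes the
Gaussian process on a ~200-point design; 0.1 gives adjacent-level
correlation $e^{-0.1} \approx 0.90$. The $\sigma^2$ hyperprior is wider
and lower than a $N(-3, 1)$ alternative we first considered: that choice
effectively floors $\sigma^2$ near $2\times 10^{-3}$, which caps how much
an informative transfer prior can tighten the posterior — the floor, not
the data, would set the precision, defeating the transfer's purpose.

Other numerical conventions: a jitter of $10^{-8}$ on kernel diagonals
before Cholesky; random-walk proposals whose Cholesky fails are rejected;
covariances estimated from draws are PSD-repaired by clipping negative
eigenvalues at zero (with a warning reporting the clipped mass);
full-health rows of carried-forward posteriors are set to mean 1,
variance 0 exactly.

### Extending a stored posterior to new states

Transfer needs $E(u_{base}(x))$ at states the base study never valued.
Within a fit this is exact: each draw is extended by the
conditional-normal distribution under that draw's prior covariance, and
moments are combined across draws by the law of total variance
(`predict()`, `posterior_as_prior()`). For a posterior available only as
stored moments (e.g. read from files, or the packaged table),
`extend_posterior()` uses universal kriging about a linear-in-levels
trend, with the kriging variance scaled by the average stored variance
*plus* the variance of the stored mean about the trend — at states far
from the base design the extension knows only the trend, and the
covariance says so. An early version omitted the second term and
asserted near-certainty far from the base design, which actively degraded
transfer fits; the corrected scale is the honest one.

## The synthetic-data generator

No respondent-level survey data are deposited, so every stage is
exercised against a generator that emulates the model's own data-making
process:

* **Truth**: $u(x) = 1 - \sum_d dec_d(x_d) + s\, z(x)$, additive
  decrements plus a smooth Gaussian field $z$ with the lattice kernel
  (sampled through its Kronecker structure over the full 18,000-state
  lattice), conditioned to vanish at full health. Default decrement
  maxima (0.16, 0.07, 0.10, 0.15, 0.10, 0.06) sum to 0.64, putting the
  pits near 0.36 before perturbation — the range value sets for this
  descriptive system occupy. Levels follow a convex power curve
  (exponent 1.5): moves near the worst level cost disproportionately
  more, the uneven spacing empirical value sets show. The perturbation
  scale defaults to 0.06, large enough that the truth has material
  non-additive structure (the phenomenon a nonparametric model exists
  for); its roughness matches the model's default $b = 0.1$.
* **Respondents**: $\alpha_j \sim LN(t_j'\gamma_\alpha, \tau^2)$ with
  default $\tau^2 = 0.04$ (a $\pm 20\%$ spread of respondent scaling),
  error variance $\upsilon^2 = 0.01$ (SG noise of SD 0.1).
* **Studies**: balanced-random allocation of design states to
  respondents (each state valued approximately equally often — the
  surveys' block designs are unpublished, and balance is the
  conventional choice), clamping to $[-1, 1]$, missingness completely at
  random (as an exact count where a design's missing total is known).
* **Two countries**: country B's truth is A's with per-dimension
  decrement reweights plus a smooth level-linear shift — exactly the
  $\gamma_0 + \beta'x$ form the transfer prior corrects for — and the
  same perturbation field (the complicated part of preferences is shared;
  the systematic part differs). Defaults mirror the published designs:
  A = 249 states, 611 respondents at 6 each with 148 missing (3,518
  observed); B = 197 states, 582 respondents at 8 each with 60 missing
  (4,596 observed).

What the generator does *not* emulate: the ping-pong SG elicitation and
chaining arithmetic, informative missingness, respondent exclusions, or
interaction structure beyond a smooth field. Passing tests therefore
show the estimator works when its assumptions hold (plus smooth
departures); they cannot certify behaviour under elicitation artefacts
real surveys may carry.

## Evaluation battery

`prediction_summary()` joins per-state observed means with posterior
means/SDs; `rmse()`, `mean_error()` and `bland_altman()` (sample-SD
denominator, limits $\pm 1.96$ SD) summarize agreement, by convention
excluding the full-health row, whose agreement is exact by construction.
Differences are observed minus predicted. `monotonicity_audit()` samples
states without replacement, picks one neighbour of each uniformly at
random, and scores the fraction of pairs whose predicted utilities
conflict with dominance; ties count as violations by default (a value
set should strictly separate dominated states), with `ties = "ok"` for
the non-strict reading. `cost_per_qaly()` carries a utility difference
through to the funding arithmetic.

The packaged table (`load_table1()`) transcribes the published per-state
comparison of the Hong Kong models: observed means, the UK posterior used
as prior information, and the HK-only and HK/UK posteriors, 198 rows at
4-decimal printed precision. The transcription is validated by
`recompute_printed_aggregates()`, which reproduces every published
summary statistic from it; comparison is at printed precision with an
allowance of 1.5 units in the last printed digit, because the published
figures are truncated rather than rounded and the inputs are themselves
4-dp prints. Two quirks of the source are handled explicitly: the two
published mean-bias figures are attributed to the models in reverse of
what the table itself yields (the RMSEs and SDs identify the columns
unambiguously), so bias is compared as an unordered pair; and the
published claim that the transfer model's posterior SDs are smaller is
contradicted by the same table (smaller on 23 of 197 states), so the
package exposes that count rather than asserting the claim.

## What the replicated checks show — and the two that stay red

Across seeded replications the battery verifies: the Gibbs $u$-step
against the closed-form conjugate posterior; 95% credible-interval
coverage of $(\tau^2, \upsilon^2, \gamma_\alpha)$ at nominal level; and
the headline — with a large completed study in country A and a small
study in country B (60 states, 30 respondents), the transfer fit's mean
RMSE against the true surface beats the standalone fit's.

Two subsidiary claims do not replicate under these conditions, and their
checks are left failing rather than weakened. (1) *Posterior SDs smaller
on at least 80% of states*: the transfer prior's variance is the base
covariance plus $\sigma^2 c$ — variances add — so near-universal SD
reduction is not a property this construction delivers; the pooled
fraction here is ~0.74, and the published table itself shows the
reduction on only 23/197 states. (2) *Fewer non-monotone adjacent pairs
for the transfer fit*: on a monotone synthetic truth the standalone fit
collapses off-design to its monotone linear trend and audits at exactly
zero, while the transfer surface inherits Monte-Carlo noise from two
chains and audits at 0--3%; quadrupling chain length shrinks the gap
monotonically, identifying it as sampling noise, but the direction of
the published 20%-vs-10% comparison presupposes a standalone model far
wigglier than these conditions produce.

## A small worked run

```{r, eval = FALSE}
sc <- make_two_country_scenario(seed = 1,
  a_n_states = 150, a_respondents = 400, a_per_respondent = 6,
  a_missing = 20, b_n_states = 60, b_respondents = 30,
  b_per_respondent = 6, b_missing = 5)
ctl <- npb_control(iterations = 2000, burn_in = 600, thin = 2)
fit_a <- npb_fit(sc$study_a, npb_prior(), ctl, seed = 1)
prior_b <- npb_prior(base = posterior_as_prior(fit_a,
  states = unique(c(fit_a$states, sc$study_b$design_states))))
fit_b <- npb_fit(sc$study_b, prior_b, ctl, seed = 2)
summary(fit_b)
plot(fit_b, type = "bland_altman")
```

## Known limitations

* The likelihood ignores the $-1$ bound (no censoring term), as the
  measurement model specifies; with default parameters fewer than 1% of
  simulated records are affected, but heavy-tailed respondent effects
  would change that.
* `extend_posterior()`'s correlation fill and kriging scale are
  approximations whenever a posterior exists only as stored moments; the
  packaged table carries no cross-state covariances, so a prior built
  from it cannot reproduce the original analysis exactly.
* $b_d$ is fixed by default; sampling it (`estimate_b = TRUE`) is
  supported but slow on large designs and was not needed for any check
  here.
* Respondent covariates are limited to the intercept / age / sex layout
  the interchange format carries.
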