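---
title: "Rational inattention, tonic dopamine, and the precision of belief"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational inattention, tonic dopamine, and the precision of belief}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rattention)
library(ggplot2)
```

## The problem

Tonic (slow-timescale) dopamine has been modelled both as a report of the
average reward available in a context and as a controller of the precision
of Bayesian beliefs. This package implements a model in which the two are
the same mechanism: average reward is the *incentive* that determines how
much precision a resource-rational agent should buy, and tonic dopamine,
by reporting that single quantity at both encoding and decoding, sets the
precision and keeps it calibrated across the two stages. One scalar channel
then explains exploration–exploitation shifts, asymmetric learning from
feedback, the central tendency of interval timing, clock-speed changes,
controllability effects, and post-reward delay underestimation.

## The encoding–decoding channel

A stimulus $\mu$ (seconds, or reward units) is drawn from a contextual prior
$N(\mu_0, \lambda_0^{-1})$. The agent stores a noisy signal
$m \sim N(\mu, \lambda^{-1})$ and decodes it by conjugate Bayes:
$\hat\mu(m) = w m + (1-w)\mu_0$ with $w = \lambda/(\lambda + \lambda_0)$,
posterior precision $\lambda_0 + \lambda$. Performance is quantified by
quadratic error — chosen for tractability, not psychophysical fidelity —
whose source-conditional expectation is
$w^2\lambda^{-1} + (1-w)^2(\mu-\mu_0)^2$ and whose source-average
(`marginal_error()`) is $w^2\lambda^{-1} + (1-w)^2\lambda_0^{-1}$,
collapsing to $(\lambda+\lambda_0)^{-1}$ for a calibrated channel.

Decoding may assume an *estimated* precision $\lambda' = c\lambda$ different
from the true one: then $w = c\lambda/(c\lambda+\lambda_0)$ and the marginal
error is strictly minimized at $c = 1$ — overconfidence amplifies noise
along with signal, underconfidence leans too hard on the prior.
`optimal_miscalibration()` verifies the calibrated optimum by grid search
(the default grid is geometric on $[0.05, 10]$ with 1 inserted exactly, so
the argmin can be reported without interpolation).

## Buying precision

Precision costs attention, priced as mutual information
$I(\mu; m) = \tfrac12\log(1+\lambda/\lambda_0)$ nats at unit cost $\kappa$
(reward units per nat). The agent minimizes
$R\,(\lambda+\lambda_0)^{-1} + \kappa I$, where $R \ge 0$ is the reward
incentive, yielding $\lambda^* = \max(0, 2R/\kappa - \lambda_0)$: a
piecewise-linear incentive curve with threshold $2R/\kappa = \lambda_0$ and
slope $2/\kappa$ above it, so the agent "matches" its posterior precision
$\lambda^* + \lambda_0$ to $2R/\kappa$ whenever it attends at all. The
objective is unimodal in $\lambda$, which is why a bounded one-dimensional
minimizer serves as the independent oracle in the tests.

The incentive itself comes from the context (`incentive_from_context()`):

* with no reward-rate structure, $R$ equals the tonic dopamine level
  (average reward is read straight off the signal);
* under a controllability manipulation, $R$ is the ratio of
  performance-contingent to freely delivered reward rate. The underlying
  claim is only that incentive falls as free reward rises; the ratio is the
  simplest form that is inverse in the free rate, proportional to the
  contingent rate, and invariant to common rescaling, and all simulated
  orderings follow from those three monotonicities.

When the encoding machinery has a ceiling $\lambda_{\max}$, the *estimated*
precision keeps following $\lambda^*$ while the *true* precision saturates,
so incentive beyond the saturation point buys miscalibration instead of
accuracy: decoding error over an incentive grid is U-shaped
(`bounded_performance_curve()`, experiment `inverted_u`). With
$\lambda_{\max} = \infty$ the error is monotone non-increasing. The exact
functional form of the saturation is a modelling choice here (hard clip);
only the interior optimum is treated as a robust prediction.

## The internal clock

Objective time maps to subjective time as $m = \eta\log(\mu+1)$ with fixed
subjective encoding precision $l = 1$; the gain $\eta$ is the clock speed
and $1/\eta$ the pacemaker period. By the delta method, subjective noise of
precision $l$ is objective-time precision $l\eta^2/(\mu+1)^2$ at duration
$\mu$, so the gain that realizes a prescribed $\lambda^*$ at a reference
duration is $\eta = (\mu_{ref}+1)\sqrt{\lambda^*/l}$
(`clock_gain_from_precision()`). The model fixes only that precision rises
with clock speed, not a unique formula; this is the minimal mapping with the
right monotonicity, and it is the one place where the package's plumbing
goes beyond the published equations, so it is isolated in a single function
for easy replacement. Two numerical choices follow:

* a precision floor $\lambda_{floor} = 10^{-3}$ keeps $\eta$ positive when
  $\lambda^* = 0$ — some attention always remains, and a stopped clock is
  degenerate (it also keeps every pacemaker period finite);
* the reference duration is the mean presented duration for interleaved
  designs, the duration itself for blocked ones, 25 s for the free-operant
  controllability task (its switch point), and 3 s (the average buffer) for
  post-reward delays. The reference cancels wherever only gain *ratios*
  matter (clock-speed and post-reward experiments).

The log mapping makes sampled reproductions Weber-like: decoded responses
have SD approximately proportional to $(\mu+1)/\eta$, i.e. linear growth
with duration, which the suite checks by regression ($R^2 > 0.95$ over
2–40 s). Figure-level simulations use expected (noise-free) encodings, as
the published recipes do; sampling appears only in the variance properties
and the Monte-Carlo oracles.

**Central tendency** (interleaved 8 s and 21 s): the prior is centred on the
mid-duration — a learned running average would do as well, but mid-duration
is determinate — with SD equal to the duration difference divided by 2.5,
and $\kappa = 0.05\,s^{-1}$. Encoding and decoding share the gain (no acute
manipulation), so the only dopamine effect is how much precision is bought:
at DA = 0.2 reproductions migrate toward the prior mean (short overproduced,
long underproduced); at DA = 1 they are nearer veridical. Under this
parameterization the likelihood weight reduces to
$\lambda^*/(\lambda^*+\lambda_0)$, which is close to 1 at both DA levels, so
the simulated compression is directionally strict but small; the contract
here is the ordering, not effect size.

**Clock speed** (blocked 7 s and 17 s, $\kappa = 0.1\,s^{-1}$): blocked
presentation is modelled by omitting the cross-duration prior (an
uninformative subjective prior). Encoding always happens at baseline
DA = 1; decoding at DA 0.8/1/1.2 uses the gain that DA level buys, giving
$\hat t = (\mu+1)^{\eta_{enc}/\eta_{dec}} - 1$: underproduction under high
decoding dopamine (faster clock), overproduction under low.

**Controllability**: $R$ = contingent/free reward rate, contingent rate
0.01 s⁻¹, $\kappa = 0.1\,s^{-1}$, prior precision 1 (the attentional
problem needs one; any fixed value preserves the orderings since $R$ alone
varies). Pacemaker period $1/\eta$ rises with free reward and falls with
contingent reward.

**Post-reward delays**: incentive 1 before reward, 0.7 after. Subjective
time for the buffer accumulates at the slower post-reward gain but is read
out against the pre-reward scale — the model does not fix which gain anchors
the readout, and the pre-reward gain is the scale the animal's timing is
calibrated to — giving
$w_{post} = (b+1)^{\eta_{post}/\eta_{pre}} - 1 < b$, monotone in the buffer
and veridical when the incentives match. In the fixed six-second task the
smaller/sooner option carries the longer buffer, so its perceived total
shrinks more: apparent impulsivity without discounting. The subjective
estimate is generated by the clock model itself, not fitted to choice data.

## Reinforcement learning

**Exploration–exploitation** (`bandit_winshift`): three arms with success
probabilities 7/8, 1/16, 1/16 (low risk) or 5/8, 3/16, 3/16 (high risk),
magnitude 1; arm values are expected rewards (the published recipe is
deterministic; Bernoulli trial streams exist in `generate_fixtures()` for
property tests). The shared prior sits at the across-arm mean value — the
recipe leaves it open, and the symmetric choice preserves every ordering —
with $\lambda_0 = 10$, $\kappa = 0.1$, softmax $\beta = 4$. Win-shift is the
probability of not re-choosing the just-rewarded best arm under the
stationary softmax over posterior means (no trial-by-trial learning is
modelled). Below the attention threshold (DA $\le 0.5$ here) all posterior
means collapse to the prior and win-shift is exactly 2/3 in both risk
conditions; the default grid therefore spans DA 0.55–0.9, the attending
regime, where win-shift falls strictly with dopamine and is strictly higher
under high risk.

**Feedback asymmetry** (`feedback_asymmetry`): outcomes 1 (reward) and 0
(punishment), prior mean set to the DA level (high average reward breeds
high expectations), $\lambda_0 = 5$, $\kappa = 0.1$. Accuracy is the
posterior mass on the correct side of 0.5, computed with the Gaussian CDF
(exact, no sampling). Relative accuracy — positive minus negative — crosses
zero at DA = 0.5 by symmetry and rises strictly with dopamine over the
default grid 0.1–0.9. It is not globally monotone: as DA grows without
bound both accuracies approach 1 and the difference flattens past the
baseline level of 0.9, which is why the grid stops there.

**Gain-control equivalence**: in a two-arm choice the posterior-mean
difference is $w$ times the likelihood-mean difference, so precision $w$ at
inverse temperature $\beta$ is *exactly* indistinguishable from full
precision at $\beta w$ — dopamine's decoding effect is softmax gain control
without extra machinery (`gain_equivalence_check()`; identity verified to
$10^{-12}$).

## The three discriminating predictions

All use rewards 5/7.5/10, encoding precision 1 (high controllability) vs 0.1
(low), prior precision 1 (unstated in the recipes; set to the order of the
high-controllability likelihood and exposed as an argument), softmax
$\beta = 1$, and are deterministic given parameters.

1. **Transfer** (`transfer_choice`): arms trained under low controllability
   shrink harder toward the context mean 7.5, so the low-controllability
   small-reward arm looks better than its high-controllability twin while
   the large-reward preference flips — jointly incompatible with any uniform
   preference for a controllability level.
2. **Prediction-error magnitude** (`rpe_magnitude`): the estimated deviation
   of an outcome from the expected 7.5 is $w(\text{outcome}-7.5)$; bursts
   are larger and dips deeper under high controllability, signs preserved.
3. **Gain control vs rational inattention** (`gain_vs_inattention`): two
   identical 7.5 arms trained beside a 5 arm (prior mean 6.25) and a 10 arm
   (prior mean 8.75) end up estimated on opposite sides of 7.5. Under the
   gain-control hypothesis high dopamine scales $\beta$ 1 → 10 and p(C2)
   rises; under rational inattention high dopamine multiplies decoding
   precision by 10 (mirroring the $\beta$ ratio, for a symmetric
   comparison), the central tendency relaxes, the estimates converge, and
   p(C2) falls. Opposite signs, one experiment.

## What the generator does and does not emulate

`generate_fixtures()` produces seeded Bernoulli outcome streams for both
bandit risk conditions and Gaussian subjective-space interval encodings at
$l = 1$. These share the distributional assumptions of the model — they
exercise the statistical plumbing (frequencies within binomial error,
encoding variance near $1/l$), not the model's empirical adequacy. Passing
tests show internal consistency of the implementation with its own
assumptions and the published parameter recipes; they say nothing about
non-Gaussian real response distributions, sequential (trial-by-trial)
learning, motivational confounds, or receptor-level biology, none of which
are modelled.

## Problem sizes and numerical choices

Monte-Carlo oracles use $10^5$ draws with explicit seeds and a
three-standard-error tolerance; the closed-form/optimizer equivalence checks
50 random problems against a bounded L-BFGS-B minimization on $[0, 10^3]$ at
$10^{-5}$ tolerance; the Weber regression uses 2,000 samples at each of 20
durations. Softmax evaluation subtracts the maximum before exponentiating.
Likelihood precision 0 is treated as "no signal" (posterior = prior), the
continuous limit of the update. Every experiment runs deterministically in
well under a second on one CPU; the seed only affects sampled fixtures and
oracles.

## Limitations

The quadratic loss and Gaussian conjugacy are conveniences; the
$\lambda^*\!\to\!\eta$ link is the package's own minimal construction; the
saturation mechanism behind the inverted U is a hard clip; no trial-by-trial
learning, directed exploration, phasic prediction-error dynamics, or
discrimination-task variants are implemented. Magnitudes of simulated
effects (e.g. the central-tendency compression at the published timing
parameters) are not calibrated to data — orderings are the model's contract.
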