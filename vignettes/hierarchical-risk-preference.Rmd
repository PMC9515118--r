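---
title: "Hierarchical Bayesian estimation of rank-dependent risk preferences from binary lottery choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian estimation of rank-dependent risk preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdurisk)
```

## The scientific problem

Within-subject brain-stimulation experiments on risky choice ask whether a
treatment (here: continuous theta-burst stimulation of the left or right
dorsolateral prefrontal cortex, with a sham control) changes *structural*
components of risk preference — the curvature of the utility of money, the
distortion of outcome probabilities, and choice consistency — rather than
merely shifting raw choice frequencies. `rdurisk` implements the full
analysis chain for such a study: the multiple-price-list (MPL) task design,
a generative simulator of subject populations, a hierarchical Bayesian
estimator of a rank-dependent-utility (RDU) model with
stimulation-condition shifts, information-criterion model comparison,
posterior predictive checking, and Savage–Dickey Bayes factors for the
condition effects.

## The behavioural model

Each question is a choice between two two-outcome lotteries that share the
probability `p` of their better outcome. Utility of money is CRRA,

$$U(x) = x^r \ (x \ge 0), \qquad U(x) = -(-x)^r \ (x < 0),$$

with `r > 0` indexing curvature (in gains, `r < 1` is risk averse). A
lottery's value is rank-dependent: the best outcome receives decision
weight `w(p)` and the worst outcome the complement `1 - w(p)`, with three
one-parameter weighting families:

* linear: `w(p) = p`;
* Kahneman–Tversky: `w(p) = p^γ / (p^γ + (1-p)^γ)^{1/γ}`;
* Prelec (one-parameter): `w(p) = exp(-(-ln p)^α)`.

Curvature parameters above 1 give an S-shaped weighting function
(underweighting small, overweighting large probabilities); below 1, the
familiar inverse-S. Choice is stochastic in Luce's strict-utility form,

$$P(A \succ B) = \operatorname{logit}^{-1}\!\big(\tau \tfrac{1}{r}
  \ln \tfrac{EU_A}{EU_B}\big),$$

where `τ = 1/μ` is inverse temperature (consistency) and the `1/r` factor
is the value-function transformation that decorrelates `r` from the noise
scale. As `τ → ∞` the agent deterministically picks the higher-valued
lottery.

Two notational points deserve a remark. First, two-outcome RDU is often
written with the worst outcome weighted by `1 - w(p_worst)`; since the
weights must sum to one, the worst-outcome weight is the complement of the
best-outcome weight, and the package implements `1 - w(p_best)` throughout.
Second, the choice rule above is stated for positive expected utilities.
With CRRA losses both lottery values are negative: their ratio is positive
but the preference ordering on the ratio reverses, so in the loss domain
the package flips the sign of the log-ratio term. This keeps the
deterministic limit meaningful — the option with the larger (less
negative) value is preferred — and reduces to the printed rule in gains.

## Task design

One MPL fixes four outcomes (safe option A, wide-spread option B) and
walks the shared best-outcome probability through 16 levels
`{0, .01, .05, .1, .15, .2, .3, .4, .5, .6, .7, .8, .85, .9, .95, 1}`. A
session concatenates three gain-domain MPLs and their sign-mirrored loss
twins (96 questions), shows the higher-variance option on the left for
exactly half of the questions, and randomizes presentation order.

Only the first MPL's outcomes are part of the published task description
(safe 260/180 MU vs risky 350/50 MU; option A has the higher expected
value on rows 1–9). The other two outcome sets are configuration with
defaults chosen here on design-of-experiments grounds. This choice is not
innocent: CRRA utility responds to outcome *ratios*, so if every MPL
shares the same ratio of best-outcome scale to worst-outcome scale, a
coordinated increase of `r` and the weighting curvature reproduces almost
exactly the same 96 choice probabilities, and `(r, γ)` is unidentified no
matter how much data is collected. A multi-start maximum-likelihood probe
of such a battery lands ~1 unit of log-likelihood from the generating
values while being ~1 unit of parameter distance away from them. The
shipped defaults therefore vary the spread structure across lists — one
narrow-spread list (340/300 vs 380/240) and one wide-spread list (250/120
vs 450/50) next to the published list — which breaks the ridge and makes
the baseline parameters recoverable. Users reproducing a specific
experiment should substitute their own outcome sets.

## Generative model and hierarchy

Subject `i`'s parameters in condition `c ∈ {sham, right, left}` are a
baseline plus condition shifts,

$$r_{ic} = r_i^0 + \Delta r_i^{right} I(c{=}right) + \Delta r_i^{left}
I(c{=}left),$$

and likewise for the weighting curvature and `τ`. Parameters live on
bounded supports — `r^0 ∈ (0,5)`, curvature `∈ (0,6)`, `τ^0 ∈ (0,∞)`,
`Δr ∈ (−2,2)`, `Δγ ∈ (−1.5,1.5)`, `Δτ ∈ (−5,5)` — reached from an
unconstrained working space by `exp` (one-sided) or a scaled probit
`a + (b−a)Φ(z)` (two-sided). The hierarchy is placed on the unconstrained
scale with a non-centered parameterization
(`z_{ik} = μ_k + σ_k η_{ik}`, `η ~ N(0,1)`), which is both what the stated
transforms imply and much kinder sampling geometry than a centered
hierarchy. Group-level priors (unconstrained scale): `μ` of the baselines
`~ N(0,5)`, `N(1,3)`, `N(0,10)`; all six shift means `~ N(0,1)`; all group
SDs lognormal(0, 3) — equivalently `log σ ~ N(0,3)`, which is how the
package parameterizes it (the Jacobian of `σ → log σ` turns one into the
other exactly). Under the `N(0,1)`-then-probit construction the implied
prior of each constrained shift mean is uniform on its interval, giving
closed-form prior densities at zero of 1/4, 1/3 and 1/10 — used by the
Savage–Dickey ratio and cross-checked by transform sampling in the tests.

Composed per-condition parameters are not separately bounded; the
likelihood only requires positivity, so the generator and likelihood floor
them at `1e-6` (the floor region has zero gradient, and in practice is
never visited at realistic parameter values).

### Simulator defaults

`group_hyper()` defaults to the headline gain-domain estimates — baseline
curvature 1.03, weighting 2.5, consistency 6.68, a left-stimulation
weighting shift of 0.61, other shifts null — so simulated cohorts mimic
the study's fitted regime without claiming data equivalence. Between-
subject heterogeneity defaults to SD 0.25 on the unconstrained scale,
i.e. roughly ±50% variation in `r^0` and `τ^0` across subjects, a typical
magnitude for lab risk-preference samples. Condition order is
counterbalanced with a Latin-square rotation over the six orders; each
session re-randomizes question order.

What the simulator deliberately does *not* emulate: reaction times,
fatigue and order effects, payment realization, discomfort covariates, or
any deviation from the RDU functional form (e.g. heuristic rules). Passing
recovery tests on synthetic data therefore validates the estimation
machinery — not the behavioural adequacy of RDU for any particular real
dataset.

## Inference

Sampling uses a self-contained Hamiltonian Monte Carlo sampler (Rcpp) with
analytic gradients of the joint log density: static trajectories whose
length is jittered uniformly up to `max_leapfrog`, dual-averaging
step-size adaptation to a 0.8 acceptance target, and a diagonal mass
matrix estimated from the middle half of warm-up. Chains run sequentially
from a single seeded RNG stream, so fits are bit-reproducible given
`(seed, config)`. Gradients are verified against numerical differentiation
in the test suite; divergent transitions (energy error > 1000) are counted
and surfaced as warnings, as are group-level split-Rhat values above 1.01.

Two configurations are first-class: the full-scale profile (8 chains,
1000 warm-up + 4000 sampling iterations, 32,000 kept draws per parameter)
and a desk-scale profile used by the test-suite and the numbered analysis
scripts (2 chains, 1000 + 1000, `max_leapfrog` 48). The desk profile was
sized so that a 12-subject fit is well mixed in well under a minute:
warm-up must be long enough for the mass matrix to adapt to the
posterior's ridge-like geometry, and trajectories long enough to traverse
it. With very short warm-up (say 200 iterations) chains can linger where
the probit transforms saturate and group-level intervals become
unreliable. Chains start near the complete-pooling maximum-likelihood
point by default (jittered per chain), which keeps early warm-up out of
the saturation region; fully random starts are available via
`init = "random"`.

Convergence diagnostics are split-chain R-hat and an
autocorrelation-based effective sample size (Geyer initial-monotone
truncation), computed for every constrained parameter.

## Model comparison and checking

Pointwise log-likelihoods of every kept draw feed WAIC and PSIS-LOO
(generalized-Pareto smoothing of the top 20% of importance weights, with
the Zhang–Stephens profile-posterior tail fit; observations with tail
shape k > 0.7 are flagged). Selection is by smallest LOOIC, falling back
to WAIC and then to the simpler family on ties. The posterior predictive
check draws parameter vectors from the joint posterior and scores the
proportion of observed choices that the model predicts correctly; the
default prediction rule is modal (choose the option whose predicted
probability exceeds one half — the natural reading of "correctly fitted
choices"), with a sampled-prediction variant behind a flag.

## Hypothesis testing

Condition effects are summarized on the constrained scale of the group
shift means: posterior mean, equal-tailed 89% and 95% percentile
intervals (type-7 quantiles; equal-tailed was chosen over HDIs because the
reported intervals are symmetric summaries and the estimator is simple
and order-statistic exact), and the Savage–Dickey Bayes factor at zero —
prior density at zero (closed form, or transform-sampling as a
cross-check) divided by a Gaussian kernel density estimate of the
posterior at zero with Silverman's bandwidth (configurable; calibration
tests sweep it over an order of magnitude). Bayes factors are binned on
the usual Jeffreys-style scale, e.g. values in (1, 3) are anecdotal
evidence for an effect. No multiplicity correction is applied: the
hierarchical model's partial pooling already shrinks the six shift
estimates toward zero.

## Numerical choices and degenerate inputs

* Probabilities are exact grid decimals; `p_best + p_worst = 1` is
  enforced to 1e-12, and interior probabilities are clamped to
  `[1e-12, 1-1e-12]` before logs inside the weighting functions, with the
  exact endpoints short-circuited (`w(0)=0`, `w(1)=1`; the Prelec endpoint
  is the limit).
* Expected-value ties in the risk-neutral reference pattern break to
  option A (the task forbids expressing indifference, so a rule is
  needed).
* Choice probabilities require the two lottery values to be nonzero and
  share a sign; violations raise an error rather than returning NaN.
* WAIC/LOO use log-sum-exp stabilization throughout; a pointwise matrix
  with non-finite entries is rejected.
* Degenerate lotteries (`x_best = x_worst`) are allowed and have zero
  payoff SD; a choice between identical lotteries has probability exactly
  1/2.

## Reduced-scale validation and its limits

The test suite validates the chain end to end at desk scale: simulate 12
subjects at the headline generating values, refit, and require the
group-mean 95% intervals to cover the truth across replicates, with the
left-stimulation weighting shift detected in most of them; re-select the
generating weighting family by LOOIC against the linear model across
replicates; and calibrate the Savage–Dickey machinery (prior-in ⇒ BF ≈ 1,
closed-form conjugate example, null-generated data ⇒ evidence for the
null). Problem sizes (12 or 8 subjects, 2 × 1000/1000 draws, 10 replicates)
were chosen as the smallest at which these statistical properties are
stable; they are not estimates of the full design's power. In particular,
detecting a weighting shift of 0.6 with 12 subjects is near the edge of
what the design supports — precisely mirroring the original study's
"anecdotal" evidence label at full scale.

## Known limitations

* Two-parameter weighting families (Prelec-2, Gonzalez–Wu) are out of
  scope by design.
* The sampler is a fixed-length HMC, not NUTS; very long ridges mix more
  slowly than an adaptive-trajectory sampler would, which is why the desk
  profile uses generous trajectory lengths.
* Loss-domain fits are supported (`domain = "loss"`) but the shipped
  analyses, like the study's headline results, focus on gains.
* Real-data re-analysis requires the deposited trial table; `read_trials`
  accepts any file matching the documented schema.
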