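---
title: "Rational sequential choice in groups with differing preferences"
author: "ratdecide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational sequential choice in groups with differing preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratdecide)
```

## The model

A group of $N$ agents chooses sequentially between two mutually exclusive
options, A and B.  Agent $k$'s preference is summarized by a utility
difference $U_k$ (positive values favour A).  Utilities are built from a
large number of standardized environmental factors through unit-norm
weight vectors, so that a priori each $U_k$ is standard normal and any
two agents' utilities correlate at $\rho_{k,l}$, the dot product of
their weight vectors.  In an *undifferentiated* population every pair
shares the same correlation $\rho$; the package also supports two
*cryptic subtypes* (below).

No agent observes $U_k$ directly.  Each receives a private estimate
$\hat U_k = U_k + e_k$ with independent Gaussian noise of scale
$\epsilon$, the **habitual environmental noise**: the noise-to-signal
ratio the agent's decision rule is calibrated to.  Jointly,

$$\mathrm{cov}(U_k, U_l) = \mathrm{cov}(\hat U_k, U_l)
  = \rho_{k,l} + \delta_{k,l}(1-\rho_{k,l}), \qquad
  \mathrm{cov}(\hat U_k, \hat U_l)
  = \rho_{k,l} + \delta_{k,l}(1+\epsilon^2-\rho_{k,l}).$$

The first decider chooses A exactly when $\hat U_1 > 0$.  Each later
agent combines its prior, its private estimate, and the ordered choices
it has observed.  Because every choice reveals on which side of a
*critical value* the chooser's private estimate fell, the social
likelihood of a history $C_1 \ldots C_{k-1}$ given $U_k$ is a rectangle
probability of $(\hat U_1, \ldots, \hat U_{k-1})$ under the exact
Gaussian conditional law given $U_k$ — each coordinate bounded above its
own threshold if that agent chose A, below it if B.  The critical value
$\hat U_k^*$ solves

$$E(U_k \mid \hat U_k = \hat U_k^*,\; C_1 \ldots C_{k-1}) = 0,$$

and agent $k$ chooses A exactly when $\hat U_k > \hat U_k^*$ (ties go to
B; a measure-zero convention fixed for determinism).  Because each
agent can reconstruct every predecessor's threshold, the computation is
recursive: thresholds for all prefixes feed the likelihood for the next
agent.  `decision_model()` memoizes this recursion inside the model
object; mirrored histories (A and B swapped) are computed once and
negated, which enforces the model's exact antisymmetry and halves the
work.

All conditional means and covariances are derived mechanically from the
joint covariance above by Schur complement; no displayed special-case
matrix is hard-coded.  In particular the conditional variance of a
predecessor's estimate given $U_k$ is $1+\epsilon^2-\rho^2$, and the
package validates the whole recursion against a generative
rejection-sampling oracle (`mc_posterior_mean()`), level by level: at
every history the posterior mean at the computed threshold is zero
within Monte-Carlo error, where each level's conditioning box uses only
thresholds already validated at lower levels.

## Observation: two distinct probabilities

An external observer records behaviour under an **experimental noise**
$\eta$, which may differ from $\epsilon$ (laboratory conditions remove
much environmental noise; agents keep applying their
$\epsilon$-calibrated thresholds).  Two observer-side quantities must
not be conflated, and the package exposes both:

* `sequence_probability()` / `conditional_choice_probability()` — the
  *generative* law of freely deciding groups: the probability of an
  ordered choice sequence is one multivariate-normal rectangle
  probability under the $\eta$-noise joint, and the conditional
  probability that the next agent chooses A is a ratio of two such
  probabilities.  This is what the Monte-Carlo simulator estimates, and
  what outcome enumeration and consensus are built from.

* `response_probability()` — the focal agent's *social response curve*:
  the probability of choosing A when a history is presented as a
  stimulus (as with replica conspecifics in an experiment), the focal
  estimate being drawn from its marginal $N(0, 1+\eta^2)$:
  $\Phi\!\left(-\hat U^*(h)/\sqrt{1+\eta^2}\right)$.

The two differ whenever $0 < \rho < 1$: in a free group the observed
history also carries information about the correlated utilities, so
even with vanishing thresholds the conditional frequency stays away
from $1/2$ (about $0.40$ after B,B,A at $\rho = 0.5$), while the
response curve returns exactly to $1/2$ as thresholds vanish.  The
response curve's $P = 1/2$ contour is the set where the threshold is
zero and is therefore *exactly* independent of $\eta$.  Figure-style
sweeps (`sweep_conditional()`, `sweep_conflict()`, `sweep_subtypes()`)
report response curves; group-level quantities (`sweep_consensus()`,
`outcome_distribution()`) use the generative law.

### Relative social weighting

For the second decider the posterior weights private information by
$1/\epsilon$ and the first choice by $\rho/\sqrt{1+\epsilon^2-\rho^2}$;
their ratio is the relative social weighting
$\mathrm{RSW} = \rho\epsilon/\sqrt{1+\epsilon^2-\rho^2}$, which is $1$
for identical preferences, $0$ for uncorrelated ones, $\to 0$ as
$\epsilon \to 0$ and $\to \rho$ as $\epsilon \to \infty$.  It organizes
the sweeps: recency-following, majority-following and consensus all
track the RSW far more closely than $\rho$ or $\epsilon$ separately.

### A note on the identical-preferences limit

At $\rho = 1$ the most recent decision is always favoured, at every
noise level — the package tests this ordering property.  Choice
probabilities themselves are only *approximately* noise-invariant
there: with a proper $N(0,1)$ utility prior, the threshold scales
almost, but not exactly, in proportion to the estimate's scale (exact
proportionality would require a scale-free prior), so the response
after a single observed A moves from about $0.65$ to $0.77$ as
$\epsilon$ goes from $0.5$ to $2$.  The acceptance suite states the
idealized exact-invariance claim and reports its failure rather than
hiding it; the same applies to the location of the recency-majority
crossover, which sits at $\mathrm{RSW} \approx 0.71$ for $\rho = 0.9$
(computed by `find_recency_crossover()` and confirmed by the generative
oracle), not at $0.5$.

## Cryptic subtypes

`subtype_decision_model()` draws each agent's type independently: type
$\alpha$ with probability $\gamma$, else $\beta$.  Same-type pairs
correlate at $\rho_{high}$, different-type pairs at $\rho_{low}$.  Types
are *cryptic* — visible only through choices — so every posterior
marginalizes the type sequence $s$ of previous deciders with prior
weight $\gamma^{n_\alpha}(1-\gamma)^{n_\beta}$, using the
type-dependent covariance and, for each putative sequence, the
threshold each predecessor of that type would have used.  Thresholds
are keyed by (own type, observed history): an agent knows its own type,
while earlier types are always marginalized identically, so no deeper
key is needed.  The focal agent's prior over others' types uses the
population frequencies $(\gamma, 1-\gamma)$ regardless of its own type
— types are assigned independently, so knowing one's own type carries
no information about others'.

Two scenario parameterizations recur in the tests: two equally
prevalent types with identical within-type preferences
($\gamma = 0.5$, $\rho_{high} = 1$, $\rho_{low} = 0$), where unanimity
among predecessors produces qualitatively stronger following than any
split history; and a 90/10 population ($\gamma = 0.9$,
$\rho_{high} = 0.9$, $\rho_{low} = 0.25$), where majority-type agents
respond socially like a strongly aligned population and minority-type
agents like a weakly aligned one.

## Numerical choices

* **Rectangle probabilities** (`mvn_rectangle_probability()`):
  dimensions 1–4 use exact deterministic algorithms (closed form, then
  the Miwa recursion with 512–1024 grid steps, absolute error well
  below $10^{-6}$); higher dimensions use Genz–Bretz quasi-Monte-Carlo
  with absolute tolerance $10^{-7}$ under a fixed internal seed, with
  the caller's RNG state saved and restored, so every number in the
  package is bit-reproducible run to run.  Supported dimension is
  about 12; group enumeration is capped at $N = 10$.
* **Posterior expectations**: the prior-times-private factors form a
  conjugate Gaussian envelope $N(\hat u/(1+\epsilon^2),
  \epsilon^2/(1+\epsilon^2))$; posterior moments are 64-node
  Gauss–Hermite sums of the (smooth, bounded) social likelihood against
  that envelope, evaluated once per node.
* **Root finding**: thresholds are roots of the strictly increasing
  posterior mean, bracketed by geometric expansion from $[-1, 1]$
  (failure past $\pm 50$ signals degenerate input) and solved by
  Brent's method to $10^{-8}$ — far below the integration noise that
  dominates downstream probabilities.
* **Degenerate inputs**: non-PSD correlation structures are rejected at
  construction with the violated bound named
  ($\rho \ge -1/(N-1)$ for homogeneous groups; every type-count
  assignment checked for subtype models).  Conditioning on a history
  with probability below $10^{-12}$ raises an error rather than
  returning a ratio of near-zeros.

## The simulator and what passing tests show

`simulate()` draws utilities from the exact multivariate normal prior
(eigendecomposition square root, so singular cases like $\rho = 1$
work), adds independent $\eta$-scale noise — given the utility-level
correlation this reproduces the required joint for the estimates, since
the estimate residuals are independent across agents — and applies the
sequential threshold rule.  `simulate_factor_level()` rebuilds the
covariance from first principles: explicit orthonormal-basis weight
vectors $\alpha_k = \sqrt{\rho}\,a_0 + \sqrt{1-\rho}\,a_k$ over 64
factors, factor-level noise, and an empirical covariance check.

The simulator emulates the model's own idealizations: a single
well-ordered sequence of irrevocable binary choices, homogeneous
sensory noise, common knowledge of $\rho$, $\gamma$ and all thresholds,
and exactly Gaussian factors.  Real groups violate most of these
(simultaneous or repeated choices, heterogeneous and unknown noise,
heuristic rather than fully Bayesian responses), so agreement between
the exact computations and the simulator validates the implementation
against its own generative law — not the model against data.

Default problem sizes in the test suite were chosen to make Monte-Carlo
error bars small relative to the effects tested while keeping the whole
suite desk-scale: groups of 4 (5 for consensus monotonicity, 8 for the
independent-choice consensus value), $10^5$ replicate groups for choice
frequencies, $4\times 10^5$–$10^6$ proposals for rejection-sampled
posterior means with acceptance window half-width $0.05$, and
agreement asserted within three standard errors.

## Known limitations

* Exhaustive outcome enumeration is exponential in $N$ (capped at 10),
  and threshold tables grow as $2^{N-1}$; large-group asymptotics are
  out of scope.
* Exactly two subtypes; no agent-specific sensory noise; no estimation
  of $\rho$, $\epsilon$, $\eta$ from behavioural data.
* Choice revision (iterated agreement dynamics) is not modelled; the
  consensus numbers are for one pass of irrevocable choices and are
  best read as lower bounds on achievable consensus.
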