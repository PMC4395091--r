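---
title: "Modelling sequential binary decisions under social information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sequential binary decisions under social information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesherd)
```

## The model

An agent holds a belief $P[A] \in [0,1]$ that option A — by convention the
correct answer — is true. Observing one peer answer, the agent updates by
Bayes' rule under a symmetric likelihood: a peer's answer agrees with the
agent's hypothesis with probability $c$, the *flexibility*, with
$1/2 \le c < 1$. After an A observation,

$$P[A]_{\text{post}} = \frac{c\,P[A]_{\text{pre}}}
  {c\,P[A]_{\text{pre}} + (1-c)\,(1-P[A]_{\text{pre}})},$$

and symmetrically for a B observation. Because each update multiplies the
odds against A by a constant factor, folding any sequence of observations
gives a closed form that depends only on the counts $(n_A, n_B)$:

$$P[A \mid n_A, n_B] = \frac{1}{1 + p\,s^{\,n_A-n_B}}, \qquad
  p = \frac{1-P_0}{P_0},\quad s = \frac{1-c}{c},$$

where $P_0$ is the initial belief. `iterate_updates()` implements the fold,
`belief_from_counts()` the closed form; the test suite verifies their
equality exhaustively over all label sequences up to length 8. The log-odds
rescaling $z = (n_A-n_B)\ln s + \ln p$ (`z_transform()`) maps every
condition onto the single curve $1/(1+e^z)$, which is the basis of the
per-question collapse diagnostic.

Two consequences matter for inference. First, the belief depends on the
*difference* $n_A - n_B$, not the total $r = n_A + n_B$: adding one A and
one B observation changes nothing. Second, as $r \to \infty$ at a fixed
fraction $x = n_A/r$ the model becomes a step function at $x = 1/2$ —
infinitely many peers are infinitely persuasive.

## The competing families

`model_probability()` evaluates six families; `M6` is the Bayesian model,
the others are quorum-response and interpolation forms proposed elsewhere in
the collective-behaviour literature:

| family | $P[A\mid n_A,n_B]$ | parameters |
|---|---|---|
| M1 | $\delta^{n_A}/(\delta^{n_A}+\delta^{n_B})$ | $\delta>0$ |
| M2 | $(\delta+n_A)^\epsilon/[(\delta+n_A)^\epsilon+(\delta+n_B)^\epsilon]$ | $\delta>0,\ \epsilon>0$ |
| M3 | $(\delta+\epsilon n_A)/[1+\epsilon(n_A+n_B)]$ | $0\le\delta\le 1,\ \epsilon\ge 0$ |
| M4 | $1/2+\delta(n_A-n_B)/(n_A+n_B+\epsilon)$ | $\delta\ge 0,\ \epsilon\ge 0$ |
| M5 | $[1+(1+\delta\epsilon^{-n_A})/(1+\delta\epsilon^{-n_B})]^{-1}$ | $\delta\ge 0,\ \epsilon>1$ |
| M6 | $(1+p\,s^{n_A-n_B})^{-1}$ | $p>0,\ 0<s\le 1$ |

M1 is exactly M6 with an unbiased prior: $M1(\delta) = M6(p=1, s=1/\delta)$.
The admissible domains above are a package design choice — the source
formulas are published without them — selected as the smallest boxes that
contain the published fitted values while keeping outputs in $[0,1]$.
Within its box M3 cannot leave $[0,1]$; M4 can (e.g. $\delta=1,
\epsilon=0$ at $(5,0)$), and such evaluations *raise an error rather than
clamp*, so that a grid search can never quietly exploit an invalid corner of
parameter space.

Their large-group limits (`asymptotic_limit()`) differ qualitatively — step
function (M1, M6), $x^\epsilon/[x^\epsilon+(1-x)^\epsilon]$ (M2, Weber's law
at $\epsilon = 1$), $x$ (M3), $1/2+\delta(2x-1)$ (M4), constant $1/2$ (M5) —
which is why data at large $r$ would discriminate between them. The tests
confirm each finite-$r$ evaluation approaches its limit (within 0.02 at
$r = 500$ for M2–M5, within $10^{-6}$ of the step at $r = 200$ for M6).

## The simulated protocols

`protocol_config()` encodes two sequential answering protocols. In both, a
question passes through rounds of increasing information condition $r$:
round one is private ($r = 0$, answer drawn from $P_0$); in the round with
finite $r \ge 1$, subjects labelled $1..r$ have left the question, and each
remaining subject $i$, in ascending label order, tallies the most recent
answers of subjects $i-1, \dots, i-r$ and answers A with probability
`belief_from_counts(p_q, s_q, n_A, n_B)`. "Most recent" means the answer
already given *in the current round* when the predecessor has answered this
round, else the last recorded one — a departed subject's answer stays
visible, frozen ("quenched") at its final value. In the last round
($r = \infty$) the remaining subjects see all of their predecessors.

The `D1` style has 31 subjects, 100 questions, rounds
$r = 0, 1, 2, 3, 5, 7, 9, \infty$ and fixed labels; the `D2` style has 52
subjects, 120 questions, rounds $r = 0, 1, 5, 11, 21, \infty$ and labels
reshuffled every question. Three mechanics are design choices where the
protocol descriptions leave gaps:

* **Leave rule.** Every documented departure fits "subjects $1..r$ have left
  before the finite-$r$ round", so that rule is applied generally — to the
  larger D2 conditions as well, where participation mechanics are not
  described — and nobody further leaves before the $r=\infty$ round. This
  uniformity is an approximation for D2.
* **No cross-round memory.** An agent's answer in a round depends only on
  the currently displayed $(n_A, n_B)$ and the question's $(p_q, s_q)$ — the
  belief is recomputed, not accumulated across rounds. This is precisely the
  quantity the fitting stage models; conditioning on one's own earlier
  answers is a real-data feature deliberately not simulated.
* **Participation.** Full participation by default; an optional per-answer
  non-response probability models time-outs, in which case observed counts
  can fall below $r$.

The default ground-truth sampler draws $\ln p_q \sim N(\ln 0.8,\,0.8^2)$
truncated to $[0.05, 20]$ and $s_q \sim U(0.4, 1)$, independently: most
questions start better than a coin flip, a sizeable minority worse, and
social responsiveness varies but never reverses ($s \le 1$). These ranges
emulate the spread of per-question estimates seen in real quiz data without
being tied to any specific data set.

What simulated data do *not* contain: individual differences in flexibility
(all agents share the question's $s_q$), history effects, biased label
sampling, incentives. Passing tests on synthetic data therefore demonstrate
the correctness and self-consistency of the pipeline — the generative model,
aggregation and fitting agree with each other — not that human data follow
the model.

## Aggregation

`aggregate_conditions()` collapses records to conditions $(n_A, n_B)$,
counting answers $R$ and correct answers $N_A$. Defaults, configurable:
$r=0$ records are *included* (the $(0,0)$ condition is what identifies $p$),
sentinel-round records are included under their literal observed counts, and
no minimum-count filter is applied (`min_R = 1`). `weber_table()` instead
groups by finite $r$ and the exact fraction $x = n_A/(n_A+n_B)$; sentinel
records are excluded there by default because their effective $r$ varies
with the subject's label.

## Fitting

`grid_fit()` is exhaustive sampling on a parameter lattice. The fit error is

$$\mathrm{RMSE} = \sqrt{\tfrac1K \sum_{\text{conditions}}
  \left(P_{\text{model}} - N_A/R\right)^2},$$

*unweighted* over the $K$ populated conditions. The error description this
implements ("total square distance summed over the available pairs") does
not say whether the mean divides by conditions or by responses; the
unweighted form matches the minimiser of the plain sum over conditions, and
count-weighting is available via `weight_by_R = TRUE` for sensitivity
analysis.

Default grids: `p` log-spaced, 241 points on $[0.05, 20]$ (log-symmetric, so
$p = 1$ and every reciprocal pair are lattice points; step ratio about
2.5%), `s` linear with step 0.005 on $[0.005, 1]$; M1 shares the log grid
for $\delta$; M2–M5 use $100 \times 100$ lattices inside their admissible
boxes. Ties are broken deterministically (smallest second parameter, then
smallest first). Inadmissible lattice points are skipped; an all-inadmissible
grid is an error. An optional single refinement pass (`refine = TRUE`)
re-searches a factor-10 finer lattice around the coarse minimum and is
guaranteed never to increase the minimum; it is off by default so that
results come from one exhaustive pass.

`fit_all_models()` augments M6's lattice with the reciprocal images of M1's
$\delta$ lattice, so the nesting inequality (best M6 error $\le$ best M1
error) holds by construction whenever M1's best $\delta \ge 1$, and verifies
it after fitting. `per_question_fit()` requires at least 3 populated
conditions per question (two parameters plus one residual degree of
freedom); sparser questions are flagged unfit rather than fitted.
`weber_slopes()` regresses fraction-correct on $x$ per $r$ by unweighted
ordinary least squares (weighting optional), omitting groups with fewer than
two distinct $x$ bins.

## Numerical choices

All belief evaluations go through the log-odds form
$1/(1+e^z)$ via `plogis`, so $s^{n_A-n_B}$ never overflows even at count
differences in the thousands; where the naive product is finite the two
agree to machine precision. Degenerate priors (0 or 1) are absorbing fixed
points of the update. Empty record sets aggregate to empty tables, while
empty condition tables are a fitting error.

## Problem sizes used in the checks

The test suite exercises the pipeline at sizes chosen to make the
statistical checks sharp at desk scale: exhaustive update/closed-form
equivalence to sequence length 8; six-family noiseless self-fits on
conditions with $n_A+n_B \le 6$; generative-frequency checks on 150
simulated questions; pooled stochastic recovery on a 200-question
fixed-truth D1-style simulation with a 100-resample question-level
bootstrap, whose 95% percentile interval is required to cover the
generating $(p, s)$.

## Known limitations

* The simulator's leave rule for the label-shuffled protocol is an
  extrapolation of the fixed-label protocol's documented departures.
* Per-question fits on realistic per-question sample sizes are noisy, and
  `p` is less well identified than `s` (the error surface is flat along
  `p`); the z-collapse diagnostic reflects that scatter.
* Grid search reports lattice points: estimates inherit the lattice
  resolution, and bootstrap intervals are unions of lattice values.
* RMSE comparison is descriptive, not inferential — no likelihoods, no
  information criteria, no formal model-selection uncertainty.
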