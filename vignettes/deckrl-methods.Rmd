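---
title: "Models and methods behind deckrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deckrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deckrl)
```

## The tasks

The Iowa Gambling Task (IGT) and the Soochow Gambling Task (SGT) are
experience-based risky decision-making tasks: on each of 120 trials a
participant draws a card from one of four decks (A--D) and receives a payoff.
In the IGT, decks A and B pay $1.00 per trial and decks C and D $0.50, with
losses added on 5 of every 10 trials (decks A, C) or 1 of every 10 (decks B,
D), calibrated so that A and B net $-2.50$ and C and D $+2.50$ per 10 trials.
The SGT keeps the same expected values but makes every card a pure gain or a
pure loss in 5-trial blocks, decoupling gain--loss *frequency* from expected
value: its good decks (C, D) lose on 4 of 5 trials.

`igt_schedule()` and `sgt_schedule()` encode these payoff tables exactly;
`validate_schedule()` re-derives the structural invariants (loss counts,
pure-outcome property, per-10-trial expected values) from the stored table
rather than trusting it. A `deck_dealer()` deals each block as an exact
uniform permutation of the printed block, drawn from a private RNG stream, so
per-deck totals over complete blocks are deterministic: the variance of a
simulated deck's long-run net payoff is exactly zero, which is stronger than
real card shuffling needs to be but matches the tasks' design. Where the task
description says only that within-block positions are "randomized", we chose
independent uniform permutations per deck per block. Decks never run out. The
starting balance of $20.00 is carried in simulated sessions as bookkeeping
only; no model consumes it.

## The model space

Eighteen cognitive models arise factorially from three utility functions,
three expectancy-updating rules, and two choice rules. Writing $win(t)$ and
$loss(t)$ for the trial-$t$ gain and loss magnitude:

**Utility.** The weighted expected-utility function
$u(t) = (1-W)\,win(t) - W\,loss(t)$ with attention weight $W \in [0,1]$
(`utility_eu()`); the prospect utility of the net payoff
$x(t) = win(t) - loss(t)$,
$u(t) = x^\alpha$ for $x \ge 0$ and $-\lambda |x|^\alpha$ otherwise
(`utility_pu()`); and a prospect utility that evaluates gains and losses
separately before aggregating,
$u(t) = win(t)^\alpha - \gamma\, loss(t)^\alpha$ (`utility_pu2()`). The last
combines the separate-evaluation feature of the first with the curvature and
loss aversion of the second: an outcome with equal gain and loss need not
feel neutral. At $\alpha = 0$ both prospect forms become step functions; we
take the $x = 0$ corner on the nonnegative branch ($0^\alpha = 0$ for
$\alpha > 0$, $= 1$ at $\alpha = 0$), reading the branch condition as
$x \ge 0$.

**Updating.** With $\delta_j(t)$ the indicator of the chosen deck, the delta
rule $E_j(t) = E_j(t-1) + A\,\delta_j(t)[u(t) - E_j(t-1)]$
(`update_delta()`); the decay-reinforcement rule
$E_j(t) = A\,E_j(t-1) + \delta_j(t)\,u(t)$ (`update_drl()`), under which
unchosen decks decay and the chosen deck's new expectancy can exceed both its
old value and $u$ (with $A = 0.9$, $E = 10$, $u = 5$: $E' = 14$); and a mixed
rule $E_j(t) = (1-D)E_j(t-1) + A\,\delta_j(t)[u(t) - (1-D)E_j(t-1)]$
(`update_mixed()`) that decays everything by $(1-D)$ and then takes a delta
step. The mixed rule nests the delta rule exactly at $D = 0$; this identity
is enforced by tests and underwrites the nested-model dominance property
(the mixed fit can never be worse than the delta fit beyond optimizer
tolerance). Expectancies start at $E_j(0) = 0$ for all decks, which makes
the first prediction uniform; the EVL/PVL literature the models come from
does the same.

**Choice.** Softmax over $\theta \cdot E_j$ (`choice_probabilities()`), with
either trial-dependent sensitivity $\theta(t) = (t/10)^c$
(`sensitivity_tdc()`) or trial-independent $\theta = 3^c - 1$
(`sensitivity_tic()`). At $c = 0$ the trial-independent rule gives
$\theta = 0$: choices are uniformly random no matter the expectancies.

Presets: EVL = EU + delta + trial-dependent; PVL = PU + decay-reinforcement +
trial-independent; PVL2 = PU2 + decay-reinforcement + trial-independent.
PVL2 has four free parameters ($\alpha$, $\gamma$, $A$, $c$).

### Parameter bounds

$W$, $A$, $D$, $\alpha$ live in $[0,1]$ by construction. The literature
states no upper bounds for the loss-aversion multipliers or the consistency
parameter; we fix $\lambda, \gamma \in [0, 10]$ and $c \in [0, 5]$ for the
trial-independent rule ($\theta$ up to $242$, effectively deterministic
choice) and $c \in [-5, 5]$ for the trial-dependent rule, whose sensitivity
may legitimately *decrease* over trials. These are package choices, wide
enough that fitted values rarely touch them on data the models can describe.

## Numerical choices

**Softmax stability.** Decay-reinforcement expectancies are unbounded, so
$\theta E_j$ can be astronomically large. All softmax computations subtract
the maximum and floor shifted exponent arguments at $-700$ (just above the
double-precision underflow of $e^x$), which keeps every probability strictly
positive and every log-likelihood finite. The floor is part of the model's
computational definition here: the independent reference recursion in the
test suite applies the same convention, and the two agree to $10^{-10}$.

**Likelihood.** `one_step_ahead_loglik()` implements the one-step-ahead
criterion: the log-probability of each observed choice on trials $2..T$
given everything up to the previous trial; trial 1 contributes no term
(nothing has been learned yet). The recursion is compiled (C++ via Rcpp), at
about 20 microseconds per 120-trial evaluation, which is what makes
multi-start fitting of whole cohorts interactive. For the trial-dependent
rule, $\theta$ for the prediction of trial $t+1$ is evaluated at the
predicted trial's index $t+1$; the alternative convention (index $t$) is
exposed as `tdc_index = "current"` because the equations' indexing is
genuinely ambiguous on this point.

**Fitting.** `fit_model()` spreads `n_starts` (default 50) Latin-hypercube
points over the parameter box, evaluates the likelihood at each, and refines
the best `n_refine` (default 5) by Nelder--Mead simplex on a logistic
reparameterization of the box (so the simplex is unconstrained and no
penalty terms contaminate the likelihood). Function tolerance is $10^{-8}$,
iteration cap $500 \times k$ for $k$ parameters; the best point over all
starts and refinements is returned, so the fitted log-likelihood can never
fall below the best start. The logistic map cannot represent a bound
exactly; degenerate data (e.g. one deck chosen always) drive estimates
toward, not onto, a bound, which is the behaviour we want reported. Fits
are deterministic given the configuration seed.

**Baseline and BIC.** The baseline model chooses decks independently with
constant probabilities (3 free parameters). Its MLE is closed-form —
empirical proportions over the *predicted* trials $2..T$ — so both
likelihoods condition on exactly the same 119 observations; a test verifies
the closed form against an independent simplex optimization of the
multinomial likelihood. The BIC difference score is
$2(\widehat{LL}_M - \widehat{LL}_{Base}) - k \ln n$ with $k$ the extra
parameters and $n = T - 1 = 119$ by default (the number of predicted data
points; `n_convention = "all"` switches to $T$, since sources are not
explicit about this convention). Positive scores favour the cognitive model.
In `summarize_bic()`, the "% (BIC > 0)" column counts *strictly* positive
scores; sample SD uses the $n-1$ denominator and is `NA` for a single score.

**Consistency test.** `spearman_consistency()` computes Spearman's $\rho$
on average ranks with a one-tailed p-value for $\rho > 0$ from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. We use
Spearman unconditionally (no normality-test gating). An exact permutation
p-value is available for $n \le 8$ — full enumeration beyond that costs more
than the approximation is worth, and the approximation is what the analysis
uses at cohort sizes anyway.

## What the synthetic agents emulate — and what they do not

`simulate_agent()` runs any of the 18 models generatively on the exact task
schedules, and `generate_cohort()` gives every synthetic participant one
parameter vector used for *both* tasks — the cross-task consistency
assumption (parameters measure stable characteristics of a person) built
into the data-generating process, so the downstream Spearman analysis has a
known positive signal to find. The default parameter sampler is uniform
within bounds except for $c$, drawn from $[0.5, 3]$: near $c = 0$ an agent
is noise and near the upper bound it is deterministic, and both extremes
make parameters unidentifiable for reasons that have nothing to do with the
estimator. Per-agent, per-task seeds derive from the master seed by a fixed
integer scheme, so cohorts are bit-reproducible.

Synthetic agents are exactly the model class being fitted. Passing recovery
and identification tests therefore demonstrates that the pipeline is
correct and the models identifiable *under their own assumptions* — it says
nothing about whether human choices follow these equations. Real
participants perseverate, alternate after losses in frequency-sensitive
ways (a known issue specifically for SGT data), and drift over a session;
none of that is in the generator, deliberately. Group structure (e.g.
clinical vs control labels) is supported in summaries as an arbitrary
grouping column, with no clinical semantics.

## Problem sizes used in the shipped checks

The test suite exercises: oracle agreement on 100 random
model-parameter-sequence triples; the PU/PU2 fit identity on SGT sequences
across all six updating-choice combinations; self-recovery on a 50-agent
PVL2 cohort (120 trials per task, 15 starts per fit, both tasks), requiring
every generating-vs-recovered and every cross-task rank correlation to be
positive; and model identification on a 53-agent PVL2 cohort, requiring
PVL2 to beat EVL in pairwise BIC wins for a majority of agents in each
task. These sizes mirror the study design (120 trials, 53 participants)
while keeping a full run around half a minute.

## Known limitations

- Perseveration terms and hierarchical/Bayesian estimation are out of
  scope; the package fits individuals independently by maximum likelihood.
- The logistic reparameterization reports near-bound rather than on-bound
  estimates for degenerate data.
- The exact permutation option of the consistency test stops at $n = 8$.
- On SGT data the PU and PU2 models are the same likelihood surface (single
  outcomes make the two prospect utilities coincide with $\lambda =
  \gamma$); their identical fits there are a property, not a bug.
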