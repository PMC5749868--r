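---
title: "How many spacers should a CRISPR array carry?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many spacers should a CRISPR array carry?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispropt)
```

## The question and the model

A prokaryote with an active CRISPR-Cas system holds an array of spacers, each
remembering a previously encountered virus. Two forces pull the useful array
size in opposite directions. More spacers hedge against protospacer mutation:
a virus escapes only if *every* targeted protospacer has mutated. But the
cell's effector complexes are limited in number, and crRNA abundance decays
along the array, so every extra spacer dilutes the effectors armed with the
youngest — least-mutated, hence most useful — spacers. `crispropt` quantifies
this trade-off and finds the array size and crRNA decay that maximize the
cell's survival probability.

The model is a chain of closed forms:

1. **Effector allocation.** Spacers are indexed by age, youngest first. With
   total effector count $C$ and crRNA decay coefficient $\delta \in (0,1]$,
   spacer $i$ charges $C_i = C\,\delta^{i-1}(1-\delta)/(1-\delta^S)$
   complexes (`effector_allocation()`); $\delta = 1$ is the uniform limit
   $C_i = C/S$, handled analytically rather than by perturbation.
2. **Occupancy.** Binding/dissociation kinetics give the steady-state
   probability that protospacer $i$ is occupied,
   $B_i = [1 + (1/\beta)\,\delta^{1-i}(1-\delta^S)/(1-\delta)]^{-1}$, where
   $\beta = C k^{+}/k^{-}$ is the dimensionless binding efficiency. A
   single-spacer array has $B = 1/(1+1/\beta)$ regardless of $\delta$ —
   exactly $1/2$ at $\beta = 1$.
3. **Interference.** Bound effectors degrade viral DNA at rate $a$ during an
   interference window $\tau$ (roughly the first round of viral replication);
   with $\chi = \tau a$, interference succeeds with probability
   $I = 1 - \exp(-\chi \sum_i B_i)$.
4. **Mutation.** Under periodic spacer acquisition the protospacer matching
   spacer $i$ stays recognizable with probability $m_i = \mu^{i-1/2}$,
   assessed mid-interval; a custom $m$ vector models conserved protospacers.
5. **Survival.** Infections arrive as a Poisson process with mean $rNt$; the
   cell survives with probability
   $E = \exp[-rNt \prod_{i=1}^{S} (1 - m_i(1 - e^{-\chi B_i}))]$.

The factor inside the product is the chance that the $i$-th spacer fails
against a random virion; the product is the chance the whole array fails. An
independent route to the same number enumerates all $2^S$ mutation variants
of the virus explicitly (`survival_by_variant_enumeration()`); the test suite
holds the two routes together to $10^{-10}$ over randomized parameter sets,
which is the package's primary correctness oracle.

On the interference ceiling: a formula for the maximal interference
probability that places the age exponent on $1-\mu$ circulates in print. That
reading contradicts its own definition — the probability that at least one
targeted protospacer is intact — under the $m_i = \mu^{i-1/2}$ schedule, so
`max_interference()` implements $1 - \prod_i (1 - \mu^{i-1/2})$, the form the
definition dictates. Likewise, the explicit four-variant expansion of the
two-spacer survival is sometimes typeset with a minus sign on the
doubly-mutated term; the factorized form fixes the sign as positive (the
escape probability of the doubly-mutated variant is 1) and that is what the
enumeration implements.

## Multiple viral species

With $\nu$ species at fractions $v_j$, an array is described by which species
each age position targets. Given an assignment, the per-infection escape
probability splits over species,
$\sum_j v_j \prod_{i \in S_j} (1 - m_i(1 - e^{-\chi B_i}))$, with an
untargeted species always escaping. Two conventions matter and both follow
the global age index: $B_i$ is computed from the *full* array (effector
dilution does not care which species a spacer targets), and $m_i$ keeps its
$\mu^{i-1/2}$ schedule even when acquisitions from different species
interleave — the model states no alternative ordering, so the literal global
index is used.

Spacers are acquired independently, each from species $j$ with probability
$v_j$, so an assignment has probability $\prod_k v_{a_k}$ and the pool-level
performance is the weighted average over all $\nu^S$ assignments.
`average_survival()` enumerates them exactly when $\nu^S$ fits under the
plan's cap and otherwise samples assignments position-wise from $v$ — drawing
from the acquisition distribution itself, so the estimator is the plain
sample mean, reported with its standard error. A pool with a single species
reduces identically (not just approximately) to the single-virus formula.

## Optimization and numerical choices

`survival_surface()` evaluates $E$ on the full $(S,\delta)$ grid and takes
the argmax. Choices a user should know:

- **Default grid.** $S \in 1..30$, $\delta \in \{0.01, \dots, 0.99\}$ in
  steps of $0.01$ plus the $\delta = 1$ limit point. This resolves the
  reference optimum ($S_{\rm opt} = 6$, $\delta_{\rm opt} \approx 0.7$ at
  $\beta = 1$, $\chi = 1.4$, $\mu = 0.9$, $rNt = 5$) at the grid's own
  resolution; $\delta$-optima are only ever meaningful to $\pm$ one grid
  step.
- **Tie-breaking.** Ties at the maximum go to the smallest $S$, then the
  smallest $\delta$ — deterministic, and biased toward cheaper arrays. (A
  fully mutating virus, $\mu = 0$, makes the surface exactly flat; the
  reported optimum is then the grid origin by this rule.)
- **rNt-invariance.** $E = \exp(-rNt\,g(S,\delta))$ with $g$ free of $rNt$,
  so the argmax cannot depend on the infection load; the tests assert this
  rather than assume it.
- **Exact/Monte-Carlo switch.** For multi-virus surfaces the default plan
  enumerates cells with $\nu^S \le 2^{14}$ and samples 20&nbsp;000
  assignments per cell above that; the stand-alone `averaging_plan()` default
  cap is $2^{20}$, which is comfortable for a single cell but not for a
  $30 \times 100$ surface. Requesting exact mode above the cap is a hard
  capacity error, never a silent fallback.
- **Seeding.** Monte-Carlo cells draw their seed as `plan$seed + row counter`
  so any cell is reproducible in isolation. The assignment draw is made once
  per $S$ and reused across $\delta$ (the assignment distribution depends
  only on $S$ and the pool): these common random numbers make the
  $\delta$-profile smooth at fixed $S$ and the argmax far less noise
  sensitive, at no cost in bias.
- **Underflow.** Failure products are taken in log space for $S > 50$; every
  factor is bounded below by $e^{-\chi B_i} > 0$, so the logarithm is always
  defined.
- **Degenerate inputs.** $\delta = 0$ is rejected (only the first spacer
  would exist); zero-fraction species are rejected at `viral_pool()`
  construction — drop them instead, the survival is continuous in a
  vanishing fraction.

Parameter defaults and units, all dimensionless: $\beta > 0$ (binding
efficiency; 1 means a lone spacer occupies its target half the time),
$\chi \ge 0$ (interference efficiency; the working value 1.4 is
`calibrate_chi()` applied to a measured single-spacer interference
probability of 0.5 at assumed $\beta = 1$, giving $2\ln 2 \approx 1.386$),
$\mu \in [0,1]$ (per-acquisition-interval non-mutation probability; 0.9 is
the reference), and $rNt \ge 0$ (expected infections over the observation
window; 5 is the reference). $\beta$ and $\chi$ cannot be identified
separately from one interference measurement, which is why the calibration
takes $\beta$ as an assumption.

`burst_optimal_array()` covers the altruistic objective: minimizing the viral
burst released by a doomed cell is the same optimization with
$\chi' = \nu_{\rm repl}\,\chi$, where $\nu_{\rm repl} \approx 6\!-\!7$ is the
number of viral replications in an unprotected cell. The rescaled efficiency
shifts the optimum to slightly larger arrays ($S_{\rm opt} = 9$ at
$\nu_{\rm repl} = 7$ versus 6 for survival, reference parameters).

## What the fixture generator emulates — and what it does not

`generate_fixtures()` draws randomized scenarios for property testing:
$\beta$ log-uniform on $[0.1, 10]$ (weak to near-saturated binding), $\chi$
uniform on $[0.1, 5]$, $\mu$ on $[0.3, 0.99]$, $rNt$ on $[1, 20]$, arrays of
up to 12 spacers, and pools of 1–3 species with Dirichlet(1) fractions.
These spans bracket the calibrated working point rather than any measured
distribution of natural systems. Passing tests therefore demonstrate internal
consistency of the closed forms, the enumeration, and the estimators across
the physically sensible parameter box — not that real arrays sit at the
predicted optimum. Real data would also break several idealizations the
model states up front: static array composition over the observation window,
single-copy infection, constant Cas levels, equal per-protospacer mutation
rates, and no primed adaptation (its first-order effect is an increase in
effective $\mu$).

## Problem sizes used by the test suite

The suite runs the default $30 \times 100$ grid for the single-virus
reference optimum, coarser $15 \times 20$ or $20 \times 20$ grids for
multi-virus trend checks (with 20&nbsp;000 Monte-Carlo samples per sampled
cell), 200 randomized parameter sets for the enumeration-versus-closed-form
oracle, and $2 \times 10^5$ samples for the exact-versus-Monte-Carlo
agreement checks. These sizes resolve every claimed effect well beyond its
noise level; the trends they probe are monotone over whole parameter ranges,
so finer grids change the reported optima by at most one grid step.

## Known limitations

- The $\delta$-optimum is reported at grid resolution; no continuous
  refinement is attempted.
- Monte-Carlo surfaces estimate the argmax from noisy cells; with the default
  sample size the induced uncertainty is invisible at the reported grid
  resolution, but pathological flat surfaces will tie-break on noise rather
  than on the documented rule.
- The multi-species model assumes uncorrelated acquisition (no primed
  adaptation) and a static pool; the burst objective implements only the
  stated $\chi' = \nu_{\rm repl}\chi$ rescaling.
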