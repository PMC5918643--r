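---
title: "A hybrid fuzzy agent-based / system-dynamics model of intervention implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid fuzzy agent-based / system-dynamics model of intervention implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyhybrid)
library(dplyr)
```

## The modelling problem

Community health interventions — building safe outdoor activity spaces,
bringing stores that serve healthy food into a neighbourhood — are implemented
by an institution that allocates a finite fund, but their success is judged by
a heterogeneous population whose members *perceive* the same objective
capacity very differently. `fuzzyhybrid` couples these two levels:

* **Micro level (agent-based).** Each agent perceives each intervention
  outcome through a *linguistic variable* with three terms (Low, Medium,
  High). The terms are triangular membership functions over the base
  variable's universe, defined by agent-specific constants `0 < b < c < d`:
  Low is 1 on `[0, b]` and falls to 0 at `c`; Medium peaks at `c`; High is 1
  from `d` upward. The three terms share their breakpoints, so the degrees
  always sum to 1 (a partition of unity) — a property the test suite checks to
  `1e-12` over random values and constants.

* **Macro level (system dynamics).** The institution maintains two capacity
  stocks, COASF ("capacity of safe outdoor activity space and facilities",
  `s1`) and CSSHF ("capacity of stores serving healthy food", `s2`). Each
  stock is filled by an investment inflow and drained by capacity decay with
  lifetime `d1`, `d2`. A fixed initial fund `C` is spent at rate
  `omega(t) = z_COG * rho(t) / d3`, where `rho` is the remaining fund, `d3`
  an investment delay, and `z_COG` the defuzzified output of a Mamdani
  controller that reads the institution's own fuzzified perception of the two
  stocks through a nine-rule base (all 3 x 3 antecedent pairs).

* **Coupling.** Agents perceive the current stocks as their base values;
  peer interactions then adjust the Low-term memberships; agents are binned by
  Low membership, and the unmet-need ("discrepancy") signal per variable sets
  the next stage's allocation split `p` / `1 - p` between the two stocks.

## Membership dynamics along known paths

Before trusting the simulator, the membership dynamics can be studied in
closed form for two analytic base-variable paths: linear decay
`f(t) = -alpha*t + beta` and exponential decay `g(t) = exp(beta - alpha*t)`.
For a decreasing path that crosses `d`, `c`, `b` at times `t1 < t2 < t3`,
the Low degree ramps up on `[t2, t3]` and saturates at 1; High does the
mirror image early on — Low and High exchange their relative location over
time, which is exactly what makes clustering agents by membership values a
moving target.

```{r}
spec <- trajectory_spec("linear", alpha = 1, beta = 10, t4 = 9.5)
params <- term_params(2, 5, 8)
trajectory_breakpoints(spec, params)
derivative_signs(spec, params, "low", c(5.5, 7.5))
```

Along the linear path every active branch is affine (zero second
derivative); along the exponential path the surviving exponential makes the
Low ramp concave down and the High descent concave up. `derivative_signs()`
reports these signs analytically, and the tests confirm them against central
finite differences of `membership_trajectory()` at 100 interior points per
regime. `membership_trajectory()` itself is tested to be *identical* (to
`1e-12`) to evaluating `fz_membership()` on `base_value()` — the closed forms
are re-derivations, so this equality is the core oracle for the simulator's
membership dynamics: inside the engine, a freely decaying stock follows a
discrete exponential, and the agent memberships along it reproduce the
closed-form trajectory to `1e-9` (see `test-engine.R`).

## Peer effects

Each time unit an agent contacts `k` others (default 3, capped at 5), either
uniformly at random or along a fixed scale-free network whose degree
distribution targets `P(k) ~ k^-q` with `2 < q < 3` (configuration model on a
truncated power-law degree sequence, collapsed to a simple graph; the tests
recover the exponent from the generated graph by maximum likelihood). Only
the Low term is socially updated — resources target the worst-off — under one
of three rules applied pairwise:

* **pessimistic** — both take the minimum;
* **optimistic** — both take the maximum;
* **realistic** — each takes a convex combination weighted by the pair's `b`
  constants, `omega_i = b_r / (b_i + b_r)`, so the agent with smaller
  constants (the more intervention-sensitive one) defers more to its peer.
  The weight convention is the simplest one satisfying the required
  inequality `phi_i < omega_i` iff `b_r > b_i`, is symmetric, and reduces to
  equal weights for equal constants; each side of a pair derives its weights
  from its own perspective.

Pairs are processed **sequentially in randomized order** within a round
(later pairs see earlier updates), matching the update equations that
reference already-updated values; the order is reproducible under the run
seed. The pessimistic rule is per-agent nonincreasing and preserves the
population minimum; the optimistic rule is its dual; the realistic rule never
widens the population range. The acceptance suite verifies all three over
every ordering of a five-pair contact list.

The socially updated Low value lives in a shadow column
(`mu_low_social`) next to the geometry-derived memberships. At the next
perception step the shadow value is **replaced** by the fresh geometric
value: interventions re-determine perceptions each period, and peer influence
acts within the period. Persistent social memory would be a plausible
alternative semantics; it is deliberately not the default and would change
how quickly the population homogenizes.

## Clustering and feedback

After the interactions, each (agent, variable) pair is binned by its Low
membership into the intervals `0, (0, 0.1], ..., (0.9, 1.0]` — bin 0 means
"no resources needed". Zero is detected with an absolute tolerance of
`1e-12` so round-off cannot create spurious demand. The discrepancy signal
is deliberately simple: `need_j` is the mean Low membership over the agents
outside bin 0 for variable `j` (monotone in unmet need, bounded in `[0, 1]`),
and the next stage's allocation fraction is the normalized relative need
`p = need_1 / (need_1 + need_2)`, falling back to the configured default when
nobody needs resources. Resources are not yet scaled by bin depth within a
variable; the binning is retained in the traces so a depth-weighted variant
can be layered on.

## The institutional controller

The Mamdani controller uses the canonical operator set: min-conjunction for
the rule antecedents, min (clipping) implication, max aggregation, and
centre-of-gravity defuzzification `z_COG = integral(z mu) / integral(mu)` on
a 1,001-point grid over the impact universe `[0, 1]` (trapezoidal rule). The
consequent term shapes are a symmetric partition-of-unity cover of `[0, 1]`:
Low = triangle(0, 0, 0.5), Medium = triangle(0, 0.5, 1),
High = triangle(0.5, 1, 1), giving analytic pure-term centroids 1/6, 1/2,
5/6 that the numeric COG matches to `1e-4` at 1,001 points and `1e-6` at
100,001. If no rule fires the COG ratio is 0/0; the controller then reuses
the previous defuzzified value (0 at the start of a run) and warns — with a
complete rule base this can only happen for degenerate term shapes.

The stocks integrate by explicit Euler with default `dt = 1/16` time unit,
guarded by `dt <= min(d1, d2, d3)/4` so the decay terms cannot overshoot.
For frozen controller output the fund ODE has the exact solution
`rho(t) = C * exp(-z t / d3)`; the Euler error at `t = 50` halves when `dt`
halves (first order), and the running invariants
`rho + invested = C` (fund conservation) and the per-stock mass balance hold
to `1e-9` over 50-unit runs. Perception of the stocks is instantaneous: the
delay `d3` already enters the outflow equation, and adding a perception
smoother on top would double-count it.

## The staged loop

A run proceeds in stages of `tau_len` time units. Within each time unit,
the three dynamics keep their fixed order:

1. the SD model integrates one time unit in `dt` sub-steps, re-evaluating
   the controller each sub-step from the perceived stocks;
2. agents perceive the updated stocks (intervention impact);
3. one interaction round runs over freshly drawn contact pairs.

At stage end, agents are clustered, and the discrepancy signal both sets the
next stage's allocation fraction (when `adaptive_p` is on; the feedback is
stage-lagged by construction) and decides termination: the run stops once the
homogenized fraction — the share of (agent, variable) pairs in bin 0 —
reaches the configured threshold, or when the stage budget runs out. Agent
dynamics live on the integer time-unit clock; the SD sub-step grid is purely
an integration detail.

```{r}
sim <- run_simulation(demo_config("small", seed = 1))
glance(sim)
tidy(sim)
```

## What the scenario generator emulates — and what it does not

`demo_config("small")` is the default study condition used throughout the
tests: 50 agents, two linguistic variables with constants drawn from
`N(2, 0.3^2)`, `N(5, 0.3^2)`, `N(8, 0.3^2)`, both stocks starting at 0 (every
agent fully Low — maximal need), random contacts with `k = 3`, the realistic
interaction rule, and an institution with `C = 200`, `d1 = d2 = 20`,
`d3 = 5`, `dt = 1/16`, 5 time units per stage, 3 stages. The fund was sized
once, at design time, so that built capacity can exceed the agents' upper Low
breakpoints (`c` constants around 5) within the fund's lifetime — with these
lifetimes and delay the stocks comfortably clear that level during the first
stages, so homogenization is expected early for most seeds, and the
acceptance suite checks exactly that across 20 seeds (allowing up to 10
stages). `large` scales the same shape to 1,000 agents with wider
heterogeneity (`sd = 0.5`), a larger fund, and longer stages, producing the
characteristic growth-then-saturation capacity curves with heterogeneous
membership fans.

Synthetic populations emulate heterogeneous perception thresholds and densely
mixing or hub-dominated contact structures. They do **not** emulate: real
survey-calibrated membership constants; correlation between an agent's
constants across variables; assortative or spatially structured mixing;
behaviour feeding back into the stocks (agents only perceive); or fund
replenishment. A passing test suite therefore shows the mechanism is
implemented correctly and behaves as the theory predicts under these
idealized conditions — not that any particular real intervention would
homogenize in a given number of stages.

## Numerical choices and degenerate inputs

* Ordered-triple sampling uses rejection (resample the whole triple, up to
  1,000 rounds) rather than sorting, keeping each accepted marginal normal
  conditional on acceptance; triples with `b <= 0` are rejected for the same
  reason. Heavily overlapping specifications fail loudly with the offending
  specification in the message.
* Strict ordering `b < c < d` is enforced because the membership formulas
  divide by `c - b` and `d - c`.
* Membership bin 0 uses `|mu| <= 1e-12`; bins are half-open below, closed
  above, so `assign_bin` is total and single-valued on `[0, 1]`.
* Derivative signs at regime breakpoints are undefined (kinks) and only
  reported on open intervals inside one regime.
* The trajectory horizon starts at `t0 = 0`; increasing base paths are
  rejected rather than silently extrapolated.
* One time unit must be an integer number of `dt` steps, so stage and agent
  clocks align exactly.
* Exactly two linguistic variables are supported end-to-end (they map onto
  the two stocks); the fuzzy-core and agent layers are variable-count
  agnostic, so widening the engine is an extension, not a rewrite.

## Known limitations

The model inherits the framework's simplifications: three-term triangular
memberships only (no trapezoidal or bell shapes), social operations on the
Low term only, a single shared intervention signal per variable, no
optimization of the allocation policy, and no ingestion of observed data.
The closed-form trajectory API covers exactly the two analytic families;
arbitrary user-supplied base functions go through the engine's numeric path
instead.

## Problem sizes used by the checks

The test and acceptance workloads are sized for quick, repeatable runs:
10,000 random cases for the partition-of-unity and binning properties,
1,000-point grids for the oracle-equivalence checks, a 5,000-node graph for
the degree-law fit, 50-time-unit integrations for the conservation and
convergence checks, and 20 seeded small-scenario runs for the homogenization
property.
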