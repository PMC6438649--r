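---
title: "Crossing fitness valleys: models, exact analysis, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossing fitness valleys: models, exact analysis, and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valleycross)
```

## The problem

A local optimum of a fitness landscape is only locally attractive: between
it and a better optimum lies a *fitness valley* — a stretch of search points
of lower fitness.  How a single-trajectory stochastic searcher crosses such
a valley depends on its selection strategy.  An elitist hill-climber (the
(1+1) EA with standard bit mutation) never accepts a worse point, so it has
to *jump* the valley in one multi-bit mutation; a non-elitist walker (the
SSWM process of molecular evolution, or the Metropolis algorithm) can
*wade* through it, accepting a chain of small fitness losses.  The package
provides both kinds of dynamics on a common family of landscapes, plus the
exact Markov-chain machinery to compute crossing times and drifts without
simulation, so that the two regimes — runtime exponential in the valley's
*length* for elitism versus exponential in its *depth* for non-elitism —
can be verified numerically at desk scale.

## Landscapes

### Long k-paths

All landscapes live on a *long k-path*: a recursively constructed sequence
of `n`-bit strings forming a Hamming path (consecutive points differ in one
bit) with the property that any shortcut spanning `k` or more path
positions requires flipping at least `k` bits at once.  The path of
dimension `n` is built from the path of dimension `n - k` as
`S0` (the sub-path prefixed with `0^k`), a bridge `B` that converts the
leading block to `1^k` one bit at a time, and `S1` (the reversed sub-path
prefixed with `1^k`); its length is `k * 2^(n/k) - k + 1`.

```{r}
build_path(long_k_path(6, 3))
```

Because paths are exponentially long, `build_path()` constructs points
lazily by recursion and refuses full materialisation above a cap
(`max_points`, default `2^20`); `index_of()` decodes an arbitrary string to
its path index (or `NA` off the path) by inverting the recursion, and
`verify_hamming_property()` checks exhaustively on small instances that the
Hamming distance between points `s` and `s+i` is exactly `i` for `i < k`
and at least `k` otherwise.

Fitness is embedded with `embed_fitness()`: the first `m` path points get
the heights of a valley profile, every other string gets the sentinel
`-Inf`.  The sentinel is an exact IEEE infinity, not a large negative
float, so every acceptance rule maps it to probability exactly 0 and no
trajectory can leave the embedded landscape.  This mirrors the modelling
assumption that off-path fitness is low enough never to be accepted; the
search starts at path point 0 (the left peak) by construction.

### Valleys and chains of valleys

A `valley(l1, l2, d1, d2)` is piecewise linear over positions `0..l1+l2`:
height `d1 - i*d1/l1` down to 0 at the bottom (`i = l1`), then
`(i-l1)*d2/l2` up to `d2`.  The constraint `d1 <= d2` makes the right peak
the optimum.  Its *effective length*

```{r}
effective_length(valley(2, 2, 1, 2))
```

is the distance from the start to the first point of at least equal
fitness, `l1 + ceiling(d1*l2/d2)`: the minimum jump an elitist searcher
must make.  `valleypath(m, valley)` concatenates `m` identical valleys,
each shifted up by `d2 - d1` so the peaks rise towards the global optimum
at position `m*(l1+l2)`.  Valley indexing follows the printed convention in
which the first peak sits at height `d2` rather than `d1`; the constant
offset cancels from every fitness difference, so no dynamical quantity
depends on it.

## Acceptance rules

All three rules share the interface `accept_probability(rule, delta_f)`:

* `elitist_rule()` — 1 if `delta_f >= 0`, else 0 (ties accepted);
* `sswm_rule(beta, N)` — Kimura's fixation probability
  `p_fix = (1 - e^(-2*beta*delta_f)) / (1 - e^(-2*N*beta*delta_f))`, with
  the defined limit `1/N` at `delta_f = 0` and identically 1 at `N = 1`;
  `beta` is the selection strength, `N` the population size of the
  underlying evolutionary process (algorithmically just a parameter);
* `metropolis_rule(alpha)` — 1 for improvements, `e^(alpha*delta_f)` for
  worsenings; `alpha` is the inverse temperature.

The SSWM tie value `1/N` versus the elitist/Metropolis tie value 1 is a
deliberate, visible difference between the rules, implemented exactly.

Two identities drive all the exact analysis and are exported as checkable
operations: the symmetric ratio `p_fix(-d)/p_fix(d) = e^(-2*(N-1)*beta*d)`
(`fixation_ratio()`, evaluated in log space) and elementary lower/upper
bounds on `p_fix` (`fixation_bounds()`).

### Numerical policy

`p_fix` is evaluated through `expm1`/`log1p` with three regimes: the
`1/N` limit is returned when `|2*N*beta*delta_f| < 1e-12` (continuity,
avoids 0/0); for negative differences with large `|2*N*beta*delta_f|` the
computation moves to log space (`log(e^y - 1)` expanded as
`y + log1p(-e^(-y))` beyond `y = 30`), so arguments up to
`|2*N*beta*delta_f| = 700` neither overflow nor collapse to wrong values.
The unit tests pin a stress grid against 50-digit reference values at
relative error `1e-10`.

## Exact analysis

### Gambler's Ruin with self-loops

The reduced walk on a slope of constant gradient is a ruin game in which a
round may also change nothing.  `ruin_win_probability()` implements
`n1/(n1+n2)` for the fair game and
`(1-(p2/p1)^n1)/(1-(p2/p1)^(n1+n2))` otherwise, with powers in log space.
Self-loops leave winning probabilities untouched and stretch durations by
the waiting factor `1/(p1+p2)`; carrying that factor through the standard
duration formula gives

* fair: `n1*n2/(p1+p2)`,
* biased: `(n1 - (n1+n2)*P1)/(p2 - p1)`,

both homogeneous of degree −1 in `(p1, p2)`, as the self-loop
interpretation requires (halving both probabilities doubles the game).
Near the fair point the biased formula's numerator cancels to
`O(log(p2/p1))`, so for `|log(p2/p1)| < 1e-5` the implementation switches
to a second-order series in `log(p2/p1)`; the equal branch proper is used
within relative `1e-12` of `p1 = p2`.  Everything is regression-tested
against dense first-step solves on random games, including near-equal ones
that straddle the branch switch.

### Chains, hitting times, absorption

`valley_chain(heights, rule)` turns any height profile into the reduced
birth–death chain: up/down proposals with probability 1/2 each, accepted
with the rule's probability at the local height step, remainder a
self-loop; the two ends fold the missing direction into a self-loop of at
least 1/2.

Exact expectations come from first-step equations, but *how* they are
solved matters numerically, because hitting times grow like `e^(lambda*d)`
and absorption probabilities shrink symmetrically:

* single-barrier hitting times (`hitting_time()`, and through it
  `valley_crossing_time()` and `valleypath_expected_time()`) use the
  ladder recurrence `t_s = (1 + q_s*t_(s-1))/p_s` for the expected time to
  advance one state towards the target — all operations positive, hence
  componentwise stable under arbitrarily strong biases;
* two-barrier absorption probabilities (`absorption_probability()`) use
  the classical ratio of partial sums of products of down/up odds,
  accumulated in log space with log-sum-exp, which keeps full relative
  accuracy on *both* the likely and the exponentially unlikely side
  (values down to ~1e-110 arise on the test grids and are still good to
  ~1e-14);
* genuine two-barrier durations fall back to tridiagonal elimination,
  which is adequate in the moderate regimes where durations are finite
  numbers one actually wants.

A generic sparse or dense solver fails both extremes — condition-number
guards reject the system, and elimination cancels the tiny components —
which is why the package carries these three small special-purpose
routines instead of a linear-algebra dependency.

### Valley descent, escape bounds, and peak drift

`valley_descent_time()` evaluates the decomposition of the expected time
from one step inside the valley to the bottom: a ruin game on the
descending slope (`p1 = p_acc(-d1/l1)/2` towards the bottom,
`p2 = p_acc(+d1/l1)/2` back up, stakes 1 and `l1 - 1`), restarted through
the peak each time it loses:

`E(T) = (1/p_win) * (E(T_game) + p_lose / p_restart)`.

It must and does agree with the linear-solve hitting time to relative
`1e-9` across the test grids — the two routes share no code.
`sswm_ruin_bounds()`/`metropolis_ruin_bounds()` expose the printed
closed-form brackets on the downhill escape probability; the implementation
orients player 1 as the downhill direction (reaching the bottom before
returning to the peak), the orientation under which the brackets do
bracket the exact value, which the tests verify on 200-point random grids.

For chains of valleys, `drift_report()` computes the four peak/minimum
absorption probabilities exactly and forms the product ratio

`(p_down_left * p_up_left) / (p_down_right * p_up_right) = e^(-lambda*(d2-d1))`,

with `lambda = 2*beta*(N-1)` (SSWM) or `alpha` (Metropolis).  The
probability that a transition between peaks moves towards the optimum is
`1/(1 + ratio)` and the drift over peaks is `2/(1 + ratio) - 1`; a
positive constant drift makes the total crossing time linear in the number
of valleys `m`.  Each of the four probabilities gets its own solve — taking
complements would destroy the relative accuracy of the exponentially small
side.

```{r}
drift_report(valleypath(2, valley(2, 2, 2, 4)), sswm_rule(1, 2))
```

## Simulation

Three modes, all driven by `sim_config(seed, replicates, budget)`;
replicate `r` is seeded with `seed + r`, so results are reproducible bit
for bit, and an exhausted budget is a reported outcome (censoring), never
an error.

* **Bit-string mode** (`run_bitstring()`): the full mutate/accept loop on
  the embedded path, local (single uniform bit flip) or global (each bit
  with probability `1/n`) mutation.  Off-path offspring cost an evaluation
  and are rejected through the sentinel; that is what makes the `n/2`
  waiting factor between function evaluations and relevant steps emerge
  rather than being hard-coded.  Relevant steps are counted so as to
  reproduce the reduced chain exactly: a proposal of a profile neighbour
  counts always, and at the two boundary states a non-neighbour proposal
  counts as a boundary self-loop with probability `1/(n-1)`, preserving
  the reduced chain's self-loop probability of 1/2 at the ends.
* **Chain mode** (`run_chain()`): the reduced process itself, exact for
  local mutations; the designated mode for SSWM/Metropolis experiments.
* **Segment-jump mode** (`run_segment_jump()`): the elitist EA on a
  shortcut-free segment (fold parameter exceeding the segment length, so
  path distance equals index distance).  Signed jumps of length `i` occur
  with probability `n^-i (1-1/n)^(n-i)` per direction; the simulator draws
  geometric waiting times between *accepted* jumps, which is exact in
  distribution for hitting times measured in evaluations and removes the
  `O(n^(l*))` per-evaluation loop — this is what makes the length-scaling
  study run in seconds.

Cross-mode agreement (bit-string vs chain vs exact solve, and the
evaluations-per-relevant-step ratio against `n/2`) is asserted in the test
suite at three standard errors / 10%.

## Experiments

`ea_length_scaling()` fits the log–log slope of mean elitist crossing time
against `n`; the law predicts the effective length `l*`.
`depth_scaling()` regresses the log of the *exact* crossing time on the
depth `d1` (with `d2 = d1 + 1`) and checks the slope against the sandwich
`[2*(N-1)*beta*(l1-1)/l1, 2*N*beta*(l1+1)/l1]` (SSWM) or
`[alpha*(1-1/l1), alpha*(1+1/l1)]` (Metropolis).
`valleypath_scaling()` verifies that exact crossing time per valley stays
within a bounded factor when the drift condition holds.  Asymptotic
side-conditions of the form "scaled gradient bounded below" are
instantiated as `>= 0.5`, checked per grid cell, and violations are
reported, never silently dropped.

Problem sizes are deliberately desk-scale and chosen once: the length law
uses `n` in `{16, 24, 32, 48}` with 200 replicates (the event-skipping
simulator makes this cheap); the depth law uses `d1` in `{4, ..., 12}`
exactly (no sampling noise); the chain-of-valleys law uses `m` up to 8;
Monte-Carlo cross-checks use 400–3000 replicates, sized so that
three-standard-error bands are decisive.

## What the generator does and does not emulate

The landscape family isolates two control dials — valley length and valley
depth — on a path with *no mutational bias*: forward and backward proposals
are exactly equally likely everywhere.  Real fitness landscapes have
neither piecewise-linear slopes nor bias-free geometry, and real valleys
are rarely isolated from competing paths.  Passing tests therefore
establish the runtime laws *for this model class* — they quantify the
elitism-vs-depth trade-off cleanly, but they do not certify performance on
arbitrary rugged landscapes.  Heterogeneous valley sizes within one chain
are excluded by construction (the flattener would admit them, but all
analysis assumes identical valleys).

## Known limitations

* SSWM is implemented with local mutations only; combining non-elitist
  acceptance with global mutations is out of scope.
* The population parameter `N` never materialises as explicit individuals;
  it only shapes the acceptance probability.
* Two-barrier expected *durations* (unlike winning probabilities) are
  solved by plain elimination and lose accuracy in regimes where they are
  astronomically large; the package's own analyses never need them there.
* `valleypath_expected_time()` refuses chains above `1e5` states and
  points to the simulator instead.
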