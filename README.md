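# valleycross

Stochastic search meets fitness valleys: **valleycross** builds landscapes
in which two local optima are separated by a valley of tunable *length* and
*depth*, runs elitist and non-elitist search dynamics on them, and computes
exact crossing times and drifts from absorbing-Markov-chain theory.  It is
aimed at people studying randomised search heuristics and at population
geneticists interested in how evolving populations traverse adaptive
valleys.

## The model

Landscapes live on a **long k-path**: a recursively built Hamming path of
`n`-bit strings of length `k·2^(n/k) − k + 1` on which any shortcut
requires flipping at least `k` bits at once.  A **valley** assigns heights
to the first path points: from the start peak at height `d₁` fitness falls
linearly over `ℓ₁` steps to 0, then rises over `ℓ₂` steps to `d₂ ≥ d₁`;
`m` valleys can be chained with peaks rising by `d₂ − d₁` per valley.  All
other strings get fitness `−∞` and are never accepted.

Three single-trajectory algorithms share one loop (mutate, then accept
with probability `p_acc(Δf)`):

| algorithm | mutation | acceptance `p_acc(Δf)` |
|---|---|---|
| (1+1) EA | each bit w.p. `1/n` | `1` if `Δf ≥ 0`, else `0` (elitist) |
| SSWM | one uniform bit | `p_fix(Δf) = (1 − e^(−2βΔf))/(1 − e^(−2NβΔf))` |
| Metropolis | one uniform bit | `1` if `Δf ≥ 0`, else `e^(αΔf)` |

The SSWM rule is Kimura's fixation probability with selection strength `β`
and population-size parameter `N` (`p_acc(0) = 1/N`; `N = 1` accepts
everything).

Under local mutation the on-path dynamics reduce to a birth–death chain
(up/down proposals with probability 1/2 each, `n/2` function evaluations
per relevant step).  On a slope of constant gradient that chain is a
**Gambler's Ruin with self-loops**, giving closed forms for winning
probabilities and expected durations; first-step linear systems give exact
hitting times for anything else.  Two laws emerge and are verified
numerically by the package:

* **elitist length law** — the (1+1) EA must jump the *effective length*
  `ℓ* = ℓ₁ + ⌈d₁ℓ₂/d₂⌉` in one mutation, so its expected crossing time is
  `Θ(n^ℓ*)`;
* **non-elitist depth law** — SSWM and Metropolis cross in time
  exponential in the *depth* (`≈ e^(2Nβd₁)` resp. `e^(αd₁)`), essentially
  independent of the length, and cross `m` chained valleys in time linear
  in `m` whenever the drift over peaks
  `Δ = 2/(1 + e^(−λ(d₂−d₁))) − 1` (λ = `2β(N−1)` or `α`) is a positive
  constant.

## Worked example

```r
library(valleycross)

v <- valley(2, 2, 1, 2)       # l1 = l2 = 2, d1 = 1, d2 = 2
v
#> Valley: l1 = 2, l2 = 2, d1 = 1, d2 = 2 (length 4, effective length 3)

rule <- sswm_rule(beta = 1, N = 2)

# exact expected crossing time, in relevant steps and in evaluations (n = 16)
valley_crossing_time(v, rule)
#> [1] 65.99288
relevant_to_evaluations(valley_crossing_time(v, rule), n = 16)
#> [1] 527.9431

# simulation agrees
r <- run_chain(valley_height(v, 0:v$l), rule,
               sim_config(seed = 1, replicates = 1000), n = 16)
mean(r$relevant_steps)
#> [1] 68.848

# the elitist EA on the same valley needs ~ e * n^3 evaluations (l* = 3)
ea <- run_segment_jump(v, n = 16, sim_config(seed = 2, replicates = 1000))
mean(ea$evaluations)
#> [1] 8903.386

# positive drift over the peaks of a chain of valleys
drift_report(valleypath(3, valley(2, 2, 2, 4)), rule)
#> Peak drift: ratio = 0.0183156 (closed form 0.0183156), P(step right) = 0.982014, drift = 0.964028
```

The SSWM walker crosses this shallow valley in ~530 evaluations where the
elitist EA needs ~8900 — and the gap widens polynomially in `n`, since the
EA pays `Θ(n^3)` while SSWM pays `Θ(n)`.  The drift report shows the exact
product-ratio identity `e^(−λ(d₂−d₁))` (here `λ = 2β(N−1) = 2`,
`d₂ − d₁ = 2`) and the resulting strong pull towards the global optimum.

## Command line

A thin CLI over the same functions ships in `inst/scripts/valleycross`:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "valleycross", package = "valleycross"))')
Rscript $CLI path build --n 9 --k 3                    # TSV: index, bits
Rscript $CLI accept eval --rule sswm --beta 1 --N 2 --delta 0
Rscript $CLI exact valley --algo sswm --beta 1 --N 2 \
        --l1 2 --l2 2 --d1 2 --d2 4 --n 16 --json
Rscript $CLI experiment depth --algo sswm --beta 1 --N 2 \
        --l1 4 --l2 4 --out results/
```

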