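---
title: "Stochastic simulation of Boolean networks: model, conventions, verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic simulation of Boolean networks: model, conventions, verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolss)
```

## The model

A Boolean signaling network has `n` binary nodes; the joint state
`S ∈ {0,1}^n` is packed into an integer bitmask (node `i` occupies bit
`i`, little-endian; this is a convention the package fixes, not a
property of the model). Under asynchronous updating exactly one node
changes per transition, so the reachable neighbors of `S` are the `n`
single-bit flips `S ⊕ 2^i`. Node `i` carries a Boolean formula `f_i`
over the node values and two positive rates; its flip rate in state `S`
is

* `0` when `S_i = f_i(S)` — the logic agrees with the current value, the
  node cannot move;
* `rate_up_i` when `S_i = 0` and `f_i(S) = 1`;
* `rate_down_i` when `S_i = 1` and `f_i(S) = 0`.

A single symmetric rate `r` is the special case
`rate_up = rate_down = r`. These rates define a continuous-time Markov
chain on the `2^n` states. States with zero total exit rate are fixed
points (absorbing); models whose attractors are limit cycles have no
fixed points and trajectories there end only by timeout.

`simulate_trajectory()` realizes the chain with the Gillespie
algorithm. In state `S` at time `t`, with rate vector `B(S)` and total
`R = Σ_i B_i(S)`:

1. if `R = 0`, the trajectory is absorbed (`FIXED_POINT`);
2. otherwise draw `u₁, u₂ ∈ (0,1)`; the jump time is
   `t' = t − ln(u₁)/R`;
3. the flipping node is the smallest `j` whose cumulative rate
   `Σ_{i ≤ j} B_i(S)` strictly exceeds `u₂·R` — each node is chosen with
   probability `B_j(S)/R`, and zero-rate nodes can never be selected,
   even at boundary draws;
4. a jump that would land beyond `max_time` is not taken; the pre-jump
   state occupies the rest of the horizon and the trajectory ends by
   `TIMEOUT`.

The inverse-transform details in steps 2–3 (open-interval uniforms,
strict cumulative-sum inequality) are deliberate choices where the
textbook algorithm leaves room; they make boundary behavior exact and
testable.

## Statistics and their conventions

Three compound statistics are accumulated over the **non-internal**
nodes (projection drops internal bits; labels name the active
non-internal nodes joined by `" -- "`, with `<nil>` for all-inactive):

* **Windowed state probabilities.** Window `k` covers the half-open
  interval `[kτ, (k+1)τ)` with `τ = time_tick`; if `max_time` is not a
  multiple of `τ` the last window is truncated and normalized by its
  true length. Every stay of a trajectory in a state adds its overlap
  with each window; weights divide by `sample_count · length` so each
  window is a probability distribution.
* **Final states.** The state occupied at exactly `max_time`, under the
  absorbing-continuation convention: a trajectory that hit a fixed point
  at `t < max_time` keeps occupying it. This convention is what keeps
  every window a full distribution; whether the "final" state should
  instead be the last *transition* target is a genuinely open choice,
  and the continuation variant is this package's contract.
* **Fixed points.** Counted per full, unprojected state — an absorbing
  state is a property of the whole model state, and projecting first
  could merge distinct attractors. Because the normalization base
  (absorbed trajectories vs. all trajectories) is also a convention that
  differs between tools, `fixed_points()` reports both fractions.

Two interchangeable storage backends hold the distributions: a dense
histogram with `2^width` slots (one per projected state) and a hashmap
keyed by observed states. The histogram is chosen automatically up to
16 non-internal bits (65,536 slots — the common case of "a handful of
readout nodes" with headroom); both backends produce bit-identical
results, which the tests assert rather than assume.

## Determinism and the reduction tree

Reproducibility is keyed by `(seed, global trajectory index)`: each
trajectory consumes its own xoshiro256++ substream (seeded through
splitmix64), so trajectory `i` is the same random object no matter which
worker simulates it. The same C++ generator drives both the R reference
simulator and the batch engine; the test suite checks that the two
produce bit-identical trajectories.

Floating-point addition is not associative, so summing per-worker
partial statistics naively would make results depend on the worker
count. The engine instead folds every trajectory's contribution into a
pairwise reduction tree whose shape depends only on `sample_count`:
workers emit aligned power-of-two blocks of the tree, and the master
recombines them in canonical order. Consequently `workers` is a purely
structural parameter — `run_simulation()` results are bit-identical for
any value, which the acceptance tests verify for workers ∈ {1, 2, 8}.
The R-level `merge_stats()` is the reference merge; its partition
invariance is checked to 1e-12 (sequential fold order differs, so exact
bitwise equality is not claimed there).

## Runtime compilation of the logic

Evaluating formulas is the inner loop, so a model is compiled once, not
interpreted per step. Two compiled forms are produced by
`compile_model()`: generated R source for a whole-network rate-vector
function (compiled in-process with `compiler::cmpfun`; inspectable via
`$source`) and flattened postfix programs executed by a small stack VM
in the C++ engine. The AST interpreter (`evaluate_formula()`,
`transition_rates()`) remains the reference; tests sweep all `2^n`
states of 10-node models and random state samples of larger ones to
assert exact three-way equality. The code generators perform **no**
simplification or constant folding — generated code size must track
formula size so that padded benchmark formulas (below) cost what they
appear to cost.

States cross the R/C++ boundary as doubles, which are exact integers up
to 2^53; the simulation and oracle paths therefore guard `n ≤ 53`
(parsing, serialization and model generation have no such limit). This
covers the model sizes the statistics machinery is built for — beyond
~16 non-internal nodes the histogram is infeasible anyway — while
keeping the interface free of 64-bit integer workarounds.

## The synthetic benchmark generator

Benchmarking a stochastic simulator needs models whose cost is
predictable. The generator builds, for each node,

```
f_i = (!S_i) XOR (g_i AND !g_i)
```

where `g_i` is a random sub-formula over other nodes. The padding
`g_i AND !g_i` is identically false, so `f_i(S) = !S_i` for every state:
every node is always enabled, no state is ever fixed, and the total exit
rate is `n·r` everywhere. The transition count on `[0, T]` is therefore
exactly Poisson(`n·r·T`), and the generator sets `max_time = L/(n·r)` to
pin the designed mean trajectory length `L`. Defaults are the standard
benchmark conditions: 5 non-internal nodes, `L = 100`, unit rates,
initial activation probability 0.5 for every node, formula-size targets
of 10–100 operands. The padding sub-formula sizes alternate between
`⌊(F−1)/2⌋` and `⌈(F−1)/2⌉` operands so the mean operand count per
formula (`1 + 2·|g_i|`) stays within 1 of the target `F`; operands are
drawn without replacement from the other nodes (refilling the pool when
a formula is longer than the node count allows), with a seeded stream so
a spec maps to exactly one model.

What these models deliberately do **not** exercise: absorption (no
fixed points), heterogeneous rates, state-dependent total rates, or
logic with actual dynamics (every node is an independent toggle in
disguise). Passing the trajectory-length and no-stable-state checks
therefore validates the engine's event clock and the generator's
construction — conclusions about real signaling models rest on the
closed-form and master-equation checks instead.

## The exact oracle

For `n ≤ 20` (tests use `n ≤ 10`), `build_rate_matrix()` materializes
the sparse `2^n × 2^n` rate matrix `Q` with `Q[S, S⊕2^i] = B_i(S)` and
zero row sums, plus the product-form initial distribution. The master
equation `dp/dt = pQ` is solved as `p(t) = p(0)·exp(Qt)`
(`Matrix::expm`); window averages integrate `p(t)` by composite Simpson
quadrature with 100 steps per window (fourth-order error, orders of
magnitude below the Monte-Carlo tolerances it is compared against), and
absorption mass is read off the fixed-point states of `p(max_time)`.

Verification strategy, in increasing strength:

* closed forms: one-node decay `P(active at t) = e^{−rt}` and toggle
  `P(active at t) = ½ + (p₀−½)e^{−2rt}`, compared window-by-window at
  10⁵ trajectories within 3 conservative binomial standard errors;
* master equation: ten seeded random 5-node models, per-window total
  variation between simulation (10⁵ trajectories) and the exact window
  averages below 0.01;
* conservation, monotone absorption, per-window sums of 1, one-bit
  transitions, and exact worker/backend invariances as above.

## Problem sizes and defaults

The shipped test and verification runs use 10⁵ trajectories for
distributional comparisons, 10⁴ for the benchmark-length check, 5–10
node models for exhaustive sweeps — sizes at which the Monte-Carlo
tolerances above are meaningful and a full run of everything stays
comfortably interactive. `sample_count` defaults to 10⁴, `time_tick` to
0.1, `max_steps` to unbounded (the cap exists as an explicit safety
valve, ending trajectories with `STEP_CAP` and a warning, not as a
default behavior).

## Known limitations

* Only the asynchronous update semantics is implemented; synchronous
  updating is a different model family.
* The `.bnd`/`.cfg` dialect covers per-node logic, symbolic `$param`
  rates, internal flags and independent per-node initial probabilities;
  conditional rate expressions and joint initial-state distributions
  from the wider MaBoSS format family are out of scope, so upstream
  files using them will not parse.
* Limit cycles are not detected or summarized (no entropy traces);
  cyclic behavior shows up only implicitly, as timeout-terminated
  trajectories with oscillating window probabilities.
* The exact solver is a verification instrument: dense `exp(Qt)` work
  beyond ~2^10 states is slow, and the guard refuses `n > 20` outright.
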