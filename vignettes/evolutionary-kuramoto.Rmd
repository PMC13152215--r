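---
title: "Evolutionary Kuramoto games on weighted directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary Kuramoto games on weighted directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ekgraph)
```

## The model

`ekgraph` studies why oscillating agents — the motivating system is neurons in
a connectome — commit to *communication*, and how partial commitment produces
chimera states in which coherent and disordered subpopulations coexist. Each
of the `N` players carries a strategy with two components: a communicative
label, `C` or `N`, and a discrete phase `phi = 2 pi k / m` with
`k = 0, ..., m - 1`. Payoffs flow along the directed edges of a weighted
**interaction graph**: the edge `u -> v` delivers a payoff to the head `v`,
scaled by its integer weight, which is read as the number of games played
along that connection. With `f(dphi) = (1 + cos(dphi)) / 2` the per-game
payoff to the head is

| head | tail | payoff to head              |
|------|------|-----------------------------|
| C    | C    | `B0 f(dphi) - c`            |
| C    | N    | `2 alpha beta0 f(dphi) - c` |
| N    | C    | `2 (1 - alpha) beta0 f(dphi)` |
| N    | N    | `0`                         |

Communication costs `c` unconditionally; benefits require phase alignment.
The asymmetry `alpha` splits the mixed-interaction benefit between the
communicator (factor `2 alpha`) and the non-communicator (factor
`2 (1 - alpha)`); `alpha = 1/2` is the symmetric model, where both mixed
payoffs carry the plain `beta0 f` benefit — that is why the factors of two
are there. In a live population the C–C payoff uses the *actual* phase
difference of the two players (it is a Kuramoto coupling); the `f(0)` form
appears only in the hypothetical-switch matrix below, in the cell where both
players adopt one common state.

Strategies spread by a birth–death Moran process on a **reproduction graph**
— the interaction graph plus one self-loop on every originally dangling node
(out-degree zero), so the death draw is always defined. Per step, a birth
node is drawn proportionally to the exponential fitness
`exp(delta * total payoff)` (total, not degree-averaged, so high in-degree
amplifies selection); a death node is drawn among the birth node's
reproduction out-neighbours proportionally to edge weight; with probability
`mu` the death node gets a uniformly random strategy out of all `2 m`,
otherwise a copy of the birth node's. A dangling node selected for birth
replaces itself: a no-op except under mutation.

## Parameters

The defaults of `ek_params()` are the standard operating point used
throughout and in all reported numbers:

| parameter | default | meaning |
|-----------|---------|---------|
| `c`       | 0.1     | communication cost (payoff units; sets the scale) |
| `B0`      | 0.15 (`1.5 c`) | max joint C–C benefit — deliberately below the `~2.1 c` break-even, biasing against communication |
| `beta0`   | `0.95 B0` | max mixed benefit: one-sided communication pays slightly less than joint |
| `alpha`   | 0.5     | mixed-benefit asymmetry in `[0, 1]` |
| `delta`   | 0.2     | selection strength (weak, keeping the analytics accurate) |
| `mu`      | 1e-4    | mutation rate; one mutation per ~1e4 steps, the rare-mutation regime |
| `m`       | 20      | phase discretization (the communicative fraction is already converged at 20) |

The dynamics depend only on `B0/c`, `beta0/B0`, `alpha`, `delta * c` (plus
`mu`, `m`), so `c` is a unit choice.

## Game types

Every edge at every instant defines a 2x2 game: each player is given the
hypothetical option of switching to the other's strategy/phase
(`switch_game_matrix()`), and the ordinal pattern of the row player's four
payoffs — `R` (both in the C state), `S` (C against N), `T` (N against C),
`P` (both N) — is mapped to a named game type (`classify_game()`). The
twelve strict symmetric orderings are named staghunt, concord, harmony,
peace, assurance, coordination (R on top) and dilemma, chicken, battle,
hero, deadlock, compromise (T on top); relabelling which strategy is "kept"
maps `(R, S, T, P) -> (P, T, S, R)`, so patterns with `S` or `P` on top
canonicalize onto these twelve. C–C pairs are always `cooperation` and N–N
pairs always `neutral`.

Ties (entries closer than `tol = 1e-9` — exact ties such as `beta = 0` at
anti-phase must be caught) collapse onto an adjacent named game: after
canonicalizing, tied entries are ordered by the fixed preference
`R > T > S > P`. This single rule reproduces the three conventional
collapses: deadlock/compromise ties at `alpha = 1` report deadlock,
assurance/staghunt ties at `beta = 0` report staghunt, and harmony/peace
ties report harmony; the `collapsed` flag records that a tie was involved.

At the default operating point (`B0/c = 1.5`, `alpha = 0.5`) the realised
mixed benefit `beta = beta0 f(dphi)` sweeps the phase diagram from chicken
(`beta/c > 1`) through dilemma (`0.5 < beta/c < 1`) to staghunt
(`beta/c < 0.5`) as the phase mismatch grows:

```{r region}
game_region_map(B0_over_c = 1.5,
                beta_over_c = seq(0, 1.4, by = 0.2), alpha = 0.5)
```

The per-step population-level summaries are the **plurality game**
(weight-heaviest type over all edges, with fully-C and fully-N populations
labelled `all-C` / `all-N`) and the **plurality mixed game**, restricted to
C/N pairings; ties break alphabetically on the game name so runs are
reproducible.

## Synchronization and chimera metrics

The Kuramoto order parameter `rho = |sum_j exp(i phi_j)| / N` measures
global coherence. For community structure we use the constant Potts model
optimized by the Leiden algorithm (via igraph) with resolution 0.1,
refinement randomness 0.01 and 2 iterations — `detect_communities()` —
collapsing the directed weighted graph to a weighted undirected one
(reciprocal weights summed) because igraph's Leiden requires undirected
input; fixed assignments can also be read from a TSV for exact
reproducibility across igraph versions. Given per-community traces
`rho_m(t)`:

* the **chimera-like index** `chi` is the time average of the
  across-community sample variance (`1/(M-1)`); it is 0 for homogeneous
  communities and at most `M / (4 (M - 1))` — 0.3 for `M = 6` — attained
  when half the communities are fully coherent and half fully disordered
  for all time;
* the **metastability index** `lambda` is the community average of the
  temporal sample variance (`1/(T-1)`); 0 for pinned communities, rising
  to 1/4 in the large-`T` limit for communities spending equal time at
  coherence and disorder. Because the sample (not population) variance is
  used, a T-step equal-occupancy 0/1 trace gives `T/(4(T-1))` — e.g. 0.5 at
  `T = 2`, 0.2500 at `T = 1e4` — and 0.25 is approached, not exceeded.

Both indices follow the printed `1/(M-1)`, `1/(T-1)` normalizations exactly
and are tested against naive two-pass variance oracles at 1e-12.

## Rare-mutation analytics for the well-mixed population

On the complete graph with `mu << 1`, a mutant lineage fixates or dies out
long before the next mutation arrives (at the defaults, single-mutant
lineages resolve in a few hundred steps versus `1/mu = 1e4`), so the
population hops between the `2 m` monomorphic states. `stationary_fcomm()`
builds the embedded Markov chain whose `A -> B` rate is proportional to
`pairwise_fixation(A, B) / 2m` — the standard birth–death fixation
probability with exponential fitness, `1 / (1 + sum_k prod_j gamma_j)` with
`gamma_j = exp(delta (pi_res(j) - pi_mut(j)))` — solves the stationary
distribution by a linear solve, and sums the mass on C-labelled states.
Exact exponential-fitness probabilities are used rather than a
weak-selection expansion; `pairwise_fixation()` is validated against an
absorbing-chain linear-solve oracle at 1e-10.

The resulting `f_comm(B0)` is sigmoidal; `break_even_B0()` bisects the 1/2
crossing:

```{r breakeven}
break_even_B0(N = 20, ek_params())
closed_form_break_even(N = 20, c = 0.1)
```

Both land at `B0/c ≈ 2.1` for `N = 20`. The analytics apply to complete
graphs only; no analogous theory is provided for structured networks.

## Synthetic fixtures

`synth_connectome()` draws a random graph matching the structural census of
the *C. elegans* chemical connectome exactly — 300 nodes, 38 self-loops, 669
reciprocal pairs, 2,331 unpaired edges (3,707 directed edges in total), 5
dangling nodes — with i.i.d. `1 + Geometric` integer weights of mean 3 (the
real weight distribution is not printed, so no claim is made to match it;
the law and mean are configurable). Dangling nodes are designated up front
and a repair pass re-sources edges so non-designated nodes keep positive
out-degree — a fixture artifact, not biology. What the fixture preserves is
the census; what it deliberately does not preserve is the real connectome's
community structure and weight heterogeneity. Its dynamics are accordingly
closer to well-mixed (it tends to synchronize), so tests built on it
exercise the full pipeline and the indices' bounds but say nothing
quantitative about the real network's chimera values, which additionally
require 8e6-step runs. `synth_rho_traces()` builds constant / alternating /
noisy community traces whose indices are known in closed form.

## Numerical choices

* Fitness weights are computed as `exp(delta (payoff - max payoff))` — the
  normalization is shift-invariant, so this is exact and overflow-safe.
* Payoffs are maintained incrementally (O(degree) per step); equivalence
  with full recomputation is a tested invariant at 1e-12.
* One global RNG stream per run (R's generator, also inside the compiled
  loop): a single seed makes initial state and trajectory bit-reproducible.
* Step 0 (the random initial state) is recorded; `burn_in` filtering is
  opt-in and defaults to 0, since the study-length runs amortize transients.
* Duplicate edge rows merge by weight summation with a warning;
  `symmetrize()` sums reciprocal weights by default (preserving the total
  game count; `max`/`mean` available), so an already-symmetric pair doubles
  — a documented consequence.
* Payoff tie tolerance `1e-9`; plurality ties break alphabetically.
* Mutation draws uniformly over all `2 m` strategies *including* the current
  one (the simplest reading of a uniformly random strategy).

## Problem sizes in the test-suite

The packaged checks scale the study down to keep the suite fast while
retaining hundreds of mutation periods: well-mixed monomorphy uses
`N = 20`, 8e5 steps, 3 seeds per asymmetry; simulation-versus-theory
comparisons use 4e5-step runs at three `B0` values with a band of
`3 x max(seed sd, 0.05)` (the floor covers the saturated sigmoid ends where
the seed standard deviation degenerates); neutral-drift fixation uses 2e4
Monte-Carlo replicates at `N = 5` with a 99% binomial band; the fixture
chimera pipeline runs 4e5 steps on the 300-node synthetic graph. The
acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities from scratch at these scales.

## Limitations

* The analytic module covers complete graphs only.
* Neuron types are not distinguished; all nodes share one parameter set, and
  only the chemical-synapse style of connectome (one directed weighted
  graph) is represented — no gap-junction layer.
* Community detection depends on the igraph/Leiden version; for archival
  reproducibility store the assignment TSV rather than re-detecting.
* The synthetic connectome is a census-matched stand-in, not a generative
  brain-network model; conclusions about real connectomes require loading
  the real edge list via `load_edge_list()`.
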