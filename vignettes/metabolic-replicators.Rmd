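---
title: "The metabolic replicator model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metabolic replicator model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mcrs` simulates a population of surface-bound, template-copied replicator
molecules (RNA-like) on an `L x L` toroidal lattice. Each site is empty or
holds one replicator, whose heritable phenotype is a triple `(E1, E2, k)`:
two enzyme activities catalysing the two keystone reactions of a shared
metabolism, and a basic replication rate. The population is metabolically
coupled: monomers for replication are produced locally only where **both**
activities are present within a replicator's metabolic neighbourhood, so
pure-strategy patches starve and the community survives only through local
complementarity.

A replicator with two positive activities folds into one of two secondary
structures and expresses only one activity per generation (its
*conformation*); between generations it refolds with probability `1 - s`,
where `s = |E1 - E2| / (E1 + E2)` is its degree of specialization. Pure
specialists (`s = 1`) never switch; symmetric generalists switch every
generation, which lets even a clonal generalist patch keep both reactions
running.

One generation consists of `L^2` asynchronous elementary updates (a random
site each time, drawn with replacement), randomly interleaved with
`round(D * L^2)` diffusion events, followed by the conformation-switch sweep:

* **Death.** An occupied site is vacated with probability `p_d = 0.1`,
  independent of the occupant's traits.
* **Replication lottery.** For an empty site, the occupants of its von
  Neumann neighbourhood compete: claimant `i` wins with probability
  `W_i / (W_e + sum_j W_j)` and the site stays empty with the complementary
  `W_e / (W_e + sum_j W_j)`, `W_e = 20`. A claimant's fitness is
  `W = k * M`, with metabolic supply `M = sqrt(A1 * A2)` the geometric mean
  of the two expressed-activity totals over its own Moore (3x3, focal site
  included) neighbourhood. The winner's copy mutates with probability `p_m`.
* **Diffusion.** A site-swap event exchanges the contents of a uniform
  random site and a uniform random Moore neighbour, modelling mobility of
  surface-adsorbed molecules; `D` is the expected number of swaps per site
  update.

### The trade-off surface

Mutant phenotypes are constrained by a three-way trade-off: catalytically
good molecules fold compactly and are hard to copy, and one activity can
only grow at the other's expense. The feasible volume is bounded by

\[
C(E_1, E_2) = k_{min} + (k_{max} - k_{min})\,(1 - u)^{1/g}, \qquad
u = \frac{(E_1^{\,b} + E_2^{\,b})^{1/b}}{E_{max}},
\]

with `k_min <= k <= C(E1, E2)` and `u <= 1`. `b` shapes the enzyme/enzyme
trade-off (`b < 1` convex/strong; `b = 1` the line `E1 + E2 = E_max`;
`b -> Inf` no trade-off) and `g` the enzymes/replication trade-off. Mutants
are drawn **uniformly from the feasible volume** (rejection from the
bounding box), independently of the parent: mutations in a complex folded
molecule can have effects of any magnitude, and the average mutation is
deleterious because selection concentrates the population near the surface
while mutants fall anywhere below it.

### Phenotype classes

The trait space is continuous, so the reported classes are regions of its
`E1-E2` projection, tested in fixed order so they partition the plane:
*parasites* near the origin (`E1 + E2 <= 1`, a tenth of `E_max`), then
*specialists* within 0.5 activity units of an axis, then *generalists* with
`s <= 0.2` around the diagonal, then *the rest*. The boundaries are honest
free parameters of the analysis (the underlying regions are defined only
graphically); they ship in `class_regions()`, are recorded in every run's
metadata, and the parasite share in particular is sensitive to the triangle
size, since the near-origin band holds a standing mutation--selection tail
(see below).

## What a run computes

`run_single()` seeds the RNG, fills `round(0.8 * L^2)` uniformly chosen
sites with independent uniform feasible phenotypes, advances the automaton
with a compiled kernel, and records per-generation summaries
(`summarize_lattice()`): occupancy, the four class frequencies and trait
means. `quasi_equilibrium()` averages the final 10% of records — the
published results sample one late generation of a very long run, and the
tail average is the steadier desk-scale analogue. `run_sweep()` +
`crossover_estimate()` locate the specialist/generalist phase transition
along a parameter axis by linear interpolation of the class-frequency
crossing.

## Numerical and design choices

* **Metabolism normalisation.** `M` is the geometric mean of the
  neighbourhood-summed expressed activities, `sqrt(A1 * A2)`, with the
  neighbourhood size entering only as the summation range. A per-site
  density form `sqrt((A1/9) * (A2/9))` was evaluated and rejected: against
  the fixed constants `W_e = 20` and `p_d = 0.1` it suppresses every claim
  so strongly that the standard 80%-random initialization collapses to
  extinction for all convex trade-offs, on desk- and full-scale lattices
  alike, while hand-built specialist communities remain viable — i.e. it
  makes the model's documented phase behaviour unreachable from its
  documented initial condition.
* **Scheduling.** A generation is exactly `L^2` site updates with diffusion
  events interleaved uniformly at rate `D` per site update (a random
  permutation of the two event multisets); conformation switching happens
  once per generation boundary, not inside it.
* **Metabolic self-inclusion.** The focal replicator belongs to its own
  metabolic neighbourhood (`n = 9`), the convention of the antecedent
  surface-metabolism models.
* **Diffusion partners.** Swaps may involve an empty partner (otherwise
  replicators could never advance into empty territory and the mixing that
  rescues specialists would be crippled); the literal occupied-pairs-only
  reading is available as `diffusion_occupied_only = TRUE`.
* **Offspring conformation.** Faithful copies inherit the parent's fold; a
  mutant is a new sequence with no memory, so it draws uniformly among its
  expressible states.
* **Boundaries.** Points on the trade-off surface (`u = 1` or `k = C`)
  count as feasible, so absolute specialists `(E_max, 0, k_min)` exist.
  The lottery needs no tie-breaking: it is a single categorical draw.
* **Degenerate volumes.** When `k_max = k_min` the `k` dimension collapses
  and the sampler returns `k = k_min` exactly, with `(E1, E2)` uniform on
  the feasible enzyme region.
* **RNG.** The initializer uses R's RNG (`set.seed(params$seed)`); the
  compiled kernel owns a xoshiro256+ stream expanded from the same seed, so
  a run is bit-reproducible given `(params, seed)` while elementary-operation
  wrappers remain testable under R's RNG. All stochastic draws consume their
  stream in schedule order.

## Desk scale and what it shows

The published experiments use a `300 x 300` lattice for 150,000 generations;
the package's defaults are `L = 100` and 10,000 generations (`preset_fig3()`
exposes the full scale behind `full_scale = TRUE`). At desk scale the model
reproduces the qualitative phase structure: strongly convex enzyme
trade-offs plus moderate mobility give specialist-dominated communities
(~90% specialist at `b = 0.4`, `D = 5`); without diffusion generalists
exclude specialists once `b` exceeds roughly 0.5–0.6; weak trade-offs give
generalist dominance; parasites persist at low frequency and never take
over; pure-parasite and single-conformation monocultures go extinct.

Two desk-scale caveats, both visible in the test suite rather than assumed:
domain coarsening near the transition is far slower than 10,000 generations,
so the `D = 5` specialist/generalist crossover estimate sits lower
(~`b` = 1.0–1.2) than the long-run threshold (~1.67) and replicate seeds near
the transition can land in different dominance states; and the parasite-class
frequency depends on the origin-triangle size of the classification, because
uniform mutant draws under convex trade-offs concentrate near the origin and
maintain a standing tail of weak phenotypes there.

What the initializer does *not* emulate: real prebiotic populations would
not start from a uniform sample of the feasible trait volume, and nothing in
the model represents sequences, replicator length, or spatially
heterogeneous surfaces. Conclusions are about the ecology of
metabolically coupled phenotypes, not about any particular chemistry.

## A worked example

```{r, eval = FALSE}
library(mcrs)

run <- run_single(mcrs_params(L = 100, generations = 10000,
                              b = 0.4, D = 5, p_m = 0.01, seed = 1))
glance(run)          # quasi-equilibrium class frequencies
autoplot(run)        # class-frequency time series
plot_phenotype_histogram(run)

sweep <- run_sweep(preset_fig3(D = 5, replicates = 3))
crossover_estimate(sweep)
plot_sweep(sweep)
```
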