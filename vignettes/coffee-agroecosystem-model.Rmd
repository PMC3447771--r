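---
title: "An ant-scale-ladybeetle lattice model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ant-scale-ladybeetle lattice model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antscape)
```

## The system and the model

In shaded coffee, the arboreal ant *Azteca instabilis* nests in about 3% of
the shade trees, and its nests are strongly clustered. The ant tends the
green coffee scale (a honeydew mutualism), and a predatory ladybird beetle
(*Azya orbigera*) eats the scale. The twist is the beetle's split life
history: its wax-covered larvae are protected from their own enemies by
the patrolling ants, so larvae do well *inside* ant territories, while
adult beetles are harassed by ants and feed mostly *outside* them.
antscape implements a spatially explicit caricature of this web to ask two
questions: can beetle predation on the scales, by starving ant nests of
honeydew, produce the observed clustered nest pattern; and is that pattern
in turn what lets the beetle persist?

The model couples a binary cellular automaton (nest present/absent) to
three coupled map lattices (scale, larva, adult densities) on a 120 x 90
toroidal grid representing an 800 m x 600 m plot; one cell is a shade
tree with its surrounding coffee bushes, and one time step is six months.
Each step applies, synchronously and in order:

1. **Beetle demography.** Every larva either ecloses or dies within a
   step and every adult lives one step, so both stages are replaced:
   `A' = e f(c_L, N) L` and `L' = b f(c_A(h), N) A`, where
   `f(c, N) = cN / (1 + gcN)` is a Holling type II response with maximum
   `1/g`, and the adult consumption rate `c_A` is much smaller in ant
   cells (harassment) than outside.
2. **Nest turnover.** Occupied cells die with probability
   `clamp(d0 - d1 N)` — a *decreasing* linear function of the local scale
   density, which is how beetle predation feeds back on the ants — while
   empty cells are colonized locally with probability
   `clamp(a0 + a1 n_occ)` (satellite nests, Moore neighborhood) and
   globally with probability `m_ant` (queen nuptial flights as propagule
   rain).
3. **Migration.** Adults and scales migrate locally (a cell receives a
   fraction `mu_loc` from each Moore neighbor, with receive probability
   increasing in the neighborhood's density) and globally (a fraction
   `mu_glob` of the lattice total is pooled and split equally among
   "chosen" cells). Adults orient to ant pheromones, so ant cells are
   chosen with much higher probability; wind-dispersed scales have no
   preference. Both operations conserve total population exactly.
4. **Scale demography.** Rosenzweig-MacArthur form with K = 1:
   logistic growth (slightly faster in ant cells, where the ants tend
   them) minus the same two predation terms, floored at zero.
5. **Differential survival.** Deterministic thinning by habitat:
   adults survive better away from ants, larvae better with them.

## What makes the four scenarios behave

The calibrated defaults (see below) sit in a regime with three
properties, and the scenario experiments are direct probes of them:

* **Homogeneous habitat is fatal.** In a uniform all-ant world the
  beetle-scale interaction has no stable interior state: beetles overshoot,
  graze the scales toward zero, and then starve (the classic predator-prey
  overexploitation crash). Freezing ants at 100% cover (scenario B, and
  the GA's "100%" criterion) therefore kills the beetles. With no ants at
  all (scenario A, `d0 = 0.85, d1 = 0`), larvae have no protected cells
  (`s_L_noant = 0`), the beetles collapse immediately, and the scales
  relax to carrying capacity.
* **Clusters are nurseries.** In the full model (scenario D) the few ant
  cells hold high scale densities (adults barely feed there), larvae
  thrive in them, and the adult global migration concentrates the whole
  lattice's adults onto exactly those cells. Different clusters run
  out of phase — a cluster booms, its scales are grazed down, its nests
  (starved of honeydew) die, and the beetles' offspring ride the
  migration to younger clusters. This shifting mosaic is what sustains
  the beetle, and the localized bursts of nest mortality around beetle
  concentrations are what carve the nest distribution into clusters.
* **Perception is load-bearing.** Scenario C destroys the beetles'
  ability to target clusters (local migration off, global reception
  uniform). Adults are then spread over 10800 cells of which only ~3%
  can rear larvae; the effective reproductive gain drops well below
  replacement and the beetles die out in a few tens of steps, after which
  mortality loses its spatial structure and the nest pattern degrades.

## Parameters

`model_params()` ships the calibrated set. A few quantities are fixed by
the system's description rather than calibration: the lattice (120 x 90,
periodic), K = 1, the six-month time step, and the scenario overrides
`d0 = 0.85, d1 = 0` (A) and `d0 = 0.2, d1 = 0.3` (B). The saturation
scenario fixes the *mortality* pair and raises expansion until the
lattice fills; the shipped scenario-B config uses `a0 = 1`, which
refills every emptied cell each step and guarantees 100% occupancy.

Everything else is the product of calibration: a constrained search with
the package's genetic algorithm ([run_ga()] over [param_bounds()], with
[evaluate_fitness()] scoring the nest count against ~3% occupancy,
beetle extinction under 0% and 100% frozen ant cover, and per-cell stage
abundances by habitat) followed by refinement against the four scenario
outcomes at the full 500-step horizon. Highlights, with units:

* `e, b` (per-step eclosion and birth rates) and `c_L, c_A_*, g`
  (consumption rates; `1/g` is the per-capita saturation) jointly set the
  beetle's boom amplitude. The regime deliberately overshoots:
  a beetle generation in a fresh ant cell multiplies several-fold.
* `s_A_ant < s_A_noant` and `s_L_ant > s_L_noant` encode the
  harassment/protection asymmetry. `s_L_noant = 0` is the calibrated
  limit of the constraint "larval survival is lower without ants": away
  from ants the larvae starve or are parasitized within the half-year
  step. It is also what makes ant-free landscapes an absolute larval
  sink.
* `d0, d1` (nest mortality intercept/slope on scale density) and
  `a0, a1, m_ant` (expansion) set the nest turnover scale; the defaults
  put uncontested nests (N near K) at essentially zero mortality and
  grazed-down nests at ~10-20% per step, balancing expansion at a few
  hundred nests.
* Migration: adults are highly mobile (`mu_glob_A` near 1) with strong
  ant preference (`p_glob_A_ant = 1` versus `0.01`); scales disperse as
  true propagule rain (`p_glob_N = 1`, no preference). The deterministic
  (probability-one) receive events are a calibrated choice: they keep
  the homogeneous scenarios well-mixed, which is what lets the B and C
  crashes complete instead of being rescued by lattice noise.

Beetle densities are in units of roughly ten individuals per cell, so
the field's 3.8 larvae and 5.8 adults per bush map to targets of 0.38
and 0.58 used in [fitness_spec()].

## Randomness and reproducibility

One global RNG stream drives a run. Each stochastic sub-operation
consumes exactly one `runif(n_cells)` vector laid out in column-major
order, in a fixed sequence per step (nest mortality, expansion, rain,
adult local, adult global, scale local, scale global), whether or not
the draw can change anything. Identical seeds therefore give bit-identical
trajectories, and the test suite checks a loop-coded straight-line
reimplementation of the whole step against the vectorized one, cell by
cell. Lattice indices are 1-based `(col, row)` as usual in R; the metric
center of cell `(col, row)` is `((col - 0.5) cell, (row - 0.5) cell)`,
so spatial statistics see the same coordinates a 0-based convention
would produce.

## Spatial statistics

Nest patterns (from the model via `grid_to_points()`, or field-style CSV
coordinates) are summarized two ways:

* **Cluster sizes.** Single-linkage components at an inclusive 20 m
  threshold (two nests exactly three cells apart axially — 20.0 m — are
  one cluster; a small numerical tolerance absorbs floating-point error
  at the boundary). The cumulative size distribution is fit by
  unweighted OLS on log10-log10 axes, purely as a comparative yardstick;
  no claim is made that the power law is the best-fitting model.
* **Ripley's K / centered L.** `K(r) = (A/n^2) sum w_ij 1[d_ij <= r]`,
  reported as `L(r) - r = sqrt(K/pi) - r`, which is zero in expectation
  under complete spatial randomness and positive for clustered patterns.
  Model output uses toroidal distances (the lattice is periodic, so no
  edge correction is needed); imported bounded-window patterns use the
  translation edge correction. Pointwise 95% envelopes come from 200
  Monte Carlo realizations (CSR with the observed n, by default).

## The synthetic-data generators

No field survey ships with the package. `make_fixture()` produces
synthetic stand-ins: CSR patterns (the null), Thomas-like clustered
patterns (uniform parents, Poisson offspring counts, Gaussian
displacements wrapped into the window) that exceed CSR envelopes the way
the published survey maps do, and Bernoulli occupancy grids. They mimic
the first- and second-order structure of nest maps but none of the
field's covariates (tree species, shade, management), so a green test
against them establishes the statistical machinery and the model's
qualitative behavior — not agreement with any particular farm.

## Numerical choices and edge cases

* Scale densities are floored at 0; no ceiling at K is imposed, so
  logistic overshoot above K = 1 is allowed transiently.
* Migration debits are computed against the time-t snapshot; if several
  receivers oversubscribe a source, its outflows are scaled down
  proportionally. Conservation is exact to floating point (tested at
  1e-9 relative).
* If global migration chooses no cell, the pool stays with its sources.
* "Extinct" for the continuous populations means a lattice total below
  1e-6 (configurable via `extinct_tol`); multiplicative dynamics never
  reach exact zero on their own. `run_scenario()` additionally applies
  this threshold as an absorbing quasi-extinction floor in `run_model()`:
  once the combined beetle total (or the scale total) drops below it, the
  population is set to exactly zero. Without the floor a population can
  linger at ~1e-30 per cell and later "rebound", which has no biological
  reading; with it, a crash is a crash.
* Power-law fits require at least two distinct cluster sizes; `R^2` is
  `NA` for a constant response.
* The `L(r) - r` statistic needs n >= 2 points and radii no larger than
  half the shorter window side.

## Known limitations

* The phorid-fly parasitoid of the companion model is not represented;
  nest mortality is driven only by local scale density.
* Beetle stages have no age structure beyond larva/adult, and the
  six-month step makes larval and adult lifespans exactly one step.
* The GA calibration replaces unavailable fitted values; it reproduces
  the qualitative scenario contrasts, not any published numeric table.
* Scenario outcomes are stochastic. The replicate counts (20) and the
  500-step horizon used in the acceptance checks are package choices;
  the original figures show single representative runs.
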