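---
title: "Evidential naming-game dynamics: model, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential naming-game dynamics: model, choices, and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(beliefgame)
```

## The model

`beliefgame` simulates how a population embedded in a social network settles
on linguistic conventions — concretely, whether speakers converge on the
regular or irregular past-tense form of each of `n` verbs. Unlike classical
naming-game agents that occupy one of a few discrete states, every agent here
carries a Dempster–Shafer belief function: a mass assignment over the
non-empty subsets of the frame

$$\Theta = \{R_1,\dots,R_n, I_1,\dots,I_n\},$$

where $R_v$/$I_v$ denote the regular and irregular form of verb $v$. Mass on
a singleton expresses committed preference for one form; mass on a composite
subset expresses genuine indecision among its members; mass on $\Theta$ is
total ignorance. The empty set carries no mass and the total is 1
(`1e-9` tolerance everywhere). Subsets are encoded as bitmasks over the fixed
element order $R_1..R_n, I_1..I_n$, and every iteration runs in ascending
bitmask order, which also resolves all argmax ties deterministically (lowest
bitmask wins).

Each round, every edge of the network activates independently with
probability `f`. An activated edge hosts social learning with probability
`p_s`, otherwise both endpoints self-learn. Three operators drive the belief
updates.

**Social learning.** For each social edge a speaker/hearer direction is drawn
with equal probability; the hearer collects the speakers of all its activated
edges into a learning set, ordered by descending weight. The weight is the
speaker's degree share in the hearer's neighbourhood,
$w_{ij} = d_j / \sum_{l\in\Gamma(i)} d_l$, an extrinsic "importance" read off
the topology. The intrinsic attribute is reliability: the cosine similarity
between mass vectors, passed through a mapping that sends similarities at or
above the threshold `r_eta` onto the trust scale `[r_fair, r_max]` (identity
below `r_eta`). Reliability of the k-th source in the sequence is recursive:
half the ego–source similarity plus the within-group pairwise similarity sum
scaled by $1/(k(k-1))$, so a source that conflicts with the ego gains
credibility once other sources corroborate it. Weight and reliability merge
into the discount coefficient $c = w/(1+w-r)$. The hearer then folds its own
(undiscounted, $w_{ii}=r_{ii}=1$) belief with each discounted source through
the weighted evidential-reasoning rule: subset-intersection products plus
cross-terms against the unassigned discount slot, renormalized at each step
(which silently discards conflicting products), with the residual unassigned
slot redistributed proportionally at the end.

Two structural facts are worth recording. First, with the coefficients held
fixed, the fold is a commutative, associative conjunctive rule — the
*sequence* matters only because the recursive reliabilities depend on each
source's position, and the *direction* matters because ego and source play
asymmetric roles. The test suite asserts both the commutativity and the
sequence effect. Second, an agent with unit mass on a singleton is absorbing:
conflicting input is discarded wholesale by the renormalization, so committed
agents never move. Final polarization-vs-consensus outcomes are therefore
decided by who commits to what, and when.

All folds within a round read the round-start snapshot of beliefs
(asynchronous updating), so the order in which hearers are processed is
immaterial.

**Self-learning.** Both endpoints of a self-learning edge reinforce the
regular form of one uniformly chosen verb: an `alpha`-fraction of the mass on
that verb's irregular singleton moves to its regular singleton. Agents
already committed to the irregular form no longer engage (and such an agent
is stable anyway). This models the regularity bias of child learners.

**Forgetting.** After learning, any agent that is not stable (maximum mass
below 1) and engaged in fewer than `eta` learning events this round forgets
with probability `p_f`: a `beta`-fraction of its largest non-$\Theta$ focal
mass moves to $\Theta$. One social fold counts as one engagement event
regardless of how many sources it folded, as does one applied self-learning
event; a skipped (committed) self-learning draw does not count. The letter of
the stability criterion also exempts an agent with all mass on $\Theta$ —
which is consistent, as it has nothing left to forget.

## Initialization

Initial beliefs are Dirichlet draws over **all** $2^{2n}-1$ non-empty
subsets, with the concentration of a subset equal to the mean of its element
concentrations: 1 per regular element, `phi` per irregular element. `phi = 1`
therefore gives equal concentration on every proposition of the power set —
the natural reading of a "no preference" start in a belief-function model —
and smaller `phi` shrinks everything containing irregular forms.

This was a genuinely open design point: the alternative of seeding only the
singletons (a Bayesian-style start) was implemented and rejected, because it
makes early commitment too fast — agents lock into their initial favourites
before network-scale alignment can occur, and heterogeneous (scale-free)
networks then stabilize far below the near-consensus the model is meant to
produce there. Full-power-set support starts agents with substantial overlap
(higher mutual similarity, hence reliability), which delays commitment and
lets hubs align the population first; the acceptance checks on all network
families pass under this choice with no other knob touched.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `f` | 0.1 | per-edge activation probability per round |
| `p_s` | 1.0 | social (vs self-) learning probability on an active edge |
| `alpha` | 0 (0.05 in self-learning studies) | self-learning rate |
| `p_f` | 0.05 | forgetting probability for eligible agents |
| `beta` | 0.04 | forgetting rate |
| `eta` | 2 | engagement threshold exempting an agent from forgetting |
| `phi` | 1 | Dirichlet concentration on irregular elements |
| `n_verbs` | 2 | verbs in the frame (15 non-empty subsets) |
| `r_max`, `r_eta`, `r_fair` | 0.95, 0.2, 0.5 | reliability mapping |
| `t_max` | 5000 | round cap |
| `stall_window` | 200 | stabilization window (below) |

## Termination and observables

"Stabilization" is not defined operationally in the underlying model
description, so the driver stops when (a) every agent is stable, or (b) no
agent's maximum-mass proposition has changed for `stall_window` consecutive
rounds, or (c) `t_max` is reached (reported with a warning). The stall rule
on the argmax proposition is the weakest criterion that makes terminal
("infinity") observables well defined; the convergence index keeps growing
slowly with longer windows (commitment is asymptotic), while the belief
index is insensitive to the window, which is why the default window of 200
rounds is acceptable at the default problem size.

Terminal observables (package functions in parentheses): the dominant
singleton $b_1$ is the max-mass singleton adhered to by the most agents
(`dominant_element`); $L_1$ is the fraction of agents with unit mass on
$b_1$ (`compute_L1`); the belief index $R$ averages $m(b_1)$ minus the
summed mass on all other singletons (`compute_R`); the local index $r$
applies the same contrast inside each known community against its own
dominant singleton, averaged over communities (`compute_local_r`); the
regularization fraction $\rho_R$ sums, over verbs, the fraction of agents
whose strongest singleton is that verb's regular form (`compute_rho_R`).
"Adhering" is max-mass adherence rather than strict commitment, so $\rho_R$
is defined even when agents never commit; $L_1$ separately captures strict
commitment. Per-round trajectories measure the same quantities against the
current round's dominant singleton.

## Networks

Watts–Strogatz, Erdős–Rényi, and Barabási–Albert graphs come from igraph
(`make_ws`, `make_er`, `make_ba`); realizations are regenerated until simple
and connected. The defaults (N = 100 with k = 10, p = 0.1, or
$n_e$ = 5) all have density near 0.1. Two generators are implemented in the
package because no installed package provides them:

* `make_gm` — the one-parameter interpolation between scale-free and
  homogeneous topologies at fixed node and edge count: a fully connected
  core of $m$ nodes, then each remaining node attaches $m$ links, each going
  to a uniformly random node with probability $\kappa$ and by preferential
  attachment otherwise. $\kappa = 0$ grows a BA-like graph; $\kappa = 1$ a
  Poisson-like homogeneous graph whose minimum degree is still $m$ — it
  "mirrors" an ER graph in its degree homogeneity, not in its low-degree
  tail.
* `make_lfr` — an LFR-style community benchmark: power-law degrees (exponent
  `tau1`, truncated so the mean hits `avg_deg`), power-law community sizes
  (`tau2`), and external stubs allocated by largest remainder so the global
  inter-community edge fraction matches `mu`; internal and external stubs
  are paired by configuration-model matching with iterative rewiring of
  invalid pairs. Realizations must have exactly the requested number of
  communities and be connected (per community when `mu = 0`, since zero
  mixing disconnects communities by construction). This reproduces the
  benchmark's defining statistics — degree and community-size distributions
  and the mixing fraction — but is not byte-identical to the reference
  implementation's rewiring schedule.

Zachary's karate club is bundled (via igraph) with its two canonical
factions; the college-football network is deliberately not bundled and must
be supplied as a GML file.

## Problem sizes and reproducibility

All shipped checks run at the study's scale of N = 100 (34 for karate):
single runs stabilize in a few hundred to a few thousand rounds and take
tens of milliseconds thanks to the compiled driver, so the acceptance
checks afford 100–200 replicates for the small-world scenarios, 40
fresh-realization replicates for the community benchmark, and 15–20 per cell
of the self-learning/forgetting grid. Every random element — initialization,
activations, directions, verb choices, forgetting draws, and all generators —
goes through R's RNG, so `(seed, config, graph)` determines a trajectory
bit-for-bit; replicates derive per-replicate seeds from one master seed.
Comparisons across a parameter sweep reuse the same master seed per point
(common random numbers), which sharpens between-point contrasts without
touching the marginal distributions.

## What the generators do and do not emulate

The synthetic families isolate single structural factors: clustering and
path length (WS), degree homogeneity (ER/GM at $\kappa=1$), hub dominance
(BA/GM at $\kappa=0$), and mesoscale modularity (LFR, karate). Passing
checks on them demonstrates that the implementation reproduces the model's
qualitative and quantitative behaviour *under those controlled conditions* —
half-converged polarization on small worlds, near-consensus on heterogeneous
graphs, local-versus-global consensus splits under community structure, and
self-learning-driven regularization. They do not establish anything about
real conversational networks, which are weighted, dynamic, assortative, and
in which belief exchange is not restricted to a fixed two-form frame.

## Known limitations

* Commitment is absorbing by construction; any quantity that depends on the
  exact commitment times (notably $L_1$) grows slowly with the stall window,
  so terminal $L_1$ is mildly conservative under the default window.
* The belief index on the default small-world scenario stabilizes slightly
  above zero (about +0.14), at the edge of the ±0.15 acceptance band around
  the study's "approximately zero" reading.
* In the self-learning grid, the scale-free cell with `p_s = 1` and
  `p_f = 0` — no self-learning events and no forgetting, i.e. pure social
  learning — stabilizes near $R \approx 0.83$, below the ≈1 claimed for the
  grid at large; with forgetting on (the configuration the study actually
  displays), the scale-free index is ≈0.95.
* Frames beyond ~5 verbs make the $O(4^{2n})$ combination step expensive;
  the implementation caps `n_verbs` at 8.

## A worked run

```{r}
g <- make_ws(100, 10, 0.1)
res <- sim_run(g, sim_config(), seed = 42)
res
head(res$trajectory[, 1:5])
```

```{r}
agg <- sim_replicate(load_fixture("karate"), sim_config(), n_reps = 20,
                     seed = 5)
agg
```

The karate-club factions illustrate the community effect: the local belief
index `r_local` sits near 1 (each faction internally unanimous) while the
global index `R` is far lower — the two factions often settle on different
conventions.
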