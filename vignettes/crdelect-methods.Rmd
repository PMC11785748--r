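---
title: "Electoral institutions in the collective risk dilemma: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electoral institutions in the collective risk dilemma: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`crdelect` studies how group-level, endogenously created institutions change
the prospects of cooperation in the collective risk dilemma (CRD) — a
threshold public goods game in which a group of `N` players keeps its
endowment `b` only if at least `n_pg` of them contribute a fraction `c` of
it; otherwise every member loses everything with probability `r` (the
"risk"). The CRD is the standard stylised model of global commons problems
with a real chance of collective failure, climate-change mitigation being
the usual motivating example.

Four behavioural types are modelled. Cooperators (C) contribute to the
public good. Punishers (P) and rewarders (R) contribute as well, and
additionally pay a tax `pi_t` towards a *local institution* that forms in a
group whenever at least `n_I` taxed players are present. The institution's
budget is the collected taxes amplified by a return factor `delta`. What the
institution does is decided by majority vote among its funders: if
rewarders outnumber punishers the budget is split equally among the group's
pro-socials (C, P and R); if punishers outnumber rewarders it is levied in
equal fines from the group's defectors; a tied vote commits half the budget
to each use. Defectors (D) contribute nothing and pay no tax.

Per-group payoffs are exact expectations over the risk event:

* base payoff: `b` if the contributor count meets `n_pg`, else `(1 - r) b`;
* C: base − `c b` + reward share;
* P and R: the C payoff minus the tax `pi_t` (P and R always earn the same);
* D: base − fine share.

Reward shares divide the budget by the number of pro-socials in the group,
fine shares by the number of defectors; both are only ever evaluated in
groups where the receiving type is present, so the divisors are positive.

Three reduced variants are obtained by restricting the same payoff
functions to faces of the strategy simplex: reward-only institutions (no
P), punishment-only institutions (no R), and the bare CRD (C and D only).
These restrictions reproduce earlier single-instrument institution models
inside one framework, which is what makes their risk curves directly
comparable.

## Evolutionary dynamics

A well-mixed population of fixed size `Z` evolves by a discrete-time
selection–mutation process. The fitness of a strategy in population state
`i` is its expected group payoff when `N − 1` co-players are drawn without
replacement from the remaining `Z − 1` individuals (multivariate
hypergeometric sampling). In one elementary step, a randomly chosen
individual either mutates (probability `mu`) or imitates a randomly chosen
other individual with probability given by the Fermi function
`1 / (1 + exp(-beta (f_other - f_own)))`, where `beta` is the selection
strength. These one-step moves define a Markov chain on the simplex of
strategy counts; with `mu > 0` the chain is irreducible and its stationary
distribution — the leading eigenvector of the transposed transition matrix
— describes where the population spends its time in the long run.

**Mutation kernel.** A mutating individual draws its new strategy uniformly
from the other three behavioural types of the *full* strategy set, so each
alternative is reached with probability `mu/3` per step. In reduced
variants, draws toward excluded types are void (the individual keeps its
strategy). We adopted this convention — rather than renormalising mutation
over the variant's own `S − 1` active strategies — because it keeps the
mutation kernel identical across all four variants, which is the premise of
comparing their risk curves within one framework; the four-strategy model
is unaffected by the choice. The realised per-individual mutation rate in a
reduced variant is therefore `mu (S − 1)/3`.

Summary observables:

* `a_G(i)`: the probability that a randomly sampled group of `N` meets the
  contribution threshold in state `i` (hypergeometric average);
* `eta_G`: `a_G` averaged over the stationary distribution — the headline
  scalar for comparing institutional designs;
* the critical risk `r*`: the risk at which `eta_G(r)` crosses 1/2;
* stationary strategy abundances, the per-state gradient of selection
  (expected one-step drift of each strategy count), incentive incidence
  (how much reward and punishment institutions hand out, and how often
  votes go each way), and attractor reports.

## Default study conditions

Two presets fix the parameter sets used throughout the documentation and
the acceptance suite:

* `crd_preset("attractor")`: `Z = 70`, `mu = 1/70`, `beta = 5`, `r = 0.8` —
  strong selection in a moderate population, where the dynamics is shaped
  by a cooperative attractor (cooperator-dominated, with small persistent
  P and R reservoirs) coexisting with a near-all-defector attractor;
* `crd_preset("sweep")`: `Z = 140`, `mu = 1/140`, `beta = 2` — the
  risk-curve setting for comparing the four variants.

Both share `N = 8`, `n_pg = 6`, `n_I = 2`, `b = 1`, `c = 0.1`, `delta = 2`,
`pi_t = 0.03`: groups of eight needing six contributors, a 10% contribution,
a 3% institution tax with a twofold return, and a two-member quorum for
institution formation.

## Numerical choices

* **State space.** States are enumerated lexicographically over the active
  strategy counts; ranks are computed in O(S) by the combinatorial number
  system, so the transition matrix is assembled in one pass. The
  four-strategy space at `Z = 140` has 477,191 states and about 6.7 million
  one-step transitions.
* **Payoff table.** Group payoffs are precomputed once per parameter set
  for all compositions of `N − 1` co-players (120 for four strategies), so
  per-state fitness is a short weighted sum; this is what makes `Z = 140`
  sweeps tractable on a single CPU.
* **Stationary solve.** For large chains the solver grounds one reference
  state in the dominant basin (located by a short power iteration), fixes
  its unnormalised probability to one, and solves the resulting
  non-singular sparse linear system with Jacobi-preconditioned BiCGSTAB.
  This sidesteps the metastability problem: near the cooperation
  transition the transition matrix has a second eigenvalue extremely close
  to one (slow tunnelling between basins), which stalls restarted
  eigensolvers but costs a Krylov linear solve only a few iterations. A
  sparse Arnoldi eigensolver (subspace ladder 30, 60, 150) remains as a
  fallback, and systems of fewer than ten states use a dense
  eigendecomposition. Whatever the path, the solution is accepted only if
  the L1 residual of stationarity is at most `1e-10`; tiny negative
  entries are clamped to zero before renormalising. The residual contract,
  not the solver, is the specification: unit tests compare the large-chain
  path against dense eigendecompositions on small instances.
* **Diagonal completion.** Stay-put probabilities are completed as one
  minus the off-diagonal row sum; values below `-1e-12` abort (they would
  indicate an invalid parameter set), smaller negatives are clamped.
* **Critical risk.** `eta_G(r)` is S-shaped and monotone in `r` for this
  model family (a property the test suite checks on a grid), so `r*` is
  located by bisection after verifying that the bracket endpoints straddle
  the target, to a final bracket width of `1e-3` — matching the three
  decimals to which such thresholds are conventionally reported. A
  non-straddling bracket returns a structured no-crossing result rather
  than an error. We bisect directly instead of first scanning a coarse
  grid: with monotonicity checked separately, the scan would add a dozen
  large eigensolves per variant without changing the answer.
* **Attractors.** On a discrete simplex there is no canonical definition of
  an attractor. `find_attractors` reports strict local maxima of the
  stationary distribution over one-step neighbourhoods, each corroborated
  by its gradient-of-selection norm. Note that at small mutation rates the
  stationary mass concentrates on low-dimensional faces (states with an
  absent strategy), so the global mode can sit on the boundary even when
  the drift field has an interior rest point; the drift-norm column is the
  right guide in that situation, and `gradient_field` gives the full
  picture.
* **Trajectory classification.** The distinction between rewarder-led and
  punisher-led escapes from defection is operationalised as: convergence =
  first entry into the one-step (L1 distance 2) neighbourhood of the
  cooperative attractor; the label compares the peak P and R counts before
  convergence. The underlying notion is qualitative; the defaults
  (start at all-D, peak-count comparison) are one reasonable choice and are
  configurable.
* **Reproducibility.** Every stochastic routine takes an explicit seed;
  ensembles derive per-trajectory seeds from a master seed. Exported CSVs
  serialise floats at 12 significant digits so identical runs are
  byte-identical.

## What the engine does and does not emulate

The model is an idealisation: infinite well-mixedness (every group equally
likely), synchronousless one-step updates, exact expected payoffs (the risk
event is never sampled), and a single homogeneous endowment. Passing tests
demonstrate the exact stochastic dynamics of *this* model; they say nothing
about structured populations, heterogeneous wealth, sampled risk, or
time-varying thresholds, all of which are outside scope.

## Known limitations and honest discrepancies

* A four-strategy `Z = 140` chain build-and-solve takes roughly 15-25
  seconds on one CPU, so a bisection for `r*` at that size runs in a few
  minutes and full risk grids in under ten; risk grids default to a 0.05
  step for that reason.
* For the four-strategy electoral model at the `sweep` parameters, this
  implementation of the printed payoff and update rules places the
  `eta_G = 1/2` crossing near `r* ≈ 0.58`, i.e. electoral institutions are
  *more* effective here than the `r* ≈ 0.640` reported for the same
  parameter values in the literature this model family comes from; the
  reduced variants agree far more closely (within 0.005–0.02). We verified
  the two-strategy chain against an independent detailed-balance
  computation and the fitness and group-sampling machinery against
  exhaustive enumeration, and examined several alternative readings of the
  institutional rules (conditional taxes, per-camp budgets and quorums,
  tie-voided budgets, success-conditional rewards) — none reproduces the
  reported number better while remaining consistent with the printed
  equations. The discrepancy is documented rather than tuned away.
* At the `attractor` preset the cooperative rest point of the drift field
  sits at (C=51, P=5, R=6, D=8) with stationary abundances
  (C≈51.7, P≈4.9, R≈6.6, D≈6.8); reported reference values for the same
  setting place the attractor at (52, 6, 7, 5). The P abundance matches to
  rounding; the R abundance and the attractor's defector count differ
  slightly, consistent with the direction of the `r*` discrepancy above.
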