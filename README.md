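# crdelect

Exact stochastic evolutionary dynamics for the **collective risk dilemma
(CRD) with electoral institutions** — a finite-population engine for asking
when groups facing a risky threshold public goods game will self-organise
cooperation, and how much group-level institutions that *vote* on whether
to reward contributors or punish free-riders help.

It is written for researchers in evolutionary game theory and behavioural
ecology who want reproducible, exact (not simulated) stationary statistics
for this model family, plus seeded Monte Carlo trajectories for dynamical
questions.

## The model in brief

A well-mixed population of `Z` individuals plays a CRD in groups of `N`:
each contributor pays a fraction `c` of the endowment `b`, and a group that
gathers fewer than `n_pg` contributors loses everything with probability
`r`. Strategies are cooperators (C), punishers (P), rewarders (R) — all
three contribute, P and R additionally pay a tax `pi_t` towards a local
institution — and defectors (D). An institution forms in a group when at
least `n_I` taxed players are present; its budget is
`Delta = delta * pi_t * (j_P + j_R)`, and a majority vote among the P's and
R's decides its use: rewards split equally among the group's pro-socials
(`j_R > j_P`), fines levied equally on defectors (`j_P > j_R`), or half
each on a tie.

Evolution follows the pairwise-comparison rule: a focal player imitates a
random other with probability `1/(1 + exp(-beta * (f_other - f_own)))`,
where fitness `f` is the expected payoff under hypergeometric sampling of
`N - 1` co-players; with probability `mu` the player instead mutates to a
random other strategy. The exact one-step Markov chain over all
`C(Z+S-1, S-1)` population states is assembled sparsely, and the stationary
distribution is obtained as the leading eigenvector of its transpose.

Headline observables: the population-average group achievement `eta_G`
(long-run probability that a random group meets the threshold), the
critical risk `r*` where `eta_G` crosses 1/2, stationary strategy
abundances, attractors, and the incidence of rewards vs. fines. Setting the
variant to `"reward"`, `"punish"` or `"none"` restricts the same equations
to the corresponding simplex face, reproducing reward-only,
punishment-only, and institution-free baselines inside one framework.

## Worked example

```r
library(crdelect)

p <- crd_params(Z = 50, N = 8, n_pg = 6, n_I = 2, b = 1, c = 0.1,
                r = 0.75, delta = 2, pi_t = 0.03, mu = 1/50, beta = 2)

st <- stationary_distribution(p)
st
#> <crd_stationary> electoral, Z=50, 23426 states, residual 2.08e-15
#>   p = 0.001562 at (C=50, P=0, R=0, D=0)
#>   p = 0.001143 at (C=45, P=0, R=0, D=5)
#>   p = 0.00113 at (C=44, P=0, R=0, D=6)

round(stationary_abundance(st), 2)
#>     C     P     R     D
#> 22.50 10.04 11.81  5.65

eta_G(st)
#> [1] 0.9063546

incidence_of_incentives(st)$frac_reward
#> [1] 0.4978502
```

At these settings the modal population state is fully cooperative, the
long-run strategy mix keeps sizeable reservoirs of punishers and rewarders
(10–12 individuals each, taxed but protected by the institutions they
fund), defectors are held to about 11% of the population, about 91% of
randomly formed groups would meet the contribution threshold, and formed
institutions split almost evenly between rewarding and punishing.

The critical risk for a variant:

```r
critical_risk(crd_preset("sweep", variant = "none"))
#> <crd_critical_risk> r* = 0.7651 (target 0.5, bracket [0.7646, 0.7656], eta_G 0.4950..0.5021)
```

Command-line interface (same functionality, shell-friendly):

```sh
inst/cli/crd risk-curve --preset sweep --variant electoral \
    --r-grid 0.4:0.9:0.05 --out curve.csv
inst/cli/crd attractors --preset attractor --out attractors.json
```

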