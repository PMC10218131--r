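# mobgame

Evolutionary "mobilization–participation" games on emergency resource
networks.

When a public-health emergency strikes, resource support depends on two
kinds of actors: **government resource subjects** (GRSs — emergency-management
departments, reserve agencies) that choose whether to *mobilize* positively,
and **social resource subjects** (SRSs — enterprises, charities, volunteer
groups) that choose whether to *participate* positively. `mobgame` is for
researchers in emergency management and evolutionary game theory who want to
study how rewards, penalties, and initial conditions shape the collective
outcome of that interaction. It provides:

* the asymmetric two-role payoff model with reward/penalty interventions,
* a mean-field replicator-dynamics analyzer (expected gains, fixed points,
  Jacobian stability classification, RK4 trajectory integration),
* a typed-network data model with CSV/GraphML I/O and a synthetic generator
  emulating a 19-GRS / 49-SRS case network,
* a complex-network game engine (Boltzmann learning-object selection, Fermi
  strategy adoption, synchronous rounds, replicated trajectories), and
* scenario runners for the canonical baseline, initial-condition, reward,
  and penalty experiments.

## The model in brief

A cross-type encounter pays off by the matrix (SRS payoff first):

| SRS \ GRS | positive | negative |
|---|---|---|
| **positive** | π<sub>e</sub>−c<sub>e</sub>+γ, π<sub>g</sub>−c<sub>g</sub> | π<sub>e</sub>−c<sub>e</sub>, −c<sub>v</sub> |
| **negative** | π<sub>e</sub>−δ, π<sub>g</sub>−c<sub>g</sub>+βδ | π<sub>e</sub>, −c<sub>v</sub>−c<sub>s</sub> |

Mean-field, the positive fractions (m, r) of the two roles follow the
replicator equations

```
dm/dt = m(1−m)(r(γ+δ) − c_e)
dr/dt = r(1−r)(π_g − c_g + βδ + c_s + c_v − m(c_s + βδ))
```

whose five equilibrium candidates (four corners plus an interior point
m\* = (π_g−c_g+βδ+c_v+c_s)/(βδ+c_s), r\* = c_e/(γ+δ)) are classified by the
Det/Tr sign pattern of the analytic Jacobian. On a network, each node sums
the payoff-matrix gains over its cross-type neighbors each round, picks one
neighbor to observe with Boltzmann probability ∝ exp((u_j+α_j)/λ), and
adopts the observed strategy with Fermi probability
ω = 1/(1+exp((u_i−u_j)/ξ)).

## Worked example

```r
library(mobgame)

p <- game_params(delta = 2.4)   # baseline payoffs, penalty switched on
find_fixed_points(p)
#>      point         m         r exists      det_j  tr_j     stability
#> 1    (0,0) 0.0000000 0.0000000   TRUE -3.4400000 -0.28        SADDLE
#> 2    (0,1) 0.0000000 1.0000000   TRUE -0.6880000 -1.32        SADDLE
#> 3    (1,0) 1.0000000 0.0000000   TRUE -2.0000000  1.00        SADDLE
#> 4    (1,1) 1.0000000 1.0000000   TRUE -0.4000000  0.60        SADDLE
#> 5 interior 0.6323529 0.8333333   TRUE  0.2107843  0.00 NONHYPERBOLIC
```

With δ = 2.4 the penalty exceeds the participation cost (γ+δ > c_e = 2), so
the all-negative-SRS corner loses stability: every corner is a saddle and an
interior candidate appears at m\* = 1.72/2.72 ≈ 0.63, r\* = 2/2.4 ≈ 0.83
(a center candidate, Tr J = 0). Without intervention the same call reports
(0,1) — SRSs negative, GRSs positive — as the unique stable sink
(Det J = 2, Tr J = −3).

The networked game, at the no-intervention baseline:

```r
net <- generate_network(generator_config(seed = 1))
net
#> Typed network: 19 GRS + 49 SRS nodes, 136 edges, connected

traj <- run_simulation(simulation_config(network = net, m0 = 0.1, r0 = 0.4,
                                         seed = 1))
traj
#> Networked game trajectory: 20 replicate(s) x 100 rounds
#>   final replicate-mean PPS (last 20 rounds): 0.0556
#>   replicates quiescent before horizon: 9 of 20
```

Starting from 10% positive SRSs and 40% positive GRSs, the proportion of
positive strategies (PPS) collapses: negative SRSs out-earn positive ones by
c_e per game, and GRSs imitate their high-earning negative SRS neighbors, so
the system ends near the all-negative absorbing state (a few frozen positive
nodes remain; see the vignette's *Limitations*). The canonical experiments
are one call each:

```r
run_scenario(scenario_penalty_sweep(seed = 1), out_dir = "out")
run_scenario(scenario_initial_conditions(gamma = 0.6, seed = 1))
```

A thin command-line wrapper over the same functions ships at
`inst/cli/mobgame.R` (`generate-network`, `meanfield`, `simulate`,
`reproduce <scenario>`).

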