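# neqdecide

Non-equilibrium thermodynamics of bounded-rational decision-making, in R.

## The problem

A decision-maker with limited information-processing resources cannot simply
pick the argmax of a utility function. A standard way to model this is to let
the decision-maker trade off expected utility against the informational cost
of moving away from a prior strategy `p0`:

    ΔF[p] = Σ_x p(x) ΔU(x) − (1/β) KL(p ‖ p0)

The optimum is the Boltzmann-like *equilibrium strategy*
`p_eq(x) ∝ p0(x) exp(β ΔU(x))`, with certainty-equivalent value
`ΔF = (1/β) log Z_β`. The inverse temperature `β` interpolates between no
processing at all (`β → 0`, the prior) and perfect rationality (`β → ∞`, the
maximizer).

When the utility landscape *changes over time* — externally driven, like a
protocol dragging an energy function — a decision-maker with finite
adaptation or deliberation time cannot follow the path of equilibrium
strategies. Its behaviour is then a non-equilibrium stochastic process, and
the machinery of stochastic thermodynamics applies:

- utility gains play the role of work; for deliberating agents the *net*
  utility subtracts a per-step deliberation cost
  `(1/β) log[p(x_n|x_{n−1}, t_n) / p(x_n|x_{n−1}, t_{n−1})]`;
- the dissipated utility `U_diss = ΔF − U_net ≥ 0` quantifies the
  performance lost to lag or limited deliberation (a second law);
- a Crooks fluctuation theorem holds trajectory-wise,
  `p(x)/p†(x) = exp(β U_diss(x))`, comparing forward trajectories with
  trajectories of the time-reversed protocol;
- a Jarzynski equality, `⟨exp(β U_net)⟩ = exp(β ΔF)`, lets one estimate the
  equilibrium free-energy difference from finite-time decision trajectories.

The package implements this framework end to end for audiences in
computational cognitive science and anyone studying resource-rational
agents: equilibrium policies and free energies, two sampling decision
mechanisms (rejection sampling with an aspiration level; Metropolis–Hastings
in discrete and continuous action spaces) with their anytime finite-budget
behaviour, trajectory-level thermodynamic ledgers with exhaustive-enumeration
oracles for both theorems, one-step-lag adaptation and quasi-static limits,
Bayesian inference as free-energy maximization (surprise and dissipation as
functions of batch size), and Langevin (Ornstein–Uhlenbeck) deliberation
dynamics with closed-form Fokker–Planck solutions.

## A worked example

Two actions, uniform prior, a utility advantage of 1 for the first action at
`β = 1`:

```r
library(neqdecide)

prior <- uniform_policy(2)
du    <- utility_tabular(c(1, 0), prior$labels)

policy_prob(equilibrium_policy(prior, du, beta = 1))
#>        a1        a2
#> 0.7310586 0.2689414          # e/(1+e): soft-max, not arg-max

equilibrium_free_energy(prior, du, beta = 1)
#> [1] 0.6201145               # log((e+1)/2), between mean 0.5 and max 1

expected_sample_count(prior, du, beta = 1)
#> [1] 1.462117                # prior draws needed per accepted decision
```

A decision-maker interrupted after `k = 3` proposal draws acts by the anytime
mixture and pays for it in dissipation:

```r
p3 <- anytime_rejection_policy(prior, du, beta = 1, k = 3)
policy_prob(p3)
#>        a1        a2
#> 0.7237635 0.2762365

dF <- equilibrium_free_energy(prior, du, 1)
u_net <- free_energy_functional(p3, du, prior, 1)
dissipated_utility(u_net, dF)
#> [1] 0.0001345783            # tiny here; grows with beta and shrinks with k
```

Trajectory thermodynamics on a random three-epoch protocol, verified by
exhaustive enumeration:

```r
set.seed(42)
prior <- policy(runif(3) + 0.2)
prot  <- utility_protocol(lapply(1:3, function(i)
           utility_tabular(runif(3), prior$labels)))
ks  <- protocol_kernels(prot, prior, beta = 1.7, sweeps = 2)
X   <- enumerate_trajectories(prior$labels, 3)
led <- thermo_ledger(X, prot, ks, beta = 1.7, prior)

max(abs(led$log_crooks_lhs - led$log_crooks_rhs))  # Crooks, per trajectory
#> [1] 9.367507e-16
jarzynski_exact(led$u_net, led$logp_fwd, 1.7) - exp(1.7 * attr(led, "delta_f"))
#> [1] -2.220446e-16                                # Jarzynski, exactly
```

Experiment runners return tibbles (`run_bayes_batches()`,
`run_hysteresis()`, `run_episodic()`, `run_langevin()`, `run_lag_curve()`),
have `plot_*()` companions, and are also reachable from the shell via the
thin CLI in `exec/neqdecide`:

```sh
Rscript exec/neqdecide bayes-batches --seed 1 --out results/
```

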