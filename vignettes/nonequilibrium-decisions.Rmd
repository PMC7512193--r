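---
title: "Non-equilibrium relations for bounded-rational decision-making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-equilibrium relations for bounded-rational decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqdecide)
```

## The model

A bounded-rational decision-maker over a finite action set maximizes the
free-energy functional

$$\Delta F[p] = \sum_x p(x)\,\Delta U(x) - \tfrac{1}{\beta}\,
  D_{\mathrm{KL}}(p \,\|\, p_0),$$

trading utility gain against the informational distance from its prior
strategy $p_0$. The optimum is the equilibrium strategy
$p^{\mathrm{eq}}(x) \propto p_0(x) e^{\beta \Delta U(x)}$, and the value at
the optimum is the certainty-equivalent $\Delta F = \beta^{-1}\log Z_\beta$.
The inverse temperature $\beta \ge 0$ converts informational units (nats)
into utility units; we treat $\beta U$ as dimensionless throughout, since no
absolute utility scale is assumed anywhere in the framework — only products
$\beta \times$ utility ever enter a probability.

When the utility landscape is a time-indexed protocol
$U(x, t_0), \dots, U(x, t_N)$ driven externally (the decision-maker's actions
never influence the schedule), behaviour is a Markov process
$p(\mathbf{x}) = p(x_0|t_0)\prod_n p(x_n|x_{n-1}, t_n)$ that in general
cannot follow the equilibrium path. Three regimes are implemented:

* **no-deliberation** — the action must be emitted before any adaptation;
  the work analog is the utility change at the held action,
  $\sum_n [U(x_{n-1}, t_n) - U(x_{n-1}, t_{n-1})]$;
* **deliberation** — the agent partially adapts before acting; the net
  utility subtracts the deliberation cost
  $\beta^{-1}\log[p(x_n|x_{n-1}, t_n)/p(x_n|x_{n-1}, t_{n-1})]$, the
  change in conditional stochastic entropy;
* **episodic fixed-prior** — independent episodes that always restart from
  the same prior, with per-episode choice distributions (e.g. the anytime
  mixture).

In all three, dissipation is $U_{\mathrm{diss}} = \Delta F - U_{\mathrm{net}}$,
the Crooks relation $p(\mathbf{x})/p^\dagger(\mathbf{x}) =
e^{\beta U_{\mathrm{diss}}(\mathbf{x})}$ holds trajectory-wise, and the
Jarzynski equality $\langle e^{\beta U_{\mathrm{net}}}\rangle =
e^{\beta \Delta F}$ holds in expectation, provided every per-epoch kernel
satisfies detailed balance with respect to its epoch's equilibrium and both
temporal directions start in equilibrium.

### Conventions that matter

* **Epoch-0 conditional.** In the deliberation regime the conditional in
  force at $t_0$ is, by default, the equilibrium policy at $t_0$ independent
  of the conditioning state (a rank-one kernel): the agent starts adapted,
  and this is the convention under which the theorems' standard proofs
  proceed. The implementation also accepts any detailed-balanced kernel at
  epoch 0 (`protocol_kernels(..., epoch0 = "mh")`); both the Crooks and
  Jarzynski identities survive, which the enumeration tests check for both
  conventions. The continuous (Langevin) reproduction uses the
  Ornstein–Uhlenbeck transition kernel at epoch 0 for exactly this reason.
* **Two path-scoring conventions.** Discrete theorem checks use the *exact
  kernel* convention, in which Metropolis–Hastings rejection mass sits on
  the diagonal and the kernel is a proper stochastic matrix. The hysteresis
  analysis additionally implements the *accepted-move product*
  (`accepted_path_logprob()`), which scores only accepted moves and is not
  the full MH path measure. The two conventions are never mixed within one
  computation; the accepted-move form is kept because it is the natural
  observable when only distinct actions are recorded.
* **Backward process.** Reversed-protocol probabilities start from the
  final epoch's equilibrium and use the detailed-balance reversal of each
  epoch kernel (which, for reversible kernels, is the kernel itself applied
  in the reverse direction).

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `beta` | inverse temperature, (utility)$^{-1}$ | per call | the resource level under study |
| `T` | aspiration level, utility units | `max ΔU` | the most efficient valid sampler; larger values cost draws by `exp(β(T−maxΔU))` |
| `k` | anytime budget (draws / chain steps) | per call | the finite-time resource |
| `sweeps` | MH sweeps per epoch | 1 | one deliberation step per epoch; powers of a reversible kernel stay reversible |
| `sigma_p` | random-walk proposal sd | 0.1 (hysteresis) | order of the equilibrium sd at β = 22.5, giving healthy acceptance rates |
| `alpha`, `D` | Langevin learning rate and noise | per call | only the products `c = 2αa` and `αD` matter; `D` is set to `1/(αβ)` to realize a target β |
| `dt` | Langevin time step | `1e-3` | keeps `c·dt ≤ 0.01` for the default tasks, so discretization bias is far below Monte-Carlo error |
| burn-in | discarded chain prefix | `1e3` | conservative for the chain lengths used |

## The synthetic-data generator and study conditions

All inputs are generated in code; the generator defaults *are* the study
conditions:

* **Batched inference**: $T = 100$ observations from
  $\mathcal{N}(\mu_d = 5, \sigma_d^2 = 4)$, batch sizes
  $\{100, 50, 25, 20, 10, 5, 2, 1\}$, conjugate known-variance learner. The
  learner's prior is $\mathcal{N}(0, 10^2)$: broad relative to the data
  scale, so the posterior is data-dominated; the identities tested (constant
  $\Delta F$, first law $\Delta F + S = U_{\mathrm{diss}}$, monotone
  dissipation) hold for any proper prior.
* **Hysteresis**: tracking utility $U(x) = -(x-\mu)^2$, $\beta = 22.5$,
  proposal sd $0.1$, 80 trials, $\mu: 0 \to 1$ either instantly or in 23
  steps; 200 replicates for the dissipation comparison.
* **Episodic eight-option task**: uniform prior $1/8$; the two per-episode
  utility vectors are synthetic stand-ins (the original task defines them
  only graphically), so every check on this task is invariant-based —
  monotonicity in $k$, $k$-invariance of $\Delta F$, second law — rather
  than value-based.
* **Continuous deliberation**: $U_1(x) = -(0.2x^2 - 0.4x) - 0.8$ and
  $U_2(x) = -(0.4x^2 - 1.8x) + 1.025$ with prior $\mathcal{N}(0, 1)$. The
  printed coefficient lists for these landscapes admit a convex reading; we
  adopt the concave mapping (curvatures $0.2$ and $0.4$), because only a
  concave landscape yields normalizable equilibria and a mean-reverting
  closed-form law.
* **Random discrete instances** for the theorem oracles: 2–5 actions, 2–4
  epochs, i.i.d. uniform utilities, $\beta \in [0.3, 3]$ — small enough for
  exhaustive enumeration, which is the independent oracle.

What the generator does *not* emulate: real response data (choice
stochasticity beyond the model class, non-stationary $\beta$, model
misspecification in the inference task). Passing tests therefore certify
the mathematics and the implementation under the model's own assumptions,
not the behavioural adequacy of the model for any organism.

## Numerical choices

* All probability arithmetic is in the log domain with log-sum-exp;
  $\beta$ up to 22.5 with quadratic utilities overflows linear-domain
  exponentials.
* $\beta = 0$ is an explicit limit branch: the equilibrium policy returns
  the prior, and the free energy returns the prior-expected utility flagged
  as a limit value.
* Jarzynski averages are computed as
  $\mathrm{logsumexp}(\beta U_{\mathrm{net}}) - \log n$; standard errors use
  plain sample variance (no bootstrap), since all stochastic checks use
  3–4σ bands.
* Utility offsets are carried in the quadratic form but cancel in all
  Δ-quantities.
* Trajectory enumeration is capped at $10^6$ paths; larger requests error
  with guidance to sample.
* The anytime sampler, when its budget is exhausted, emits a fresh prior
  draw. This is the rule that makes the mixture
  $(1-q_k)p^{\mathrm{eq}} + q_k p_0$ with $q_k = (1 - Z_\beta e^{-\beta T})^k$
  exact, as the simulation-versus-closed-form tests confirm.
* Ties in the maximum utility at large $\beta$ resolve to an even split
  across the argmax set, by the symmetry of the Boltzmann form.
* The Langevin effective temperature is **derived**, not quoted: for the
  SDE $\dot x = \alpha U'(x) + \alpha\xi$, $\langle\xi\xi'\rangle =
  2D\delta$, the moment equations give stationary variance $\alpha D/(2a)$,
  hence $\beta_{\mathrm{eff}} = 1/(\alpha D)$. A relation
  $\beta = 2\alpha D$ circulates in the literature for this setup but is
  inconsistent with the stationary Fokker–Planck solution of this SDE (and
  with the qualitative statement that less noise means more precision);
  `effective_beta(..., printed = TRUE)` exposes it for comparison. The
  variance prefactor of the closed-form law is likewise derived from the
  moment ODEs (and unit-tested against an independent ODE integration)
  rather than transcribed.
* "Quasi-static" is operationalized as $N = 4096$ sub-steps with tolerance
  $10^{-3}$, rather than a symbolic limit. On the Gaussian test instance the
  dissipation is exactly $1/N$, so the limit behaviour is known analytically.

## Problem sizes

Test and reproduction sizes are chosen so the whole suite runs comfortably
on a single core: $10^5$ decisions for sampler-exactness checks, $10^4$
trajectories for Monte-Carlo Jarzynski checks, $2\times10^4$ particles for
Langevin ensembles, 200 replicates for the hysteresis comparison, and
exhaustive enumeration ($\le 5^5$ paths) for every theorem oracle. These are
the package's reference conditions; all runners scale up by argument.

## A compact demonstration

```{r demo}
set.seed(1)
inst_prior <- policy(runif(3) + 0.2)
prot <- utility_protocol(lapply(1:3, function(i)
  utility_tabular(runif(3), inst_prior$labels)))
ks <- protocol_kernels(prot, inst_prior, beta = 1.5, sweeps = 2)
X <- enumerate_trajectories(inst_prior$labels, 3)
led <- thermo_ledger(X, prot, ks, beta = 1.5, inst_prior)

# Crooks, trajectory-wise, and Jarzynski, in expectation:
max(abs(led$log_crooks_lhs - led$log_crooks_rhs))
jarzynski_exact(led$u_net, led$logp_fwd, 1.5) - exp(1.5 * attr(led, "delta_f"))

# the quasi-static staircase
run_lag_curve(Ns = c(1, 4, 16, 64, 256, 1024, 4096))
```

## Known limitations

* Temperature is constant along a protocol (isothermal transformations
  only); $\beta$-varying protocols are out of scope.
* No bidirectional free-energy estimators (e.g. acceptance-ratio methods);
  the Jarzynski estimator is one-sided and inherits its usual heavy-tail
  variance at large $\beta \Delta F$.
* Continuous utilities are quadratic only — the regime with closed-form
  non-equilibrium laws; non-quadratic landscapes would require numerical
  Fokker–Planck solutions.
* The Gaussian inference path is implemented at $\beta = 1$ (exact Bayes);
  tempering at other $\beta$ is available for discrete hypothesis spaces.
* One-step-lag learners assume perfect adaptation after one step; partially
  adapted lag learners are not modelled.
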