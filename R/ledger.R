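#' Equilibrium policy for one epoch of a tabular protocol
#'
#' @param protocol A tabular `br_protocol`.
#' @param prior Base-measure policy (the fixed prior `p0`).
#' @param beta Inverse temperature.
#' @param epoch Epoch index `0..N`.
#' @return A `br_policy`, `p_eq(x, t) = prior(x) exp(beta U(x, t)) / Z_t`.
#' @export
protocol_equilibrium <- function(protocol, prior, beta, epoch) {
  stopifnot(inherits(protocol, "br_protocol"), protocol$form == "tabular")
  equilibrium_policy(prior, protocol$epochs[[epoch + 1]], beta)
}

#' Log partition function of one epoch
#' @inheritParams protocol_equilibrium
#' @return `log Z_t = log sum_x prior(x) exp(beta U(x, t))`.
#' @export
protocol_log_z <- function(protocol, prior, beta, epoch) {
  stopifnot(inherits(protocol, "br_protocol"), protocol$form == "tabular")
  logsumexp(prior$lp + beta * protocol$epochs[[epoch + 1]]$values)
}

#' Equilibrium free-energy difference of a protocol
#'
#' `dF = (1/beta) (log Z_N - log Z_0)`: the bounded-optimal utility
#' achievable across the whole protocol, a state function independent of the
#' adaptation path.
#'
#' @inheritParams protocol_equilibrium
#' @return Scalar.
#' @export
protocol_delta_f <- function(protocol, prior, beta) {
  N <- length(protocol)
  (protocol_log_z(protocol, prior, beta, N) -
     protocol_log_z(protocol, prior, beta, 0)) / beta
}

#' Per-epoch Metropolis-Hastings kernels for a protocol
#'
#' Builds one detailed-balanced kernel per epoch `t_0 ... t_N`. The epoch-0
#' kernel is by default the rank-one equilibrium kernel at `t_0` (the
#' decision-maker starts in equilibrium and its "prior conditional" is the
#' equilibrium strategy regardless of the previous state); later epochs get
#' `sweeps` compositions of the prior-proposal MH kernel for their utility.
#'
#' @inheritParams protocol_equilibrium
#' @param sweeps Number of MH sweeps composing each epoch kernel (more sweeps
#'   = more deliberation time = closer to equilibrium).
#' @param epoch0 Either `"equilibrium"` (rank-one kernel at `t_0`) or `"mh"`
#'   (same MH construction as later epochs).
#' @return List of `N + 1` `br_kernel` objects, indexed by epoch `+ 1`.
#' @export
protocol_kernels <- function(protocol, prior, beta, sweeps = 1,
                             epoch0 = c("equilibrium", "mh")) {
  epoch0 <- match.arg(epoch0)
  N <- length(protocol)
  ks <- vector("list", N + 1)
  for (t in 0:N) {
    if (t == 0 && epoch0 == "equilibrium") {
      ks[[1]] <- policy_kernel(protocol_equilibrium(protocol, prior, beta, 0))
    } else {
      k <- mh_discrete_kernel(prior, protocol$epochs[[t + 1]], beta)
      if (sweeps > 1) k <- kernel_power(k, sweeps)
      ks[[t + 1]] <- k
    }
  }
  ks
}

#' Total utility gain of a no-deliberation trajectory
#'
#' The work analog for a decision-maker that must act before it can adapt:
#' at each environmental change the held action `x_{n-1}` is re-evaluated,
#' `U(x) = sum_n [U(x_{n-1}, t_n) - U(x_{n-1}, t_{n-1})]`. The final action
#' `x_N` never contributes.
#'
#' @param x Character vector of actions `x_0 ... x_N` (length `N + 1`).
#' @param protocol Tabular `br_protocol` with `N + 1` epochs.
#' @return Scalar total utility gain.
#' @export
utility_gain_no_deliberation <- function(x, protocol) {
  stopifnot(inherits(protocol, "br_protocol"), protocol$form == "tabular")
  N <- length(protocol)
  stopifnot(length(x) == N + 1)
  x <- as.character(x)
  gains <- vapply(seq_len(N), function(n) {
    utility_value(protocol$epochs[[n + 1]], x[n]) -
      utility_value(protocol$epochs[[n]], x[n])
  }, numeric(1))
  sum(gains)
}

#' Deliberation cost of one transition
#'
#' The stochastic-entropy difference charged for adapting the conditional
#' choice distribution to the new utility:
#' `log p(x_n | x_prev, t_now) - log p(x_n | x_prev, t_prev)`. Divide by
#' `beta` to convert to utility units. Its expectation under the posterior
#' conditional is the KL divergence of the two conditionals, hence
#' non-negative on average.
#'
#' @param x_n Chosen action (label).
#' @param x_prev Previous action (label).
#' @param kernel_now Kernel in force at the current epoch.
#' @param kernel_prev Kernel in force at the previous epoch.
#' @return Scalar log-probability ratio (nats).
#' @export
deliberation_cost <- function(x_n, x_prev, kernel_now, kernel_prev) {
  stopifnot(inherits(kernel_now, "br_kernel"), inherits(kernel_prev, "br_kernel"))
  p_now <- kernel_now$P[as.character(x_prev), as.character(x_n)]
  p_prev <- kernel_prev$P[as.character(x_prev), as.character(x_n)]
  if (p_prev == 0) stop("deliberation cost undefined: zero prior conditional probability")
  log(p_now) - log(p_prev)
}

#' Net utility of a deliberation trajectory
#'
#' The generalized work: utility gain evaluated at the *newly chosen* action
#' minus the deliberation cost, summed over transitions:
#' `U_net(x) = sum_n [U(x_n, t_n) - U(x_n, t_{n-1})
#'   - (1/beta) log(p(x_n|x_{n-1}, t_n) / p(x_n|x_{n-1}, t_{n-1}))]`.
#' This is a non-equilibrium free energy at the trajectory level.
#'
#' @param x Actions `x_0 ... x_N`.
#' @param protocol Tabular `br_protocol`.
#' @param kernels List of `N + 1` per-epoch kernels as from
#'   [protocol_kernels()]; kernel `n + 1` is the conditional in force at
#'   epoch `t_n`.
#' @param beta Inverse temperature.
#' @param prior Base-measure policy used to check detailed balance.
#' @param db_tol Detailed-balance residual above which a warning is attached.
#' @return Scalar net utility; attribute `db_warning` flags kernels that are
#'   not detailed-balanced with respect to their epoch equilibrium.
#' @export
net_utility_deliberation <- function(x, protocol, kernels, beta, prior = NULL,
                                     db_tol = 1e-9) {
  stopifnot(inherits(protocol, "br_protocol"), protocol$form == "tabular")
  N <- length(protocol)
  stopifnot(length(x) == N + 1, length(kernels) == N + 1)
  x <- as.character(x)
  warn <- FALSE
  if (!is.null(prior)) {
    for (t in 0:N) {
      res <- detailed_balance_residual(
        kernels[[t + 1]], protocol_equilibrium(protocol, prior, beta, t))
      if (res > db_tol) warn <- TRUE
    }
  }
  total <- 0
  for (n in seq_len(N)) {
    gain <- utility_value(protocol$epochs[[n + 1]], x[n + 1]) -
      utility_value(protocol$epochs[[n]], x[n + 1])
    cost <- deliberation_cost(x[n + 1], x[n], kernels[[n + 1]], kernels[[n]])
    total <- total + gain - cost / beta
  }
  structure(total, db_warning = warn)
}

#' Dissipated utility
#'
#' `U_diss = dF - U_net`: the utility lost to imperfect or finite-time
#' adaptation. For a single decision with non-equilibrium strategy `p~` it
#' equals `(1/beta) KL(p~ || p_eq)`; averaged over forward trajectories it is
#' `(1/beta) KL(p || p_dagger) >= 0` (the second law).
#'
#' @param u_net Net (or total) utility of one or more trajectories.
#' @param delta_f Equilibrium free-energy difference of the protocol.
#' @return `delta_f - u_net`, vectorized over `u_net`.
#' @export
dissipated_utility <- function(u_net, delta_f) {
  delta_f - u_net
}

#' Forward trajectory log-probability
#'
#' `log p(x) = log p(x_0 | t_0) + sum_n log p(x_n | x_{n-1}, t_n)` where the
#' initial draw follows the epoch-0 equilibrium (encoded in `kernels[[1]]`).
#'
#' @inheritParams net_utility_deliberation
#' @param initial_policy `br_policy`: the law of `x_0`, the equilibrium at
#'   `t_0` (the decision-maker starts adapted to the initial landscape).
#' @return Scalar log-probability; `-Inf` with attribute `zero_step = TRUE`
#'   if any step has zero probability.
#' @export
forward_trajectory_logprob <- function(x, kernels, initial_policy) {
  N <- length(kernels) - 1L
  stopifnot(length(x) == N + 1, inherits(initial_policy, "br_policy"))
  x <- as.character(x)
  lp <- unname(initial_policy$lp[x[1]])
  for (n in seq_len(N)) {
    lp <- lp + log(kernels[[n + 1]]$P[x[n], x[n + 1]])
  }
  if (lp == -Inf) attr(lp, "zero_step") <- TRUE
  lp
}

#' Backward trajectory log-probability under the reversed protocol
#'
#' The time-reversed process starts in equilibrium at `t_N` and runs the
#' kernels in reverse order and reverse direction:
#' `log p^t(x) = log p_eq(x_N | t_N) + sum_n log p^t(x_{n-1} | x_n, t_{n-1})`,
#' where for detailed-balanced kernels the reversed conditional equals the
#' forward kernel applied backwards,
#' `p^t(x_{n-1} | x_n, t_{n-1}) = K_{t_{n-1}}(x_{n-1} | x_n)`.
#'
#' @inheritParams net_utility_deliberation
#' @param final_equilibrium `br_policy`: equilibrium at the final epoch.
#' @return Scalar log-probability (same flagging as the forward version).
#' @export
backward_trajectory_logprob <- function(x, kernels, final_equilibrium) {
  N <- length(kernels) - 1L
  stopifnot(length(x) == N + 1, inherits(final_equilibrium, "br_policy"))
  x <- as.character(x)
  lp <- final_equilibrium$lp[x[N + 1]]
  for (n in seq_len(N)) {
    lp <- lp + log(kernels[[n]]$P[x[n + 1], x[n]])
  }
  lp <- unname(lp)
  if (lp == -Inf) attr(lp, "zero_step") <- TRUE
  lp
}

#' Enumerate all trajectories of a finite protocol
#'
#' @param labels Action labels.
#' @param n_epochs Number of epochs `N + 1` (trajectory length).
#' @param max_paths Cap on the number of enumerated paths.
#' @return Character matrix, one row per trajectory.
#' @export
enumerate_trajectories <- function(labels, n_epochs, max_paths = 1e6) {
  n_paths <- length(labels)^n_epochs
  if (n_paths > max_paths) {
    stop("enumeration would generate ", n_paths,
         " paths (cap ", max_paths, "); sample trajectories instead")
  }
  g <- do.call(expand.grid,
               c(rep(list(labels), n_epochs),
                 list(stringsAsFactors = FALSE)))
  unname(as.matrix(g))
}

#' Simulate forward trajectories from per-epoch kernels
#'
#' @param kernels List of `N + 1` kernels.
#' @param initial_policy Law of `x_0` (equilibrium at `t_0`).
#' @param n Number of trajectories.
#' @return Character matrix `n x (N + 1)` of action labels.
#' @export
simulate_trajectories <- function(kernels, initial_policy, n) {
  N <- length(kernels) - 1L
  labels <- kernels[[1]]$labels
  X <- matrix("", n, N + 1)
  X[, 1] <- sample(labels, n, replace = TRUE, prob = policy_prob(initial_policy))
  for (t in seq_len(N)) {
    P <- kernels[[t + 1]]$P
    for (lab in labels) {
      idx <- X[, t] == lab
      if (any(idx)) {
        X[idx, t + 1] <- sample(labels, sum(idx), replace = TRUE, prob = P[lab, ])
      }
    }
  }
  X
}

#' Full thermodynamic ledger of a discrete deliberation protocol
#'
#' Scores a set of trajectories: net utility, dissipation, forward and
#' backward log-probabilities, and the two sides of the Crooks fluctuation
#' theorem `p(x)/p^t(x) = exp(beta * U_diss(x))`.
#'
#' @param X Character matrix of trajectories (rows) as from
#'   [simulate_trajectories()] or [enumerate_trajectories()].
#' @inheritParams net_utility_deliberation
#' @return A tibble with one row per trajectory: `u_net`, `u_diss`,
#'   `logp_fwd`, `logp_bwd`, `log_crooks_lhs` (= `logp_fwd - logp_bwd`) and
#'   `log_crooks_rhs` (= `beta * u_diss`).
#' @export
thermo_ledger <- function(X, protocol, kernels, beta, prior) {
  stopifnot(is.matrix(X))
  N <- length(protocol)
  dF <- protocol_delta_f(protocol, prior, beta)
  init_eq <- protocol_equilibrium(protocol, prior, beta, 0)
  final_eq <- protocol_equilibrium(protocol, prior, beta, N)
  rows <- lapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    u_net <- as.numeric(net_utility_deliberation(x, protocol, kernels, beta))
    lf <- as.numeric(forward_trajectory_logprob(x, kernels, init_eq))
    lb <- as.numeric(backward_trajectory_logprob(x, kernels, final_eq))
    u_diss <- dissipated_utility(u_net, dF)
    tibble::tibble(u_net = u_net, u_diss = u_diss,
                   logp_fwd = lf, logp_bwd = lb,
                   log_crooks_lhs = lf - lb,
                   log_crooks_rhs = beta * u_diss)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "delta_f") <- dF
  attr(out, "beta") <- beta
  out
}

#' Crooks fluctuation-theorem check for one trajectory
#'
#' @param x Actions `x_0 ... x_N`.
#' @inheritParams thermo_ledger
#' @return List with `lhs = p(x)/p^t(x)`, `rhs = exp(beta U_diss(x))` and
#'   their logs; trajectories with zero forward probability are flagged via
#'   `excluded = TRUE`.
#' @export
crooks_check <- function(x, protocol, kernels, beta, prior) {
  N <- length(protocol)
  dF <- protocol_delta_f(protocol, prior, beta)
  init_eq <- protocol_equilibrium(protocol, prior, beta, 0)
  final_eq <- protocol_equilibrium(protocol, prior, beta, N)
  lf <- forward_trajectory_logprob(x, kernels, init_eq)
  if (lf == -Inf) {
    return(list(lhs = NA_real_, rhs = NA_real_, excluded = TRUE))
  }
  lb <- backward_trajectory_logprob(x, kernels, final_eq)
  u_net <- as.numeric(net_utility_deliberation(x, protocol, kernels, beta))
  list(lhs = exp(as.numeric(lf) - as.numeric(lb)),
       rhs = exp(beta * dissipated_utility(u_net, dF)),
       log_lhs = as.numeric(lf) - as.numeric(lb),
       log_rhs = beta * dissipated_utility(u_net, dF),
       excluded = FALSE)
}

#' Net utility of an episodic fixed-prior trajectory
#'
#' For tasks whose episodes are independent and always restart from the same
#' prior `p0`: `U0_net(x) = sum_n [dU_n(x_n) - (1/beta) log(p_n(x_n)/p0(x_n))]`
#' where `p_n` is the (possibly non-equilibrium, e.g. anytime-mixture) choice
#' distribution of episode `n`.
#'
#' @param x Vector of `N` episode actions.
#' @param delta_us List of `N` tabular utility changes, one per episode.
#' @param policies List of `N` `br_policy` choice distributions.
#' @param prior The fixed prior policy.
#' @param beta Inverse temperature.
#' @return Scalar net utility.
#' @export
episodic_net_utility <- function(x, delta_us, policies, prior, beta) {
  N <- length(delta_us)
  stopifnot(length(x) == N, length(policies) == N)
  x <- as.character(x)
  total <- 0
  for (n in seq_len(N)) {
    lpn <- policies[[n]]$lp[x[n]]
    lp0 <- prior$lp[x[n]]
    if (lpn == -Inf || lp0 == -Inf) stop("policy support violation at episode ", n)
    total <- total + utility_value(delta_us[[n]], x[n]) - (lpn - lp0) / beta
  }
  unname(total)
}

#' Equilibrium free energy of an episodic task
#'
#' Decomposes as the sum of per-episode certainty-equivalent values
#' `(1/beta) log Z_n`.
#'
#' @inheritParams episodic_net_utility
#' @return Scalar.
#' @export
episodic_delta_f <- function(delta_us, prior, beta) {
  sum(vapply(delta_us, function(du) {
    as.numeric(equilibrium_free_energy(prior, du, beta))
  }, numeric(1)))
}

#' Jarzynski estimate of the free-energy difference
#'
#' Empirical estimator of `<exp(beta U_net)> = exp(beta dF)` from sampled
#' trajectories. The mean is computed in the log domain (log-sum-exp) to
#' avoid overflow at large `beta`; the implied estimate is
#' `dF_hat = (1/beta) log mean`, which by Jensen's inequality always lies
#' above the sample mean of `U_net`.
#'
#' @param u_net Numeric vector of per-trajectory net utilities.
#' @param beta Inverse temperature.
#' @return Object of class `jarzynski_estimate` with fields `n`, `mean`
#'   (of `exp(beta U_net)`), `se`, `log_mean` and `delta_f_hat`. Use
#'   [tidy.jarzynski_estimate()] / [glance.jarzynski_estimate()] for tabular
#'   access.
#' @export
jarzynski_estimate <- function(u_net, beta) {
  n <- length(u_net)
  if (n == 0) stop("no trajectories supplied")
  lw <- beta * u_net
  log_mean <- logsumexp(lw) - log(n)
  w <- exp(lw - log_mean) # weights relative to the mean, O(1)
  se <- exp(log_mean) * stats::sd(w) / sqrt(n)
  structure(list(n = n, mean = exp(log_mean), se = if (n > 1) se else NA_real_,
                 log_mean = log_mean, beta = beta,
                 delta_f_hat = log_mean / beta,
                 mean_u_net = mean(u_net)),
            class = "jarzynski_estimate")
}

#' Exact (enumeration-weighted) Jarzynski expectation
#'
#' @param u_net Per-trajectory net utilities.
#' @param logp Per-trajectory forward log-probabilities (must normalize).
#' @param beta Inverse temperature.
#' @return `sum_x p(x) exp(beta U_net(x))`, computed in the log domain.
#' @export
jarzynski_exact <- function(u_net, logp, beta) {
  exp(logsumexp(beta * u_net + logp))
}

#' @export
print.jarzynski_estimate <- function(x, ...) {
  cat(sprintf("<Jarzynski estimate: n = %d, <exp(beta U_net)> = %.6g (se %.3g), dF_hat = %.6g>\n",
              x$n, x$mean, x$se, x$delta_f_hat))
  invisible(x)
}

#' Tidy a Jarzynski estimate
#' @param x A `jarzynski_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the estimator components.
#' @export
tidy.jarzynski_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, beta = x$beta, mean_exp = x$mean, se = x$se,
                 delta_f_hat = x$delta_f_hat, mean_u_net = x$mean_u_net)
}

#' Glance at a Jarzynski estimate
#' @inheritParams tidy.jarzynski_estimate
#' @return One-row tibble: `n`, `delta_f_hat`, `mean_u_net` and the Jensen
#'   gap `delta_f_hat - mean_u_net` (non-negative).
#' @export
glance.jarzynski_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, delta_f_hat = x$delta_f_hat,
                 mean_u_net = x$mean_u_net,
                 jensen_gap = x$delta_f_hat - x$mean_u_net)
}

#' Generic tidiers
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Second-law check from a set of scored trajectories
#'
#' Returns the two sides of
#' `<U_diss> = (1/beta) KL(p || p^t) >= 0`: the mean dissipated utility and
#' the plug-in KL estimate `(1/beta) mean(log p - log p^t)`. They agree
#' exactly under enumeration weighting and within Monte-Carlo error on
#' sampled sets.
#'
#' @param ledger Tibble from [thermo_ledger()] (sampled trajectories), or any
#'   data frame with `u_diss`, `logp_fwd`, `logp_bwd` columns.
#' @param beta Inverse temperature.
#' @param weights Optional probability weights (e.g. `exp(logp_fwd)` for an
#'   enumerated ledger); defaults to equal weights (i.i.d. samples).
#' @return List with `mean_u_diss`, `kl_estimate` and `se_u_diss`.
#' @export
second_law_check <- function(ledger, beta, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / nrow(ledger), nrow(ledger))
  weights <- weights / sum(weights)
  mean_diss <- sum(weights * ledger$u_diss)
  kl <- sum(weights * (ledger$logp_fwd - ledger$logp_bwd)) / beta
  n <- nrow(ledger)
  list(mean_u_diss = mean_diss,
       kl_estimate = kl,
       se_u_diss = stats::sd(ledger$u_diss) / sqrt(n))
}

#' Log-probability of an accepted-move Metropolis-Hastings path
#'
#' The continuous-domain path-scoring convention used for hysteresis
#' analysis: only accepted moves are represented,
#' `log p(x) = log p(x_0) + sum_t [log g(x_t | x_{t-1}) + log a(x_t | x_{t-1})]`
#' with Gaussian proposal `g` and acceptance
#' `a = min(1, exp(beta (U_t(x_t) - U_t(x_{t-1}))))`. Unlike the exact-kernel
#' convention this omits rejection events, so it is not the full MH path
#' measure; the two conventions are never mixed within one computation.
#'
#' @param x Numeric vector of accepted states `x_0 ... x_T`.
#' @param utilities List of `T` quadratic `br_utility` objects, `utilities[[t]]`
#'   in force at move `t`.
#' @param beta Inverse temperature.
#' @param sigma_p Proposal standard deviation.
#' @param initial_logdens Function giving the log density of `x_0`.
#' @return Scalar log path density.
#' @export
accepted_path_logprob <- function(x, utilities, beta, sigma_p, initial_logdens) {
  Tn <- length(x) - 1L
  stopifnot(length(utilities) == Tn, sigma_p > 0)
  lp <- initial_logdens(x[1])
  for (t in seq_len(Tn)) {
    u <- utilities[[t]]
    lalpha <- min(0, beta * (utility_value(u, x[t + 1]) - utility_value(u, x[t])))
    lp <- lp + stats::dnorm(x[t + 1], x[t], sigma_p, log = TRUE) + lalpha
  }
  lp
}
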