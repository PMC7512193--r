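#' Rejection-sampling decision with aspiration level
#'
#' Implements the probabilistic satisficing decision-maker: proposals are
#' drawn from the prior and the first sample whose utility reaches the
#' aspiration level `T` is accepted with certainty; inferior samples are
#' accepted with probability `exp(beta * (dU(x) - T))`. Accepted actions are
#' distributed exactly as the equilibrium policy.
#'
#' @param prior Prior policy.
#' @param delta_u Tabular utility change.
#' @param beta Inverse temperature (`beta >= 0`).
#' @param T Aspiration level; must satisfy `T >= max(dU)`. The most efficient
#'   sampler uses `T = max(dU)` (the default).
#' @param n Number of independent decisions to simulate.
#' @param max_draws Hard cap on proposal draws per decision (diagnostic
#'   safeguard; acceptance happens with probability one).
#' @return A tibble with columns `action` (factor over the action labels) and
#'   `n_draws` (number of proposals consumed, `>= 1`).
#' @examples
#' set.seed(1)
#' rejection_decide(uniform_policy(2), utility_tabular(c(1, 0)), beta = 1, n = 5)
#' @export
rejection_decide <- function(prior, delta_u, beta, T = NULL, n = 1,
                             max_draws = 1e7) {
  stopifnot(inherits(prior, "br_policy"), inherits(delta_u, "br_utility"),
            delta_u$form == "tabular", beta >= 0, n >= 1)
  check_same_space(prior, delta_u)
  v <- delta_u$values
  if (is.null(T)) T <- max(v)
  if (T < max(v)) stop("aspiration level T must be >= max utility")
  labels <- prior$labels
  pr <- policy_prob(prior)
  lacc <- beta * (v - T) # log acceptance prob per action, <= 0

  action <- integer(n)
  n_draws <- integer(n)
  pending <- seq_len(n)
  draws <- rep(0L, n)
  while (length(pending)) {
    m <- length(pending)
    props <- sample.int(length(labels), m, replace = TRUE, prob = pr)
    draws[pending] <- draws[pending] + 1L
    acc <- log(stats::runif(m)) <= lacc[props]
    done <- pending[acc]
    action[done] <- props[acc]
    n_draws[done] <- draws[done]
    pending <- pending[!acc]
    if (length(pending) && max(draws[pending]) >= max_draws) {
      stop("rejection sampler exceeded ", max_draws,
           " draws for a decision; check beta/T configuration")
    }
  }
  tibble::tibble(action = factor(labels[action], levels = labels),
                 n_draws = n_draws)
}

#' Expected number of prior draws until acceptance
#'
#' The closed-form sampling complexity of the rejection decision-maker,
#' `n_bar = exp(beta * T) / Z_beta`, which is bounded below by
#' `exp(KL(p_eq || prior))`: informational distance from the prior costs
#' samples. At `beta = 0` exactly one draw suffices.
#'
#' @inheritParams rejection_decide
#' @return Scalar `>= 1`.
#' @export
expected_sample_count <- function(prior, delta_u, beta, T = NULL) {
  stopifnot(inherits(prior, "br_policy"), inherits(delta_u, "br_utility"),
            delta_u$form == "tabular", beta >= 0)
  check_same_space(prior, delta_u)
  v <- delta_u$values
  if (is.null(T)) T <- max(v)
  if (T < max(v)) stop("aspiration level T must be >= max utility")
  if (beta == 0) return(1)
  exp(beta * T - logsumexp(prior$lp + beta * v))
}

#' Anytime rejection-sampling policy after k proposal draws
#'
#' If the sampler is interrupted after `k` draws the emitted action follows
#' the non-equilibrium mixture
#' `p_k(x) = (1 - q_k) p_eq(x) + q_k prior(x)` with
#' `q_k = (1 - Z_beta exp(-beta T))^k`, the probability that none of the `k`
#' draws was accepted (in which case a fresh prior draw is emitted). `k = 0`
#' returns the prior; `k -> Inf` reaches equilibrium.
#'
#' @inheritParams rejection_decide
#' @param k Non-negative integer sample budget.
#' @return A `br_policy`.
#' @export
anytime_rejection_policy <- function(prior, delta_u, beta, T = NULL, k) {
  stopifnot(inherits(prior, "br_policy"), inherits(delta_u, "br_utility"),
            delta_u$form == "tabular", beta >= 0,
            length(k) == 1, k >= 0, k == round(k))
  check_same_space(prior, delta_u)
  v <- delta_u$values
  if (is.null(T)) T <- max(v)
  if (T < max(v)) stop("aspiration level T must be >= max utility")
  if (k == 0) return(prior)
  p_acc <- exp(logsumexp(prior$lp + beta * v) - beta * T) # Z_beta e^{-beta T}
  qk <- (1 - p_acc)^k
  peq <- equilibrium_policy(prior, delta_u, beta)
  policy((1 - qk) * policy_prob(peq) + qk * policy_prob(prior), prior$labels)
}

#' Simulate the anytime rejection sampler
#'
#' Runs the rejection sampler with a hard budget of `k` proposal draws per
#' decision; if no draw is accepted within the budget, a fresh draw from the
#' prior is emitted. The emitted actions follow
#' [anytime_rejection_policy()] exactly.
#'
#' @inheritParams anytime_rejection_policy
#' @param n Number of decisions.
#' @return Factor vector of emitted actions.
#' @export
anytime_rejection_sample <- function(prior, delta_u, beta, T = NULL, k, n) {
  stopifnot(k >= 0, n >= 1)
  v <- delta_u$values
  if (is.null(T)) T <- max(v)
  labels <- prior$labels
  pr <- policy_prob(prior)
  lacc <- beta * (v - T)
  out <- integer(n)
  pending <- seq_len(n)
  if (k > 0) {
    for (j in seq_len(k)) {
      m <- length(pending)
      if (!m) break
      props <- sample.int(length(labels), m, replace = TRUE, prob = pr)
      acc <- log(stats::runif(m)) <= lacc[props]
      out[pending[acc]] <- props[acc]
      pending <- pending[!acc]
    }
  }
  if (length(pending)) { # budget exhausted: emit a fresh prior draw
    out[pending] <- sample.int(length(labels), length(pending),
                               replace = TRUE, prob = pr)
  }
  factor(labels[out], levels = labels)
}

#' Discrete Metropolis-Hastings kernel with prior proposals
#'
#' The incremental decision-maker: proposals from the prior, acceptance with
#' probability `min(1, exp(beta * (dU(x') - dU(x))))`. Rejection mass is
#' folded into the diagonal, so each row is a proper probability
#' distribution. The kernel satisfies detailed balance with respect to the
#' equilibrium policy, which is therefore its stationary distribution.
#'
#' @inheritParams rejection_decide
#' @param utility Tabular `br_utility` (absolute utilities or changes; only
#'   differences matter).
#' @return An object of class `br_kernel`: list with `labels` and
#'   row-stochastic matrix `P` (rows = current state, columns = next state).
#' @export
mh_discrete_kernel <- function(prior, utility, beta) {
  stopifnot(inherits(prior, "br_policy"), inherits(utility, "br_utility"),
            utility$form == "tabular", beta >= 0)
  check_same_space(prior, utility)
  v <- utility$values
  pr <- policy_prob(prior)
  n <- length(pr)
  A <- outer(rep(1, n), pr) * pmin(1, exp(beta * outer(v, v, function(vi, vj) vj - vi)))
  diag(A) <- diag(A) + (1 - rowSums(A)) # fold rejection mass into self-loop
  br_kernel(A, prior$labels)
}

#' Construct a Markov kernel from a row-stochastic matrix
#'
#' @param P Square matrix with non-negative entries and unit row sums
#'   (within 1e-12).
#' @param labels State labels.
#' @return A `br_kernel`.
#' @export
br_kernel <- function(P, labels = rownames(P)) {
  P <- as.matrix(P)
  if (is.null(labels)) labels <- paste0("a", seq_len(nrow(P)))
  stopifnot(nrow(P) == ncol(P), length(labels) == nrow(P))
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("kernel rows must be probability distributions")
  }
  P[P < 0] <- 0
  dimnames(P) <- list(labels, labels)
  structure(list(labels = as.character(labels), P = P), class = "br_kernel")
}

#' Rank-one kernel that draws from a fixed policy regardless of state
#'
#' Used for the epoch-0 conditional of the deliberation regime, where the
#' decision-maker acts according to the equilibrium distribution of the
#' initial utility independently of any previous state.
#'
#' @param p A `br_policy`.
#' @return A `br_kernel` whose rows all equal `p`.
#' @export
policy_kernel <- function(p) {
  stopifnot(inherits(p, "br_policy"))
  pr <- policy_prob(p)
  br_kernel(matrix(pr, length(pr), length(pr), byrow = TRUE,
                   dimnames = list(p$labels, p$labels)), p$labels)
}

#' Compose a kernel with itself s times
#'
#' Powers of a reversible kernel remain reversible with the same stationary
#' distribution; used to model decision-makers allowed several chain sweeps
#' per epoch.
#'
#' @param kernel A `br_kernel`.
#' @param s Positive integer number of applications.
#' @return A `br_kernel`.
#' @export
kernel_power <- function(kernel, s) {
  stopifnot(inherits(kernel, "br_kernel"), s >= 1, s == round(s))
  P <- kernel$P
  out <- diag(nrow(P))
  base <- P
  while (s > 0) { # exponentiation by squaring
    if (s %% 2 == 1) out <- out %*% base
    base <- base %*% base
    s <- s %/% 2
  }
  out <- out / rowSums(out)
  br_kernel(out, kernel$labels)
}

#' Maximum detailed-balance violation of a kernel
#'
#' `max over (x, x') of | pi(x) K(x'|x) - pi(x') K(x|x') |`; zero (to
#' rounding) iff the kernel is reversible with respect to `stationary`.
#'
#' @param kernel A `br_kernel`.
#' @param stationary Candidate stationary policy.
#' @return Non-negative scalar.
#' @export
detailed_balance_residual <- function(kernel, stationary) {
  stopifnot(inherits(kernel, "br_kernel"), inherits(stationary, "br_policy"))
  check_same_space(kernel, stationary)
  flux <- policy_prob(stationary) * kernel$P
  max(abs(flux - t(flux)))
}

#' Stationary distribution of a Markov kernel
#'
#' Leading left eigenvector of the transition matrix, normalized to a policy.
#'
#' @param kernel A `br_kernel`.
#' @return A `br_policy`.
#' @export
stationary_distribution <- function(kernel) {
  stopifnot(inherits(kernel, "br_kernel"))
  e <- eigen(t(kernel$P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("leading eigenvector is not a distribution")
  policy(pmax(v, 0), kernel$labels)
}

#' Apply a kernel to a policy (one step of the chain)
#'
#' @param kernel A `br_kernel`.
#' @param p A `br_policy` (row vector of state probabilities).
#' @return The pushed-forward `br_policy`.
#' @export
kernel_step <- function(kernel, p) {
  stopifnot(inherits(kernel, "br_kernel"), inherits(p, "br_policy"))
  check_same_space(kernel, p)
  policy(as.numeric(policy_prob(p) %*% kernel$P), kernel$labels)
}

#' Continuous Metropolis-Hastings chain with Gaussian random-walk proposals
#'
#' One-dimensional MH targeting the Boltzmann density `exp(beta * U(x)) / Z`
#' of a quadratic utility, with symmetric proposal
#' `g(x'|x) = N(x'; x, sigma_p^2)` (the proposal density cancels in the
#' acceptance ratio). The long-run histogram converges to the Gaussian with
#' mean `-b/(2a)` and variance `1/(2 beta a)`.
#'
#' @param x0 Initial state.
#' @param utility Quadratic `br_utility`.
#' @param beta Inverse temperature (`> 0`).
#' @param sigma_p Proposal standard deviation (`> 0`).
#' @param n_steps Number of MH steps.
#' @param burn_in Steps discarded from the front of the returned chain.
#' @return Numeric vector of states after each retained step.
#' @export
mh_continuous_chain <- function(x0, utility, beta, sigma_p, n_steps,
                                burn_in = 0) {
  stopifnot(inherits(utility, "br_utility"), utility$form == "quadratic",
            beta > 0, n_steps >= 1, burn_in >= 0, burn_in < n_steps)
  if (!is.numeric(sigma_p) || length(sigma_p) != 1 || sigma_p <= 0) {
    stop("sigma_p must be a positive number")
  }
  x <- numeric(n_steps)
  cur <- x0
  u_cur <- utility_value(utility, cur)
  z <- stats::rnorm(n_steps, 0, sigma_p)
  lu <- log(stats::runif(n_steps))
  for (i in seq_len(n_steps)) {
    prop <- cur + z[i]
    u_prop <- utility_value(utility, prop)
    if (lu[i] <= beta * (u_prop - u_cur)) {
      cur <- prop
      u_cur <- u_prop
    }
    x[i] <- cur
  }
  if (burn_in > 0) x <- x[-seq_len(burn_in)]
  x
}
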