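#' Dissipation of a one-step-lag learner under a sudden utility change
#'
#' A learner that adapts perfectly but one step late dissipates
#' `U_diss = (1/beta) KL(p0 || p_eq)` when the utility jumps by `dU` in a
#' single step: during the lag it still acts by the old (prior) strategy.
#' Algebraically this equals `dF - <dU>_{p0}`.
#'
#' @param prior Prior (old equilibrium) policy.
#' @param delta_u Tabular utility change.
#' @param beta Inverse temperature (`> 0`).
#' @return Non-negative scalar.
#' @export
sudden_change_dissipation <- function(prior, delta_u, beta) {
  stopifnot(beta > 0)
  p1 <- equilibrium_policy(prior, delta_u, beta)
  kl_divergence(prior, p1) / beta
}

#' Stepped interpolation protocol for a utility change
#'
#' Splits a total change `dU` into `N` equal sub-steps,
#' `U_t(x) = U_0(x) + (t/N) dU(x)`.
#'
#' @param delta_u Tabular utility change (`br_utility`).
#' @param N Number of sub-steps (`>= 1`).
#' @return Object of class `br_stepped` with fields `delta_u` and `N`.
#' @export
stepped_protocol <- function(delta_u, N) {
  stopifnot(inherits(delta_u, "br_utility"), N >= 1, N == round(N))
  structure(list(delta_u = delta_u, N = as.integer(N)), class = "br_stepped")
}

#' N-step dissipation of a one-step-lag learner (discrete case)
#'
#' Along the equilibrium path
#' `p_eq(x, t) ~ p_eq(x, t-1) exp((beta/N) dU(x))` the learner lags one step
#' everywhere, dissipating
#' `U_diss^N = (1/beta) sum_t KL(p_eq(., t-1) || p_eq(., t))`. The sum is
#' non-increasing in `N` and vanishes in the quasi-static limit.
#'
#' @param protocol A `br_stepped` (tabular utility change).
#' @param prior Prior policy (equilibrium before the change).
#' @param beta Inverse temperature (`> 0`).
#' @return List with `u_diss` and `path` (matrix of the `N + 1` equilibrium
#'   distributions, rows = time).
#' @export
nstep_dissipation <- function(protocol, prior, beta) {
  stopifnot(inherits(protocol, "br_stepped"),
            protocol$delta_u$form == "tabular", beta > 0)
  check_same_space(prior, protocol$delta_u)
  N <- protocol$N
  v <- protocol$delta_u$values
  path <- matrix(NA_real_, N + 1, length(v),
                 dimnames = list(NULL, prior$labels))
  pols <- vector("list", N + 1)
  pols[[1]] <- prior
  path[1, ] <- policy_prob(prior)
  kl_sum <- 0
  for (t in seq_len(N)) {
    pols[[t + 1]] <- policy_from_log(prior$lp + (beta * t / N) * v, prior$labels)
    path[t + 1, ] <- policy_prob(pols[[t + 1]])
    kl_sum <- kl_sum + kl_divergence(pols[[t]], pols[[t + 1]])
  }
  list(u_diss = kl_sum / beta, path = path)
}

#' N-step dissipation for a Gaussian (quadratic-utility) learner
#'
#' Closed-form specialization: the interpolated utilities
#' `U_t = U_0 + (t/N)(U_1 - U_0)` stay quadratic, so every equilibrium on the
#' path is a Gaussian with mean `-b_t/(2 a_t)` and variance `1/(2 beta a_t)`,
#' and the stepwise KL divergences are Gaussian KLs.
#'
#' @param u0,u1 Quadratic `br_utility` objects (initial and final landscape).
#' @param N Number of sub-steps.
#' @param beta Inverse temperature (`> 0`).
#' @return Scalar `U_diss^N`.
#' @export
nstep_dissipation_gaussian <- function(u0, u1, N, beta) {
  stopifnot(inherits(u0, "br_utility"), u0$form == "quadratic",
            inherits(u1, "br_utility"), u1$form == "quadratic",
            N >= 1, N == round(N), beta > 0)
  ts <- 0:N / N
  a_t <- u0$a + ts * (u1$a - u0$a)
  b_t <- u0$b + ts * (u1$b - u0$b)
  if (any(a_t <= 0)) stop("interpolated curvature must stay positive")
  mu <- -b_t / (2 * a_t)
  s2 <- 1 / (2 * beta * a_t)
  # KL(N(mu1, s1) || N(mu2, s2)) summed over consecutive path points
  kl <- 0.5 * (log(s2[-1] / s2[-(N + 1)]) +
                 (s2[-(N + 1)] + (mu[-(N + 1)] - mu[-1])^2) / s2[-1] - 1)
  sum(kl) / beta
}

#' Free-energy difference of a Gaussian utility change
#'
#' @inheritParams nstep_dissipation_gaussian
#' @return `(1/beta) (log Z_1 - log Z_0)` in closed form.
#' @export
delta_f_gaussian <- function(u0, u1, beta) {
  (log_partition_quadratic(u1, beta) - log_partition_quadratic(u0, beta)) / beta
}

#' Quasi-static curve: dissipation and net utility versus number of steps
#'
#' For each `N` in `Ns`, computes the N-step dissipation `U_diss^N` along the
#' equilibrium path, the net utility `U_net^N = dF - U_diss^N`, and the
#' (path-independent) free-energy difference `dF`. As `N` grows the
#' dissipation falls monotonically to zero and the net utility approaches
#' `dF`, the quasi-static limit.
#'
#' @param delta_u Either a tabular `br_utility` (with `prior`) or a list
#'   `list(u0, u1)` of two quadratic utilities for the Gaussian closed form.
#' @param Ns Integer vector of step counts.
#' @param prior Prior policy (tabular case only).
#' @param beta Inverse temperature (`> 0`).
#' @return Tibble with columns `N`, `u_diss`, `u_net`, `delta_f`.
#' @export
quasistatic_curve <- function(delta_u, Ns, prior = NULL, beta = 1) {
  stopifnot(beta > 0, all(Ns >= 1))
  if (inherits(delta_u, "br_utility")) {
    stopifnot(delta_u$form == "tabular", inherits(prior, "br_policy"))
    dF <- as.numeric(equilibrium_free_energy(prior, delta_u, beta))
    ud <- vapply(Ns, function(N) {
      nstep_dissipation(stepped_protocol(delta_u, N), prior, beta)$u_diss
    }, numeric(1))
  } else {
    stopifnot(is.list(delta_u), length(delta_u) == 2)
    dF <- delta_f_gaussian(delta_u[[1]], delta_u[[2]], beta)
    ud <- vapply(Ns, function(N) {
      nstep_dissipation_gaussian(delta_u[[1]], delta_u[[2]], N, beta)
    }, numeric(1))
  }
  tibble::tibble(N = as.integer(Ns), u_diss = ud, u_net = dF - ud,
                 delta_f = dF)
}
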