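#' Free-energy functional of a bounded-rational decision-maker
#'
#' The variational objective traded off by a decision-maker with limited
#' information-processing resources:
#' `F[p] = sum_x p(x) dU(x) - (1/beta) KL(p || prior)`.
#' Expected utility gain is balanced against the informational distance from
#' the prior strategy, with the inverse temperature `beta` converting
#' informational units into utility units.
#'
#' @param p Candidate policy.
#' @param delta_u Tabular utility change (`br_utility`).
#' @param prior Prior policy; `p` must not place mass outside its support.
#' @param beta Inverse temperature, `beta > 0`.
#' @return Scalar value of the functional; maximized by
#'   [equilibrium_policy()], where it equals [equilibrium_free_energy()].
#' @export
free_energy_functional <- function(p, delta_u, prior, beta) {
  stopifnot(inherits(p, "br_policy"), inherits(prior, "br_policy"),
            inherits(delta_u, "br_utility"), delta_u$form == "tabular",
            is.numeric(beta), length(beta) == 1, beta > 0)
  check_same_space(p, prior, delta_u)
  eu <- sum(exp(p$lp) * ifelse(p$lp == -Inf, 0, delta_u$values))
  eu - kl_divergence(p, prior) / beta
}

#' Bounded-optimal (equilibrium) policy
#'
#' The Boltzmann-like maximizer of the free-energy functional:
#' `p_eq(x) = prior(x) exp(beta * dU(x)) / Z_beta`, computed in the log
#' domain. At `beta = 0` the prior is returned unchanged (no
#' information-processing affordable); as `beta -> Inf` mass concentrates on
#' the maximizers of `dU` (split evenly across ties by symmetry).
#'
#' @param prior Prior policy.
#' @param delta_u Tabular utility change.
#' @param beta Inverse temperature, `beta >= 0`.
#' @return A `br_policy`.
#' @examples
#' equilibrium_policy(uniform_policy(2), utility_tabular(c(1, 0)), 1)
#' @export
equilibrium_policy <- function(prior, delta_u, beta) {
  stopifnot(inherits(prior, "br_policy"), inherits(delta_u, "br_utility"),
            delta_u$form == "tabular",
            is.numeric(beta), length(beta) == 1, beta >= 0)
  check_same_space(prior, delta_u)
  if (beta == 0) return(prior)
  policy_from_log(prior$lp + beta * delta_u$values, prior$labels)
}

#' Equilibrium free energy (certainty-equivalent value)
#'
#' The value of the equilibrium strategy,
#' `dF = (1/beta) log Z_beta` with `Z_beta = sum_x prior(x) exp(beta dU(x))`.
#' It interpolates between the prior-expected utility (`beta -> 0`) and the
#' maximum utility (`beta -> Inf`), and is a state function of the utility
#' landscape independent of the adaptation path.
#'
#' @inheritParams equilibrium_policy
#' @return Scalar. At `beta = 0` the limit value `sum prior * dU` is returned
#'   with attribute `limit = TRUE`.
#' @export
equilibrium_free_energy <- function(prior, delta_u, beta) {
  stopifnot(inherits(prior, "br_policy"), inherits(delta_u, "br_utility"),
            delta_u$form == "tabular",
            is.numeric(beta), length(beta) == 1, beta >= 0)
  check_same_space(prior, delta_u)
  if (beta == 0) {
    val <- sum(exp(prior$lp) * ifelse(prior$lp == -Inf, 0, delta_u$values))
    return(structure(val, limit = TRUE))
  }
  logsumexp(prior$lp + beta * delta_u$values) / beta
}

#' Log partition function of a quadratic utility
#'
#' `log Z = log integral exp(beta * U(x)) dx` for
#' `U(x) = -(a x^2 + b x) + offset`, in closed form:
#' `beta * offset + beta * b^2 / (4 a) + 0.5 * log(pi / (beta * a))`.
#'
#' @param u Quadratic `br_utility`.
#' @param beta Inverse temperature, `beta > 0`.
#' @return Scalar log partition function.
#' @export
log_partition_quadratic <- function(u, beta) {
  stopifnot(inherits(u, "br_utility"), u$form == "quadratic", beta > 0)
  beta * u$offset + beta * u$b^2 / (4 * u$a) + 0.5 * log(pi / (beta * u$a))
}

#' Gaussian equilibrium of a quadratic utility
#'
#' @inheritParams log_partition_quadratic
#' @return List with `mean = -b/(2a)` and `var = 1/(2 beta a)`.
#' @export
equilibrium_gaussian <- function(u, beta) {
  stopifnot(inherits(u, "br_utility"), u$form == "quadratic", beta > 0)
  list(mean = -u$b / (2 * u$a), var = 1 / (2 * beta * u$a))
}
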