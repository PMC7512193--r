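#' Tempered (generalized) posterior over discrete hypotheses
#'
#' Bayesian inference as free-energy maximization: the posterior
#' `p(theta | D) = p0(theta) p(D | theta)^beta / Z` trades off log-likelihood
#' (the utility) against the KL distance from the prior. At `beta = 1` this
#' is exactly Bayes' rule; `beta = 0` returns the prior; `beta -> Inf`
#' concentrates on the maximum-likelihood hypothesis.
#'
#' @param prior Numeric vector of prior probabilities over hypotheses.
#' @param loglik Numeric vector of log-likelihoods `log p(D | theta)`.
#' @param beta Non-negative inverse temperature.
#' @return Named numeric vector of posterior probabilities.
#' @examples
#' generalized_posterior(c(0.5, 0.3, 0.2), log(c(0.1, 0.6, 0.3)), beta = 1)
#' @export
generalized_posterior <- function(prior, loglik, beta) {
  stopifnot(length(prior) == length(loglik), all(prior >= 0), sum(prior) > 0,
            beta >= 0, !any(is.nan(loglik)), !any(loglik == Inf))
  lw <- log(prior / sum(prior)) + beta * loglik
  lz <- logsumexp(lw)
  if (lz == -Inf) stop("degenerate posterior: all hypotheses have zero weight")
  p <- exp(lw - lz)
  names(p) <- names(prior)
  p
}

#' Gaussian belief state
#'
#' @param mean Belief mean.
#' @param var Belief variance (`> 0`).
#' @return Object of class `br_belief`.
#' @export
gaussian_belief <- function(mean, var) {
  stopifnot(is.finite(mean), is.finite(var), var > 0)
  structure(list(mean = mean, var = var), class = "br_belief")
}

#' @export
print.br_belief <- function(x, ...) {
  cat(sprintf("<Gaussian belief N(%.4g, %.4g)>\n", x$mean, x$var))
  invisible(x)
}

#' Conjugate update of a Gaussian belief (known observation variance)
#'
#' Standard known-variance Gaussian conjugacy: observing a batch `y` with
#' per-observation variance `obs_var` maps `N(m, v)` to the posterior with
#' precision `1/v + length(y)/obs_var`. An empty batch is the identity, and
#' splitting the data into batches never changes the final posterior.
#'
#' @param belief A `br_belief`.
#' @param y Numeric vector of observations (may be empty).
#' @param obs_var Known observation variance (`> 0`).
#' @return Updated `br_belief`.
#' @export
conjugate_gaussian_update <- function(belief, y, obs_var) {
  stopifnot(inherits(belief, "br_belief"), obs_var > 0)
  m <- length(y)
  if (m == 0) return(belief)
  prec <- 1 / belief$var + m / obs_var
  mean <- (belief$mean / belief$var + sum(y) / obs_var) / prec
  gaussian_belief(mean, 1 / prec)
}

split_batches <- function(y, b) {
  stopifnot(b >= 1, b == round(b))
  split(y, ceiling(seq_along(y) / b)) # final short batch allowed
}

#' Expected surprise of a sequential Gaussian learner
#'
#' Each incoming batch is scored under the belief held *before* it is
#' incorporated:
#' `S = -sum_n E_{p(theta | X_{<n})} [log p(X_n | theta)]`, the work analog
#' of the inference process. In the Gaussian known-variance case each term is
#' available in closed form:
#' `sum_j [log(2 pi s2)/2 + ((y_j - m)^2 + v)/(2 s2)]`.
#'
#' @param belief Prior `br_belief`.
#' @param y Numeric data vector.
#' @param batch_size Batch size `b`; the data are processed in chunks of `b`
#'   (final chunk may be shorter).
#' @param obs_var Known observation variance.
#' @return List with total `surprise`, per-batch `terms`, and the final
#'   `belief`.
#' @export
expected_surprise <- function(belief, y, batch_size, obs_var) {
  stopifnot(inherits(belief, "br_belief"), obs_var > 0)
  batches <- split_batches(y, batch_size)
  terms <- numeric(length(batches))
  for (i in seq_along(batches)) {
    yb <- batches[[i]]
    terms[i] <- sum(0.5 * log(2 * pi * obs_var) +
                      ((yb - belief$mean)^2 + belief$var) / (2 * obs_var))
    belief <- conjugate_gaussian_update(belief, yb, obs_var)
  }
  list(surprise = sum(terms), terms = terms, belief = belief)
}

#' Log marginal likelihood of Gaussian data under a Gaussian prior
#'
#' The free-energy optimum `dF = log integral p0(theta) p(D | theta) dtheta`,
#' a state function of the data independent of any batching. Computed
#' exactly by chaining one-observation predictive densities
#' `N(y_i; m_{i-1}, v_{i-1} + obs_var)`.
#'
#' @inheritParams expected_surprise
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(belief, y, obs_var) {
  stopifnot(inherits(belief, "br_belief"), obs_var > 0)
  total <- 0
  for (yi in y) {
    total <- total + stats::dnorm(yi, belief$mean,
                                  sqrt(belief$var + obs_var), log = TRUE)
    belief <- conjugate_gaussian_update(belief, yi, obs_var)
  }
  total
}

#' Dissipation of a batched Bayesian learner
#'
#' `U_diss = (1/beta) sum_n KL(p(theta | X_{<n}) || p(theta | X_{<=n}))`:
#' the KL divergences between consecutive beliefs along the update path.
#' Satisfies the inference first law `dF + S = U_diss` exactly, where `S` is
#' the expected surprise and `dF` the log marginal likelihood. Implemented
#' for the exact-Bayes case `beta = 1` (Gaussian closed forms throughout).
#'
#' @inheritParams expected_surprise
#' @param beta Inverse temperature; must be 1 (exact Bayes) for the Gaussian
#'   closed-form path.
#' @return List with `u_diss`, per-batch `terms` and final `belief`.
#' @export
bayes_dissipation <- function(belief, y, batch_size, obs_var, beta = 1) {
  stopifnot(inherits(belief, "br_belief"), obs_var > 0)
  if (beta != 1) stop("Gaussian closed-form dissipation is implemented for beta = 1")
  batches <- split_batches(y, batch_size)
  terms <- numeric(length(batches))
  for (i in seq_along(batches)) {
    nxt <- conjugate_gaussian_update(belief, batches[[i]], obs_var)
    terms[i] <- gaussian_kl(belief$mean, belief$var, nxt$mean, nxt$var)
    belief <- nxt
  }
  list(u_diss = sum(terms) / beta, terms = terms, belief = belief)
}

#' KL divergence between two univariate Gaussians
#'
#' @param m1,v1 Mean and variance of the first Gaussian.
#' @param m2,v2 Mean and variance of the second Gaussian.
#' @return `KL(N(m1, v1) || N(m2, v2))`, non-negative.
#' @export
gaussian_kl <- function(m1, v1, m2, v2) {
  0.5 * (log(v2 / v1) + (v1 + (m1 - m2)^2) / v2 - 1)
}

#' Batch-size experiment: surprise, dissipation and free energy
#'
#' Reproduces the sequential-inference study: a synthetic dataset of `T`
#' Gaussian draws is incorporated by a conjugate Gaussian learner in batches
#' of each requested size. For every batch size the expected surprise `S`,
#' the dissipation `U_diss` and the free-energy optimum `dF` (log marginal
#' likelihood, identical across batch sizes) are returned; each row satisfies
#' the first law `dF + S = U_diss`.
#'
#' @param seed Integer seed for the synthetic dataset.
#' @param T Number of observations.
#' @param mu_d,var_d Mean and variance of the data-generating Gaussian.
#' @param batch_sizes Integer vector of batch sizes.
#' @param prior_mean,prior_var Learner's Gaussian prior over the unknown mean.
#' @return Tibble with columns `b`, `delta_f`, `surprise`, `u_diss`; the
#'   dataset is attached as attribute `data`.
#' @examples
#' figure_batches_experiment(seed = 1, T = 20, batch_sizes = c(20, 5, 1))
#' @export
figure_batches_experiment <- function(seed = 1L, T = 100L, mu_d = 5,
                                      var_d = 4,
                                      batch_sizes = c(100, 50, 25, 20, 10, 5, 2, 1),
                                      prior_mean = 0, prior_var = 100) {
  stopifnot(T >= 1, var_d > 0)
  set.seed(seed)
  y <- stats::rnorm(T, mu_d, sqrt(var_d))
  prior <- gaussian_belief(prior_mean, prior_var)
  dF <- log_marginal_likelihood(prior, y, var_d)
  rows <- lapply(batch_sizes, function(b) {
    S <- expected_surprise(prior, y, b, var_d)$surprise
    ud <- bayes_dissipation(prior, y, b, var_d)$u_diss
    tibble::tibble(b = as.integer(b), delta_f = dF, surprise = S, u_diss = ud)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "data") <- y
  out
}
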