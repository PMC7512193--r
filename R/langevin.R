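#' Configuration for Langevin deliberation dynamics
#'
#' The deliberation process is the stochastic differential equation
#' `dx/dt = alpha U'(x) + alpha xi(t)` with white noise of correlation
#' `<xi(t) xi(t')> = 2 D delta(t - t')`: gradient ascent on the utility plus
#' exploration noise, both scaled by the learning rate `alpha`. For a
#' quadratic utility this is an Ornstein-Uhlenbeck process with relaxation
#' rate `c = 2 alpha a`.
#'
#' @param alpha Learning rate (`> 0`).
#' @param D Noise scale (`> 0`).
#' @param dt Time step of the Euler-Maruyama discretization (`> 0`).
#' @param mu0,var0 Initial Gaussian law (`var0 > 0`).
#' @return Object of class `br_langevin_config`.
#' @export
langevin_config <- function(alpha, D, dt = 1e-3, mu0 = 0, var0 = 1) {
  stopifnot(alpha > 0, D > 0, dt > 0, var0 > 0, is.finite(mu0))
  structure(list(alpha = alpha, D = D, dt = dt, mu0 = mu0, var0 = var0),
            class = "br_langevin_config")
}

#' Effective inverse temperature of the Langevin decision-maker
#'
#' The `beta` for which the stationary law of the Fokker-Planck equation
#' equals the Boltzmann density `exp(beta U) / Z`. For the implemented
#' dynamics (drift `alpha U'`, diffusion `alpha^2 D`) the stationary variance
#' of a quadratic utility is `alpha D / (2 a)`, matching the equilibrium
#' Gaussian variance `1 / (2 beta a)` at `beta = 1 / (alpha D)`. With
#' `printed = TRUE` the relation `beta = 2 alpha D` quoted in parts of the
#' literature is returned instead; it disagrees with the stationary solution
#' of this SDE and is provided for comparison/logging only.
#'
#' @param config A `br_langevin_config`.
#' @param printed Return the literature-quoted relation instead of the
#'   derived one.
#' @return Scalar inverse temperature.
#' @export
effective_beta <- function(config, printed = FALSE) {
  stopifnot(inherits(config, "br_langevin_config"))
  if (printed) 2 * config$alpha * config$D else 1 / (config$alpha * config$D)
}

#' Noise scale realizing a target inverse temperature
#'
#' @param alpha Learning rate.
#' @param beta Target effective inverse temperature.
#' @return `D = 1 / (alpha beta)`.
#' @export
noise_for_beta <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  1 / (alpha * beta)
}

#' Closed-form Gaussian law of the Langevin process
#'
#' Solution of the Fokker-Planck equation for a quadratic utility
#' `U(x) = -(a x^2 + b x) + offset` started from `N(mu0, var0)`:
#' mean `mu(t) = exp(-c t) mu0 - b/(2a) (1 - exp(-c t))` and variance
#' `var(t) = s_inf (1 - exp(-2 c t)) + var0 exp(-2 c t)` with rate
#' `c = 2 alpha a` and stationary variance `s_inf = alpha D / (2 a)`
#' (derived from the moment equations of the Fokker-Planck dynamics).
#'
#' @param config A `br_langevin_config` (supplies `alpha`, `D`, `mu0`, `var0`).
#' @param utility Quadratic `br_utility`.
#' @param t Physical time (`>= 0`); vectorized.
#' @return List of numeric vectors `mean`, `var`, plus `t`.
#' @export
gaussian_law <- function(config, utility, t) {
  stopifnot(inherits(config, "br_langevin_config"),
            inherits(utility, "br_utility"), utility$form == "quadratic",
            all(t >= 0))
  a <- utility$a; b <- utility$b
  cc <- 2 * config$alpha * a
  s_inf <- config$alpha * config$D / (2 * a)
  e1 <- exp(-cc * t)
  e2 <- exp(-2 * cc * t)
  list(mean = e1 * config$mu0 - (b / (2 * a)) * (1 - e1),
       var = s_inf * (1 - e2) + config$var0 * e2,
       t = t)
}

#' Exact Ornstein-Uhlenbeck transition law
#'
#' Conditional law of the Langevin state after deliberating for time `tau`
#' under a quadratic utility, given the starting point: the `var0 = 0` case
#' of [gaussian_law()].
#'
#' @param x_prev Starting point(s).
#' @param utility Quadratic `br_utility`.
#' @param alpha,D Langevin parameters.
#' @param tau Deliberation time (`> 0`).
#' @return List with vectors `mean` and scalar `var`.
#' @export
ou_transition <- function(x_prev, utility, alpha, D, tau) {
  stopifnot(inherits(utility, "br_utility"), utility$form == "quadratic",
            alpha > 0, D > 0, tau > 0)
  a <- utility$a; b <- utility$b
  cc <- 2 * alpha * a
  e1 <- exp(-cc * tau)
  list(mean = e1 * x_prev - (b / (2 * a)) * (1 - e1),
       var = (alpha * D / (2 * a)) * (1 - exp(-2 * cc * tau)))
}

#' Euler-Maruyama simulation of the Langevin deliberation ensemble
#'
#' Discretizes `dx = alpha U'(x) dt + alpha sqrt(2 D dt) z` for an ensemble
#' of particles; the empirical mean/variance trajectories converge to
#' [gaussian_law()].
#'
#' @param config A `br_langevin_config`.
#' @param utility Quadratic `br_utility`.
#' @param n_steps Number of time steps.
#' @param n_particles Ensemble size.
#' @param keep Integer vector of step indices at which to record the ensemble
#'   (default: final step only). `0` records the initial state.
#' @return Tibble with columns `step`, `t`, `mean`, `var`, and a list-column
#'   `x` holding the particle positions at each kept step.
#' @export
euler_maruyama_ensemble <- function(config, utility, n_steps, n_particles,
                                    keep = n_steps) {
  stopifnot(inherits(config, "br_langevin_config"),
            inherits(utility, "br_utility"), utility$form == "quadratic",
            n_steps >= 1, n_particles >= 1)
  cc <- 2 * config$alpha * utility$a
  if (config$dt >= 1 / cc) {
    warning("dt >= 1/(2 alpha a): Euler-Maruyama discretization is unstable")
  }
  x <- stats::rnorm(n_particles, config$mu0, sqrt(config$var0))
  sd_noise <- config$alpha * sqrt(2 * config$D * config$dt)
  keep <- sort(unique(as.integer(keep)))
  recs <- vector("list", length(keep))
  ki <- 1L
  if (length(keep) && keep[1] == 0L) {
    recs[[1]] <- tibble::tibble(step = 0L, t = 0, mean = mean(x),
                                var = stats::var(x), x = list(x))
    ki <- 2L
  }
  for (j in seq_len(n_steps)) {
    drift <- -(2 * utility$a * x + utility$b) # U'(x)
    x <- x + config$alpha * drift * config$dt + sd_noise * stats::rnorm(n_particles)
    if (ki <= length(keep) && j == keep[ki]) {
      recs[[ki]] <- tibble::tibble(step = j, t = j * config$dt, mean = mean(x),
                                   var = stats::var(x), x = list(x))
      ki <- ki + 1L
    }
  }
  dplyr::bind_rows(recs)
}

#' Net utility and Jarzynski terms for Langevin deliberation
#'
#' Simulates an ensemble of deliberation trajectories across a sequence of
#' quadratic utility epochs, drawing each epoch's action from the exact
#' Ornstein-Uhlenbeck transition law after deliberation time `tau = k dt`.
#' The initial state follows the equilibrium of the first epoch (which must
#' coincide with the configured prior Gaussian). Net utility per trajectory
#' is the utility gain at the newly chosen action minus the `(1/beta)`-scaled
#' log-ratio of the new to old transition densities; the free-energy
#' difference comes from the closed-form Gaussian partition functions.
#'
#' @param utilities List of `N + 1` quadratic `br_utility` objects; the first
#'   is the baseline landscape whose equilibrium is the prior.
#' @param alpha Learning rate.
#' @param beta Inverse temperature; the noise scale is set to
#'   `D = 1/(alpha beta)` so the dynamics equilibrate to `exp(beta U)/Z`.
#' @param k Number of deliberation steps per epoch.
#' @param dt Reference time step (deliberation time is `tau = k dt`).
#' @param n_particles Number of independent trajectories.
#' @return List with per-trajectory `u_net`, `delta_f`, the trajectory matrix
#'   `x`, and the [jarzynski_estimate()] of `exp(beta dF)`.
#' @export
langevin_net_utility <- function(utilities, alpha, beta, k, dt = 1e-3,
                                 n_particles = 1000) {
  stopifnot(is.list(utilities), length(utilities) >= 2,
            all(vapply(utilities, function(u)
      inherits(u, "br_utility") && u$form == "quadratic", logical(1))),
            alpha > 0, beta > 0, k >= 1, dt > 0, n_particles >= 1)
  D <- noise_for_beta(alpha, beta)
  tau <- k * dt
  N <- length(utilities) - 1L
  eq0 <- equilibrium_gaussian(utilities[[1]], beta)
  x <- matrix(NA_real_, n_particles, N + 1)
  x[, 1] <- stats::rnorm(n_particles, eq0$mean, sqrt(eq0$var))
  u_net <- numeric(n_particles)
  for (n in seq_len(N)) {
    u_now <- utilities[[n + 1]]
    u_prev <- utilities[[n]]
    now <- ou_transition(x[, n], u_now, alpha, D, tau)
    prev <- ou_transition(x[, n], u_prev, alpha, D, tau)
    x[, n + 1] <- stats::rnorm(n_particles, now$mean, sqrt(now$var))
    gain <- utility_value(u_now, x[, n + 1]) - utility_value(u_prev, x[, n + 1])
    cost <- stats::dnorm(x[, n + 1], now$mean, sqrt(now$var), log = TRUE) -
      stats::dnorm(x[, n + 1], prev$mean, sqrt(prev$var), log = TRUE)
    u_net <- u_net + gain - cost / beta
  }
  dF <- (log_partition_quadratic(utilities[[N + 1]], beta) -
           log_partition_quadratic(utilities[[1]], beta)) / beta
  list(u_net = u_net, delta_f = dF, x = x,
       jarzynski = jarzynski_estimate(u_net, beta))
}
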