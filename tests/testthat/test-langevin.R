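test_that("Gaussian law starts at the prior and relaxes to the Boltzmann
           equilibrium of the effective temperature", {
  cfg <- langevin_config(alpha = 0.7, D = 0.4, mu0 = 2, var0 = 3)
  u <- utility_quadratic(0.8, -1.2, 0.3)
  at0 <- gaussian_law(cfg, u, 0)
  expect_equal(at0$mean, 2, tolerance = 1e-14)
  expect_equal(at0$var, 3, tolerance = 1e-14)

  beta_eff <- effective_beta(cfg)
  eq <- equilibrium_gaussian(u, beta_eff)
  late <- gaussian_law(cfg, u, 1e4)
  expect_equal(late$mean, eq$mean, tolerance = 1e-10)
  expect_equal(late$var, eq$var, tolerance = 1e-10)
  expect_equal(late$var, 1 / (2 * beta_eff * u$a), tolerance = 1e-10)

  # effective beta is invariant to translations of the landscape and prior
  cfg2 <- langevin_config(alpha = 0.7, D = 0.4, mu0 = -5, var0 = 3)
  expect_identical(effective_beta(cfg), effective_beta(cfg2))
  # a vanishing learning rate freezes the law
  slow <- langevin_config(alpha = 1e-12, D = 0.4, mu0 = 2, var0 = 3)
  frozen <- gaussian_law(slow, u, 10)
  expect_equal(frozen$mean, 2, tolerance = 1e-9)
  expect_equal(frozen$var, 3, tolerance = 1e-9)
  expect_error(utility_quadratic(-1, 0), "concavity")
})

test_that("closed-form moments solve the Fokker-Planck moment equations", {
  cfg <- langevin_config(alpha = 1.3, D = 0.25, mu0 = -1, var0 = 0.5)
  u <- utility_quadratic(0.6, 1.1, -2)
  cc <- 2 * cfg$alpha * u$a
  # dmu/dt = alpha E[U'(x)] ; dvar/dt = -2 c var + 2 alpha^2 D
  rhs <- function(t, y, parms) {
    list(c(-cc * y[1] - cfg$alpha * u$b,
           -2 * cc * y[2] + 2 * cfg$alpha^2 * cfg$D))
  }
  ts <- seq(0, 5, by = 0.25)
  ode <- deSolve::ode(c(cfg$mu0, cfg$var0), ts, rhs, NULL,
                      atol = 1e-12, rtol = 1e-12)
  law <- gaussian_law(cfg, u, ts)
  expect_equal(unname(ode[, 2]), law$mean, tolerance = 1e-8)
  expect_equal(unname(ode[, 3]), law$var, tolerance = 1e-8)
})

test_that("Euler-Maruyama ensembles track the closed-form law", {
  set.seed(81)
  beta <- 2
  cfg <- langevin_config(alpha = 1, D = noise_for_beta(1, beta),
                         dt = 1e-3, mu0 = 0, var0 = 1)
  u <- utility_quadratic(0.5, -1, 0)
  n <- 2e4
  keep <- c(200, 500, 1000, 2000)
  ens <- euler_maruyama_ensemble(cfg, u, n_steps = 2000, n_particles = n,
                                 keep = keep)
  for (i in seq_along(keep)) {
    law <- gaussian_law(cfg, u, keep[i] * cfg$dt)
    se_mean <- sqrt(law$var / n)
    se_var <- law$var * sqrt(2 / (n - 1))
    expect_lt(abs(ens$mean[i] - law$mean), 4 * se_mean)
    expect_lt(abs(ens$var[i] - law$var), 4 * se_var)
  }
  # long-time histogram agrees with the stationary Boltzmann Gaussian
  # (t = 10 >> 1/c, so the transient from the prior has fully decayed)
  eq <- equilibrium_gaussian(u, beta)
  ens_long <- euler_maruyama_ensemble(cfg, u, n_steps = 1e4, n_particles = n,
                                      keep = 1e4)
  ks <- stats::ks.test(ens_long$x[[1]], "pnorm", eq$mean, sqrt(eq$var))
  expect_gt(ks$p.value, 0.001)
  # doubling the noise doubles the stationary variance (halves beta_eff)
  cfg2 <- langevin_config(alpha = 1, D = 2 * cfg$D, dt = 1e-3)
  expect_equal(effective_beta(cfg2), beta / 2, tolerance = 1e-12)
  set.seed(82)
  ens2 <- euler_maruyama_ensemble(cfg2, u, n_steps = 2000, n_particles = n,
                                  keep = 2000)
  law2 <- gaussian_law(cfg2, u, 2)
  expect_lt(abs(ens2$var[1] - law2$var), 4 * law2$var * sqrt(2 / (n - 1)))
  expect_equal(law2$var / eq$var, 2, tolerance = 0.01)
  expect_warning(
    euler_maruyama_ensemble(langevin_config(1, 1, dt = 2), u, 2, 10),
    "unstable")
})

test_that("Langevin net utility obeys the second law and Jarzynski equality", {
  set.seed(83)
  beta <- 0.5
  utils_b <- langevin_task_utilities(beta)
  res <- langevin_net_utility(utils_b, alpha = 1, beta = beta, k = 200,
                              dt = 1e-3, n_particles = 1e4)
  jz <- res$jarzynski
  expect_lt(abs(jz$mean - exp(beta * res$delta_f)), 3 * jz$se)
  se_unet <- sd(res$u_net) / sqrt(length(res$u_net))
  expect_lt(mean(res$u_net), res$delta_f + 3 * se_unet)

  # mean net utility grows with deliberation time and approaches dF
  means <- vapply(c(50, 500, 5000), function(k) {
    set.seed(84)
    mean(langevin_net_utility(utils_b, 1, beta, k, 1e-3, 4000)$u_net)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  set.seed(85)
  res_inf <- langevin_net_utility(utils_b, 1, beta, k = 2e4, dt = 1e-3,
                                  n_particles = 1e4)
  se_inf <- sd(res_inf$u_net) / sqrt(length(res_inf$u_net))
  expect_lt(abs(mean(res_inf$u_net) - res_inf$delta_f), 3 * se_inf + 1e-3)
})
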