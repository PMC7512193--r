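test_that("policies are normalized, log-stable, and validate their inputs", {
  p <- policy(c(a = 1, b = 3))
  expect_equal(sum(policy_prob(p)), 1, tolerance = 1e-12)
  expect_equal(unname(policy_prob(p)["b"]), 0.75)

  # extreme log-weights survive via log-sum-exp
  q <- policy_from_log(c(1000, 999))
  expect_equal(unname(policy_prob(q)[1]), 1 / (1 + exp(-1)), tolerance = 1e-12)

  expect_error(policy(c(-1, 2)), "non-negative")
  expect_error(policy_from_log(c(-Inf, -Inf)), "all log-weights")
  expect_error(policy(c(a = 1, a = 2)))
})

test_that("KL divergence matches hand values and enforces support", {
  expect_equal(kl_divergence(policy(c(1, 0)), policy(c(0.5, 0.5))), log(2))
  for (n in c(2, 8, 100)) {
    expect_identical(kl_divergence(uniform_policy(n), uniform_policy(n)), 0)
  }
  expect_error(kl_divergence(policy(c(0.5, 0.5)), policy(c(1, 0))), "support")
  expect_error(kl_divergence(uniform_policy(2), uniform_policy(3)),
               "different action spaces")
})

test_that("equilibrium policy follows the Boltzmann form and its limits", {
  prior <- uniform_policy(2)
  du <- utility_tabular(c(1, 0), prior$labels)

  # beta = 0: no information-processing affordable, prior returned
  expect_identical(equilibrium_policy(prior, du, 0), prior)
  # constant utility change: shift invariance
  du_const <- utility_tabular(c(2, 2), prior$labels)
  expect_equal(policy_prob(equilibrium_policy(prior, du_const, 1.3)),
               policy_prob(prior), tolerance = 1e-12)
  # direct Boltzmann evaluation
  p1 <- equilibrium_policy(prior, du, 1)
  expect_equal(unname(policy_prob(p1)[1]), exp(1) / (1 + exp(1)),
               tolerance = 1e-12)
})

test_that("equilibrium free energy interpolates between prior mean and max", {
  prior <- uniform_policy(2)
  du <- utility_tabular(c(1, 0), prior$labels)
  expect_equal(as.numeric(equilibrium_free_energy(prior, du, 1)),
               log((exp(1) + 1) / 2), tolerance = 1e-12)

  f0 <- equilibrium_free_energy(prior, du, 0)
  expect_true(isTRUE(attr(f0, "limit")))
  expect_equal(as.numeric(f0), 0.5)
  expect_equal(as.numeric(equilibrium_free_energy(prior, du, 1e-8)), 0.5,
               tolerance = 1e-6)
  expect_equal(as.numeric(equilibrium_free_energy(prior, du, 1e3)), 1,
               tolerance = 1e-2)

  # monotone, bounded interpolation in beta
  set.seed(7)
  pr <- policy(runif(6) + 0.05)
  duu <- utility_tabular(runif(6), pr$labels)
  betas <- c(1e-6, 10^seq(-3, 3, length.out = 40))
  fs <- vapply(betas, function(b)
    as.numeric(equilibrium_free_energy(pr, duu, b)), numeric(1))
  expect_true(all(diff(fs) >= -1e-10))
  expect_true(all(fs <= max(duu$values) + 1e-12))
})

test_that("free-energy functional is maximized at the equilibrium policy", {
  prior <- uniform_policy(2)
  du <- utility_tabular(c(1, 0), prior$labels)
  # identity case: KL term vanishes
  expect_equal(free_energy_functional(prior, du, prior, 2.5),
               sum(policy_prob(prior) * du$values), tolerance = 1e-14)
  # value at the optimum equals the closed form
  peq <- equilibrium_policy(prior, du, 1)
  expect_equal(free_energy_functional(peq, du, prior, 1),
               log((exp(1) + 1) / 2), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    pr <- policy(runif(n) + 0.05)
    duu <- utility_tabular(runif(n))
    beta <- runif(1, 0.1, 5)
    peq <- equilibrium_policy(pr, duu, beta)
    f_eq <- free_energy_functional(peq, duu, pr, beta)
    # algebraic identity with the log-partition value
    expect_equal(f_eq, as.numeric(equilibrium_free_energy(pr, duu, beta)),
                 tolerance = 1e-12)
    # optimality against random perturbed policies
    perturbed <- replicate(100, {
      policy(policy_prob(peq) * exp(runif(n, -0.5, 0.5)))
    }, simplify = FALSE)
    f_other <- vapply(perturbed, free_energy_functional, numeric(1),
                      delta_u = duu, prior = pr, beta = beta)
    expect_true(all(f_eq >= f_other - 1e-10))
  }
})

test_that("functional errors on mismatched spaces and support violations", {
  expect_error(
    free_energy_functional(uniform_policy(3), utility_tabular(c(1, 0)),
                           uniform_policy(2), 1),
    "different action spaces")
  expect_error(
    free_energy_functional(policy(c(0.5, 0.5)), utility_tabular(c(1, 0)),
                           policy(c(1, 0)), 1),
    "support")
})
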