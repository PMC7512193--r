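test_that("work and heat analogs telescope to the total utility change", {
  set.seed(51)
  for (i in 1:10) {
    inst <- random_instance()
    N <- length(inst$protocol)
    x <- sample(inst$prior$labels, N + 1, replace = TRUE)
    work <- utility_gain_no_deliberation(x, inst$protocol)
    heat <- sum(vapply(seq_len(N), function(n) {
      utility_value(inst$protocol$epochs[[n + 1]], x[n + 1]) -
        utility_value(inst$protocol$epochs[[n + 1]], x[n])
    }, numeric(1)))
    total <- utility_value(inst$protocol$epochs[[N + 1]], x[N + 1]) -
      utility_value(inst$protocol$epochs[[1]], x[1])
    expect_equal(work + heat, total, tolerance = 1e-12)
  }
  # constant protocol: no work
  prot <- utility_protocol(list(utility_tabular(c(1, 2)),
                                utility_tabular(c(1, 2))))
  expect_identical(utility_gain_no_deliberation(c("a1", "a2"), prot), 0)
})

test_that("one-step-lag decision-makers obey the second law on average", {
  set.seed(52)
  prior <- uniform_policy(6)
  prot <- utility_protocol(list(utility_tabular(runif(6), prior$labels),
                                utility_tabular(runif(6), prior$labels)))
  beta <- 2
  eq0 <- protocol_equilibrium(prot, prior, beta, 0)
  dF <- protocol_delta_f(prot, prior, beta)
  x0 <- sample(eq0$labels, 1e4, replace = TRUE, prob = policy_prob(eq0))
  gains <- utility_value(prot$epochs[[2]], x0) - utility_value(prot$epochs[[1]], x0)
  se <- sd(gains) / sqrt(length(gains))
  expect_lt(mean(gains), dF + 3 * se)
  # exact expectation is below dF (strictly, for a non-constant change)
  exact <- sum(policy_prob(eq0) * (prot$epochs[[2]]$values - prot$epochs[[1]]$values))
  expect_lt(exact, dF)
})

test_that("deliberation cost reduces to conditional log-ratios and KL on average", {
  set.seed(53)
  prior <- policy(runif(3) + 0.1)
  u1 <- utility_tabular(runif(3), prior$labels)
  u2 <- utility_tabular(runif(3), prior$labels)
  K1 <- mh_discrete_kernel(prior, u1, 1.2)
  K2 <- mh_discrete_kernel(prior, u2, 1.2)
  lab <- prior$labels

  expect_identical(deliberation_cost(lab[2], lab[1], K1, K1), 0)
  # direct matrix lookup
  expect_equal(deliberation_cost(lab[3], lab[1], K2, K1),
               log(K2$P[1, 3]) - log(K1$P[1, 3]), tolerance = 1e-14)
  # expectation under the posterior conditional is the conditional KL >= 0
  for (xp in lab) {
    costs <- vapply(lab, deliberation_cost, numeric(1), x_prev = xp,
                    kernel_now = K2, kernel_prev = K1)
    expected <- sum(K2$P[xp, ] * costs)
    kl_cond <- sum(K2$P[xp, ] * (log(K2$P[xp, ]) - log(K1$P[xp, ])))
    expect_equal(expected, kl_cond, tolerance = 1e-12)
    expect_gte(expected, 0)
  }
})

test_that("fully equilibrated decision-makers attain the free-energy bound", {
  set.seed(54)
  inst <- random_instance(n_actions = 4, n_epochs = 3)
  N <- length(inst$protocol)
  beta <- inst$beta
  # perfect per-epoch equilibration: rank-one equilibrium kernels
  ks <- lapply(0:N, function(t)
    policy_kernel(protocol_equilibrium(inst$protocol, inst$prior, beta, t)))
  X <- enumerate_trajectories(inst$prior$labels, N + 1)
  led <- thermo_ledger(X, inst$protocol, ks, beta, inst$prior)
  w <- exp(led$logp_fwd)
  expect_equal(sum(w * led$u_net), attr(led, "delta_f"), tolerance = 1e-12)
  expect_equal(sum(w * led$u_diss), 0, tolerance = 1e-12)

  # one-sweep MH kernels deliberate imperfectly: strictly positive dissipation
  ks1 <- protocol_kernels(inst$protocol, inst$prior, beta, sweeps = 1)
  led1 <- thermo_ledger(X, inst$protocol, ks1, beta, inst$prior)
  expect_lt(sum(exp(led1$logp_fwd) * led1$u_net), attr(led1, "delta_f"))
})

test_that("zero-change protocols neither gain nor dissipate on average", {
  prior <- uniform_policy(3)
  u <- utility_tabular(c(0.3, 0.7, 0.1), prior$labels)
  prot <- utility_protocol(list(u, u, u))
  beta <- 1.5
  X <- enumerate_trajectories(prior$labels, 3)
  # same reversible MH kernel at every epoch: every deliberation cost is zero,
  # dF = 0, and the process is time-symmetric trajectory-by-trajectory
  ks <- protocol_kernels(prot, prior, beta, epoch0 = "mh")
  led <- thermo_ledger(X, prot, ks, beta, prior)
  expect_equal(attr(led, "delta_f"), 0, tolerance = 1e-14)
  expect_equal(led$u_net, rep(0, nrow(led)), tolerance = 1e-12)
  expect_equal(led$logp_fwd, led$logp_bwd, tolerance = 1e-12)
  # equilibrium epoch-0 conditional: the first deliberation still incurs a
  # non-negative expected cost, so mean net utility is <= 0
  ks_eq <- protocol_kernels(prot, prior, beta, epoch0 = "equilibrium")
  led_eq <- thermo_ledger(X, prot, ks_eq, beta, prior)
  expect_lte(sum(exp(led_eq$logp_fwd) * led_eq$u_net), 1e-12)
})

test_that("trajectory measures normalize and degenerate kernels behave", {
  set.seed(55)
  inst <- random_instance(n_actions = 3, n_epochs = 2)
  ks <- protocol_kernels(inst$protocol, inst$prior, inst$beta)
  eq0 <- protocol_equilibrium(inst$protocol, inst$prior, inst$beta, 0)
  eqN <- protocol_equilibrium(inst$protocol, inst$prior, inst$beta,
                              length(inst$protocol))
  X <- enumerate_trajectories(inst$prior$labels, 3)
  lf <- apply(X, 1, forward_trajectory_logprob, kernels = ks,
              initial_policy = eq0)
  lb <- apply(X, 1, backward_trajectory_logprob, kernels = ks,
              final_equilibrium = eqN)
  expect_equal(sum(exp(lf)), 1, tolerance = 1e-12)
  expect_equal(sum(exp(lb)), 1, tolerance = 1e-12)

  # identity (deterministic) transition kernels: only the initial draw counts
  idk <- br_kernel(diag(3), inst$prior$labels)
  ks_id <- list(ks[[1]], idk, idk)
  x_const <- rep(inst$prior$labels[2], 3)
  expect_equal(
    as.numeric(forward_trajectory_logprob(x_const, ks_id, eq0)),
    unname(eq0$lp[x_const[1]]), tolerance = 1e-14)
  # zero-probability step is flagged
  x_move <- c(inst$prior$labels[2], inst$prior$labels[1], inst$prior$labels[1])
  lf0 <- forward_trajectory_logprob(x_move, ks_id, eq0)
  expect_identical(as.numeric(lf0), -Inf)
  expect_true(isTRUE(attr(lf0, "zero_step")))
})

test_that("Crooks fluctuation theorem holds trajectory-wise under enumeration", {
  set.seed(56)
  for (i in 1:8) {
    inst <- random_instance()
    sweeps <- sample(1:3, 1)
    ks <- protocol_kernels(inst$protocol, inst$prior, inst$beta, sweeps = sweeps)
    X <- enumerate_trajectories(inst$prior$labels, length(inst$protocol) + 1)
    led <- thermo_ledger(X, inst$protocol, ks, inst$beta, inst$prior)
    expect_lt(max(abs(led$log_crooks_lhs - led$log_crooks_rhs)), 1e-10)
  }
  # single-trajectory interface, including lhs/rhs in the linear domain
  inst <- random_instance(n_actions = 3, n_epochs = 2)
  ks <- protocol_kernels(inst$protocol, inst$prior, inst$beta)
  x <- sample(inst$prior$labels, 3, replace = TRUE)
  cc <- crooks_check(x, inst$protocol, ks, inst$beta, inst$prior)
  expect_false(cc$excluded)
  expect_equal(cc$log_lhs, cc$log_rhs, tolerance = 1e-10)
  expect_equal(cc$lhs, cc$rhs, tolerance = 1e-10)
})

test_that("Jarzynski equality holds exactly under enumeration and within
           Monte-Carlo error when sampling", {
  set.seed(57)
  inst <- random_instance(n_actions = 4, n_epochs = 3)
  ks <- protocol_kernels(inst$protocol, inst$prior, inst$beta, sweeps = 2)
  X <- enumerate_trajectories(inst$prior$labels, 4)
  led <- thermo_ledger(X, inst$protocol, ks, inst$beta, inst$prior)
  dF <- attr(led, "delta_f")
  expect_equal(jarzynski_exact(led$u_net, led$logp_fwd, inst$beta),
               exp(inst$beta * dF), tolerance = 1e-12)

  eq0 <- protocol_equilibrium(inst$protocol, inst$prior, inst$beta, 0)
  Xs <- simulate_trajectories(ks, eq0, 5000)
  leds <- thermo_ledger(Xs, inst$protocol, ks, inst$beta, inst$prior)
  jz <- jarzynski_estimate(leds$u_net, inst$beta)
  expect_lt(abs(jz$mean - exp(inst$beta * dF)), 3 * jz$se)
  # Jensen chain: implied free-energy estimate dominates the mean net utility
  expect_gte(jz$delta_f_hat, jz$mean_u_net)
  expect_error(jarzynski_estimate(numeric(0), 1), "no trajectories")
})

test_that("second law: mean dissipation equals the path KL divergence", {
  set.seed(58)
  inst <- random_instance(n_actions = 3, n_epochs = 3)
  ks <- protocol_kernels(inst$protocol, inst$prior, inst$beta)
  X <- enumerate_trajectories(inst$prior$labels, 4)
  led <- thermo_ledger(X, inst$protocol, ks, inst$beta, inst$prior)
  chk <- second_law_check(led, inst$beta, weights = exp(led$logp_fwd))
  expect_equal(chk$mean_u_diss, chk$kl_estimate, tolerance = 1e-12)
  expect_gte(chk$mean_u_diss, 0)

  eq0 <- protocol_equilibrium(inst$protocol, inst$prior, inst$beta, 0)
  Xs <- simulate_trajectories(ks, eq0, 3000)
  leds <- thermo_ledger(Xs, inst$protocol, ks, inst$beta, inst$prior)
  chs <- second_law_check(leds, inst$beta)
  expect_gt(chs$mean_u_diss, -3 * chs$se_u_diss)
})

test_that("episodic fixed-prior relations hold by enumeration", {
  fx <- generate_fixture("episodic-8", seed = 3)
  prior <- fx$prior
  dus <- fx$delta_us
  beta <- 1.5
  dF <- episodic_delta_f(dus, prior, beta)

  # budget-limited mixture policies
  pols_k <- lapply(dus, function(du) anytime_rejection_policy(prior, du, beta, k = 2))
  X <- enumerate_trajectories(prior$labels, 2)
  u_net <- apply(X, 1, episodic_net_utility, delta_us = dus,
                 policies = pols_k, prior = prior, beta = beta)
  logp <- apply(X, 1, function(x)
    sum(vapply(1:2, function(n) pols_k[[n]]$lp[x[n]], numeric(1))))
  # Jarzynski with fixed prior, exact under enumeration
  expect_equal(exp(logsumexp(beta * u_net + logp)), exp(beta * dF),
               tolerance = 1e-12)
  # fixed-prior Crooks: p~(x)/p_eq(x) = exp(beta U_diss(x)) trajectory-wise
  pols_eq <- lapply(dus, function(du) equilibrium_policy(prior, du, beta))
  logp_eq <- apply(X, 1, function(x)
    sum(vapply(1:2, function(n) pols_eq[[n]]$lp[x[n]], numeric(1))))
  expect_equal(logp - logp_eq, beta * (dF - u_net), tolerance = 1e-10,
               ignore_attr = TRUE)

  # equality case: equilibrium policies achieve mean U0net = dF
  u_net_eq <- apply(X, 1, episodic_net_utility, delta_us = dus,
                    policies = pols_eq, prior = prior, beta = beta)
  expect_equal(sum(exp(logp_eq) * u_net_eq), dF, tolerance = 1e-12)
  # prior policies (k = 0): zero cost, mean = prior-expected utility <= dF
  pols_0 <- list(prior, prior)
  u_net_0 <- apply(X, 1, episodic_net_utility, delta_us = dus,
                   policies = pols_0, prior = prior, beta = beta)
  logp_0 <- apply(X, 1, function(x) sum(prior$lp[x]))
  m0 <- sum(exp(logp_0) * u_net_0)
  expect_equal(m0, sum(vapply(dus, function(du)
    sum(policy_prob(prior) * du$values), numeric(1))), tolerance = 1e-12)
  expect_lt(m0, dF)
})

test_that("dissipation of a single anytime decision equals its KL form", {
  prior <- uniform_policy(2)
  du <- utility_tabular(c(1, 0), prior$labels)
  beta <- 1
  dF <- as.numeric(equilibrium_free_energy(prior, du, beta))
  peq <- equilibrium_policy(prior, du, beta)
  # p~ = equilibrium: no dissipation
  u_net_eq <- free_energy_functional(peq, du, prior, beta)
  expect_equal(dissipated_utility(u_net_eq, dF), 0, tolerance = 1e-12)
  # p~ = prior: dissipation is (1/beta) KL(prior || equilibrium), both sides
  # computed independently
  u_net_pr <- sum(policy_prob(prior) * du$values)
  expect_equal(dissipated_utility(u_net_pr, dF),
               kl_divergence(prior, peq) / beta, tolerance = 1e-12)
})

test_that("accepted-move path probabilities follow the product formula", {
  u <- utility_quadratic(1, 0, 0) # -(x^2)
  init <- function(x) dnorm(x, 0, 1, log = TRUE)
  sp <- 0.5
  # single uphill move: acceptance probability one
  lp <- accepted_path_logprob(c(1, 0.2), list(u), beta = 2, sigma_p = sp, init)
  expect_equal(lp, init(1) + dnorm(0.2, 1, sp, log = TRUE), tolerance = 1e-12)
  # three-move path: independent term-by-term evaluation
  x <- c(0.5, 1.2, 0.9, -0.3)
  us <- list(u, utility_quadratic(2, -1, 0), u)
  beta <- 1
  manual <- init(x[1])
  for (t in 1:3) {
    manual <- manual + dnorm(x[t + 1], x[t], sp, log = TRUE) +
      min(0, beta * (utility_value(us[[t]], x[t + 1]) - utility_value(us[[t]], x[t])))
  }
  expect_equal(accepted_path_logprob(x, us, beta, sp, init), manual,
               tolerance = 1e-12)
  # palindromic path under a constant utility: forward equals backward
  xp <- c(0.3, 0.8, 0.3)
  us2 <- list(u, u)
  expect_equal(accepted_path_logprob(xp, us2, beta, sp, init),
               accepted_path_logprob(rev(xp), us2, beta, sp, init),
               tolerance = 1e-12)
})
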