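# Random problem instances and small statistical helpers shared across tests.

# A random discrete decision instance: prior, tabular protocol, beta.
random_instance <- function(n_actions = NULL, n_epochs = NULL,
                            beta_range = c(0.3, 3)) {
  n <- n_actions %||% sample(2:5, 1)
  N <- n_epochs %||% sample(2:4, 1)
  prior <- policy(stats::runif(n) + 0.1)
  protocol <- utility_protocol(lapply(seq_len(N + 1), function(i) {
    utility_tabular(stats::runif(n), prior$labels)
  }))
  list(prior = prior, protocol = protocol,
       beta = stats::runif(1, beta_range[1], beta_range[2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Total variation distance between two policies.
tv_dist <- function(p, q) {
  0.5 * sum(abs(policy_prob(p) - policy_prob(q)))
}

# Chi-square goodness-of-fit p-value of observed action counts vs a policy.
chisq_pvalue <- function(actions, pol) {
  counts <- table(factor(actions, levels = pol$labels))
  suppressWarnings(stats::chisq.test(counts, p = policy_prob(pol))$p.value)
}
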