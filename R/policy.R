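#' Numerically stable log-sum-exp
#'
#' @param x Numeric vector (may contain `-Inf`).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Construct a stochastic policy over a finite action set
#'
#' A policy is a normalized probability distribution over a finite set of
#' actions, stored in the log domain so that very peaked distributions (large
#' inverse temperature beta) remain representable.
#'
#' @param prob Non-negative numeric vector of (possibly unnormalized)
#'   probabilities, one per action.
#' @param labels Action identifiers; defaults to `names(prob)` or
#'   `a1, a2, ...`.
#' @return An object of class `br_policy` with fields `labels` and `lp`
#'   (log-probabilities summing to one in the linear domain).
#' @examples
#' p <- policy(c(a = 1, b = 3))
#' policy_prob(p)
#' @export
policy <- function(prob, labels = NULL) {
  if (is.null(labels)) labels <- names(prob)
  if (is.null(labels)) labels <- paste0("a", seq_along(prob))
  stopifnot(length(labels) == length(prob), !anyDuplicated(labels))
  if (any(prob < 0) || all(prob == 0) || any(!is.finite(prob))) {
    stop("`prob` must be non-negative, finite and not all zero")
  }
  policy_from_log(log(prob), labels)
}

#' Construct a policy from unnormalized log-probabilities
#'
#' @param lp Numeric vector of log-weights (entries may be `-Inf`).
#' @param labels Action identifiers.
#' @return A `br_policy`.
#' @export
policy_from_log <- function(lp, labels = NULL) {
  if (is.null(labels)) labels <- names(lp)
  if (is.null(labels)) labels <- paste0("a", seq_along(lp))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(lp), !anyDuplicated(labels))
  if (any(is.nan(lp)) || any(lp == Inf)) stop("log-weights must be finite or -Inf")
  lz <- logsumexp(lp)
  if (lz == -Inf) stop("all log-weights are -Inf; policy undefined")
  structure(list(labels = labels, lp = stats::setNames(lp - lz, labels)),
            class = "br_policy")
}

#' Uniform policy over n actions
#'
#' @param n Number of actions, or a character vector of labels.
#' @return A `br_policy` with probability `1/n` on each action.
#' @export
uniform_policy <- function(n) {
  labels <- if (is.character(n)) n else paste0("a", seq_len(n))
  policy_from_log(rep(0, length(labels)), labels)
}

#' Linear-domain probabilities of a policy
#'
#' @param p A `br_policy`.
#' @return Named numeric vector of probabilities.
#' @export
policy_prob <- function(p) {
  stopifnot(inherits(p, "br_policy"))
  exp(p$lp)
}

#' @export
print.br_policy <- function(x, ...) {
  cat("<policy over", length(x$labels), "actions>\n")
  print(round(policy_prob(x), 6))
  invisible(x)
}

#' Number of actions of a policy
#' @param x A `br_policy`.
#' @param ... Unused.
#' @export
length.br_policy <- function(x) length(x$labels)

check_same_space <- function(...) {
  objs <- list(...)
  labs <- lapply(objs, function(o) o$labels)
  if (!all(vapply(labs[-1], identical, logical(1), labs[[1]]))) {
    stop("objects are defined over different action spaces")
  }
  invisible(labs[[1]])
}

#' Kullback-Leibler divergence between two policies
#'
#' Computes `KL(p || q) = sum_x p(x) log(p(x)/q(x))` with the `0 * log 0 = 0`
#' convention. The divergence is the information cost of moving from the prior
#' strategy `q` to the posterior strategy `p`.
#'
#' @param p,q Policies over the same action space; `p` must be absolutely
#'   continuous with respect to `q` (no mass where `q` has none).
#' @return Non-negative scalar; zero iff `p == q`.
#' @examples
#' kl_divergence(policy(c(1, 0)), policy(c(0.5, 0.5)))  # log 2
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "br_policy"), inherits(q, "br_policy"))
  check_same_space(p, q)
  sup <- p$lp > -Inf
  if (any(sup & q$lp == -Inf)) {
    stop("KL undefined: p has support where q has none")
  }
  val <- sum(exp(p$lp[sup]) * (p$lp[sup] - q$lp[sup]))
  max(val, 0) # clip tiny negative rounding
}
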