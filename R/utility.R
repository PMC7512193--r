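#' Tabular utility over a finite action set
#'
#' A utility epoch assigns a (change in) utility to each action during one
#' time slice of an externally driven protocol.
#'
#' @param values Named numeric vector of finite utilities, one per action.
#' @param labels Action identifiers; defaults to `names(values)`.
#' @param epoch Integer epoch index (time slice) this utility belongs to.
#' @return An object of class `br_utility` (form `"tabular"`).
#' @export
utility_tabular <- function(values, labels = NULL, epoch = 0L) {
  if (is.null(labels)) labels <- names(values)
  if (is.null(labels)) labels <- paste0("a", seq_along(values))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(values), all(is.finite(values)))
  structure(list(form = "tabular",
                 values = stats::setNames(as.numeric(values), labels),
                 labels = labels, epoch = as.integer(epoch)),
            class = "br_utility")
}

#' Quadratic (concave) utility on the real line
#'
#' Represents `U(x) = -(a * x^2 + b * x) + offset` with `a > 0`, so that the
#' Boltzmann equilibrium `exp(beta * U) / Z` is a proper Gaussian with mean
#' `-b / (2 a)` and variance `1 / (2 beta a)`.
#'
#' @param a Positive curvature coefficient.
#' @param b Linear coefficient.
#' @param offset Additive constant; carried for plotting but cancels in all
#'   utility differences.
#' @param epoch Integer epoch index.
#' @return An object of class `br_utility` (form `"quadratic"`).
#' @export
utility_quadratic <- function(a, b, offset = 0, epoch = 0L) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a),
            is.numeric(b), length(b) == 1, is.finite(b),
            is.numeric(offset), length(offset) == 1, is.finite(offset))
  if (a <= 0) stop("quadratic utility requires a > 0 (concavity)")
  structure(list(form = "quadratic", a = a, b = b, offset = offset,
                 epoch = as.integer(epoch)),
            class = "br_utility")
}

#' Evaluate a utility epoch at actions
#'
#' @param u A `br_utility`.
#' @param x Action labels (tabular form) or real positions (quadratic form).
#' @return Numeric vector of utilities.
#' @export
utility_value <- function(u, x) {
  stopifnot(inherits(u, "br_utility"))
  if (u$form == "tabular") {
    v <- u$values[as.character(x)]
    if (anyNA(v)) stop("unknown action label(s): ",
                       paste(setdiff(as.character(x), u$labels), collapse = ", "))
    unname(v)
  } else {
    -(u$a * x^2 + u$b * x) + u$offset
  }
}

#' @export
print.br_utility <- function(x, ...) {
  if (x$form == "tabular") {
    cat("<tabular utility, epoch", x$epoch, ">\n")
    print(x$values)
  } else {
    cat(sprintf("<quadratic utility U(x) = -(%g x^2 + %g x) + %g, epoch %d>\n",
                x$a, x$b, x$offset, x$epoch))
  }
  invisible(x)
}

#' Time-indexed utility protocol
#'
#' The external driving signal: an ordered sequence of utility epochs over one
#' shared action space. Epoch `i` is in force during time slice `t_{i-1}`
#' (the first epoch is the baseline at `t0`).
#'
#' @param epochs List of `br_utility` objects (all tabular over the same
#'   labels, or all quadratic).
#' @return An object of class `br_protocol`.
#' @export
utility_protocol <- function(epochs) {
  stopifnot(is.list(epochs), length(epochs) >= 2,
            all(vapply(epochs, inherits, logical(1), "br_utility")))
  forms <- vapply(epochs, function(e) e$form, character(1))
  if (length(unique(forms)) != 1) stop("all epochs must share one form")
  if (forms[1] == "tabular") {
    labs <- lapply(epochs, function(e) e$labels)
    if (!all(vapply(labs[-1], identical, logical(1), labs[[1]]))) {
      stop("all epochs must share one action space")
    }
  }
  epochs <- lapply(seq_along(epochs), function(i) {
    e <- epochs[[i]]; e$epoch <- i - 1L; e
  })
  structure(list(epochs = epochs, form = forms[1],
                 labels = if (forms[1] == "tabular") epochs[[1]]$labels else NULL),
            class = "br_protocol")
}

#' Number of transitions (decision steps) in a protocol
#' @param x A `br_protocol`.
#' @param ... Unused.
#' @export
length.br_protocol <- function(x) length(x$epochs) - 1L
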