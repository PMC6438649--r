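#' Acceptance rules for single-trajectory stochastic search
#'
#' Three rules share one interface.  The elitist rule of the (1+1) EA
#' accepts a mutant iff its fitness difference `delta_f >= 0` (ties in
#' favour of the mutant).  The SSWM rule accepts with Kimura's fixation
#' probability
#' `p_fix(delta_f) = (1 - exp(-2*beta*delta_f)) / (1 - exp(-2*N*beta*delta_f))`,
#' where `beta` is the selection strength and `N` the population-size
#' parameter of the underlying population-genetic process; its value at
#' `delta_f = 0` is the continuous limit `1/N`, and for `N = 1` it is
#' identically 1.  The Metropolis rule accepts improvements always and a
#' worsening with probability `exp(alpha*delta_f)` with `alpha` the inverse
#' temperature.
#'
#' @param variant One of `"elitist"`, `"sswm"`, `"metropolis"`.
#' @param beta Selection strength (positive; SSWM only).
#' @param N Population-size parameter (integer >= 1; SSWM only).
#' @param alpha Inverse temperature (positive; Metropolis only).
#' @return An object of class `"acceptance_rule"`.
#' @examples
#' accept_probability(sswm_rule(beta = 1, N = 2), 0)    # 1/2
#' accept_probability(metropolis_rule(alpha = 1), -1)   # exp(-1)
#' @export
acceptance_rule <- function(variant = c("elitist", "sswm", "metropolis"),
                            beta = NULL, N = NULL, alpha = NULL) {
  variant <- match.arg(variant)
  if (variant == "sswm") {
    if (is.null(beta) || is.null(N)) stop("SSWM requires 'beta' and 'N'")
    stopifnot(is.numeric(beta), length(beta) == 1, beta > 0)
    N <- as.integer(N)
    if (is.na(N) || N < 1) stop("'N' must be an integer >= 1")
    if (!is.null(alpha)) stop("'alpha' applies only to the Metropolis rule")
    rule <- list(variant = variant, beta = beta, N = N)
  } else if (variant == "metropolis") {
    if (is.null(alpha)) stop("Metropolis requires 'alpha'")
    stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
    if (!is.null(beta) || !is.null(N)) {
      stop("'beta'/'N' apply only to the SSWM rule")
    }
    rule <- list(variant = variant, alpha = alpha)
  } else {
    if (!is.null(beta) || !is.null(N) || !is.null(alpha)) {
      stop("the elitist rule takes no parameters")
    }
    rule <- list(variant = variant)
  }
  structure(rule, class = "acceptance_rule")
}

#' @rdname acceptance_rule
#' @export
elitist_rule <- function() acceptance_rule("elitist")

#' @rdname acceptance_rule
#' @export
sswm_rule <- function(beta, N) acceptance_rule("sswm", beta = beta, N = N)

#' @rdname acceptance_rule
#' @export
metropolis_rule <- function(alpha) acceptance_rule("metropolis", alpha = alpha)

#' @export
print.acceptance_rule <- function(x, ...) {
  cat(switch(x$variant,
             elitist = "Elitist acceptance: accept iff delta_f >= 0\n",
             sswm = sprintf("SSWM acceptance (Kimura fixation): beta = %g, N = %d\n",
                            x$beta, x$N),
             metropolis = sprintf("Metropolis acceptance: alpha = %g\n", x$alpha)))
  invisible(x)
}

## log(exp(y) - 1), stable for large y.
log_expm1 <- function(y) {
  ifelse(y > 30, y + log1p(-exp(-y)), log(expm1(y)))
}

## log p_fix(delta_f) for a single finite delta_f.  p_fix = (1 - e^-x) /
## (1 - e^-Nx) with x = 2*beta*delta_f; both factors have the same sign, so
## the log decomposes as log|1 - e^-x| - log|1 - e^-Nx|.
log_pfix <- function(beta, N, delta_f) {
  x <- 2 * beta * delta_f
  if (N == 1) return(0)
  if (abs(N * x) < 1e-12) return(-log(N)) # delta_f = 0 limit: 1/N
  if (x > 0) {
    # numerator 1 - e^-x = -expm1(-x) in (0, 1); same for the denominator
    log(-expm1(-x)) - log(-expm1(-N * x))
  } else {
    # rewrite as (e^-x - 1)/(e^-Nx - 1), both positive, evaluated in logs
    log_expm1(-x) - log_expm1(-N * x)
  }
}

#' Acceptance probability of a rule at a fitness difference
#'
#' Total on its domain: finite `delta_f` evaluates the rule's formula, and
#' the off-path sentinel `-Inf` yields exactly 0 for every rule, so a mutant
#' that falls off the embedded path is always rejected.
#'
#' @param rule An [acceptance_rule()].
#' @param delta_f Fitness difference(s) mutant minus parent; finite numeric
#'   or `-Inf` (vectorised).
#' @return Probabilities in `[0, 1]`.
#' @export
accept_probability <- function(rule, delta_f) {
  stopifnot(inherits(rule, "acceptance_rule"), is.numeric(delta_f))
  vapply(delta_f, function(d) {
    if (is.infinite(d) && d < 0) return(0) # off-path sentinel
    if (is.na(d) || is.infinite(d)) stop("'delta_f' must be finite or -Inf")
    switch(rule$variant,
           elitist = as.numeric(d >= 0),
           metropolis = if (d >= 0) 1 else exp(rule$alpha * d),
           sswm = exp(log_pfix(rule$beta, rule$N, d)))
  }, numeric(1))
}

#' Ratio of fixation probabilities at opposite fitness differences
#'
#' Computes `p_fix(-delta_f) / p_fix(+delta_f)` in log space.  Algebraically
#' the ratio collapses to `exp(-2*(N-1)*beta*delta_f)`: a symmetric
#' worsening is exponentially less likely to fix than the matching
#' improvement, with rate `2*(N-1)*beta`.
#'
#' @param beta Selection strength (positive).
#' @param N Population-size parameter (integer >= 1).
#' @param delta_f Fitness difference(s), finite (vectorised).
#' @return The ratio(s).
#' @examples
#' fixation_ratio(1, 2, 0.5)        # exp(-1)
#' @export
fixation_ratio <- function(beta, N, delta_f) {
  stopifnot(is.numeric(beta), beta > 0, is.numeric(delta_f))
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("'N' must be an integer >= 1")
  vapply(delta_f, function(d) {
    exp(log_pfix(beta, N, -d) - log_pfix(beta, N, d))
  }, numeric(1))
}

#' Elementary bounds on the fixation probability
#'
#' For `delta_f >= 0`:
#' `2*beta*delta_f / (1 + 2*beta*delta_f) <= p_fix <= 2*beta*delta_f / (1 - exp(-2*N*beta*delta_f))`.
#' For `delta_f <= 0`:
#' `-2*beta*delta_f * exp(2*N*beta*delta_f) <= p_fix <= exp(-2*beta*delta_f) / (exp(-2*N*beta*delta_f) - 1)`.
#' At `delta_f = 0` the limits are 0 and `1/N`.
#'
#' @inheritParams fixation_ratio
#' @param delta_f A single finite fitness difference.
#' @return Named numeric vector `c(lower, upper)` bracketing
#'   `accept_probability(sswm_rule(beta, N), delta_f)`.
#' @export
fixation_bounds <- function(beta, N, delta_f) {
  stopifnot(is.numeric(beta), beta > 0, is.numeric(delta_f), length(delta_f) == 1,
            is.finite(delta_f))
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("'N' must be an integer >= 1")
  x <- 2 * beta * delta_f
  if (delta_f == 0) {
    c(lower = 0, upper = 1 / N)
  } else if (delta_f > 0) {
    c(lower = x / (1 + x), upper = x / -expm1(-N * x))
  } else {
    c(lower = -x * exp(N * x), upper = exp(-x) / expm1(-N * x))
  }
}
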