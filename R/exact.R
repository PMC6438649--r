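#' Gambler's Ruin game with self-loops
#'
#' Two players hold `n1` and `n2` dollars.  Each round player 1 wins a
#' dollar with probability `p1`, loses one with probability `p2`, and
#' nothing happens with probability `1 - p1 - p2` (a self-loop).  Self-loops
#' stretch the expected duration of the game but leave the winning
#' probability untouched.
#'
#' @param n1,n2 Starting dollars of the two players (positive integers).
#' @param p1,p2 Per-round win probabilities; `p1 + p2 <= 1` and
#'   `p1 + p2 > 0`.
#' @return An object of class `"ruin_game"`.
#' @examples
#' g <- ruin_game(1, 3, 0.25, 0.25)
#' ruin_win_probability(g)    # 1/4
#' ruin_expected_duration(g)  # 6
#' @export
ruin_game <- function(n1, n2, p1, p2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || n1 < 1 || is.na(n2) || n2 < 1) {
    stop("'n1' and 'n2' must be positive integers")
  }
  stopifnot(is.numeric(p1), is.numeric(p2), length(p1) == 1, length(p2) == 1)
  if (p1 < 0 || p2 < 0 || p1 + p2 > 1 + 1e-12) {
    stop("need p1, p2 >= 0 and p1 + p2 <= 1")
  }
  if (p1 + p2 == 0) stop("invalid game: p1 + p2 must be positive")
  structure(list(n1 = n1, n2 = n2, p1 = p1, p2 = p2), class = "ruin_game")
}

## Branch tolerance for the equal-probability closed forms.
ruin_equal <- function(g) abs(g$p1 - g$p2) <= 1e-12 * (g$p1 + g$p2)

#' Winning probability of player 1
#'
#' `n1 / (n1 + n2)` in the fair case, otherwise
#' `(1 - (p2/p1)^n1) / (1 - (p2/p1)^(n1+n2))`, with the powers evaluated in
#' log space so extreme ratios and large stakes do not overflow.
#'
#' @param game A [ruin_game()].
#' @return Probability that player 1 wins all `n1 + n2` dollars.
#' @export
ruin_win_probability <- function(game) {
  stopifnot(inherits(game, "ruin_game"))
  if (game$p1 == 0) return(0)
  if (game$p2 == 0) return(1)
  if (ruin_equal(game)) return(game$n1 / (game$n1 + game$n2))
  lr <- log(game$p2) - log(game$p1) # log of the ratio r = p2/p1
  a <- game$n1; b <- game$n1 + game$n2
  if (lr > 0) {
    # rewrite as (r^n1 - 1) / (r^(n1+n2) - 1), both positive
    exp(log_expm1(a * lr) - log_expm1(b * lr))
  } else {
    expm1(a * lr) / expm1(b * lr)
  }
}

#' Expected duration of the game
#'
#' Self-loops stretch the standard game's duration by the waiting factor
#' `1/(p1 + p2)`, which gives `n1 * n2 / (p1 + p2)` in the fair case and
#' `(n1 - (n1 + n2) * P1) / (p2 - p1)` otherwise, with `P1` the winning
#' probability (the unfair branch is already homogeneous of degree -1, so
#' the waiting factor is absorbed into the unnormalised `p1`, `p2`).
#' Scaling both `p1` and `p2` down by a common factor (more self-loops)
#' scales the duration up by that factor.
#'
#' @param game A [ruin_game()].
#' @return Expected number of rounds until one player is bankrupt.
#' @export
ruin_expected_duration <- function(game) {
  stopifnot(inherits(game, "ruin_game"))
  n1 <- game$n1; n2 <- game$n2; M <- n1 + n2
  p1 <- game$p1; p2 <- game$p2
  if (ruin_equal(game)) return(n1 * n2 / (p1 + p2))
  if (p1 == 0 || p2 == 0) {
    # one-sided walk: sum of geometric waits over the distance covered
    return(if (p1 == 0) n1 / p2 else n2 / p1)
  }
  u <- log(p2) - log(p1)
  if (abs(u) < 1e-5) {
    # `n1 - M*P1` cancels to O(u), so expand both it and `p2 - p1` in u;
    # truncation error is O((M*u)^3), far below double precision here
    A <- 1 + (M + n1) * u / 3 + (M^2 + M * n1 + n1^2) * u^2 / 12
    B <- (1 + M * u / 2 + M^2 * u^2 / 6) * (1 + u / 2 + u^2 / 6)
    return(n1 * n2 / (2 * p1) * A / B)
  }
  if (u > 0) {
    P1 <- ruin_win_probability(game)
    (n1 - M * P1) / (p2 - p1)
  } else {
    # P1 is close to 1: work with the complement (player 2's win) instead
    Q <- ruin_win_probability(ruin_game(n2, n1, p2, p1))
    (M * Q - n2) / (p2 - p1)
  }
}

#' Birth-death chain over a height profile
#'
#' States are path positions `0..length(heights)-1`.  In each relevant step
#' a move up or down the profile is proposed with probability 1/2 each and
#' accepted with the rule's probability at the local height difference; the
#' remainder is a self-loop.  At the two ends the missing direction is
#' folded into a self-loop of at least 1/2.
#'
#' @param heights Numeric height profile (length >= 2).
#' @param rule An [acceptance_rule()].
#' @param absorbing States (0-based) to treat as absorbing by default in
#'   hitting-time queries; their outgoing probabilities are kept so the same
#'   chain can serve several queries.
#' @return An object of class `"chain_model"`: lists `p_up`, `p_down`,
#'   `p_self` indexed by state + 1, plus `n_states` and `absorbing`.
#' @export
valley_chain <- function(heights, rule, absorbing = integer(0)) {
  stopifnot(is.numeric(heights), length(heights) >= 2,
            inherits(rule, "acceptance_rule"))
  L <- length(heights)
  up <- c(0.5 * accept_probability(rule, diff(heights)), 0)
  down <- c(0, 0.5 * accept_probability(rule, -diff(heights)))
  self <- 1 - up - down
  structure(list(p_up = up, p_down = down, p_self = self,
                 n_states = L, absorbing = as.integer(absorbing),
                 heights = heights),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("Birth-death chain with %d states (0..%d)\n",
              x$n_states, x$n_states - 1))
  invisible(x)
}

## Thomas solve of a tridiagonal system.  lower[i] multiplies x[i-1],
## upper[i] multiplies x[i+1].  The first-step matrices (I - Q) of the
## chains here are weakly diagonally dominant M-matrices, for which the
## sweep is componentwise stable without pivoting even when the system is
## extremely ill-conditioned (hitting times exponential in the valley
## depth).
tridiag_solve <- function(lower, diagonal, upper, b) {
  n <- length(diagonal)
  if (n == 1) return(b / diagonal)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diagonal[1]
  dp[1] <- b[1] / diagonal[1]
  for (i in 2:n) {
    m <- diagonal[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i] <- (b[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Exact expected hitting time of a chain
#'
#' Solves the first-step equations `t_i = 1 + sum_j p_ij t_j` (with
#' `t = 0` on the target set); self-loops enter through the diagonal and
#' lengthen the time.  The walk is confined to the run of non-target
#' states around `start`.  When the run is absorbed at one end only, the
#' time is accumulated by the ladder recurrence
#' `t_s = (1 + q_s t_(s-1)) / p_s` (expected steps to first advance one
#' state towards the target), whose operations are all positive and hence
#' numerically stable under arbitrarily strong biases; a run absorbed at
#' both ends is solved by a tridiagonal elimination.
#'
#' @param chain A [valley_chain()] model.
#' @param start Starting state (0-based).
#' @param targets Target states (0-based); defaults to the chain's
#'   `absorbing` set.
#' @return Expected number of steps to first reach any target.
#' @export
hitting_time <- function(chain, start, targets = chain$absorbing) {
  stopifnot(inherits(chain, "chain_model"))
  if (length(targets) == 0) stop("no target states given")
  targets <- as.integer(targets)
  if (any(targets < 0 | targets > chain$n_states - 1)) stop("target state out of range")
  start <- as.integer(start)
  if (start < 0 || start > chain$n_states - 1) stop("start state out of range")
  if (start %in% targets) return(0)
  below <- targets[targets < start]; above <- targets[targets > start]
  lb <- if (length(below)) max(below) else NA_integer_
  rb <- if (length(above)) min(above) else NA_integer_
  if (is.na(lb) && is.na(rb)) stop("target unreachable from start")
  ts <- if (!is.na(lb) && !is.na(rb)) {
    # two absorbing barriers: eliminate over the enclosed run
    run_chain_states <- (lb + 1):(rb - 1)
    sub <- list(p_up = chain$p_up[run_chain_states + 1L],
                p_down = chain$p_down[run_chain_states + 1L])
    k <- length(run_chain_states)
    tridiag_solve(c(0, -sub$p_down[-1]),
                  sub$p_up + sub$p_down,
                  c(-sub$p_up[-k], 0),
                  rep(1, k))[start - lb]
  } else if (!is.na(rb)) {
    hitting_ladder(chain$p_up, chain$p_down, from = if (is.na(lb)) 0L else lb + 1L,
                   start = start, target = rb, direction = 1L)
  } else {
    # mirror: target below, reflecting or chain end above
    hitting_ladder(chain$p_down, chain$p_up,
                   from = chain$n_states - 1L, start = start, target = lb,
                   direction = -1L)
  }
  if (!is.finite(ts) || ts < 0) stop("target unreachable from start")
  ts
}

## Sum of expected one-state advance times towards a single absorbing end.
## `p` advances towards the target, `q` retreats; `from` is the reflecting
## end of the run.
hitting_ladder <- function(p, q, from, start, target, direction) {
  states <- seq(from, target - direction, by = direction)
  t_prev <- 0
  total <- 0
  started <- FALSE
  for (s in states) {
    t_s <- (1 + q[s + 1L] * t_prev) / p[s + 1L]
    if (s == start) started <- TRUE
    if (started) total <- total + t_s
    t_prev <- t_s
  }
  total
}

## log(sum(exp(v))) without overflow.
logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Exact absorption probability between two barriers
#'
#' Probability of reaching any state in `hit` before any state in `avoid`,
#' starting from `start`.  On a birth-death chain the walk is confined to
#' the run of non-absorbing states around `start`, delimited by (at most)
#' one barrier on each side; the two-barrier absorption probability is the
#' classical ratio of partial sums of products of down/up odds, evaluated
#' in log space so that exponentially unbalanced chains retain full
#' relative accuracy on both the likely and the unlikely side.  Self-loops
#' do not affect the result.
#'
#' @param chain A [valley_chain()] model.
#' @param start Starting state (0-based).
#' @param hit,avoid Disjoint sets of absorbing states (0-based).
#' @return A probability.
#' @export
absorption_probability <- function(chain, start, hit, avoid) {
  stopifnot(inherits(chain, "chain_model"))
  hit <- as.integer(hit); avoid <- as.integer(avoid)
  if (length(intersect(hit, avoid)) > 0) stop("'hit' and 'avoid' must be disjoint")
  start <- as.integer(start)
  if (start %in% hit) return(1)
  if (start %in% avoid) return(0)
  targets <- c(hit, avoid)
  if (any(targets < 0 | targets > chain$n_states - 1)) stop("target state out of range")
  below <- targets[targets < start]; above <- targets[targets > start]
  lb <- if (length(below)) max(below) else NA_integer_
  rb <- if (length(above)) min(above) else NA_integer_
  if (is.na(lb) && is.na(rb)) stop("no target reachable from start")
  if (is.na(lb)) return(as.numeric(rb %in% hit)) # left side reflecting
  if (is.na(rb)) return(as.numeric(lb %in% hit)) # right side reflecting
  # interior states lb+1 .. rb-1; odds ratio rho_s = p_down_s / p_up_s
  interior <- (lb + 1):(rb - 1)
  lrho <- log(chain$p_down[interior + 1L]) - log(chain$p_up[interior + 1L])
  # weights w_k = prod_{i<=k} rho, k = 0 .. rb-lb-1 (w_0 = 1), in logs
  lw <- c(0, cumsum(lrho))
  p_right <- exp(logsumexp(lw[seq_len(start - lb)]) - logsumexp(lw))
  p_left <- exp(logsumexp(lw[(start - lb + 1):length(lw)]) - logsumexp(lw))
  if (rb %in% hit) p_right else p_left
}

#' Expected descent time to the valley bottom, decomposed form
#'
#' Expected number of relevant steps to go from state 1 (one step into the
#' valley) to the bottom at state `l1`, using the Gambler's-Ruin
#' decomposition
#' `E(T) = (1/pGR_win) * (E(T_GR) + pGR_lose / p_restart)`:
#' the walk on the descending slope is a ruin game between barriers 0 and
#' `l1` with `p1 = 1/2 * p_acc(-d1/l1)` (one more step downhill) and
#' `p2 = 1/2 * p_acc(+d1/l1)` (one step back uphill); every return to the
#' start peak costs a restart through `p_restart = p(0 -> 1)`.
#'
#' @param spec A [valley()] specification.
#' @param rule An [acceptance_rule()] (any variant with positive downhill
#'   acceptance; the elitist rule never descends and has no finite value).
#' @return Expected number of relevant steps from state 1 to state `l1`.
#' @export
valley_descent_time <- function(spec, rule) {
  stopifnot(inherits(spec, "valley_spec"), inherits(rule, "acceptance_rule"))
  df <- -spec$d1 / spec$l1
  p1 <- 0.5 * accept_probability(rule, df)
  p2 <- 0.5 * accept_probability(rule, -df)
  if (p1 == 0) stop("the rule never accepts a downhill step; descent time is infinite")
  game <- ruin_game(1, spec$l1 - 1, p1, p2)
  win <- ruin_win_probability(game)
  dur <- ruin_expected_duration(game)
  (1 / win) * (dur + (1 - win) / p1)
}

#' Exact expected valley-crossing time in relevant steps
#'
#' Expected number of relevant steps from the left peak (state 0) to the
#' right peak (state `l1 + l2`), by a linear solve over the full valley
#' chain.
#'
#' @inheritParams valley_descent_time
#' @return Expected relevant steps; multiply by `n/2` for the matching
#'   number of function evaluations under local mutation on an `n`-bit path
#'   (see [relevant_to_evaluations()]).
#' @export
valley_crossing_time <- function(spec, rule) {
  stopifnot(inherits(spec, "valley_spec"))
  h <- valley_height(spec, 0:spec$l)
  hitting_time(valley_chain(h, rule), 0, spec$l)
}

#' Convert relevant steps to function evaluations
#'
#' Under local mutation on an `n`-bit Hamming path only 2 of the `n`
#' single-bit mutants are path neighbours, so the expected wait for a
#' relevant step is `n/2` evaluations.
#'
#' @param steps Number of relevant steps.
#' @param n Bit-string dimension.
#' @return `n/2 * steps`.
#' @export
relevant_to_evaluations <- function(steps, n) n / 2 * steps

#' Bounds on the downhill ruin winning probability, SSWM
#'
#' The walk one step into the descending slope is a ruin game with stakes
#' `n1 = 1`, `n2 = l1 - 1` and per-step fitness difference
#' `delta_f = -d1/l1`; player 1 is the downhill direction (reaching the
#' valley bottom before returning to the peak).  The winning probability
#' collapses to a fixation-type expression in `2*(N-1)*beta`, which these
#' elementary bounds bracket:
#' lower `-2*(N-1)*beta*delta_f * exp(2*(N-1)*beta*l1*delta_f)`,
#' upper `exp(-2*(N-1)*beta*delta_f) / (exp(-2*(N-1)*beta*l1*delta_f) - 1)`.
#' For `N = 1` the game is fair and the bounds degenerate to `(0, Inf)`.
#'
#' @param spec A [valley()] specification.
#' @param beta Selection strength.
#' @param N Population-size parameter.
#' @return List with `lower`, `upper` and the `exact` winning probability.
#' @export
sswm_ruin_bounds <- function(spec, beta, N) {
  stopifnot(inherits(spec, "valley_spec"), beta > 0, N >= 1)
  df <- -spec$d1 / spec$l1
  lam <- 2 * (N - 1) * beta
  rule <- sswm_rule(beta, N)
  game <- ruin_game(1, spec$l1 - 1,
                    0.5 * accept_probability(rule, df),
                    0.5 * accept_probability(rule, -df))
  list(lower = -lam * df * exp(lam * spec$l1 * df),
       upper = if (N == 1) Inf else exp(-lam * df) / expm1(-lam * spec$l1 * df),
       exact = ruin_win_probability(game))
}

#' Bounds on the downhill ruin winning probability, Metropolis
#'
#' Same game as [sswm_ruin_bounds()] with `p1 = 1/2 * exp(alpha*delta_f)`
#' (accepting the worsening `delta_f = -d1/l1`) and `p2 = 1/2`:
#' lower `-alpha*delta_f * exp(alpha*l1*delta_f)`,
#' upper `exp(-alpha*delta_f) / (exp(-alpha*l1*delta_f) - 1)`.
#'
#' @param spec A [valley()] specification.
#' @param alpha Inverse temperature.
#' @return List with `lower`, `upper` and the `exact` winning probability.
#' @export
metropolis_ruin_bounds <- function(spec, alpha) {
  stopifnot(inherits(spec, "valley_spec"), alpha > 0)
  df <- -spec$d1 / spec$l1
  game <- ruin_game(1, spec$l1 - 1, 0.5 * exp(alpha * df), 0.5)
  list(lower = -alpha * df * exp(alpha * spec$l1 * df),
       upper = exp(-alpha * df) / expm1(-alpha * spec$l1 * df),
       exact = ruin_win_probability(game))
}

## Decay rate of the acceptance ratio p_acc(df)/p_acc(-df) = exp(lambda*df).
rule_lambda <- function(rule) {
  switch(rule$variant,
         sswm = 2 * rule$beta * (rule$N - 1),
         metropolis = rule$alpha,
         stop("peak drift is defined for the SSWM and Metropolis rules only"))
}

#' Peak-to-peak drift diagnostics on a chain of valleys
#'
#' From an interior peak the next extreme point reached is the left or
#' right neighbouring minimum (probabilities `p_down_left`,
#' `p_down_right`); from a minimum it is the left or right neighbouring
#' peak (`p_up_left`, `p_up_right`).  All four are computed exactly as
#' absorption probabilities by linear solves on the adjacent slopes.  For
#' any rule whose acceptance ratio satisfies
#' `p_acc(df)/p_acc(-df) = exp(lambda*df)` the product ratio collapses to
#' `(p_down_left*p_up_left)/(p_down_right*p_up_right) = exp(-lambda*(d2 - d1))`
#' with `lambda = 2*beta*(N-1)` for SSWM and `lambda = alpha` for
#' Metropolis; the probability that a transition between peaks moves right
#' (towards the optimum) is `1/(1 + ratio)` and the drift over peaks is
#' `2/(1 + ratio) - 1`.
#'
#' @param spec A [valleypath()] specification with `m >= 2`.
#' @param rule An SSWM or Metropolis [acceptance_rule()].
#' @param peak Index of the interior peak to analyse, in `1..m-1`
#'   (default 1).
#' @return An object of class `"drift_report"` with the four absorption
#'   probabilities, `ratio`, its closed form `ratio_closed_form`,
#'   `peak_step_right_prob` and `drift`.
#' @export
drift_report <- function(spec, rule, peak = 1) {
  stopifnot(inherits(spec, "valleypath_spec"), inherits(rule, "acceptance_rule"))
  lam <- rule_lambda(rule)
  v <- spec$valley
  peak <- as.integer(peak)
  if (spec$m < 2) stop("peak drift needs at least 2 valleys")
  if (peak < 1 || peak > spec$m - 1) {
    stop(sprintf("boundary peak: 'peak' must be interior, in [1, %d]", spec$m - 1))
  }
  chain <- valley_chain(global_heights(spec), rule)
  g0 <- peak * v$l                 # the analysed peak
  g_min_l <- g0 - v$l2             # minimum of the valley to its left
  g_min_r <- g0 + v$l1             # minimum of the valley to its right
  g_peak_l <- (peak - 1) * v$l
  g_peak_r <- (peak + 1) * v$l
  # each probability gets its own solve: complements would lose all relative
  # precision when one side is exponentially unlikely
  p_down_right <- absorption_probability(chain, g0, hit = g_min_r, avoid = g_min_l)
  p_down_left <- absorption_probability(chain, g0, hit = g_min_l, avoid = g_min_r)
  p_up_left <- absorption_probability(chain, g_min_l, hit = g_peak_l, avoid = g0)
  p_up_right <- absorption_probability(chain, g_min_r, hit = g_peak_r, avoid = g0)
  ratio <- (p_down_left * p_up_left) / (p_down_right * p_up_right)
  structure(list(p_down_left = p_down_left, p_down_right = p_down_right,
                 p_up_left = p_up_left, p_up_right = p_up_right,
                 ratio = ratio,
                 ratio_closed_form = exp(-lam * (v$d2 - v$d1)),
                 lambda = lam,
                 peak_step_right_prob = 1 / (1 + ratio),
                 drift = 2 / (1 + ratio) - 1),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("Peak drift: ratio = %.6g (closed form %.6g), P(step right) = %.6g, drift = %.6g\n",
              x$ratio, x$ratio_closed_form, x$peak_step_right_prob, x$drift))
  invisible(x)
}

#' Exact expected time to cross a chain of valleys
#'
#' Expected number of relevant steps from global position 0 to the global
#' optimum at `m*l`, by a sparse linear solve on the flattened chain.
#'
#' @param spec A [valleypath()] specification.
#' @param rule An [acceptance_rule()].
#' @param max_states Refuse chains larger than this (default `1e5`);
#'   simulate instead.
#' @return Expected relevant steps.
#' @export
valleypath_expected_time <- function(spec, rule, max_states = 1e5) {
  stopifnot(inherits(spec, "valleypath_spec"))
  h <- global_heights(spec)
  if (length(h) > max_states) {
    stop(sprintf("chain has %d states (cap %d); use the chain-mode simulator",
                 length(h), as.integer(max_states)))
  }
  hitting_time(valley_chain(h, rule), 0, length(h) - 1)
}
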