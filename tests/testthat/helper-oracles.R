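# Independent brute-force oracles: dense first-step linear systems built
# from the full transition matrix, solved with base::solve.  These share no
# code with the package's tridiagonal/log-space routines.

dense_transition <- function(chain) {
  L <- chain$n_states
  P <- matrix(0, L, L)
  for (i in seq_len(L)) {
    if (i > 1) P[i, i - 1] <- chain$p_down[i]
    if (i < L) P[i, i + 1] <- chain$p_up[i]
    P[i, i] <- chain$p_self[i]
  }
  P
}

# Expected steps from every transient state to the target set (0-based).
dense_hitting_time <- function(chain, targets) {
  P <- dense_transition(chain)
  L <- chain$n_states
  tr <- setdiff(seq_len(L), targets + 1)
  t <- solve(diag(length(tr)) - P[tr, tr, drop = FALSE], rep(1, length(tr)))
  full <- numeric(L)
  full[tr] <- t
  full # index by state + 1
}

# P(reach `hit` before `avoid`) from every transient state.
dense_absorption <- function(chain, hit, avoid) {
  P <- dense_transition(chain)
  L <- chain$n_states
  targets <- c(hit, avoid) + 1
  tr <- setdiff(seq_len(L), targets)
  b <- rowSums(P[tr, hit + 1, drop = FALSE])
  h <- solve(diag(length(tr)) - P[tr, tr, drop = FALSE], b)
  full <- numeric(L)
  full[tr] <- h
  full[hit + 1] <- 1
  full
}

# A ruin game as an explicit (n1+n2+1)-state chain: states are player 1's
# dollars; the game itself, not the package's closed forms.
ruin_chain <- function(n1, n2, p1, p2) {
  heights <- rep(0, n1 + n2 + 1)
  ch <- list(p_up = c(rep(p1, n1 + n2), 0),
             p_down = c(0, rep(p2, n1 + n2)),
             p_self = c(1, rep(1 - p1 - p2, n1 + n2 - 1), 1),
             n_states = n1 + n2 + 1, absorbing = c(0L, n1 + n2),
             heights = heights)
  class(ch) <- "chain_model"
  ch
}

random_ruin_game <- function() {
  n1 <- sample(1:6, 1)
  n2 <- sample(1:6, 1)
  if (stats::runif(1) < 0.2) {
    p <- stats::runif(1, 0.05, 0.45) # equal-probability branch
    ruin_game(n1, n2, p, p)
  } else if (stats::runif(1) < 0.25) {
    p <- stats::runif(1, 0.05, 0.45) # near-equal: exercises branch switch
    ruin_game(n1, n2, p, p * (1 + stats::runif(1, 1e-9, 1e-7)))
  } else {
    p1 <- stats::runif(1, 0.02, 0.6)
    p2 <- stats::runif(1, 0.02, min(0.9 - p1, 0.6))
    ruin_game(n1, n2, p1, p2)
  }
}

random_valley <- function() {
  d1 <- stats::runif(1, 0.2, 3)
  valley(sample(2:7, 1), sample(2:7, 1), d1, d1 + stats::runif(1, 0, 3))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * max(abs(expected), .Machine$double.xmin))
}

# lower <= p <= upper, with relative slack for rounding in the bound
# expressions and absolute slack for values at the denormal floor
expect_bracket <- function(lower, upper, p, rel = 1e-12, abs = 1e-300) {
  expect_lte(lower, p * (1 + rel) + abs)
  expect_gte(upper, p * (1 - rel) - abs)
}
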