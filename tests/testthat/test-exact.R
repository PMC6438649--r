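test_that("ruin game validates probabilities and stakes", {
  expect_error(ruin_game(0, 2, 0.3, 0.3), "positive integers")
  expect_error(ruin_game(1, 2, 0.6, 0.6), "p1")
  expect_error(ruin_game(1, 2, 0, 0), "invalid")
})

test_that("ruin closed forms reproduce textbook values", {
  g <- ruin_game(1, 3, 0.25, 0.25)
  expect_equal(ruin_win_probability(g), 1 / 4) # fair game: n1/(n1+n2)
  expect_equal(ruin_expected_duration(ruin_game(1, 1, 0.5, 0.5)), 1)
  # ratio 1/2, single dollar each: (1 - 1/2)/(1 - 1/4) = 2/3
  expect_equal(ruin_win_probability(ruin_game(1, 1, 0.4, 0.2)), 2 / 3)
  expect_equal(ruin_win_probability(ruin_game(1, 1, 0.2, 0)), 1)
  expect_equal(ruin_win_probability(ruin_game(2, 3, 0, 0.2)), 0)
})

test_that("self-loops stretch durations but not winning probabilities", {
  g1 <- ruin_game(2, 3, 0.3, 0.2)
  g2 <- ruin_game(2, 3, 0.15, 0.1) # halved: twice the self-loop waiting
  expect_equal(ruin_win_probability(g1), ruin_win_probability(g2))
  expect_equal(2 * ruin_expected_duration(g1), ruin_expected_duration(g2))
  gf <- ruin_game(2, 2, 0.25, 0.25)
  expect_equal(2 * ruin_expected_duration(gf),
               ruin_expected_duration(ruin_game(2, 2, 0.125, 0.125)))
})

test_that("ruin closed forms agree with brute-force absorption on random games", {
  set.seed(101)
  for (i in 1:120) {
    g <- random_ruin_game()
    ch <- ruin_chain(g$n1, g$n2, g$p1, g$p2)
    top <- g$n1 + g$n2
    win_bf <- dense_absorption(ch, hit = top, avoid = 0)[g$n1 + 1]
    dur_bf <- dense_hitting_time(ch, targets = c(0, top))[g$n1 + 1]
    expect_rel_equal(ruin_win_probability(g), win_bf, 1e-9)
    expect_rel_equal(ruin_expected_duration(g), dur_bf, 1e-9)
  }
})

test_that("near-equal probabilities cross the branch switch continuously", {
  for (eps in c(0, 1e-15, 1e-13, 1e-10, 1e-8)) {
    g <- ruin_game(3, 4, 0.3, 0.3 * (1 + eps))
    expect_equal(ruin_win_probability(g), 3 / 7, tolerance = 1e-6)
    expect_equal(ruin_expected_duration(g), 12 / 0.6, tolerance = 1e-5)
  }
})

test_that("chain rows are stochastic and biases match the fixation ratio", {
  set.seed(3)
  for (i in 1:40) {
    v <- random_valley()
    rule <- if (stats::runif(1) < 0.5) {
      sswm_rule(stats::runif(1, 0.2, 2), sample(2:8, 1))
    } else {
      metropolis_rule(stats::runif(1, 0.3, 2))
    }
    ch <- valley_chain(valley_height(v, 0:v$l), rule)
    expect_equal(ch$p_up + ch$p_down + ch$p_self, rep(1, v$l + 1))
    expect_true(all(ch$p_up >= 0 & ch$p_down >= 0 & ch$p_self >= 0))
    # ends fold the missing direction into a self-loop of at least 1/2
    expect_gte(ch$p_self[1], 0.5)
    expect_gte(ch$p_self[v$l + 1], 0.5)
    if (rule$variant == "sswm") {
      # interior up/down bias on the descending flank reproduces the
      # symmetric fixation ratio of the local height step
      i <- sample(seq_len(v$l1 - 1), 1) + 1 # interior descending state
      step <- v$d1 / v$l1
      expect_rel_equal(ch$p_up[i] / ch$p_down[i],
                       fixation_ratio(rule$beta, rule$N, step), 1e-12)
    }
  }
  # the elitist rule never steps downhill
  vch <- valley_chain(valley_height(valley(3, 3, 1, 2), 0:6), elitist_rule())
  expect_equal(vch$p_up[1:3], rep(0, 3))
})

test_that("hitting times solve the first-step equations", {
  # deterministic up-chain: expected time equals twice the distance
  # (up proposed with probability 1/2, always accepted; elitism never
  # steps back down)
  ch <- valley_chain(c(0, 1, 2, 3, 4), elitist_rule())
  expect_equal(hitting_time(ch, 0, 4), 8)
  expect_equal(hitting_time(ch, 4, 4), 0)
  # against the dense first-step oracle on random chains
  set.seed(17)
  for (i in 1:30) {
    v <- random_valley()
    rule <- metropolis_rule(stats::runif(1, 0.3, 1.5))
    ch <- valley_chain(valley_height(v, 0:v$l), rule)
    bf <- dense_hitting_time(ch, targets = v$l)
    expect_rel_equal(hitting_time(ch, 0, v$l), bf[1], 1e-9)
    expect_rel_equal(hitting_time(ch, v$l1, v$l), bf[v$l1 + 1], 1e-9)
  }
  # unreachable target: elitist walk cannot descend
  ech <- valley_chain(valley_height(valley(2, 2, 1, 2), 0:2), elitist_rule())
  expect_error(hitting_time(ech, 0, 2), "unreachable")
})

test_that("hitting time on a two-barrier chain equals the ruin duration", {
  set.seed(23)
  for (i in 1:50) {
    g <- random_ruin_game()
    ch <- ruin_chain(g$n1, g$n2, g$p1, g$p2)
    expect_rel_equal(hitting_time(ch, g$n1, c(0, g$n1 + g$n2)),
                     ruin_expected_duration(g), 1e-9)
  }
})

test_that("absorption probabilities match the dense oracle in moderate regimes", {
  set.seed(29)
  for (i in 1:40) {
    v <- random_valley()
    rule <- sswm_rule(stats::runif(1, 0.2, 1), sample(2:4, 1))
    ch <- valley_chain(valley_height(v, 0:v$l), rule)
    s <- sample(seq_len(v$l - 1), 1)
    mine <- absorption_probability(ch, s, hit = v$l, avoid = 0)
    bf <- dense_absorption(ch, hit = v$l, avoid = 0)[s + 1]
    if (bf > 1e-6 && bf < 1 - 1e-6) expect_rel_equal(mine, bf, 1e-9)
    # the two sides always partition certainty
    other <- absorption_probability(ch, s, hit = 0, avoid = v$l)
    expect_equal(mine + other, 1, tolerance = 1e-12)
  }
  expect_equal(absorption_probability(valley_chain(c(0, 1), metropolis_rule(1)),
                                      1, hit = 1, avoid = 0), 1)
})

test_that("the descent-time decomposition equals the linear-solve hitting time", {
  rules <- list(sswm_rule(1, 2), sswm_rule(0.5, 4), sswm_rule(2, 3),
                metropolis_rule(1), metropolis_rule(0.4), metropolis_rule(2),
                sswm_rule(1, 1)) # N = 1: fair-walk branch
  specs <- list(valley(4, 4, 4, 5), valley(3, 3, 3, 4), valley(2, 5, 1, 3),
                valley(6, 2, 2, 2.5), valley(5, 3, 0.5, 2))
  for (rule in rules) for (v in specs) {
    dec <- valley_descent_time(v, rule)
    ch <- valley_chain(valley_height(v, 0:v$l1), rule)
    expect_rel_equal(dec, hitting_time(ch, 1, v$l1), 1e-9)
  }
  expect_error(valley_descent_time(valley(2, 2, 1, 2), elitist_rule()),
               "never accepts")
})

test_that("downhill ruin bounds bracket the exact escape probability", {
  set.seed(31)
  for (i in 1:200) {
    v <- random_valley()
    b <- sswm_ruin_bounds(v, stats::runif(1, 0.2, 3), sample(2:12, 1))
    expect_bracket(b$lower, b$upper, b$exact)
  }
  for (i in 1:200) {
    v <- random_valley()
    b <- metropolis_ruin_bounds(v, stats::runif(1, 0.2, 3))
    expect_bracket(b$lower, b$upper, b$exact)
  }
  # N = 1 plays a fair game: stake over total stakes
  v <- valley(4, 3, 2, 3)
  expect_equal(sswm_ruin_bounds(v, 1, 1)$exact, 1 / 4)
  # stronger selection makes each downhill step rarer relative to the
  # uphill retreat, so the bottom-before-peak probability shrinks
  expect_lt(metropolis_ruin_bounds(v, 50)$exact,
            metropolis_ruin_bounds(v, 0.5)$exact)
})

test_that("peak ratio identity holds across the parameter grid", {
  depths <- list(c(1, 2), c(2, 3), c(0.5, 4))
  lengths <- list(c(2, 2), c(3, 5), c(6, 3)) # includes d2/l2 < d1/l1 cases
  for (beta in c(0.25, 1, 4)) for (N in c(2, 3, 10)) {
    for (d in depths) for (l in lengths) {
      vp <- valleypath(2, valley(l[1], l[2], d[1], d[2]))
      dr <- drift_report(vp, sswm_rule(beta, N))
      expect_rel_equal(dr$ratio, exp(-2 * beta * (N - 1) * (d[2] - d[1])), 1e-9)
    }
  }
  for (alpha in c(0.5, 1, 2)) for (d in depths) for (l in lengths) {
    vp <- valleypath(2, valley(l[1], l[2], d[1], d[2]))
    dr <- drift_report(vp, metropolis_rule(alpha))
    expect_rel_equal(dr$ratio, exp(-alpha * (d[2] - d[1])), 1e-9)
  }
})

test_that("drift report is a coherent probability summary", {
  vp <- valleypath(3, valley(2, 2, 2, 4))
  dr <- drift_report(vp, sswm_rule(1, 2), peak = 2)
  expect_equal(dr$p_down_left + dr$p_down_right, 1, tolerance = 1e-12)
  expect_equal(dr$p_up_left + dr$p_up_right, 1, tolerance = 1e-12)
  expect_equal(dr$peak_step_right_prob, 1 / (1 + dr$ratio))
  expect_equal(dr$drift, 2 * dr$peak_step_right_prob - 1)
  expect_gte(dr$drift, -1); expect_lte(dr$drift, 1)
  expect_error(drift_report(vp, sswm_rule(1, 2), peak = 0), "boundary")
  expect_error(drift_report(vp, sswm_rule(1, 2), peak = 3), "boundary")
  expect_error(drift_report(vp, elitist_rule()), "SSWM")
})

test_that("chain-of-valleys crossing times behave like repeated single valleys", {
  v <- valley(2, 2, 2, 4)
  rule <- sswm_rule(1, 2)
  # one valley: identical chain, identical time
  # same chain up to a constant height offset, which no rule can see
  expect_equal(valleypath_expected_time(valleypath(1, v), rule),
               valley_crossing_time(v, rule))
  et <- vapply(1:6, function(m) {
    valleypath_expected_time(valleypath(m, v), rule)
  }, numeric(1))
  expect_true(all(diff(et) > 0)) # strictly increasing in m
  pv <- et / (1:6)
  expect_lt(max(pv) / min(pv), 3) # linear regime under strong drift
  expect_error(valleypath_expected_time(valleypath(2, v), rule, max_states = 5),
               "states")
})
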