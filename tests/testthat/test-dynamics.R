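test_that("local mutation flips exactly one uniformly chosen position", {
  set.seed(1)
  for (i in 1:50) {
    b <- paste(sample(0:1, 12, replace = TRUE), collapse = "")
    m <- mutate_local(b)
    expect_equal(sum(strsplit(b, "")[[1]] != strsplit(m, "")[[1]]), 1)
  }
  expect_equal(mutate_local("0"), "1") # n = 1 always flips the only bit
  # flip positions are uniform: multinomial check within 4 sigma per cell
  set.seed(2)
  n <- 8; draws <- 2e4
  pos <- integer(draws)
  b0 <- strrep("0", n)
  for (i in seq_len(draws)) {
    pos[i] <- which(strsplit(mutate_local(b0), "")[[1]] == "1")
  }
  counts <- tabulate(pos, n)
  expected <- draws / n
  sigma <- sqrt(draws * (1 / n) * (1 - 1 / n))
  expect_true(all(abs(counts - expected) < 4 * sigma))
})

test_that("standard bit mutation flips a Binomial(n, 1/n) number of bits", {
  expect_equal(mutate_global("0"), "1") # n = 1 flips with probability 1
  set.seed(3)
  n <- 16; draws <- 2e4
  b0 <- strrep("0", n)
  flips <- vapply(seq_len(draws), function(i) {
    sum(strsplit(mutate_global(b0), "")[[1]] == "1")
  }, numeric(1))
  # mean number of flips is 1, within 4 standard errors
  expect_lt(abs(mean(flips) - 1), 4 * sqrt(1 * (1 - 1 / n)) / sqrt(draws))
  # no-flip probability is (1 - 1/n)^n
  p0 <- (1 - 1 / n)^n
  expect_lt(abs(mean(flips == 0) - p0), 4 * sqrt(p0 * (1 - p0) / draws))
})

test_that("identical configuration reproduces runs bit for bit", {
  v <- valley(2, 2, 2, 4)
  h <- valley_height(v, 0:v$l)
  cfg <- sim_config(seed = 99, replicates = 5, budget = 1e5)
  r1 <- run_chain(h, sswm_rule(1, 2), cfg)
  r2 <- run_chain(h, sswm_rule(1, 2), cfg)
  expect_identical(r1, r2)
  sp <- long_k_path(9, 3)
  b1 <- run_bitstring(sp, h, metropolis_rule(1), "local", cfg)
  b2 <- run_bitstring(sp, h, metropolis_rule(1), "local", cfg)
  expect_identical(b1, b2)
  s1 <- run_segment_jump(valley(2, 2, 1, 2), 16, cfg)
  s2 <- run_segment_jump(valley(2, 2, 1, 2), 16, cfg)
  expect_identical(s1, s2)
  # replicate r is seeded with seed + r
  expect_equal(r1$seed, 99 + 1:5)
})

test_that("budgets censor rather than error and zero budget does nothing", {
  v <- valley(2, 2, 2, 4)
  h <- valley_height(v, 0:v$l)
  r <- run_chain(h, sswm_rule(1, 2), sim_config(seed = 1, replicates = 3,
                                                budget = 0))
  expect_equal(r$relevant_steps, rep(0, 3))
  expect_false(any(r$hit))
  r <- run_chain(h, sswm_rule(5, 50), sim_config(seed = 1, replicates = 3,
                                                 budget = 25))
  expect_true(all(r$relevant_steps <= 25))
  expect_true(all(r$evaluations <= 25 * 10 | is.na(r$evaluations)))
})

test_that("elitist trajectories never lose fitness and stay on the path", {
  sp <- long_k_path(8, 4)
  h <- c(0, 1, 1, 2, 3) # weakly increasing: elitism can reach the top
  r <- run_bitstring(sp, h, elitist_rule(), "global",
                     sim_config(seed = 4, replicates = 20, budget = 1e5))
  expect_true(all(r$hit))
  expect_true(all(r$final_index == 4))
})

test_that("single-state landscape needs no steps", {
  r <- run_chain(0, sswm_rule(1, 2), sim_config(seed = 1, replicates = 2))
  expect_equal(r$relevant_steps, c(0, 0))
  expect_true(all(r$hit))
})

test_that("climbing a monotone slope takes about two relevant steps per rung", {
  # elitist walk: uphill moves always accepted, downhill never, so each
  # rung costs a Geometric(1/2) number of proposals
  L <- 30
  r <- run_chain(seq_len(L), elitist_rule(),
                 sim_config(seed = 10, replicates = 800))
  se <- stats::sd(r$relevant_steps) / sqrt(nrow(r))
  expect_lt(abs(mean(r$relevant_steps) - 2 * (L - 1)), 4 * se)
})

test_that("chain-mode means match the exact hitting time", {
  v <- valley(2, 2, 2, 4)
  rule <- sswm_rule(1, 2)
  exact <- valley_crossing_time(v, rule)
  r <- run_chain(valley_height(v, 0:v$l), rule,
                 sim_config(seed = 12, replicates = 2000))
  se <- stats::sd(r$relevant_steps) / sqrt(nrow(r))
  expect_lt(abs(mean(r$relevant_steps) - exact), 3 * se)
})

test_that("segment-jump mode reproduces the exact jump-chain crossing time", {
  # accepted moves jump i positions with probability n^-i (1 - 1/n)^(n-i)
  # per direction; the simulator's mean crossing time must match the exact
  # expected absorption time of that jump chain (dense oracle)
  n <- 16
  v <- valley(2, 2, 1, 2)
  cfg <- sim_config(seed = 21, replicates = 3000, budget = 1e8)
  r <- run_segment_jump(v, n, cfg)
  expect_true(all(r$hit))
  expect_true(all(r$final_index == v$l))
  jp <- function(i) n^(-i) * (1 - 1 / n)^(n - i)
  states <- 0:v$l
  h <- valley_height(v, states)
  n_states <- length(states)
  P <- matrix(0, n_states, n_states)
  for (s in states) {
    for (t in states) {
      if (t != s && h[t + 1] >= h[s + 1]) P[s + 1, t + 1] <- jp(abs(t - s))
    }
    P[s + 1, s + 1] <- 1 - sum(P[s + 1, ])
  }
  tr <- seq_len(n_states - 1)
  exact <- solve(diag(n_states - 1) - P[tr, tr], rep(1, n_states - 1))[1]
  se <- stats::sd(r$evaluations) / sqrt(nrow(r))
  expect_lt(abs(mean(r$evaluations) - exact), 3 * se)
  expect_error(run_segment_jump(v, 16, cfg, k = 4), "requires k")
})

test_that("bitstring and chain modes agree on a small embedded valley", {
  v <- valley(2, 2, 2, 4)
  h <- valley_height(v, 0:v$l)
  sp <- long_k_path(16, 8)
  rule <- metropolis_rule(1)
  exact <- valley_crossing_time(v, rule)
  bs <- run_bitstring(sp, h, rule, "local",
                      sim_config(seed = 31, replicates = 400, budget = 1e6))
  ch <- run_chain(h, rule, sim_config(seed = 32, replicates = 2000), n = 16)
  se_bs <- stats::sd(bs$relevant_steps) / sqrt(nrow(bs))
  se_ch <- stats::sd(ch$relevant_steps) / sqrt(nrow(ch))
  expect_lt(abs(mean(bs$relevant_steps) - exact), 3 * se_bs)
  expect_lt(abs(mean(ch$relevant_steps) - exact), 3 * se_ch)
  # waiting-time contract: n/2 evaluations per relevant step, within 10%
  ratio <- mean(bs$evaluations) / mean(bs$relevant_steps)
  expect_lt(abs(ratio - 8), 0.8)
})

test_that("starting off the embedded profile is refused", {
  sp <- long_k_path(6, 3)
  h <- valley_height(valley(2, 2, 1, 2), 0:4)
  expect_error(run_bitstring(sp, h, elitist_rule(), "global",
                             sim_config(), start = "010101"),
               "not on")
})
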