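#' Simulation configuration
#'
#' @param seed Base RNG seed; replicate `r` uses `seed + r`, so a
#'   configuration fully determines every trajectory.
#' @param replicates Number of independent runs.
#' @param budget Maximum number of function evaluations (relevant steps in
#'   chain mode) per run; exhausting it is a reported outcome, not an error.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, replicates = 1, budget = 1e8) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(replicates), replicates >= 1,
            is.numeric(budget), budget >= 0)
  structure(list(seed = as.integer(seed), replicates = as.integer(replicates),
                 budget = budget),
            class = "sim_config")
}

#' Single-bit local mutation
#'
#' Flips one position chosen uniformly at random, so the offspring is
#' always at Hamming distance exactly 1.
#'
#' @param bits A non-empty bit string.
#' @return The mutated bit string.
#' @export
mutate_local <- function(bits) {
  v <- bits_to_int(bits)
  if (length(v) == 0) stop("'bits' must be non-empty")
  i <- sample.int(length(v), 1)
  v[i] <- 1L - v[i]
  int_to_bits(v)
}

#' Standard bit mutation
#'
#' Flips each bit independently with probability `1/n`; flipping no bit at
#' all is allowed (probability `(1 - 1/n)^n`).
#'
#' @param bits A non-empty bit string.
#' @return The mutated bit string.
#' @export
mutate_global <- function(bits) {
  v <- bits_to_int(bits)
  n <- length(v)
  if (n == 0) stop("'bits' must be non-empty")
  flip <- stats::runif(n) < 1 / n
  v[flip] <- 1L - v[flip]
  int_to_bits(v)
}

run_results_df <- function(rows) {
  out <- do.call(rbind, rows)
  class(out) <- c("run_results", "data.frame")
  out
}

#' Simulate search on an embedded landscape, full bit-string mode
#'
#' Runs the mutate / accept-with-probability loop on the long k-path with
#' the height profile embedded on its leading points.  Every iteration
#' costs one function evaluation; off-path offspring carry the sentinel
#' fitness and are always rejected, so the trajectory never leaves the
#' profile.  A run stops when the last profile point (the optimum) is
#' current or the budget is exhausted.
#'
#' Relevant steps are counted so that they reproduce the reduced up/down
#' chain exactly: a proposal of a profile neighbour is a relevant step, and
#' at the two boundary states a non-neighbour proposal is booked as a
#' self-loop relevant step with probability `1/(n-1)`, preserving the
#' boundary self-loop probability of 1/2 of the reduced process.  The mean
#' ratio of evaluations to relevant steps is then `n/2`.
#'
#' @param spec A [long_k_path()] specification.
#' @param heights Height profile for the leading path points (the last
#'   entry is the optimum).
#' @param rule An [acceptance_rule()].
#' @param mutation `"local"` (single uniform bit flip) or `"global"`
#'   (standard bit mutation).
#' @param config A [sim_config()].
#' @param start Starting bit string; defaults to path point 0 and must lie
#'   on the profile.
#' @return A data frame with one row per replicate: `replicate`, `seed`,
#'   `evaluations`, `relevant_steps`, `hit`, `final_index`.
#' @export
run_bitstring <- function(spec, heights, rule, mutation = c("local", "global"),
                          config = sim_config(), start = NULL) {
  stopifnot(inherits(spec, "long_k_path"), inherits(rule, "acceptance_rule"),
            inherits(config, "sim_config"))
  mutation <- match.arg(mutation)
  tab <- path_fitness_table(spec, heights)
  if (is.null(start)) start <- path_point_chr(spec$n, spec$k, 0)
  if (!exists(start, envir = tab, inherits = FALSE)) {
    stop("'start' is not on the embedded landscape")
  }
  n <- spec$n
  m <- length(heights)
  target <- m - 1
  mut_fun <- if (mutation == "local") mutate_local else mutate_global
  rows <- lapply(seq_len(config$replicates), function(r) {
    rs <- config$seed + r
    set.seed(rs)
    cur <- start
    info <- get(cur, envir = tab, inherits = FALSE)
    cur_idx <- info[["index"]]; cur_h <- info[["height"]]
    evals <- 0; steps <- 0
    hit <- cur_idx == target
    while (!hit && evals < config$budget) {
      cand <- mut_fun(cur)
      evals <- evals + 1
      on_prof <- exists(cand, envir = tab, inherits = FALSE)
      if (on_prof) {
        ci <- get(cand, envir = tab, inherits = FALSE)
        cand_idx <- ci[["index"]]; cand_h <- ci[["height"]]
        neighbour <- abs(cand_idx - cur_idx) == 1
      } else {
        cand_idx <- NA_real_; cand_h <- -Inf; neighbour <- FALSE
      }
      if (mutation == "local") {
        if (neighbour) {
          steps <- steps + 1
        } else if ((cur_idx == 0 || cur_idx == target) &&
                   stats::runif(1) < 1 / (n - 1)) {
          steps <- steps + 1 # boundary self-loop of the reduced chain
        }
      }
      if (stats::runif(1) < accept_probability(rule, cand_h - cur_h)) {
        cur <- cand; cur_idx <- cand_idx; cur_h <- cand_h
        hit <- cur_idx == target
      }
    }
    data.frame(replicate = r, seed = rs, evaluations = evals,
               relevant_steps = if (mutation == "local") steps else NA_real_,
               hit = hit, final_index = cur_idx)
  })
  run_results_df(rows)
}

#' Simulate the reduced relevant-step chain
#'
#' Simulates the up/down process directly on a height profile: each
#' relevant step proposes a move up or down with probability 1/2 each (a
#' self-loop at the two ends) and accepts it with the rule's probability at
#' the height difference.  Exact for local mutations on a Hamming path; one
#' relevant step corresponds to `n/2` function evaluations.
#'
#' @param heights Numeric height profile; the run stops at the last entry.
#' @param rule An [acceptance_rule()].
#' @param config A [sim_config()]; the budget caps relevant steps.
#' @param n Optional bit-string dimension used to convert relevant steps to
#'   the `evaluations` column (`n/2` per step); `NA` otherwise.
#' @return A data frame as in [run_bitstring()]; `final_index` is the
#'   position on the profile.
#' @export
run_chain <- function(heights, rule, config = sim_config(), n = NULL) {
  stopifnot(is.numeric(heights), length(heights) >= 1,
            inherits(rule, "acceptance_rule"), inherits(config, "sim_config"))
  L <- length(heights)
  p_up <- c(accept_probability(rule, diff(heights)), 0)
  p_down <- c(0, accept_probability(rule, -diff(heights)))
  rows <- lapply(seq_len(config$replicates), function(r) {
    rs <- config$seed + r
    set.seed(rs)
    pos <- 1L # 1-based over 1..L
    steps <- 0
    hit <- pos == L
    while (!hit && steps < config$budget) {
      steps <- steps + 1
      up <- stats::runif(1) < 0.5
      if (up && pos < L) {
        if (stats::runif(1) < p_up[pos]) pos <- pos + 1L
      } else if (!up && pos > 1L) {
        if (stats::runif(1) < p_down[pos]) pos <- pos - 1L
      } # else: boundary self-loop
      hit <- pos == L
    }
    data.frame(replicate = r, seed = rs,
               evaluations = if (is.null(n)) NA_real_ else n / 2 * steps,
               relevant_steps = steps, hit = hit, final_index = pos - 1)
  })
  run_results_df(rows)
}

#' Simulate the elitist EA on a shortcut-free valley segment
#'
#' On a segment of a long k-path with `k` exceeding the segment length, the
#' Hamming distance between any two used points equals their index
#' difference, so standard bit mutation moves the EA by a signed jump of
#' length `i` with probability `1/n^i * (1 - 1/n)^(n-i)` per direction.
#' The simulator works directly on valley positions and skips the long
#' stretches of rejected evaluations by drawing geometric waiting times
#' between accepted jumps, which is exact in distribution for the hitting
#' time measured in function evaluations.
#'
#' @param spec A [valley()] specification (`l1 + l2 + 1` positions,
#'   heights from [valley_height()]).
#' @param n Bit-string dimension (`n > l1 + l2`).
#' @param config A [sim_config()].
#' @param k Optional fold parameter of the surrounding path; if supplied it
#'   must exceed the segment length `l1 + l2`, otherwise the segment is not
#'   shortcut-free and this mode is invalid.
#' @return A data frame as in [run_bitstring()] (`relevant_steps` is `NA`:
#'   the EA uses global mutation).
#' @export
run_segment_jump <- function(spec, n, config = sim_config(), k = NULL) {
  stopifnot(inherits(spec, "valley_spec"), inherits(config, "sim_config"))
  if (!is.null(k) && k <= spec$l) {
    stop(sprintf("segment-jump mode requires k > l1 + l2 (got k = %d, length %d)",
                 as.integer(k), spec$l))
  }
  if (n <= spec$l) stop("'n' must exceed the segment length")
  h <- valley_height(spec, 0:spec$l)
  L <- spec$l + 1 # positions 1..L over path indices 0..l
  # jump_prob[i] = per-evaluation probability of an accepted jump by i
  # positions in one given direction
  jp <- function(i) n^(-i) * (1 - 1 / n)^(n - i)
  rows <- lapply(seq_len(config$replicates), function(r) {
    rs <- config$seed + r
    set.seed(rs)
    pos <- 1L
    evals <- 0
    hit <- pos == L
    while (!hit && evals < config$budget) {
      targets <- setdiff(seq_len(L), pos)
      ok <- targets[h[targets] >= h[pos]] # elitist: accept ties and improvements
      q <- jp(abs(ok - pos))
      ptot <- sum(q)
      wait <- stats::rgeom(1, ptot) + 1
      if (evals + wait > config$budget) {
        evals <- config$budget
        break
      }
      evals <- evals + wait
      pos <- if (length(ok) == 1) ok else sample(ok, 1, prob = q)
      hit <- pos == L
    }
    data.frame(replicate = r, seed = rs, evaluations = evals,
               relevant_steps = NA_real_, hit = hit, final_index = pos - 1)
  })
  run_results_df(rows)
}
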