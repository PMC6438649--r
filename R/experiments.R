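#' Elitist length-scaling experiment
#'
#' Measures the mean number of function evaluations the elitist EA needs to
#' cross a valley embedded on a shortcut-free segment, over a grid of
#' bit-string dimensions `n`, and fits the log-log slope of mean time
#' against `n`.  The crossing-time law is `Theta(n^(l*))` with `l*` the
#' effective length of the valley, so the fitted slope estimates `l*`.
#'
#' @param spec A [valley()] specification.
#' @param n_grid Bit-string dimensions to test (each must exceed the
#'   segment length).
#' @param config A [sim_config()]; fewer than 20 replicates triggers a
#'   warning recorded in the result.
#' @return A list with `table` (per-`n` mean/sd of evaluations), `slope`,
#'   `slope_se`, `effective_length` and `warnings`.
#' @export
ea_length_scaling <- function(spec, n_grid, config = sim_config(replicates = 50)) {
  stopifnot(inherits(spec, "valley_spec"), inherits(config, "sim_config"))
  warnings <- character(0)
  if (config$replicates < 20) {
    warnings <- c(warnings, sprintf("only %d replicates; means will be noisy",
                                    config$replicates))
  }
  tab <- do.call(rbind, lapply(seq_along(n_grid), function(i) {
    n <- n_grid[i]
    cfg <- sim_config(seed = config$seed + i * 100003L,
                      replicates = config$replicates, budget = config$budget)
    res <- run_segment_jump(spec, n, cfg)
    data.frame(n = n, mean_evaluations = mean(res$evaluations),
               sd_evaluations = stats::sd(res$evaluations),
               hit_rate = mean(res$hit), replicates = nrow(res))
  }))
  fit <- stats::lm(log(mean_evaluations) ~ log(n), data = tab)
  list(table = tab,
       slope = unname(stats::coef(fit)[2]),
       slope_se = unname(summary(fit)$coefficients[2, 2]),
       effective_length = effective_length(spec),
       warnings = warnings)
}

## Sandwich on the slope of ln E(T) vs d1 implied by the non-elitist
## depth laws (d2 = d1 + 1, fixed slopes' lengths).
depth_slope_sandwich <- function(rule, l1) {
  switch(rule$variant,
         sswm = c(lower = 2 * (rule$N - 1) * rule$beta * (l1 - 1) / l1,
                  upper = 2 * rule$N * rule$beta * (l1 + 1) / l1),
         metropolis = c(lower = rule$alpha * (1 - 1 / l1),
                        upper = rule$alpha * (1 + 1 / l1)),
         stop("depth scaling applies to the SSWM and Metropolis rules"))
}

#' Non-elitist depth-scaling experiment
#'
#' Computes the exact expected number of relevant steps to cross a valley
#' (by linear solve, no sampling noise) over a grid of depths `d1` with
#' `d2 = d1 + 1`, and regresses `ln E(T)` on `d1`.  The depth laws predict
#' a slope inside `[2*(N-1)*beta*(l1-1)/l1, 2*N*beta*(l1+1)/l1]` for SSWM
#' and `[alpha*(1-1/l1), alpha*(1+1/l1)]` for Metropolis.  Grid cells whose
#' scaled gradients `c*d1/l1` or `c*d2/l2` (with `c` = `beta` or `alpha`)
#' fall below `min_gradient` are out of the laws' regime and are skipped
#' with a reason.
#'
#' @param rule An SSWM or Metropolis [acceptance_rule()].
#' @param l1,l2 Slope lengths of the valley family.
#' @param d1_grid Depths to test; `d2 = d1 + 1` per cell.
#' @param min_gradient Constant instantiating the "scaled gradient bounded
#'   below" precondition (default 0.5).
#' @return A list with `table` (per-cell `d1`, `expected_steps`, `used`,
#'   `reason`), `slope`, `sandwich`, and `in_sandwich`.
#' @export
depth_scaling <- function(rule, l1, l2, d1_grid, min_gradient = 0.5) {
  stopifnot(inherits(rule, "acceptance_rule"))
  strength <- switch(rule$variant, sswm = rule$beta, metropolis = rule$alpha,
                     stop("depth scaling applies to the SSWM and Metropolis rules"))
  tab <- do.call(rbind, lapply(d1_grid, function(d1) {
    d2 <- d1 + 1
    g1 <- strength * d1 / l1
    g2 <- strength * d2 / l2
    if (min(g1, g2) < min_gradient) {
      return(data.frame(d1 = d1, d2 = d2, expected_steps = NA_real_,
                        used = FALSE,
                        reason = sprintf("scaled gradient %.3g below %.3g",
                                         min(g1, g2), min_gradient)))
    }
    et <- valley_crossing_time(valley(l1, l2, d1, d2), rule)
    data.frame(d1 = d1, d2 = d2, expected_steps = et, used = TRUE, reason = "")
  }))
  used <- tab[tab$used, ]
  if (nrow(used) < 2) stop("fewer than 2 in-regime grid cells; widen 'd1_grid'")
  fit <- stats::lm(log(expected_steps) ~ d1, data = used)
  slope <- unname(stats::coef(fit)[2])
  sandwich <- depth_slope_sandwich(rule, l1)
  list(table = tab, slope = slope, sandwich = sandwich,
       in_sandwich = slope >= sandwich["lower"] && slope <= sandwich["upper"])
}

#' Linear-in-m scaling over chains of valleys
#'
#' Computes the exact expected crossing time of a chain of `m` identical
#' valleys for each `m` in a grid, together with the peak drift, and checks
#' that `E(T_m)/m` stays within a bounded factor when the drift condition
#' `lambda*(d2 - d1) >= 1` holds (`lambda = 2*beta*(N-1)` or `alpha`).
#'
#' @param spec A [valley()] specification with `d1 < d2`.
#' @param rule An SSWM or Metropolis [acceptance_rule()].
#' @param m_grid Numbers of valleys to test.
#' @return A list with `table` (per-`m` `expected_steps`, `per_valley`),
#'   `drift` (from the first interior peak of the largest chain),
#'   `drift_condition` (value of `lambda*(d2-d1)`), and `ratio`
#'   (max/min of `per_valley` over the grid).
#' @export
valleypath_scaling <- function(spec, rule, m_grid = 1:8) {
  stopifnot(inherits(spec, "valley_spec"))
  lam <- rule_lambda(rule)
  tab <- do.call(rbind, lapply(m_grid, function(m) {
    et <- valleypath_expected_time(valleypath(m, spec), rule)
    data.frame(m = m, expected_steps = et, per_valley = et / m)
  }))
  drift <- if (max(m_grid) >= 2) {
    drift_report(valleypath(max(m_grid), spec), rule)$drift
  } else NA_real_
  list(table = tab,
       drift = drift,
       drift_condition = lam * (spec$d2 - spec$d1),
       ratio = max(tab$per_valley) / min(tab$per_valley))
}

#' Cross-mode consistency check
#'
#' Runs the full bit-string simulator and the reduced-chain simulator on
#' the same embedded valley and reports mean relevant steps (with standard
#' errors) from both, the exact linear-solve value, and the empirical
#' evaluations-per-relevant-step ratio, whose theoretical value is `n/2`.
#'
#' @param spec A [valley()] specification.
#' @param rule A non-elitist [acceptance_rule()].
#' @param path A [long_k_path()] whose leading `l1 + l2 + 1` points carry
#'   the valley.
#' @param config A [sim_config()].
#' @return A list with `bitstring`, `chain` (each `mean`, `se`), `exact`,
#'   and `evals_per_step` (empirical and theoretical).
#' @export
cross_mode_check <- function(spec, rule, path, config = sim_config(replicates = 500)) {
  stopifnot(inherits(spec, "valley_spec"), inherits(path, "long_k_path"))
  h <- valley_height(spec, 0:spec$l)
  bs <- run_bitstring(path, h, rule, mutation = "local", config = config)
  ch <- run_chain(h, rule, config = sim_config(seed = config$seed + 777L,
                                               replicates = config$replicates,
                                               budget = config$budget),
                  n = path$n)
  exact <- valley_crossing_time(spec, rule)
  list(bitstring = list(mean = mean(bs$relevant_steps),
                        se = stats::sd(bs$relevant_steps) / sqrt(nrow(bs))),
       chain = list(mean = mean(ch$relevant_steps),
                    se = stats::sd(ch$relevant_steps) / sqrt(nrow(ch))),
       exact = exact,
       evals_per_step = list(empirical = mean(bs$evaluations) / mean(bs$relevant_steps),
                             theoretical = path$n / 2))
}

#' Write small deterministic reference instances
#'
#' Emits plain-text fixtures for regression checks: the 22 points of the
#' long 3-path of dimension 9, height profiles of three canonical valleys
#' and one 3-valley chain, and exact crossing times for a pair of reference
#' rules.  Output is byte-identical across runs.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- file.path(dir, "long_path_n9_k3.tsv")
  utils::write.table(build_path(long_k_path(9, 3)), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  specs <- list(v_2_2_1_2 = valley(2, 2, 1, 2),
                v_3_4_1_2 = valley(3, 4, 1, 2),
                v_4_4_2_4 = valley(4, 4, 2, 4))
  hp <- do.call(rbind, lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    data.frame(spec = nm, position = 0:s$l,
               height = valley_height(s, 0:s$l))
  }))
  p <- file.path(dir, "valley_heights.tsv")
  utils::write.table(hp, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  vp <- valleypath(3, valley(2, 2, 2, 4))
  p <- file.path(dir, "valleypath_m3_heights.tsv")
  utils::write.table(data.frame(position = 0:(3 * 4),
                                height = global_heights(vp)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  rules <- list(sswm_b1_N2 = sswm_rule(1, 2), metropolis_a1 = metropolis_rule(1))
  et <- do.call(rbind, lapply(names(rules), function(nm) {
    data.frame(rule = nm, spec = names(specs),
               expected_steps = vapply(specs, valley_crossing_time,
                                       numeric(1), rule = rules[[nm]]))
  }))
  p <- file.path(dir, "exact_crossing_times.tsv")
  utils::write.table(format(et, digits = 15), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  invisible(files)
}
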