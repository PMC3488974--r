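#' Default iteration budget of the benchmarks
#'
#' For two drugs the search is allowed up to twice the total number of
#' possible combinations; for 3-6 drugs the budgets are 1,000, 2,000,
#' 3,000 and 4,000 steps; beyond 6 drugs the same linear rule
#' `1000 * (N - 2)` is extended.
#'
#' @param n_drugs Number of drugs, at least 2.
#' @param n_combinations Total grid size (required when `n_drugs == 2`).
#' @return Integer iteration budget.
#' @export
default_budget <- function(n_drugs, n_combinations = NULL) {
  if (!is.numeric(n_drugs) || length(n_drugs) != 1L || n_drugs < 2) {
    stop("`n_drugs` must be at least 2", call. = FALSE)
  }
  if (n_drugs == 2) {
    if (is.null(n_combinations)) {
      stop("`n_combinations` is required for 2 drugs", call. = FALSE)
    }
    return(as.integer(2 * n_combinations))
  }
  as.integer(1000 * (n_drugs - 2))
}

algorithm_codes <- c(gur_simultaneous = 1L, gur_sequential = 2L,
                     enhanced = 3L, aru = 4L)

#' Run one closed-loop search trial
#'
#' Draws a uniformly random initial combination, observes it (iteration 0),
#' and iterates the chosen algorithm until a visited combination has *true*
#' normalized response at or above `threshold` or the iteration budget is
#' exhausted. The algorithm only ever sees observed (possibly noisy)
#' responses; success is judged on the true response, since the benchmark
#' surfaces are known. Fully reproducible from `seed`.
#'
#' @param surface A [response_surface()].
#' @param algorithm One of `"aru"`, `"enhanced"`, `"gur_simultaneous"`,
#'   `"gur_sequential"`.
#' @param alpha Randomness control in \[0, 1\] (adaptive algorithms).
#' @param u Measurement-noise half-width (uniform on `(-u, u)`).
#' @param strategy Revisit strategy, `"A"` (cache) or `"B"` (re-measure).
#' @param budget Iteration budget; defaults to [default_budget()].
#' @param threshold Success threshold on the true normalized response
#'   (default 0.95, i.e. within 5% of the grid optimum).
#' @param seed Optional integer seed set before the trial.
#' @param edge Edge handling for the adaptive algorithms, `"reflect"` or
#'   `"clamp"` (the Gur Game automaton always clamps).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation built from the exported step functions). Both engines
#'   consume the RNG identically and return bit-identical results.
#' @return A list of class `trial_result`: `success`,
#'   `iterations_to_success` and `unique_combinations_to_success` (`NA` on
#'   failure; the initial observation counts, so a potent start gives 0
#'   iterations and 1 unique combination), `best_true` (largest true
#'   response visited before stopping), `total_evaluations` (fresh
#'   measurements), `total_unique` (distinct combinations over the whole
#'   trial), `initial_levels`, `final_levels`, and the trial settings.
#' @export
run_trial <- function(surface,
                      algorithm = c("aru", "enhanced",
                                    "gur_simultaneous", "gur_sequential"),
                      alpha = 1, u = 0, strategy = c("A", "B"),
                      budget = NULL, threshold = 0.95, seed = NULL,
                      edge = c("clamp", "reflect"),
                      engine = c("cpp", "r")) {
  algorithm <- match.arg(algorithm)
  strategy <- match.arg(strategy)
  edge <- match.arg(edge)
  engine <- match.arg(engine)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a scalar in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(budget)) {
    budget <- default_budget(surface$grid$n_drugs, surface$grid$n_combinations)
  }
  if (budget < 1) stop("`budget` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- if (engine == "cpp") {
    run_trial_engine(surface$table, surface$grid$n_levels,
                     algorithm_codes[[algorithm]], alpha, u,
                     strategy == "A", as.integer(budget), threshold,
                     edge == "reflect")
  } else {
    run_trial_r(surface, algorithm, alpha, u, strategy,
                as.integer(budget), threshold, edge)
  }
  res$algorithm <- algorithm
  res$alpha <- alpha
  res$u <- u
  res$strategy <- strategy
  res$budget <- as.integer(budget)
  res$threshold <- threshold
  res$seed <- seed
  class(res) <- "trial_result"
  res
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s: %s", x$algorithm,
              if (x$success) sprintf("success after %d iteration(s), %d unique combination(s)",
                                     x$iterations_to_success,
                                     x$unique_combinations_to_success)
              else sprintf("failure within budget %d", x$budget)))
  cat(sprintf("; best true response %.4f\n", x$best_true))
  invisible(x)
}

# reference implementation of the trial loop; mirrors the compiled engine's
# RNG draw order exactly (see tests for the bit-identity check)
run_trial_r <- function(surface, algorithm, alpha, u, strategy,
                        budget, threshold, edge) {
  grid <- surface$grid
  n <- grid$n_drugs
  oracle <- evaluation_oracle(surface, u = u, strategy = strategy)
  init <- integer(n)
  for (d in seq_len(n)) {
    init[d] <- as.integer(min(floor(stats::runif(1) * grid$n_levels[d]) + 1,
                              grid$n_levels[d]))
  }
  f0 <- observe(oracle, init)
  state <- new_search_state(grid, init, f0, algorithm)
  tf <- surface$table[combo_index(grid, init)]
  best <- tf
  success <- tf >= threshold
  it_succ <- if (success) 0L else NA_integer_
  uniq_succ <- if (success) 1L else NA_integer_
  t <- 0L
  while (!success && t < budget) {
    t <- t + 1L
    state <- switch(algorithm,
      gur_simultaneous = gur_step(state, oracle, "simultaneous"),
      gur_sequential = gur_step(state, oracle, "sequential"),
      enhanced = enhanced_step(state, oracle, alpha, edge),
      aru = aru_step(state, oracle, alpha, edge))
    tf <- surface$table[combo_index(grid, state$levels)]
    if (tf > best) best <- tf
    if (tf >= threshold) {
      success <- TRUE
      it_succ <- t
      uniq_succ <- oracle$unique_combinations
    }
  }
  list(success = success,
       iterations_to_success = it_succ,
       unique_combinations_to_success = uniq_succ,
       best_true = best,
       total_evaluations = oracle$total_evaluations,
       total_unique = oracle$unique_combinations,
       initial_levels = init,
       final_levels = state$levels)
}
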