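#' Run a Monte-Carlo benchmark of one algorithm on one surface
#'
#' Repeats [run_trial()] `n_trials` times with independent per-trial seeds
#' derived from `seed`, and aggregates the two benchmark metrics: the
#' success rate (fraction of trials that visit a combination with true
#' response at or above the threshold within the budget) and, conditional
#' on success, the mean number of unique combinations tested and the mean
#' number of iterations until the first potent combination. Identical
#' `(settings, seed)` give bit-identical summaries.
#'
#' @inheritParams run_trial
#' @param n_trials Number of independent trials (the reference setting of
#'   the benchmark tables is 5,000).
#' @param seed Master seed; per-trial seeds are drawn from it so that trial
#'   `k` is reproducible in isolation via `trial_seeds[k]`.
#' @param keep_distributions Keep the per-successful-trial vectors of
#'   unique-combination counts and iteration counts (default `TRUE`;
#'   needed for [write_benchmark_tsv()]).
#' @return An object of class `benchmark_summary`: `success_rate` (in
#'   \[0, 1\]), `success_se` (binomial standard error), `n_success`,
#'   `mean_unique_combinations`, `mean_iterations` (both over successful
#'   trials; `NaN` when no trial succeeds), `n_trials`, `trial_seeds`,
#'   distribution vectors, and the echoed configuration.
#' @export
run_benchmark <- function(surface,
                          algorithm = c("aru", "enhanced",
                                        "gur_simultaneous", "gur_sequential"),
                          alpha = 1, u = 0, strategy = c("A", "B"),
                          n_trials = 5000, budget = NULL, threshold = 0.95,
                          seed = 1, edge = c("clamp", "reflect"),
                          engine = c("cpp", "r"),
                          keep_distributions = TRUE) {
  algorithm <- match.arg(algorithm)
  strategy <- match.arg(strategy)
  edge <- match.arg(edge)
  engine <- match.arg(engine)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("`n_trials` must be at least 1", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (is.null(budget)) {
    budget <- default_budget(surface$grid$n_drugs, surface$grid$n_combinations)
  }
  set.seed(seed)
  trial_seeds <- sample.int(2147483646L, n_trials)
  succ <- logical(n_trials)
  uniq <- integer(n_trials)
  iters <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- run_trial(surface, algorithm, alpha = alpha, u = u,
                    strategy = strategy, budget = budget,
                    threshold = threshold, seed = trial_seeds[i],
                    edge = edge, engine = engine)
    succ[i] <- tr$success
    uniq[i] <- if (tr$success) tr$unique_combinations_to_success else NA_integer_
    iters[i] <- if (tr$success) tr$iterations_to_success else NA_integer_
  }
  p <- mean(succ)
  out <- list(
    success_rate = p,
    success_se = sqrt(p * (1 - p) / n_trials),
    n_success = sum(succ),
    mean_unique_combinations = mean(uniq[succ]),
    mean_iterations = mean(iters[succ]),
    n_trials = n_trials,
    trial_seeds = trial_seeds,
    unique_distribution = if (keep_distributions) uniq[succ] else NULL,
    iteration_distribution = if (keep_distributions) iters[succ] else NULL,
    config = list(surface = surface$name, algorithm = algorithm,
                  alpha = alpha, u = u, strategy = strategy,
                  budget = as.integer(budget), threshold = threshold,
                  seed = seed, edge = edge, n_trials = n_trials)
  )
  class(out) <- "benchmark_summary"
  out
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<benchmark_summary> %s on '%s' (alpha = %g, u = %g, type-%s, budget %d, %d trials)\n",
              cfg$algorithm, cfg$surface, cfg$alpha, cfg$u, cfg$strategy,
              cfg$budget, cfg$n_trials))
  cat(sprintf("  success rate: %.1f%% (SE %.2f points)\n",
              100 * x$success_rate, 100 * x$success_se))
  if (x$n_success > 0) {
    cat(sprintf("  over %d successful trials: mean unique combinations %.1f, mean iterations %.1f\n",
                x$n_success, x$mean_unique_combinations, x$mean_iterations))
  }
  invisible(x)
}

#' Export per-trial success distributions as TSV
#'
#' Writes one row per successful trial with the number of unique
#' combinations tested and the number of iterations until the first potent
#' combination.
#'
#' @param summary A [run_benchmark()] result with distributions kept.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(summary, path) {
  if (is.null(summary$unique_distribution)) {
    stop("summary was built with keep_distributions = FALSE", call. = FALSE)
  }
  df <- data.frame(unique_combinations = summary$unique_distribution,
                   iterations = summary$iteration_distribution)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate benchmark summaries side by side
#'
#' Arranges a list of [run_benchmark()] summaries into the layout of the
#' benchmark tables: one row per (surface, noise level, search type),
#' one pair of columns per algorithm, reporting the success rate in percent
#' and the efficiency metric - mean unique combinations tested for
#' noiseless or type-A runs, mean iterations for type-B runs.
#'
#' @param summaries List of `benchmark_summary` objects. Within one
#'   (surface, noise, type) row, each algorithm may appear once and all
#'   entries must share the same grid settings.
#' @return A data frame of class `benchmark_table` with attribute
#'   `"metric"` recording the efficiency metric used per row.
#' @export
compare_table <- function(summaries) {
  if (!is.list(summaries) || length(summaries) == 0L ||
      inherits(summaries, "benchmark_summary")) {
    if (inherits(summaries, "benchmark_summary")) summaries <- list(summaries)
    else stop("`summaries` must be a non-empty list of benchmark summaries",
              call. = FALSE)
  }
  ok <- vapply(summaries, inherits, logical(1), "benchmark_summary")
  if (!all(ok)) stop("`summaries` must contain benchmark_summary objects",
                     call. = FALSE)
  long <- do.call(rbind, lapply(summaries, function(s) {
    cfg <- s$config
    data.frame(surface = cfg$surface, u = cfg$u, strategy = cfg$strategy,
               budget = cfg$budget, algorithm = cfg$algorithm,
               success_pct = 100 * s$success_rate,
               effort = if (cfg$strategy == "B" && cfg$u > 0)
                 s$mean_iterations else s$mean_unique_combinations,
               stringsAsFactors = FALSE)
  }))
  groups <- split(long, interaction(long$surface, long$u, long$strategy,
                                    drop = TRUE))
  rows <- lapply(groups, function(g) {
    if (anyDuplicated(g$algorithm)) {
      stop("an algorithm appears twice in one table row", call. = FALSE)
    }
    if (length(unique(g$budget)) != 1L) {
      stop("mixed budgets (different grids?) in one table row", call. = FALSE)
    }
    row <- data.frame(surface = g$surface[1L], u = g$u[1L],
                      strategy = g$strategy[1L],
                      metric = if (g$strategy[1L] == "B" && g$u[1L] > 0)
                        "iterations" else "unique_combinations",
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(g))) {
      row[[paste0(g$algorithm[i], "_success_pct")]] <- g$success_pct[i]
      row[[paste0(g$algorithm[i], "_effort")]] <- g$effort[i]
    }
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$surface, out$u, out$strategy), , drop = FALSE]
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' @export
print.benchmark_table <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & names(y) != "u"
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark table as TSV
#'
#' @param table A [compare_table()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_benchmark_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
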