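#' Evaluation oracle: the measurement channel between algorithm and surface
#'
#' Wraps a [response_surface()] with additive uniform measurement noise and
#' a revisit strategy, and keeps the accounting the benchmarks need
#' (evaluation log, fresh-measurement count, number of distinct combinations
#' ever queried).
#'
#' Observed responses follow `f_obs(x) = f_true(x) + eta` with `eta`
#' i.i.d. uniform on `(-u, u)`; `u = 0` is noiseless. Observations are not
#' clipped to \[0, 1\]. Two revisit strategies are supported:
#'
#' * type `"A"`: a previously tested combination is never re-measured; the
#'   cached observation is returned and the fresh-measurement counter is not
#'   incremented.
#' * type `"B"`: every query draws fresh noise.
#'
#' The oracle is a mutable environment-backed object; [observe()] updates it
#' in place.
#'
#' @param surface A [response_surface()].
#' @param u Noise half-width, `u >= 0`.
#' @param strategy `"A"` (cache revisits) or `"B"` (re-measure revisits).
#' @return An object of class `evaluation_oracle`.
#' @export
evaluation_oracle <- function(surface, u = 0, strategy = c("A", "B")) {
  strategy <- match.arg(strategy)
  if (!inherits(surface, "response_surface")) {
    stop("`surface` must be a response_surface", call. = FALSE)
  }
  if (!is.numeric(u) || length(u) != 1L || u < 0) {
    stop("`u` must be a non-negative scalar", call. = FALSE)
  }
  o <- new.env(parent = emptyenv())
  o$surface <- surface
  o$u <- u
  o$strategy <- strategy
  o$cache <- new.env(hash = TRUE, parent = emptyenv())
  o$log_key <- integer(0)
  o$log_obs <- numeric(0)
  o$log_true <- numeric(0)
  o$log_levels <- list()
  o$total_evaluations <- 0L
  o$unique_combinations <- 0L
  class(o) <- "evaluation_oracle"
  o
}

#' @export
print.evaluation_oracle <- function(x, ...) {
  cat(sprintf("<evaluation_oracle> surface '%s', u = %g, type-%s; %d queries, %d fresh, %d unique\n",
              x$surface$name, x$u, x$strategy, length(x$log_obs),
              x$total_evaluations, x$unique_combinations))
  invisible(x)
}

#' Observe the (noisy) response of a combination
#'
#' Returns `f_true + eta` under the oracle's noise model and revisit
#' strategy, appends the query to the evaluation log, and updates the
#' fresh-measurement and unique-combination counters. With strategy A a
#' revisited combination returns its cached observation bit-identically and
#' draws no fresh noise.
#'
#' @param oracle An [evaluation_oracle()]; modified in place.
#' @param levels Integer vector of per-drug level indices (1-based).
#' @return The observed response (scalar).
#' @export
observe <- function(oracle, levels) {
  key <- combo_index(oracle$surface$grid, levels)
  true_f <- oracle$surface$table[key]
  kc <- as.character(key)
  obs <- if (oracle$strategy == "A") oracle$cache[[kc]] else NULL
  if (is.null(obs)) {
    obs <- true_f + if (oracle$u > 0) stats::runif(1, -oracle$u, oracle$u) else 0
    oracle$total_evaluations <- oracle$total_evaluations + 1L
    if (oracle$strategy == "A") oracle$cache[[kc]] <- obs
  }
  i <- length(oracle$log_obs) + 1L
  if (!any(oracle$log_key == key)) {
    oracle$unique_combinations <- oracle$unique_combinations + 1L
  }
  oracle$log_key[i] <- key
  oracle$log_obs[i] <- obs
  oracle$log_true[i] <- true_f
  oracle$log_levels[[i]] <- as.integer(levels)
  obs
}

#' Distinct combinations among the first queries
#'
#' Number of distinct combinations among evaluation-log entries
#' `1..stop_index` (inclusive); with `stop_index` pointing at the
#' success-triggering query this is the unique-combinations-tested metric.
#'
#' @param oracle An [evaluation_oracle()].
#' @param stop_index Log position, `0 <= stop_index <= number of queries`.
#' @return Integer count (0 for `stop_index = 0`).
#' @export
unique_count_until <- function(oracle, stop_index) {
  n <- length(oracle$log_key)
  if (!is.numeric(stop_index) || length(stop_index) != 1L ||
      stop_index < 0 || stop_index > n) {
    stop(sprintf("`stop_index` must be between 0 and %d", n), call. = FALSE)
  }
  length(unique(oracle$log_key[seq_len(stop_index)]))
}

#' Evaluation log as a data frame
#'
#' @param oracle An [evaluation_oracle()].
#' @return Data frame with one row per query: `iteration` (0 = the initial
#'   observation when the oracle is driven by [run_trial()]), `combination`
#'   (level indices as a dash-separated string), per-drug concentration
#'   columns, `observed` and `true`.
#' @export
oracle_log <- function(oracle) {
  grid <- oracle$surface$grid
  nq <- length(oracle$log_obs)
  lev <- do.call(rbind, oracle$log_levels)
  conc <- if (nq > 0) {
    vapply(seq_len(grid$n_drugs),
           function(n) grid$concentrations[[n]][lev[, n]], numeric(nq))
  } else {
    matrix(numeric(0), 0, grid$n_drugs)
  }
  if (nq == 1L) conc <- matrix(conc, nrow = 1L)
  out <- data.frame(
    iteration = seq_len(nq) - 1L,
    combination = if (nq > 0) apply(lev, 1, paste, collapse = "-") else character(0)
  )
  colnames(conc) <- names(grid$concentrations)
  out <- cbind(out, as.data.frame(conc))
  out$observed <- oracle$log_obs
  out$true <- oracle$log_true
  out
}

#' Write the evaluation log as TSV
#'
#' @param oracle An [evaluation_oracle()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oracle_log <- function(oracle, path) {
  utils::write.table(oracle_log(oracle), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
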