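#' Evenly divided concentration levels
#'
#' Divide a concentration range into `n_levels` evenly spaced values,
#' including both endpoints: level `k` (1-based) maps to
#' `low + (k - 1) * (high - low) / (n_levels - 1)`.
#'
#' @param low,high Range endpoints, `low < high`.
#' @param n_levels Number of levels, at least 2.
#' @return Numeric vector of length `n_levels`, strictly increasing.
#' @examples
#' even_levels(-2, 2, 21)
#' @export
even_levels <- function(low, high, n_levels) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high)) {
    stop("`low` and `high` must be finite numeric scalars", call. = FALSE)
  }
  if (!isTRUE(low < high)) stop("`low` must be smaller than `high`", call. = FALSE)
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2) {
    stop("`n_levels` must be at least 2", call. = FALSE)
  }
  seq(low, high, length.out = as.integer(n_levels))
}

#' Construct a discrete concentration grid
#'
#' A concentration grid defines the search space of the combinatorial drug
#' optimization problem: each drug takes one of a finite, strictly increasing
#' set of concentrations, and a drug combination is one point of the Cartesian
#' product of the per-drug sets.
#'
#' @param ... One strictly increasing numeric vector of concentrations per
#'   drug (at least 2 levels each). Use [even_levels()] for evenly divided
#'   ranges. Argument names become drug names.
#' @return An object of class `concentration_grid` with elements
#'   `concentrations` (named list of per-drug level vectors), `n_drugs`,
#'   `n_levels` (integer vector of per-drug level counts) and
#'   `n_combinations` (total grid size).
#' @examples
#' make_grid(x1 = even_levels(-2, 2, 21), x2 = even_levels(-2, 2, 21))
#' make_grid(maraviroc = c(0, 0.01, 0.03, 0.09, 0.27, 0.82, 2.47, 7.41, 22.22, 66.67),
#'           roab14 = c(0, 0.09, 0.27, 0.8, 2.41, 7.22, 21.67, 65))
#' @export
make_grid <- function(...) {
  conc <- list(...)
  if (length(conc) == 1L && is.list(conc[[1L]]) && !is.numeric(conc[[1L]])) {
    conc <- conc[[1L]]
  }
  if (length(conc) < 1L) stop("at least one drug is required", call. = FALSE)
  nm <- names(conc)
  if (is.null(nm)) nm <- rep("", length(conc))
  nm[nm == ""] <- paste0("drug", which(nm == ""))
  names(conc) <- nm
  for (n in seq_along(conc)) {
    v <- conc[[n]]
    if (!is.numeric(v) || length(v) < 2L || anyNA(v)) {
      stop(sprintf("drug %d ('%s'): need a numeric vector of at least 2 levels",
                   n, nm[n]), call. = FALSE)
    }
    if (any(diff(v) <= 0)) {
      stop(sprintf("drug %d ('%s'): concentrations must be strictly increasing",
                   n, nm[n]), call. = FALSE)
    }
    conc[[n]] <- as.numeric(v)
  }
  m <- vapply(conc, length, integer(1))
  structure(
    list(concentrations = conc,
         n_drugs = length(conc),
         n_levels = unname(m),
         n_combinations = prod(m)),
    class = "concentration_grid"
  )
}

#' @export
print.concentration_grid <- function(x, ...) {
  cat(sprintf("<concentration_grid> %d drug(s), %s combinations\n",
              x$n_drugs, format(x$n_combinations, big.mark = ",")))
  for (n in seq_len(x$n_drugs)) {
    v <- x$concentrations[[n]]
    cat(sprintf("  %s: %d levels in [%g, %g]\n",
                names(x$concentrations)[n], length(v), v[1L], v[length(v)]))
  }
  invisible(x)
}

check_levels <- function(grid, levels) {
  levels <- as.integer(levels)
  if (length(levels) != grid$n_drugs) {
    stop("`levels` must have one entry per drug", call. = FALSE)
  }
  if (any(levels < 1L) || any(levels > grid$n_levels)) {
    stop("level index out of range for grid", call. = FALSE)
  }
  levels
}

#' Linear index of a combination
#'
#' Maps per-drug level indices (1-based) to the position of the combination
#' in the mixed-radix enumeration of the grid, with drug 1 varying fastest.
#' This is the index into a surface's response table.
#'
#' @param grid A [make_grid()] object.
#' @param levels Integer vector of per-drug level indices, or a matrix with
#'   one row per combination.
#' @return Integer index (or vector of indices) in `1:grid$n_combinations`.
#' @export
combo_index <- function(grid, levels) {
  mult <- cumprod(c(1, grid$n_levels[-grid$n_drugs]))
  if (is.matrix(levels)) {
    if (ncol(levels) != grid$n_drugs) stop("`levels` must have one column per drug",
                                           call. = FALSE)
    if (any(levels < 1L) || any(levels > rep(grid$n_levels, each = nrow(levels)))) {
      stop("level index out of range for grid", call. = FALSE)
    }
    return(as.integer(1 + (levels - 1) %*% mult))
  }
  levels <- check_levels(grid, levels)
  as.integer(1 + sum((levels - 1) * mult))
}

#' Concentrations of a combination
#'
#' @param grid A [make_grid()] object.
#' @param levels Integer vector of per-drug level indices (1-based).
#' @return Numeric vector of real concentrations, one per drug.
#' @export
combo_concentrations <- function(grid, levels) {
  levels <- check_levels(grid, levels)
  vapply(seq_len(grid$n_drugs),
         function(n) grid$concentrations[[n]][levels[n]],
         numeric(1))
}

#' Nearest grid levels for a concentration vector
#'
#' Inverse of [combo_concentrations()] up to rounding: for each drug, the
#' level whose concentration is closest to the requested value.
#'
#' @param grid A [make_grid()] object.
#' @param x Numeric vector of concentrations, one per drug.
#' @return Integer vector of level indices.
#' @export
nearest_levels <- function(grid, x) {
  if (length(x) != grid$n_drugs) stop("`x` must have one entry per drug", call. = FALSE)
  vapply(seq_len(grid$n_drugs),
         function(n) which.min(abs(grid$concentrations[[n]] - x[n])),
         integer(1))
}

#' All combinations of a grid
#'
#' Enumerates the full Cartesian product as a numeric matrix of
#' concentrations, one row per combination, in [combo_index()] order
#' (drug 1 fastest). Used to tabulate response surfaces.
#'
#' @param grid A [make_grid()] object.
#' @return Numeric matrix with `n_combinations` rows and `n_drugs` columns.
#' @export
grid_combinations <- function(grid) {
  as.matrix(expand.grid(grid$concentrations, KEEP.OUT.ATTRS = FALSE))
}
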