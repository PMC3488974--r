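#' Min-max normalization of raw responses
#'
#' Rescales raw responses over the full grid so that the minimum maps to 0
#' and the maximum to 1. Order-preserving and idempotent.
#'
#' @param x Numeric vector of raw responses (the full grid's values).
#' @return Numeric vector of the same length in \[0, 1\].
#' @export
normalize_minmax <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("need at least two raw values to normalize", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("raw responses must be finite", call. = FALSE)
  }
  r <- range(x)
  if (r[1] == r[2]) {
    stop("degenerate surface: raw response is constant over the grid; min-max normalization undefined",
         call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

#' MATLAB-style peaks function
#'
#' The classic two-variable test function of three Gaussian bumps, used by
#' several builtin benchmark surfaces.
#'
#' @param x1,x2 Numeric vectors.
#' @return Numeric vector.
#' @export
peaks <- function(x1, x2) {
  3 * (1 - x1)^2 * exp(-x1^2 - (x2 + 1)^2) -
    10 * (x1 / 5 - x1^3 - x2^5) * exp(-x1^2 - x2^2) -
    (1 / 3) * exp(-(x1 + 1)^2 - x2^2)
}

#' Construct a response surface on a concentration grid
#'
#' A response surface is a deterministic map from drug combinations to the
#' normalized drug response f in \[0, 1\] (0 = completely ineffective, 1 =
#' grid optimum). The raw response is tabulated over the whole grid and,
#' by default, min-max normalized over the grid so that f spans \[0, 1\]
#' exactly.
#'
#' @param grid A [make_grid()] object.
#' @param raw Either a function taking a numeric matrix of concentrations
#'   (one row per combination, one column per drug) and returning a numeric
#'   vector, or a numeric vector of raw responses in [combo_index()] order.
#' @param name Identifier for the surface.
#' @param normalize If `TRUE` (default), min-max normalize the raw values
#'   over the grid. If `FALSE`, the raw values must already lie in \[0, 1\].
#' @return An object of class `response_surface` with elements `grid`,
#'   `name`, `table` (normalized response per combination, in
#'   [combo_index()] order), `raw_range` and `optimum_response`.
#' @export
response_surface <- function(grid, raw, name = "surface", normalize = TRUE) {
  if (!inherits(grid, "concentration_grid")) {
    stop("`grid` must be a concentration_grid", call. = FALSE)
  }
  vals <- if (is.function(raw)) raw(grid_combinations(grid)) else as.numeric(raw)
  if (length(vals) != grid$n_combinations) {
    stop("raw responses must cover the full grid exactly once", call. = FALSE)
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("raw responses must be finite", call. = FALSE)
  }
  raw_range <- range(vals)
  if (normalize) {
    vals <- normalize_minmax(vals)
  } else if (any(vals < 0) || any(vals > 1)) {
    stop("with normalize = FALSE, responses must already lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(grid = grid, name = name, table = vals,
         raw_range = raw_range, optimum_response = max(vals)),
    class = "response_surface"
  )
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> '%s': %d drug(s), %s combinations, response in [%g, %g]\n",
              x$name, x$grid$n_drugs,
              format(x$grid$n_combinations, big.mark = ","),
              min(x$table), max(x$table)))
  invisible(x)
}

#' True normalized response of combinations
#'
#' @param surface A [response_surface()].
#' @param levels Integer vector of per-drug level indices (1-based), or a
#'   matrix with one row per combination.
#' @return Numeric response value(s) in \[0, 1\].
#' @export
response <- function(surface, levels) {
  surface$table[combo_index(surface$grid, levels)]
}

# registry of builtin benchmark surfaces: grid constructor + raw function
builtin_registry <- list(
  dejong2 = list(
    grid = function() make_grid(x1 = even_levels(-2, 2, 21),
                                x2 = even_levels(-2, 2, 21)),
    raw = function(X) 100 * (X[, 1]^2 - X[, 2])^2 + (1 - X[, 1])^2
  ),
  f3a = list(
    grid = function() {
      v <- even_levels(-2.5, 2.5, 11)
      make_grid(x1 = v, x2 = v, x3 = v)
    },
    raw = function(X) X[, 1]^2 * sin(X[, 2])^2 * cos(X[, 3])^2
  ),
  f3b = list(
    grid = function() {
      v <- even_levels(-3, 3, 11)
      make_grid(x1 = v, x2 = v, x3 = v)
    },
    raw = function(X) peaks(X[, 1], X[, 2]) * X[, 3]
  ),
  f4a = list(
    grid = function() {
      a <- even_levels(-2, 2, 11); b <- even_levels(-3, 3, 11)
      make_grid(x1 = a, x2 = a, x3 = b, x4 = b)
    },
    raw = function(X) X[, 1] * exp(-(X[, 1]^2 + X[, 2]^2 + X[, 3]^2 + X[, 4]^2))
  ),
  f4b = list(
    grid = function() {
      v <- even_levels(-3, 3, 11)
      make_grid(x1 = v, x2 = v, x3 = v, x4 = v)
    },
    raw = function(X) cos(0.3 * X[, 1])^2 * sin(0.3 * X[, 2]) *
      tan(0.1 * X[, 3]) * X[, 4]
  ),
  f5a = list(
    grid = function() {
      a <- even_levels(-2, 2, 11); b <- even_levels(-4.5, 4.5, 11)
      make_grid(x1 = a, x2 = a, x3 = b, x4 = b, x5 = b)
    },
    raw = function(X) exp(-X[, 1]) * cos(X[, 2])^2 * X[, 3]^2 *
      (exp(-(X[, 4] + 2)^2 - (X[, 5] + 3)^2) +
         exp(-(X[, 4] - 2)^2 - (X[, 5] - 3)^2))
  ),
  f5b = list(
    grid = function() {
      v <- even_levels(-3, 3, 11)
      make_grid(x1 = v, x2 = v, x3 = v, x4 = v, x5 = v)
    },
    raw = function(X) 0.5 * peaks(X[, 1], X[, 2]) * cos(0.5 * X[, 3]) *
      sin(0.5 * X[, 4]) * X[, 5]^2
  ),
  f6a = list(
    grid = function() {
      v <- even_levels(-2.5, 2.5, 11)
      make_grid(x1 = v, x2 = v, x3 = v, x4 = v, x5 = v, x6 = v)
    },
    raw = function(X) exp(-0.75 * X[, 1]) * sin(X[, 2])^2 +
      cos(X[, 3]) * exp(-0.75 * (X[, 4]^2 + X[, 5]^2)) * X[, 6]
  ),
  f6b = list(
    grid = function() {
      v <- even_levels(-2.5, 2.5, 11)
      make_grid(x1 = v, x2 = v, x3 = v, x4 = v, x5 = v, x6 = v)
    },
    raw = function(X) exp(-0.1 * (X[, 1]^2 - X[, 2]^2) -
                            0.1 * (X[, 3]^2 + X[, 4]^2)) *
      cos(0.2 * X[, 5]^3)^2 * sin(0.2 * X[, 6]^3)
  )
)

surface_cache <- new.env(parent = emptyenv())

#' Names of the builtin benchmark surfaces
#'
#' @return Character vector of surface names accepted by [builtin_surface()].
#' @export
builtin_surface_names <- function() names(builtin_registry)

#' Builtin benchmark response surfaces
#'
#' Analytic multi-drug response functions on fixed discrete concentration
#' grids, min-max normalized over the grid:
#'
#' * `dejong2`: second De Jong function (Rosenbrock's saddle),
#'   `100 * (x1^2 - x2)^2 + (1 - x1)^2`, 21 levels per drug on \[-2, 2\].
#'   By default the min-max normalized saddle is maximized as-is, so the
#'   response optimum sits at the corner (-2, -2); this orientation
#'   reproduces the published benchmark behavior of all four algorithms.
#'   With `invert = TRUE` the surface is flipped so the Rosenbrock minimum
#'   at (1, 1) becomes the response optimum instead (the saddle's own
#'   minimization convention).
#' * `f3a`: `x1^2 sin^2(x2) cos^2(x3)`, 11 levels on \[-2.5, 2.5\]^3.
#' * `f3b`: `peaks(x1, x2) * x3`, 11 levels on \[-3, 3\]^3.
#' * `f4a`: `x1 exp(-(x1^2+x2^2+x3^2+x4^2))`, 11 levels on \[-2, 2\] for
#'   x1, x2 and \[-3, 3\] for x3, x4.
#' * `f4b`: `cos^2(0.3 x1) sin(0.3 x2) tan(0.1 x3) x4`, 11 levels on
#'   \[-3, 3\]^4.
#' * `f5a`: `exp(-x1) cos^2(x2) x3^2 (exp(-(x4+2)^2-(x5+3)^2) +
#'   exp(-(x4-2)^2-(x5-3)^2))`, 11 levels on \[-2, 2\] for x1, x2 and
#'   \[-4.5, 4.5\] for x3, x4, x5.
#' * `f5b`: `0.5 peaks(x1, x2) cos(0.5 x3) sin(0.5 x4) x5^2`, 11 levels on
#'   \[-3, 3\]^5.
#' * `f6a`: `exp(-0.75 x1) sin^2(x2) + cos(x3) exp(-0.75 (x4^2+x5^2)) x6`,
#'   11 levels on \[-2.5, 2.5\]^6.
#' * `f6b`: `exp(-0.1 (x1^2 - x2^2) - 0.1 (x3^2 + x4^2)) cos^2(0.2 x5^3)
#'   sin(0.2 x6^3)`, 11 levels on \[-2.5, 2.5\]^6.
#'
#' Surfaces are tabulated once per session and cached.
#'
#' @param name One of [builtin_surface_names()].
#' @param invert For `dejong2` only: invert the normalized saddle so its
#'   global minimum becomes the response optimum (default `FALSE`).
#' @return A [response_surface()].
#' @export
builtin_surface <- function(name, invert = FALSE) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(builtin_registry)) {
    stop(sprintf("unknown builtin surface; expected one of: %s",
                 paste(names(builtin_registry), collapse = ", ")), call. = FALSE)
  }
  key <- if (name == "dejong2") paste0(name, if (invert) "_inv" else "_raw") else name
  if (!is.null(surface_cache[[key]])) return(surface_cache[[key]])
  entry <- builtin_registry[[name]]
  s <- response_surface(entry$grid(), entry$raw, name = name)
  if (name == "dejong2" && invert) {
    s$table <- 1 - s$table
    s$optimum_response <- max(s$table)
  }
  surface_cache[[key]] <- s
  s
}

#' Load a tabulated response surface from CSV
#'
#' Reads a surface measured on a complete Cartesian concentration grid,
#' e.g. experimental inhibition data. The file must have a header row with
#' one column per drug followed by a `response` column (if no column is
#' named `response`, the last column is taken), and exactly one data row
#' per combination. The grid is inferred from the distinct sorted values of
#' each concentration column; row order is irrelevant.
#'
#' @param path Path to a CSV file (UTF-8, decimal point).
#' @param normalize Min-max normalize the responses over the grid
#'   (default `TRUE`). With `FALSE` the stored responses must already lie
#'   in \[0, 1\].
#' @param name Surface identifier; defaults to the file name.
#' @return A [response_surface()].
#' @export
load_tabular_surface <- function(path, normalize = TRUE, name = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) {
    stop("surface CSV needs at least one concentration column and a response column",
         call. = FALSE)
  }
  resp_col <- if ("response" %in% names(df)) "response" else names(df)[ncol(df)]
  conc_cols <- setdiff(names(df), resp_col)
  for (cn in c(conc_cols, resp_col)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1L]
      stop(sprintf("non-numeric value in column '%s' (data row %d)", cn,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    if (anyNA(df[[cn]])) {
      stop(sprintf("missing value in column '%s' (data row %d)", cn,
                   which(is.na(df[[cn]]))[1L]), call. = FALSE)
    }
  }
  levels <- lapply(df[conc_cols], function(v) sort(unique(v)))
  grid <- make_grid(levels)
  m <- grid$n_combinations
  lev_mat <- vapply(seq_along(conc_cols),
                    function(n) match(df[[conc_cols[n]]], levels[[n]]),
                    integer(nrow(df)))
  if (nrow(df) == 1L) lev_mat <- matrix(lev_mat, nrow = 1L)
  keys <- combo_index(grid, lev_mat)
  dup <- which(duplicated(keys))
  if (length(dup) > 0L) {
    stop(sprintf("duplicate combination at data row %d", dup[1L]), call. = FALSE)
  }
  if (nrow(df) != m) {
    stop(sprintf("incomplete grid: file has %d rows but the inferred grid has %d combinations",
                 nrow(df), m), call. = FALSE)
  }
  vals <- numeric(m)
  vals[keys] <- df[[resp_col]]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  response_surface(grid, vals, name = name, normalize = normalize)
}
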