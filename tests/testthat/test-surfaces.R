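test_that("min-max normalization rescales, preserves order and is idempotent", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(normalize_minmax(c(3, 3, 3)), "degenerate")
  expect_error(normalize_minmax(3), "at least two")
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(50, sd = 10)
    y <- normalize_minmax(x)
    expect_true(all(y >= 0 & y <= 1))
    expect_equal(min(y), 0)
    expect_equal(max(y), 1)
    expect_identical(order(x), order(y))
    expect_equal(normalize_minmax(y), y)
  }
})

test_that("every builtin surface spans exactly [0, 1] over its grid", {
  for (nm in builtin_surface_names()) {
    s <- builtin_surface(nm)
    expect_equal(min(s$table), 0, info = nm)
    expect_equal(max(s$table), 1, info = nm)
    expect_equal(s$optimum_response, 1, info = nm)
  }
  expect_error(builtin_surface("nope"), "unknown builtin")
})

test_that("builtin grids match their stated ranges and level counts", {
  expect_identical(builtin_surface("dejong2")$grid$n_levels, c(21L, 21L))
  expect_equal(range(builtin_surface("dejong2")$grid$concentrations[[1]]), c(-2, 2))
  expect_identical(builtin_surface("f3a")$grid$n_levels, rep(11L, 3))
  expect_equal(range(builtin_surface("f3a")$grid$concentrations[[2]]), c(-2.5, 2.5))
  g4a <- builtin_surface("f4a")$grid
  expect_equal(range(g4a$concentrations[[1]]), c(-2, 2))
  expect_equal(range(g4a$concentrations[[3]]), c(-3, 3))
  g5a <- builtin_surface("f5a")$grid
  expect_equal(range(g5a$concentrations[[5]]), c(-4.5, 4.5))
  expect_identical(builtin_surface("f6b")$grid$n_combinations, 11^6)
})

test_that("multiplicative zero factors produce zero raw response", {
  # x1 = 0 kills f3a and f4a regardless of the remaining drugs
  f3a <- builtin_surface("f3a")
  mid <- 6L  # level of concentration 0 on the 11-level symmetric grids
  lev <- rbind(c(mid, 2L, 9L), c(mid, 11L, 1L), c(mid, 5L, 5L))
  r <- response(f3a, lev)
  expect_equal(r, rep(min(f3a$table), 3))  # raw 0 is also the grid minimum
  f4a <- builtin_surface("f4a")
  r4 <- response(f4a, rbind(c(mid, 1L, 4L, 9L), c(mid, 7L, 2L, 2L)))
  expect_equal(diff(r4), 0)  # raw 0 everywhere on the x1 = 0 plane
})

test_that("the Rosenbrock saddle is oriented as published", {
  s <- builtin_surface("dejong2")
  # raw minimum at (1, 1); with the default orientation the normalized
  # optimum is the high-raw corner (-2, -2)
  lev_min <- nearest_levels(s$grid, c(1, 1))
  expect_equal(combo_concentrations(s$grid, lev_min), c(1, 1))
  expect_equal(response(s, lev_min), 0)
  expect_equal(response(s, c(1L, 1L)), 1)  # level (1,1) = concentrations (-2,-2)
  # inverted orientation puts the optimum on the Rosenbrock minimum
  si <- builtin_surface("dejong2", invert = TRUE)
  expect_equal(response(si, lev_min), 1)
  expect_equal(sum(si$table == 1), 1L)
})

test_that("peaks matches its closed form at a hand-computed point", {
  expect_equal(peaks(0, 0), (3 - 1 / 3) * exp(-1))
  expect_equal(peaks(c(0, 0), c(0, 0)), rep((8 / 3) * exp(-1), 2))
})

test_that("tabulated surfaces load from complete-grid CSV", {
  df <- expand.grid(drugA = c(0, 1), drugB = c(0, 1))
  df$response <- c(0, 0.2, 0.4, 1.0)
  s <- load_tabular_surface(write_surface_csv(df))
  expect_identical(s$grid$n_combinations, 4)
  expect_equal(response(s, c(2L, 2L)), 1.0)
  expect_equal(response(s, c(1L, 1L)), 0)
  # row order must not matter
  s2 <- load_tabular_surface(write_surface_csv(df[c(3, 1, 4, 2), ]))
  expect_identical(s2$table, s$table)
})

test_that("tabulated surfaces reject malformed grids", {
  df <- expand.grid(drugA = c(0, 1), drugB = c(0, 1))
  df$response <- c(0, 0.2, 0.4, 1.0)
  expect_error(load_tabular_surface(write_surface_csv(df[1:3, ])), "incomplete grid")
  expect_error(load_tabular_surface(write_surface_csv(df[c(1:4, 2), ])),
               "duplicate combination at data row 5")
  bad <- df
  bad$response <- as.character(bad$response)
  bad$response[2] <- "high"
  expect_error(load_tabular_surface(write_surface_csv(bad)), "non-numeric")
})

test_that("the published HIV-inhibition concentration grid loads as 80 combinations", {
  maraviroc <- c(0, 0.01, 0.03, 0.09, 0.27, 0.82, 2.47, 7.41, 22.22, 66.67)
  roab14 <- c(0, 0.09, 0.27, 0.8, 2.41, 7.22, 21.67, 65)
  df <- expand.grid(maraviroc = maraviroc, roab14 = roab14)
  set.seed(1)
  df$response <- runif(nrow(df))  # synthetic responses; only the grid is published
  s <- load_tabular_surface(write_surface_csv(df))
  expect_identical(s$grid$n_combinations, 80)
  expect_identical(s$grid$n_levels, c(10L, 8L))
  expect_equal(range(s$table), c(0, 1))
})
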