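# small fixtures built in code

# 1-D surface from explicit response values (already in [0, 1])
surface_1d <- function(values, name = "toy1d") {
  g <- make_grid(drug = seq_len(length(values)) - 1)
  response_surface(g, values, name = name, normalize = FALSE)
}

# 2-D surface from a matrix of responses (rows = drug 1 levels)
surface_2d <- function(mat, name = "toy2d") {
  g <- make_grid(a = seq_len(nrow(mat)) - 1, b = seq_len(ncol(mat)) - 1)
  response_surface(g, as.vector(mat), name = name, normalize = FALSE)
}

# write a complete-grid surface CSV and return its path
write_surface_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "surface.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# empirical one-step transition frequencies of a step function from a fixed
# state; step_fn(state, oracle) must return the updated state
transition_freq <- function(surface, state, step_fn, n_reps, seed = 1) {
  set.seed(seed)
  out <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    oracle <- evaluation_oracle(surface)
    out[i] <- step_fn(state, oracle)$levels[1L]
  }
  table(out) / n_reps
}
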