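test_that("reward probability follows (1 + alpha * max(f1, f2)) / 2 with a cap", {
  expect_equal(reward_probability(0.5, 0.3, 1), 0.75)
  expect_equal(reward_probability(0.2, 0.9, 0), 0.5)
  expect_equal(reward_probability(1, 1, 1), 1)
  expect_equal(reward_probability(1.04, 0.9, 1), 1)  # noisy obs above 1: capped
  set.seed(5)
  f1 <- runif(200); f2 <- runif(200); a <- runif(200)
  for (i in 1:200) {
    g <- reward_probability(f1[i], f2[i], a[i])
    expect_gte(g, 0.5)
    expect_lte(g, 1)
  }
  expect_error(reward_probability(0.5, 0.5, 1.2), "\\[0, 1\\]")
  expect_error(reward_probability(0.5, 0.5, -0.1), "\\[0, 1\\]")
})

test_that("Gur reward/penalty moves match the automaton on every small grid", {
  # independent enumeration of the published update rules: reward moves away
  # from the reference (clamped at the grid edge), penalty moves towards it
  for (m in 2:5) {
    for (k in seq_len(m)) {
      for (ref in seq_len(m)) {
        if (k == ref) next
        exp_reward <- if (k > ref) {
          if (k == m) k else k + 1L
        } else {
          if (k == 1L) k else k - 1L
        }
        exp_penalty <- if (k > ref) k - 1L else k + 1L
        expect_identical(gur_reward(k, ref, m), exp_reward)
        expect_identical(gur_penalize(k, ref, m), exp_penalty)
      }
    }
  }
  expect_error(gur_reward(0L, 1L, 3L), "1..m")
  expect_error(gur_penalize(2L, 4L, 3L), "1..m")
})

test_that("at the reference level both moves pick a feasible neighbor uniformly", {
  set.seed(11)
  n <- 4000
  up <- sum(replicate(n, gur_reward(3L, 3L, 5L)) == 4L)
  expect_lt(abs(up / n - 0.5), 3 * sqrt(0.25 / n))
  # at an edge the only feasible neighbor is taken deterministically
  expect_identical(gur_reward(1L, 1L, 5L), 2L)
  expect_identical(gur_penalize(5L, 5L, 5L), 4L)
})

test_that("the Gur reference level is the (lower) median of the concentration set", {
  expect_identical(gur_reference_levels(make_grid(a = even_levels(-2, 2, 21))), 11L)
  expect_identical(gur_reference_levels(make_grid(a = 1:10)), 5L)
  expect_identical(gur_reference_levels(make_grid(a = 0:2, b = 0:3)), c(2L, 2L))
})

test_that("the virtual slope predicts the beneficial direction for all sign patterns", {
  expect_identical(informed_direction(2L, 5L, 0.2, 0.7), 1L)   # below, worse: go up
  expect_identical(informed_direction(7L, 5L, 0.7, 0.2), 1L)   # above, better: go up
  expect_identical(informed_direction(2L, 5L, 0.9, 0.2), -1L)  # below, better: go down
  expect_identical(informed_direction(7L, 5L, 0.2, 0.9), -1L)  # above, worse: go down
  expect_identical(informed_direction(2L, 5L, 0.4, 0.4), 0L)   # response tie
  expect_identical(informed_direction(5L, 5L, 0.2, 0.7), 0L)   # level tie
})

test_that("the reference updates only when a strict trajectory-local maximum is passed", {
  g <- make_grid(a = 0:4)
  st <- new_search_state(g, 1L, 0.2, "aru")
  st <- update_reference(st, 2L, 0.5)       # trajectory so far: 0.2, 0.5
  expect_identical(st$ref_levels, 1L)
  st2 <- update_reference(st, 3L, 0.4)      # 0.2, 0.5, 0.4: peak at the middle
  expect_identical(st2$ref_levels, 2L)
  expect_identical(st2$ref_f, 0.5)
  st3 <- update_reference(st, 3L, 0.7)      # 0.2, 0.5, 0.7: monotone, no peak
  expect_identical(st3$ref_levels, 1L)
  # plateau: strict inequality required on both sides
  stp <- new_search_state(g, 1L, 0.5, "aru")
  stp <- update_reference(stp, 2L, 0.5)
  stp <- update_reference(stp, 3L, 0.4)     # 0.5, 0.5, 0.4
  expect_identical(stp$ref_levels, 1L)
})

test_that("a fully random search (alpha = 0) moves each drug symmetrically", {
  g <- make_grid(drug = 0:10)
  s <- response_surface(g, seq(0, 1, length.out = 11), normalize = FALSE)
  set.seed(1)
  for (step_fn in list(
    function(st, o) aru_step(st, o, alpha = 0),
    function(st, o) enhanced_step(st, o, alpha = 0)
  )) {
    n <- 6000
    ups <- 0L
    for (i in seq_len(n)) {
      o <- evaluation_oracle(s)
      st <- new_search_state(g, 6L, observe(o, 6L), "aru")
      st$ref_levels <- 3L
      st$ref_f <- 0.2
      st$mem_exists <- TRUE
      st$mem_f_low <- 0.1
      st$mem_f_high <- 0.9
      ups <- ups + (step_fn(st, o)$levels > 6L)
    }
    expect_lt(abs(ups / n - 0.5), 3 * sqrt(0.25 / n))
  }
})

test_that("extreme responses make the Gur step deterministic", {
  g <- make_grid(a = 0:4, b = 0:4)
  s <- surface_2d(matrix(0.5, 5, 5))
  # f = 1: every drug rewarded (moves away from the reference level 3)
  o <- evaluation_oracle(s)
  st <- new_search_state(g, c(2L, 4L), 1.0, "gur_simultaneous")
  st$cur_f <- 1.0
  set.seed(2)
  for (i in 1:20) {
    out <- gur_step(st, evaluation_oracle(s), "simultaneous")
    expect_identical(out$levels, c(1L, 5L))
  }
  # f = 0: every drug penalized (moves towards the reference)
  st$cur_f <- 0.0
  for (i in 1:20) {
    out <- gur_step(st, evaluation_oracle(s), "simultaneous")
    expect_identical(out$levels, c(3L, 3L))
  }
})

test_that("sequential updates touch one drug at a time in round-robin order", {
  g <- make_grid(a = 0:4, b = 0:4, c = 0:4)
  s <- response_surface(g, function(X) rowSums(X), name = "plane")
  set.seed(9)
  o <- evaluation_oracle(s)
  init <- c(2L, 2L, 2L)
  st <- new_search_state(g, init, observe(o, init), "gur_sequential")
  for (expected_drug in c(1L, 2L, 3L, 1L)) {
    old <- st$levels
    expect_identical(st$next_drug, expected_drug)
    st <- gur_step(st, o, "sequential")
    changed <- which(st$levels != old)
    expect_true(all(changed %in% expected_drug))
  }
})

test_that("Gur dynamics reproduce both over-normalization failure modes", {
  # response everywhere below 0.5: occupancy piles up at the reference level
  g <- make_grid(drug = 0:10)
  low <- response_surface(g, rep(c(0.2, 0.3), c(6, 5)), normalize = FALSE)
  set.seed(4)
  o <- evaluation_oracle(low)
  st <- new_search_state(g, 2L, observe(o, 2L), "gur_sequential")
  occ <- integer(2000)
  for (i in seq_along(occ)) {
    st <- gur_step(st, o, "sequential")
    occ[i] <- st$levels
  }
  ref <- gur_reference_levels(g)
  occ_tail <- occ[-(1:200)]
  expect_gt(mean(abs(occ_tail - ref) <= 1), 0.6)
  expect_lt(mean(abs(occ_tail - ref)), 2)  # uniform occupancy would give 2.73
  # response everywhere above 0.5: occupancy is pushed to the grid edges
  high <- response_surface(g, rep(c(0.8, 0.9), c(6, 5)), normalize = FALSE)
  o2 <- evaluation_oracle(high)
  st2 <- new_search_state(g, 6L, observe(o2, 6L), "gur_sequential")
  occ2 <- integer(2000)
  for (i in seq_along(occ2)) {
    st2 <- gur_step(st2, o2, "sequential")
    occ2[i] <- st2$levels
  }
  expect_gt(mean(occ2[-(1:200)] %in% c(1L, 2L, 10L, 11L)), 0.9)
})

test_that("ARU converges near-certainly on a unimodal 1-D response", {
  g <- make_grid(drug = seq(0, 10, length.out = 11))
  vals <- c(0, 0.1, 0.25, 0.45, 0.65, 0.8, 0.9, 1, 0.85, 0.6, 0.3)
  s <- response_surface(g, vals, "unimodal", normalize = FALSE)
  n_ok <- 0L
  for (seed in 1:500) {
    tr <- run_trial(s, "aru", budget = 2L * 11L, threshold = 0.95, seed = seed)
    n_ok <- n_ok + tr$success
  }
  expect_gte(n_ok / 500, 0.95)
})
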