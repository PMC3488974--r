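#' Reward probability of the adaptive algorithms
#'
#' The probability `g = min(1, (1 + alpha * max(f1, f2)) / 2)` of moving a
#' drug in the direction predicted to be beneficial. `alpha` in \[0, 1\]
#' controls the randomness of the search: `alpha = 0` gives `g = 0.5`
#' (a fully random walk), `alpha = 1` fully exploits past observations.
#' `g` always lies in \[0.5, 1\] for responses in \[0, 1\]; observed
#' responses pushed slightly above 1 by measurement noise are capped at
#' `g = 1`.
#'
#' @param f1,f2 Observed responses of the two compared combinations
#'   (vectorized).
#' @param alpha Randomness control in \[0, 1\].
#' @return Reward probability (vectorized).
#' @export
reward_probability <- function(f1, f2, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a scalar in [0, 1]", call. = FALSE)
  }
  pmin(1, 0.5 * (1 + alpha * pmax(f1, f2)))
}

# uniformly random feasible one-level move; draws only when both directions
# are feasible
random_feasible_neighbor <- function(k, m) {
  if (k == 1L) return(2L)
  if (k == m) return(m - 1L)
  if (stats::runif(1) < 0.5) k - 1L else k + 1L
}

check_gur_args <- function(k, ref_k, m) {
  if (k < 1L || k > m || ref_k < 1L || ref_k > m) {
    stop("level indices must lie in 1..m", call. = FALSE)
  }
}

#' Gur Game reward and penalty moves
#'
#' The finite-state-automaton update of the Gur Game: a rewarded drug moves
#' one level *away* from its fixed reference level (clamped at the grid
#' edges), a penalized drug moves one level *towards* it. The automaton does
#' not define the case `k == ref_k`; it is resolved as a uniformly random
#' feasible one-level move (a single uniform draw when both neighbors are
#' feasible).
#'
#' @param k Current level index (1-based).
#' @param ref_k Reference level index (1-based); see [gur_reference_levels()].
#' @param m Number of levels for this drug.
#' @return The new level index.
#' @export
gur_reward <- function(k, ref_k, m) {
  check_gur_args(k, ref_k, m)
  if (k > ref_k) {
    if (k < m) k + 1L else k
  } else if (k < ref_k) {
    if (k > 1L) k - 1L else k
  } else {
    random_feasible_neighbor(k, m)
  }
}

#' @rdname gur_reward
#' @export
gur_penalize <- function(k, ref_k, m) {
  check_gur_args(k, ref_k, m)
  if (k > ref_k) k - 1L
  else if (k < ref_k) k + 1L
  else random_feasible_neighbor(k, m)
}

#' Gur Game reference levels of a grid
#'
#' The per-drug reference concentration is the median of the concentration
#' set; for an even number of levels the lower middle is taken.
#'
#' @param grid A [make_grid()] object.
#' @return Integer vector of per-drug reference level indices (1-based).
#' @export
gur_reference_levels <- function(grid) {
  (grid$n_levels - 1L) %/% 2L + 1L
}

#' Beneficial update direction from two observations
#'
#' The direction predicted to increase the response, obtained from the sign
#' of the virtual slope between two points `(k1, f1)` and `(k2, f2)` on one
#' drug's concentration axis: `+1` (increase the concentration) when the
#' response at the higher level is larger, `-1` when it is smaller. Returns
#' `0` as a tie signal when the two responses are exactly equal or the two
#' levels coincide; callers resolve ties with a uniformly random direction.
#'
#' @param k1,k2 Level indices of the two compared combinations for the drug
#'   being updated.
#' @param f1,f2 The corresponding observed responses.
#' @return `+1L`, `-1L`, or `0L` (tie).
#' @export
informed_direction <- function(k1, k2, f1, f2) {
  if (k1 == k2 || f1 == f2) return(0L)
  if ((f2 - f1) * (k2 - k1) > 0) 1L else -1L
}

# resolve a direction, drawing on ties; draw order: tie draw first
resolve_direction <- function(dir) {
  if (dir != 0L) return(dir)
  if (stats::runif(1) < 0.5) -1L else 1L
}

# apply a one-level move with edge handling: a move off the grid is
# reflected one level inward, or (edge = "clamp") left in place
apply_move <- function(k, move, m, edge) {
  nk <- k + move
  if (nk < 1L || nk > m) {
    nk <- if (edge == "reflect") k - move else k
  }
  nk
}

#' Initial search state
#'
#' Bundles everything the per-step updates need: the current combination and
#' its latest observed response, the reference combination (fixed median
#' levels for the Gur Game; the adaptively updated reference for ARU), the
#' per-drug last-move memory of the informed-guess baseline, the last two
#' trajectory observations for local-maximum detection, and the round-robin
#' drug pointer.
#'
#' @param grid A [make_grid()] object.
#' @param init_levels Integer vector: the initial combination.
#' @param init_obs Its observed response.
#' @param algorithm One of `"gur_simultaneous"`, `"gur_sequential"`,
#'   `"enhanced"`, `"aru"`.
#' @return A list of class `search_state`.
#' @export
new_search_state <- function(grid, init_levels, init_obs,
                             algorithm = c("aru", "enhanced",
                                           "gur_simultaneous", "gur_sequential")) {
  algorithm <- match.arg(algorithm)
  init_levels <- check_levels(grid, init_levels)
  n <- grid$n_drugs
  structure(list(
    algorithm = algorithm,
    levels = init_levels,
    cur_f = init_obs,
    next_drug = 1L,
    ref_levels = if (algorithm %in% c("gur_simultaneous", "gur_sequential"))
      gur_reference_levels(grid) else init_levels,
    ref_f = init_obs,
    mem_exists = rep(FALSE, n),
    mem_f_low = rep(NA_real_, n),
    mem_f_high = rep(NA_real_, n),
    traj_f1 = init_obs,
    traj_f2 = NA_real_,
    traj_levels1 = init_levels
  ), class = "search_state")
}

#' One Gur Game step
#'
#' Each updated drug draws an independent uniform `r` and is rewarded
#' ([gur_reward()]) when the current observed response exceeds `r`,
#' penalized ([gur_penalize()]) otherwise. In simultaneous mode all drugs
#' are updated in one step from the same current response; in sequential
#' mode only the round-robin drug moves. The new combination is then
#' observed through the oracle.
#'
#' @param state A [new_search_state()].
#' @param oracle An [evaluation_oracle()]; updated in place.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @return The updated state.
#' @export
gur_step <- function(state, oracle, mode = c("simultaneous", "sequential")) {
  mode <- match.arg(mode)
  m <- oracle$surface$grid$n_levels
  drugs <- if (mode == "simultaneous") seq_along(state$levels) else state$next_drug
  for (n in drugs) {
    r <- stats::runif(1)
    state$levels[n] <- if (state$cur_f > r) {
      gur_reward(state$levels[n], state$ref_levels[n], m[n])
    } else {
      gur_penalize(state$levels[n], state$ref_levels[n], m[n])
    }
  }
  if (mode == "sequential") {
    state$next_drug <- state$next_drug %% length(state$levels) + 1L
  }
  state$cur_f <- observe(oracle, state$levels)
  state
}

#' One step of the informed-guess single-drug baseline
#'
#' Updates the round-robin drug using the memory of its last move: the
#' beneficial direction is read off the two responses of the last pair of
#' combinations differing only in this drug (ties resolved at random), and
#' the drug moves one level in that direction with probability
#' [reward_probability()] of the pair, in the opposite direction otherwise.
#' A drug with no memory yet moves in a uniformly random direction (first
#' probe, no reward draw). Moves off the grid are handled per `edge`; the
#' new combination is observed and seeds the drug's memory.
#'
#' @inheritParams gur_step
#' @param alpha Randomness control in \[0, 1\].
#' @param edge `"clamp"` (default): a move off the grid stays in place, as
#'   in the Gur Game automaton; `"reflect"`: it goes one level inward
#'   instead.
#' @return The updated state.
#' @export
enhanced_step <- function(state, oracle, alpha = 1, edge = c("clamp", "reflect")) {
  edge <- match.arg(edge)
  n <- state$next_drug
  m <- oracle$surface$grid$n_levels[n]
  k <- state$levels[n]
  if (!state$mem_exists[n]) {
    move <- resolve_direction(0L)
  } else {
    fl <- state$mem_f_low[n]
    fh <- state$mem_f_high[n]
    dir <- resolve_direction(if (fl == fh) 0L else if (fh > fl) 1L else -1L)
    g <- reward_probability(fl, fh, alpha)
    r <- stats::runif(1)
    move <- if (g > r) dir else -dir
  }
  nk <- apply_move(k, move, m, edge)
  old_f <- state$cur_f
  state$levels[n] <- nk
  f_new <- observe(oracle, state$levels)
  if (nk != k) {
    state$mem_exists[n] <- TRUE
    if (nk > k) {
      state$mem_f_low[n] <- old_f
      state$mem_f_high[n] <- f_new
    } else {
      state$mem_f_low[n] <- f_new
      state$mem_f_high[n] <- old_f
    }
  }
  state$cur_f <- f_new
  state$next_drug <- state$next_drug %% length(state$levels) + 1L
  state
}

#' One step of the adaptive reference update (ARU) algorithm
#'
#' The round-robin drug is updated by comparing the current combination with
#' the reference combination (the most recent trajectory-local maximum;
#' initially the trial's starting combination). The beneficial direction is
#' the sign of the virtual slope between `(k_cur, f_cur)` and
#' `(k_ref, f_ref)` on this drug's axis ([informed_direction()]). When that
#' comparison is uninformative - the drug's level equals the reference
#' level, or the two responses are exactly equal - the step falls back to
#' the drug's own last-move response pair (the same comparison the
#' informed-guess baseline uses); if the drug has no informative pair
#' either, the direction is uniformly random. The drug then moves one level
#' in the beneficial direction with probability [reward_probability()]
#' `(f_cur, f_ref)`, in the opposite direction otherwise; moves off the grid
#' are handled per `edge`. The new combination is observed, the drug's
#' move memory is refreshed, and [update_reference()] is applied.
#'
#' @inheritParams enhanced_step
#' @return The updated state.
#' @export
aru_step <- function(state, oracle, alpha = 1, edge = c("clamp", "reflect")) {
  edge <- match.arg(edge)
  n <- state$next_drug
  m <- oracle$surface$grid$n_levels[n]
  k <- state$levels[n]
  dir <- informed_direction(k, state$ref_levels[n], state$cur_f, state$ref_f)
  if (dir == 0L && state$mem_exists[n] &&
      state$mem_f_low[n] != state$mem_f_high[n]) {
    dir <- if (state$mem_f_high[n] > state$mem_f_low[n]) 1L else -1L
  }
  dir <- resolve_direction(dir)
  g <- reward_probability(state$cur_f, state$ref_f, alpha)
  r <- stats::runif(1)
  move <- if (g > r) dir else -dir
  nk <- apply_move(k, move, m, edge)
  old_f <- state$cur_f
  state$levels[n] <- nk
  f_new <- observe(oracle, state$levels)
  if (nk != k) {
    state$mem_exists[n] <- TRUE
    if (nk > k) {
      state$mem_f_low[n] <- old_f
      state$mem_f_high[n] <- f_new
    } else {
      state$mem_f_low[n] <- f_new
      state$mem_f_high[n] <- old_f
    }
  }
  state <- update_reference(state, state$levels, f_new)
  state$cur_f <- f_new
  state$next_drug <- state$next_drug %% length(state$levels) + 1L
  state
}

#' Reference update at a trajectory-local maximum
#'
#' Given the newest observation, checks the last three observed responses
#' along the visit trajectory `f(t-2), f(t-1), f(t)`: if the middle one is
#' strictly larger than both neighbors, the search has just passed a local
#' maximum and the reference becomes the combination observed at `t-1`,
#' keeping the response it had when visited (it is not re-measured). With
#' fewer than three observations, or without a strict local maximum, the
#' reference is unchanged. The trajectory tail is advanced either way.
#'
#' @param state A [new_search_state()] for the ARU algorithm.
#' @param new_levels The combination just observed.
#' @param f_new Its observed response.
#' @return The updated state.
#' @export
update_reference <- function(state, new_levels, f_new) {
  if (!is.na(state$traj_f2) &&
      state$traj_f1 > state$traj_f2 && state$traj_f1 > f_new) {
    state$ref_levels <- state$traj_levels1
    state$ref_f <- state$traj_f1
  }
  state$traj_f2 <- state$traj_f1
  state$traj_f1 <- f_new
  state$traj_levels1 <- new_levels
  state
}
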