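# The three environments: a 7-state center reaching maze (fully observable
# MDP), the same maze observed through digit images (history-independent
# partially observable RL), and a digit-matching T-maze in which the rewarded
# arm depends on whether the digits shown at the start and at the junction
# match (history-dependent partially observable RL).

#' Create a task environment
#'
#' @param task `"center"`, `"digit_center"` or `"tmaze"`.
#' @param digit_bank A [synth_digit_bank()] (required for the digit tasks).
#'   The digit tasks draw one of the bank's variants of the class tied to the
#'   current state at every observation.
#' @param corridor_len Number of corridor nodes between the T-maze start and
#'   the junction (default 1).
#' @param step_cap Maximum number of steps per episode (50 for the reaching
#'   tasks, 10 for the T-maze).
#' @return An environment description of class `ferl_env`. Call [env_reset()]
#'   before use.
#' @export
ferl_env <- function(task = c("center", "digit_center", "tmaze"),
                     digit_bank = NULL, corridor_len = 1,
                     step_cap = NULL) {
  task <- match.arg(task)
  if (task != "center" && is.null(digit_bank))
    stop("digit tasks need a digit bank")
  if (task == "digit_center" && !all(0:6 %in% digit_bank$classes))
    stop("digit center reaching needs digit classes 0..6")
  if (task == "tmaze" && !all(0:1 %in% digit_bank$classes))
    stop("the T-maze needs digit classes 0 and 1")
  if (is.null(step_cap)) step_cap <- if (task == "tmaze") 10L else 50L
  structure(list(task = task, digit_bank = digit_bank,
                 corridor_len = corridor_len, step_cap = step_cap,
                 pos = NA_integer_, digits = c(NA_integer_, NA_integer_),
                 step = 0L, done = FALSE),
            class = "ferl_env")
}

#' Reset an environment to the start of an episode
#'
#' Reaching tasks start at either end of the maze (states 0 and 6) with equal
#' probability; the T-maze starts at the bottom of the stem with two fresh
#' random digits (start and junction).
#'
#' @param env A [ferl_env()].
#' @return The reset environment.
#' @export
env_reset <- function(env) {
  env$step <- 0L; env$done <- FALSE
  if (env$task == "tmaze") {
    env$pos <- 0L
    env$digits <- sample(0:1, 2, replace = TRUE)
  } else {
    env$pos <- sample(c(0L, 6L), 1)
  }
  env
}

#' Number of discrete positions of a task
#' @param env A [ferl_env()].
#' @return Integer count of maze positions.
#' @export
env_n_states <- function(env) {
  if (env$task == "tmaze") env$corridor_len + 2L else 7L
}

#' Action labels available in a task
#' @param env A [ferl_env()].
#' @return Character vector of the two action labels.
#' @export
env_actions <- function(env) {
  if (env$task == "tmaze") c("left", "right") else c("left", "right")
}

#' One move in the 7-state center reaching maze
#'
#' Position moves by the action (-1 left, +1 right) and is clipped to
#' `[0, 6]`; reaching the middle state 3 ends the episode with reward 50000,
#' every other move costs -1000.
#'
#' @param pos Current position in `0..6`.
#' @param action `-1` or `+1`.
#' @return `list(pos, reward, done)`.
#' @export
center_step <- function(pos, action) {
  if (!action %in% c(-1, 1)) stop("action must be -1 or +1")
  if (pos == 3) stop("episode already at the goal")
  new_pos <- min(max(pos + action, 0L), 6L)
  if (new_pos == 3L) list(pos = 3L, reward = 50000, done = TRUE)
  else list(pos = as.integer(new_pos), reward = -1000, done = FALSE)
}

#' One move in the digit-matching T-maze
#'
#' Corridor nodes advance toward the junction regardless of the chosen label
#' (both action blocks act as "forward" outside the junction). At the
#' junction, turning toward the correct arm -- right when the start and
#' junction digits match, left when they differ -- pays +20000; the other arm
#' pays -500. Both turns end the episode.
#'
#' @param env A [ferl_env()] with `task = "tmaze"`.
#' @param action `"left"` or `"right"`.
#' @return `list(env, reward, done)`.
#' @export
tmaze_step <- function(env, action) {
  if (!action %in% c("left", "right")) stop("invalid action label")
  junction <- env$corridor_len + 1L
  if (env$pos < junction) {
    env$pos <- env$pos + 1L
    return(list(env = env, reward = 0, done = FALSE))
  }
  match <- env$digits[1] == env$digits[2]
  reward <- if ((match && action == "right") || (!match && action == "left"))
    20000 else -500
  env$done <- TRUE
  list(env = env, reward = reward, done = TRUE)
}

#' Advance any environment by one action
#'
#' @param env A [ferl_env()] (after [env_reset()]).
#' @param action `"left"` or `"right"` (mapped to -1/+1 in the reaching
#'   tasks).
#' @return `list(env, reward, done)`; `done` is also set when the step cap is
#'   reached.
#' @export
env_step <- function(env, action) {
  if (env$done) stop("episode is over; reset the environment")
  env$step <- env$step + 1L
  if (env$task == "tmaze") {
    out <- tmaze_step(env, action)
    env <- out$env
  } else {
    mv <- center_step(env$pos, if (action == "left") -1L else 1L)
    env$pos <- mv$pos
    out <- list(reward = mv$reward, done = mv$done)
  }
  done <- out$done || env$step >= env$step_cap
  env$done <- done
  list(env = env, reward = out$reward, done = done,
       capped = !out$done && done)
}

#' Current observation of an environment
#'
#' The plain maze observes the integer position. The digit maze observes a
#' bitmap of the digit class equal to the current state, drawn uniformly from
#' the bank's variants. The T-maze observes a random `0`/`1` digit bitmap at
#' the start and at the junction and nothing (zeros) in the corridor.
#'
#' @param env A [ferl_env()].
#' @return For `"center"`, the integer position; otherwise a bitmap matrix
#'   (possibly all zeros) with attribute `class_label`.
#' @export
env_observe <- function(env) {
  if (env$task == "center") return(env$pos)
  if (env$task == "digit_center")
    return(digit_sample(env$digit_bank, env$pos))
  junction <- env$corridor_len + 1L
  if (env$pos == 0L) digit_sample(env$digit_bank, env$digits[1])
  else if (env$pos == junction) digit_sample(env$digit_bank, env$digits[2])
  else {
    z <- matrix(0, env$digit_bank$shape[1], env$digit_bank$shape[2])
    attr(z, "class_label") <- NA_integer_
    z
  }
}

#' Exact value iteration on the 7-state center reaching maze
#'
#' Independent oracle for the task's optimum: sweeps Bellman backups to
#' convergence on the deterministic 7-state MDP (goal state 3 absorbing with
#' entry reward 50000, -1000 per other move).
#'
#' @param gamma Discount factor.
#' @param tol Convergence tolerance on the sup-norm.
#' @return List with the optimal value `V` per state (0-indexed names), the
#'   greedy policy, and `return_from_ends` (the optimal discounted return from
#'   states 0 and 6).
#' @export
center_value_iteration <- function(gamma = 0.99, tol = 1e-10) {
  V <- numeric(7)
  repeat {
    V_new <- V
    for (s in 0:6) {
      if (s == 3) { V_new[s + 1] <- 0; next }
      q <- vapply(c(-1L, 1L), function(a) {
        mv <- center_step(s, a)
        mv$reward + if (mv$done) 0 else gamma * V[mv$pos + 1]
      }, numeric(1))
      V_new[s + 1] <- max(q)
    }
    if (max(abs(V_new - V)) < tol) break
    V <- V_new
  }
  policy <- vapply(0:6, function(s) {
    if (s == 3) return(NA_integer_)
    q <- vapply(c(-1L, 1L), function(a) {
      mv <- center_step(s, a)
      mv$reward + if (mv$done) 0 else gamma * V[mv$pos + 1]
    }, numeric(1))
    c(-1L, 1L)[which.max(q)]
  }, integer(1))
  names(V) <- names(policy) <- 0:6
  list(V = V, policy = policy, return_from_ends = unname(V[c(1, 7)]))
}

#' Closed-form optimal return of the center reaching task
#'
#' From either end the shortest path is 3 moves, so the optimal discounted
#' return is `-1000 - 1000 gamma + 50000 gamma^2` (47015 at `gamma = 0.99`).
#'
#' @param gamma Discount factor.
#' @return Scalar return.
#' @export
center_optimal_return <- function(gamma = 0.99) {
  -1000 - 1000 * gamma + 50000 * gamma^2
}
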