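#' Adaptive screening environment
#'
#' A partially observable decision process over the three instruments. At
#' each step the agent either asks the next unasked question of one
#' instrument (actions 0 = anxiety, 1 = depression, 2 = stress) or stops
#' (action 3). Asking draws a 0--100 severity observation from the
#' respondent; the relevant component, rescaled to Likert units, is added to
#' that disorder's cumulative score `S`. Rewards follow the four printed
#' cases per disorder:
#' \itemize{
#'   \item `+10` -- instrument exhausted, `S >= tau`, no prediction committed
#'     yet: the prediction is committed (no item is asked, the observation
#'     repeats);
#'   \item `-5`  -- instrument exhausted otherwise (the decision for that
#'     disorder has already been taken, or it cannot reach its cutoff);
#'   \item `-1`  -- items remain: the question is asked;
#'   \item Stop: `+20` and termination when the stop predicate holds, else
#'     `-5` and the episode continues.
#' }
#' The stop predicate requires, for every disorder, at least one question
#' asked and either an exhausted instrument or a cumulative score at or below
#' the current per-question threshold. Episodes also truncate at a safety cap
#' (default 60 steps) with no terminal bonus.
#'
#' @name adaptive_env
NULL

ACTION_STOP <- 3L

new_session_state <- function() {
  list(q = stats::setNames(integer(3L), DISORDERS),
       S = stats::setNames(numeric(3L), DISORDERS),
       predicted = stats::setNames(logical(3L), DISORDERS),
       last_obs = stats::setNames(numeric(4L), c(DISORDERS, "normal")),
       t = 0L, done = FALSE, truncated = FALSE)
}

exhausted_flags <- function(state, instruments)
  stats::setNames(vapply(DISORDERS, function(d)
    state$q[[d]] >= instruments[[d]]$item_count, NA), DISORDERS)

#' Stop predicate
#'
#' `TRUE` iff for every disorder at least one question has been asked and the
#' disorder is resolved (its instrument exhausted) or its cumulative score is
#' at or below the per-question threshold for the number of questions asked
#' so far.
#'
#' @param state Session state (list with `q`, `S` named by disorder), e.g.
#'   from `env$state()`.
#' @param thresholds A `threshold_table`.
#' @param instruments Instrument list.
#' @return Logical scalar.
#' @export
stop_ok <- function(state, thresholds, instruments = load_instruments()) {
  all(vapply(DISORDERS, function(d) {
    q <- state$q[[d]]
    if (q < 1L) return(FALSE)
    q >= instruments[[d]]$item_count ||
      state$S[[d]] <= thresholds$per_question[[d]][q]
  }, NA))
}

#' Final diagnosis of a session
#'
#' A disorder is read positive when its prediction was committed during the
#' episode, or when its instrument is exhausted with a cumulative score at or
#' above the final threshold; otherwise negative.
#'
#' @inheritParams stop_ok
#' @return Named logical vector over the three disorders.
#' @export
final_diagnosis <- function(state, thresholds, instruments = load_instruments()) {
  stats::setNames(vapply(DISORDERS, function(d) {
    state$predicted[[d]] ||
      (state$q[[d]] >= instruments[[d]]$item_count &&
         state$S[[d]] >= thresholds$final[[d]])
  }, NA), DISORDERS)
}

#' Create a screening environment
#'
#' Standard episodic contract: `env$reset()` returns the initial (all-zero)
#' observation; `env$step(action)` with `action` in `{0, 1, 2, 3}` returns
#' `list(observation, reward, done, truncated, info)`; `env$state()` returns
#' a session-state snapshot. Given a deterministic respondent, the
#' environment itself is fully deterministic.
#'
#' @param respondent A `respondent` (e.g. from [make_respondent()] or
#'   [constant_respondent()]).
#' @param thresholds A `threshold_table` covering all three instruments.
#' @param instruments Instrument list.
#' @param max_steps Safety cap on episode length; the episode truncates there
#'   with no terminal bonus.
#' @param enforce_full Character vector of disorders whose instrument must be
#'   exhausted before Stop can succeed (off by default; the completion rule
#'   is otherwise reward-induced).
#' @return An object of class `screening_env`.
#' @export
screening_env <- function(respondent, thresholds,
                          instruments = load_instruments(),
                          max_steps = 60L, enforce_full = character()) {
  stopifnot(inherits(thresholds, "threshold_table"))
  if (!all(DISORDERS %in% names(thresholds$per_question)))
    stop("threshold table must cover all three instruments", call. = FALSE)
  stopifnot(is.function(respondent$answer))
  if (length(enforce_full) && !all(enforce_full %in% DISORDERS))
    stop("enforce_full must name disorders", call. = FALSE)
  max_steps <- as.integer(max_steps)
  qmax <- vapply(instruments[DISORDERS], `[[`, 0L, "item_count")
  lmax <- vapply(instruments[DISORDERS], `[[`, 0L, "likert_max")
  theta <- thresholds$per_question[DISORDERS]
  tau <- unlist(thresholds$final[DISORDERS])
  st <- NULL

  reset <- function() {
    st <<- new_session_state()
    st$last_obs
  }

  step <- function(action) {
    if (is.null(st)) stop("call reset() before step()", call. = FALSE)
    if (st$done) stop("episode is done; call reset()", call. = FALSE)
    action <- as.integer(action)
    if (length(action) != 1L || is.na(action) || action < 0L || action > 3L)
      stop("action must be one of 0, 1, 2, 3", call. = FALSE)
    s <- st
    info <- list()
    if (action == ACTION_STOP) {
      ok <- stop_ok(s, thresholds, instruments) &&
        (!length(enforce_full) ||
           all(s$q[enforce_full] >= qmax[enforce_full]))
      if (ok) {
        reward <- 20
        s$done <- TRUE
        info$diagnosis <- final_diagnosis(s, thresholds, instruments)
      } else {
        reward <- -5
      }
      # no new user reply on Stop: the last observation repeats
    } else {
      d <- DISORDERS[action + 1L]
      if (s$q[[d]] >= qmax[[d]]) {
        if (!s$predicted[[d]] && s$S[[d]] >= tau[[d]]) {
          reward <- 10            # prediction committed; no item is asked
          s$predicted[[d]] <- TRUE
          info$committed <- d
        } else {
          reward <- -5            # decision already taken for this disorder
        }
      } else {
        # items remain: under !exhausted the printed -1 condition
        # (q < Qmax or S > theta_q) always holds, so the residual -5 branch
        # is unreachable; asking consumes the next item in canonical order.
        reward <- -1
        i <- s$q[[d]] + 1L
        obs <- respondent$answer(d, i)
        s$q[[d]] <- i
        s$S[[d]] <- s$S[[d]] + obs[[d]] / 100 * lmax[[d]]
        s$last_obs <- obs
      }
    }
    s$t <- s$t + 1L
    if (!s$done && s$t >= max_steps) {
      s$done <- TRUE
      s$truncated <- TRUE
      info$diagnosis <- final_diagnosis(s, thresholds, instruments)
    }
    st <<- s
    list(observation = s$last_obs, reward = reward, done = s$done,
         truncated = s$truncated, info = info)
  }

  structure(list(reset = reset, step = step,
                 state = function() st,
                 done = function() is.null(st) || st$done,
                 thresholds = thresholds, instruments = instruments,
                 max_steps = max_steps,
                 respondent = function() respondent),
            class = "screening_env")
}

#' Immediate reward of an action in a given session state
#'
#' Pure companion to [screening_env()]: computes the reward case that fires
#' for `action` in `state` without advancing any episode. Used for
#' reward-case audits.
#'
#' @param state Session state (`q`, `S`, `predicted` named by disorder).
#' @param action Integer action code 0--3.
#' @param thresholds A `threshold_table`.
#' @param instruments Instrument list.
#' @return List with `reward` and `case` (one of `"commit"`,
#'   `"already_decided"`, `"ask"`, `"stop_valid"`, `"stop_invalid"`).
#' @export
reward_case <- function(state, action, thresholds,
                        instruments = load_instruments()) {
  action <- as.integer(action)
  if (action == ACTION_STOP) {
    if (stop_ok(state, thresholds, instruments))
      return(list(reward = 20, case = "stop_valid"))
    return(list(reward = -5, case = "stop_invalid"))
  }
  d <- DISORDERS[action + 1L]
  ins <- instruments[[d]]
  if (state$q[[d]] >= ins$item_count) {
    if (!state$predicted[[d]] && state$S[[d]] >= thresholds$final[[d]])
      return(list(reward = 10, case = "commit"))
    return(list(reward = -5, case = "already_decided"))
  }
  list(reward = -1, case = "ask")
}
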