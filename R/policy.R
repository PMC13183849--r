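#' Decision policies
#'
#' A policy is the agent side of the screening environment: given the current
#' observation and its own hidden (memory) state it returns the next action.
#' The package ships two scripted baselines -- a uniform-random policy and the
#' full-sequential policy that administers every item of every instrument in
#' canonical order, commits each prediction whose cumulative score reaches
#' the final threshold, and then stops -- plus a trainable recurrent
#' actor-critic ([train_policy()]).
#'
#' @name policy
NULL

#' Construct a policy handle
#'
#' @param act Function `(observation, hidden) -> list(action, hidden)`.
#' @param init_hidden Function returning the hidden state at an episode
#'   start; hidden state never crosses episode boundaries.
#' @param name Short identifier.
#' @param deterministic Logical: does `act` use the RNG?
#' @param params Optional parameter payload (used by trained policies).
#' @return Object of class `policy`.
#' @export
new_policy <- function(act, init_hidden = function() NULL, name = "policy",
                       deterministic = FALSE, params = NULL) {
  structure(list(act = act, init_hidden = init_hidden, name = name,
                 deterministic = deterministic, params = params),
            class = "policy")
}

#' @export
print.policy <- function(x, ...) {
  cat(sprintf("<policy> %s (%s)\n", x$name,
              if (x$deterministic) "deterministic" else "stochastic"))
  invisible(x)
}

#' Uniform-random baseline policy
#'
#' Draws each action uniformly from `{0, 1, 2, 3}` using the caller's RNG
#' stream (seed the evaluation, not the policy).
#'
#' @return A `policy`.
#' @export
random_policy <- function() {
  new_policy(function(obs, hidden) list(action = sample(0:3, 1L),
                                        hidden = hidden),
             name = "random", deterministic = FALSE)
}

#' Full-sequential baseline policy
#'
#' Asks all items of the three instruments in canonical order (anxiety,
#' depression, stress), then issues one commit action for every disorder
#' whose cumulative score has reached its final threshold, then stops.
#' Episode length is therefore `26 + number of commits + 1`. The policy
#' tracks its own cumulative scores from the observations it requested, which
#' coincide with the environment's.
#'
#' @param thresholds A `threshold_table` (for the final thresholds tau).
#' @param instruments Instrument list.
#' @return A deterministic `policy`.
#' @export
full_sequential_policy <- function(thresholds, instruments = load_instruments()) {
  qmax <- vapply(instruments[DISORDERS], `[[`, 0L, "item_count")
  lmax <- vapply(instruments[DISORDERS], `[[`, 0L, "likert_max")
  tau <- unlist(thresholds$final[DISORDERS])
  init <- function() list(asked = stats::setNames(integer(3L), DISORDERS),
                          S = stats::setNames(numeric(3L), DISORDERS),
                          pending = NA_character_,
                          committed = stats::setNames(logical(3L), DISORDERS))
  act <- function(obs, hidden) {
    if (!is.na(hidden$pending)) {
      d <- hidden$pending
      hidden$S[[d]] <- hidden$S[[d]] + obs[[d]] / 100 * lmax[[d]]
      hidden$pending <- NA_character_
    }
    open <- DISORDERS[hidden$asked < qmax]
    if (length(open)) {
      d <- open[1L]
      hidden$asked[[d]] <- hidden$asked[[d]] + 1L
      hidden$pending <- d
      return(list(action = match(d, DISORDERS) - 1L, hidden = hidden))
    }
    to_commit <- DISORDERS[!hidden$committed & hidden$S >= tau]
    if (length(to_commit)) {
      d <- to_commit[1L]
      hidden$committed[[d]] <- TRUE
      return(list(action = match(d, DISORDERS) - 1L, hidden = hidden))
    }
    list(action = 3L, hidden = hidden)
  }
  new_policy(act, init, name = "full_sequential", deterministic = TRUE)
}

#' Run a single episode
#'
#' @param env A `screening_env`.
#' @param policy A `policy`.
#' @param log_steps If `TRUE`, attach a per-step data frame (`t`, `action`,
#'   `reward`, observation components).
#' @return List with `reward` (total), `length`, `diagnosis` (named logical),
#'   `truncated`, and optionally `steps`.
#' @export
run_episode <- function(env, policy, log_steps = FALSE) {
  obs <- env$reset()
  hidden <- policy$init_hidden()
  total <- 0
  len <- 0L
  log <- if (log_steps) vector("list", env$max_steps) else NULL
  repeat {
    res <- policy$act(obs, hidden)
    hidden <- res$hidden
    out <- env$step(res$action)
    total <- total + out$reward
    len <- len + 1L
    if (log_steps)
      log[[len]] <- data.frame(t = len, action = res$action,
                               reward = out$reward,
                               t(out$observation))
    obs <- out$observation
    if (out$done) break
  }
  st <- env$state()
  diagnosis <- final_diagnosis(st, env$thresholds, env$instruments)
  rec <- list(reward = total, length = len, diagnosis = diagnosis,
              truncated = st$truncated)
  if (log_steps) rec$steps <- do.call(rbind, log[seq_len(len)])
  rec
}

#' Evaluate a policy over a synthetic respondent population
#'
#' Draws `n_episodes` respondents from the generator configuration (seeded by
#' `seed`, independently of the policy's action RNG) and runs one episode per
#' respondent. Returns one row per episode: total reward, length, truncation
#' flag, the adaptive diagnosis and the respondent's full-questionnaire
#' ground truth per disorder.
#'
#' @param policy A `policy`.
#' @param thresholds A `threshold_table`.
#' @param config A `generator_config` describing the respondent population.
#' @param n_episodes Number of episodes.
#' @param seed Integer seed controlling both respondent draws and any policy
#'   action sampling.
#' @param instruments Instrument list.
#' @param max_steps Episode safety cap.
#' @return Data frame of episode records (class `episode_records`).
#' @export
evaluate_policy <- function(policy, thresholds, config,
                            n_episodes = 200L, seed = 0L,
                            instruments = load_instruments(),
                            max_steps = 60L) {
  profile_cfg <- config
  profile_cfg$seed <- derive_seed(seed, 1L)
  profile_cfg$n <- as.integer(n_episodes)
  profiles <- sample_profiles(profile_cfg, instruments)
  rows <- with_seed(derive_seed(seed, 2L), {
    lapply(seq_len(n_episodes), function(i) {
      resp <- make_respondent(profiles[[i]], config, instruments)
      env <- screening_env(resp, thresholds, instruments, max_steps = max_steps)
      rec <- run_episode(env, policy)
      st <- env$state()
      data.frame(episode = i, reward = rec$reward, length = rec$length,
                 truncated = rec$truncated,
                 anxiety_pred = rec$diagnosis[["anxiety"]],
                 depression_pred = rec$diagnosis[["depression"]],
                 stress_pred = rec$diagnosis[["stress"]],
                 anxiety_true = resp$truth[["anxiety"]],
                 depression_true = resp$truth[["depression"]],
                 stress_true = resp$truth[["stress"]],
                 anxiety_score = st$S[["anxiety"]],
                 depression_score = st$S[["depression"]],
                 stress_score = st$S[["stress"]])
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("episode_records", class(out))
  out
}
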