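#' Recurrent actor-critic training
#'
#' The trainable policy is a recurrent actor-critic: a single tanh recurrent
#' layer summarizes the session history (the observation stream alone does
#' not reveal how many questions have been asked, so memory is what turns the
#' partially observable screening process into a learnable one), with a
#' softmax action head over the four actions and a linear value head.
#' Optimization follows the proximal-policy scheme: on-policy rollouts of
#' fixed length, generalized advantage estimation, several epochs of a
#' clipped surrogate policy-gradient objective with a value loss and an
#' entropy bonus, Adam updates with global gradient-norm clipping, and full
#' backpropagation through time within each rollout segment (hidden state
#' detaches at episode boundaries).
#'
#' @name train
NULL

#' Training configuration
#'
#' @param total_steps Total environment steps to train for (> 0).
#' @param gamma Discount factor in `[0, 1)`.
#' @param clip_ratio Clipping radius of the surrogate objective.
#' @param learning_rate Adam learning rate.
#' @param hidden_size Recurrent hidden units.
#' @param rollout_length Steps per on-policy rollout segment.
#' @param gae_lambda Generalized-advantage-estimation lambda.
#' @param entropy_coef,value_coef Loss weights of the entropy bonus and the
#'   value head.
#' @param epochs Optimization epochs per rollout.
#' @param max_grad_norm Global gradient-norm clip.
#' @param reward_scale Internal multiplier applied to rewards before
#'   advantage/return computation so the value target is well-conditioned;
#'   logged episode rewards stay on the environment's scale.
#' @param seed Integer seed for parameter initialization and action sampling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(total_steps = 50000L, gamma = 0.99, clip_ratio = 0.2,
                         learning_rate = 1e-3, hidden_size = 64L,
                         rollout_length = 128L, gae_lambda = 0.95,
                         entropy_coef = 0.01, value_coef = 0.5, epochs = 4L,
                         max_grad_norm = 0.5, reward_scale = 0.1, seed = 0L) {
  total_steps <- as.integer(total_steps)
  if (is.na(total_steps) || total_steps <= 0L)
    stop("total_steps must be > 0", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  if (clip_ratio <= 0) stop("clip_ratio must be positive", call. = FALSE)
  structure(list(total_steps = total_steps, gamma = gamma,
                 clip_ratio = clip_ratio, learning_rate = learning_rate,
                 hidden_size = as.integer(hidden_size),
                 rollout_length = as.integer(rollout_length),
                 gae_lambda = gae_lambda, entropy_coef = entropy_coef,
                 value_coef = value_coef, epochs = as.integer(epochs),
                 max_grad_norm = max_grad_norm, reward_scale = reward_scale,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Recurrent input: the 4 observation components (scaled to [0, 1]), a
# one-hot encoding of the agent's previous action, and the agent's own
# session bookkeeping -- per-disorder question counters q^X, cumulative
# scores S^X, the margin of S^X relative to the per-question threshold
# schedule, instrument-exhaustion flags and committed-prediction flags.
# Everything here is a deterministic function of the agent's own
# action/observation history together with the public threshold table the
# policy is trained against; nothing is read from the environment's latent
# state. The recurrent core handles any residual history dependence.
INPUT_DIM <- 23L

# per-episode agent-side bookkeeping
fs_init <- function() list(q = numeric(3L), S = numeric(3L),
                           pred = logical(3L), prev = numeric(4L))

# after taking `action` (0-3) and receiving `obs`, advance the bookkeeping;
# an ask only consumes an item while the instrument still has items left,
# and an ask on an exhausted instrument with S >= tau commits the prediction
fs_update <- function(fs, action, obs, ctx) {
  if (action < 3L) {
    d <- action + 1L
    if (fs$q[d] < ctx$qmax[d]) {
      fs$q[d] <- fs$q[d] + 1
      fs$S[d] <- fs$S[d] + as.numeric(obs[[d]]) / 100 * ctx$lmax[d]
    } else if (!fs$pred[d] && fs$S[d] >= ctx$tau[d]) {
      fs$pred[d] <- TRUE
    }
  }
  fs$prev <- numeric(4L)
  fs$prev[action + 1L] <- 1
  fs
}

make_input <- function(obs, fs, ctx) {
  margin <- vapply(1:3, function(d) {
    q <- max(fs$q[d], 1)
    (ctx$theta[[d]][q] - fs$S[d]) / ctx$lmax[d]
  }, 0)
  c(as.numeric(obs[1:4]) / 100, fs$prev, fs$q / ctx$qmax,
    fs$S / (ctx$qmax * ctx$lmax), clip(margin, -3, 3),
    as.numeric(fs$q >= ctx$qmax), as.numeric(fs$pred))
}

policy_ctx <- function(thresholds, instruments) {
  list(qmax = vapply(instruments[DISORDERS], `[[`, 0L, "item_count"),
       lmax = vapply(instruments[DISORDERS], `[[`, 0L, "likert_max"),
       theta = lapply(thresholds$per_question[DISORDERS], as.numeric),
       tau = as.numeric(unlist(thresholds$final[DISORDERS])))
}

init_params <- function(hidden_size) {
  H <- hidden_size
  list(Wxh = matrix(stats::rnorm(H * INPUT_DIM, 0, 1 / sqrt(INPUT_DIM)),
                    H, INPUT_DIM),
       Whh = matrix(stats::rnorm(H * H, 0, 0.5 / sqrt(H)), H, H),
       bh = numeric(H),
       Wp = matrix(stats::rnorm(4L * H, 0, 0.01), 4L, H),
       bp = numeric(4L),
       Wv = stats::rnorm(H, 0, 0.01),
       bv = 0)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_update <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grads[[nm]]
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Wrap trained parameters as a policy
#'
#' @param params Parameter list from [train_policy()] (`policy$params`).
#' @param deterministic If `TRUE`, act by argmax over action probabilities;
#'   otherwise sample from them (the default, matching how training-time
#'   behaviour is evaluated).
#' @return A `policy`.
#' @export
trained_policy <- function(params, deterministic = FALSE) {
  H <- length(params$bh)
  ctx <- params$ctx
  # the observation that answers action `a` only arrives with the next call,
  # so bookkeeping advances lazily: fold the pending action in first
  act <- function(obs, hidden) {
    if (!is.null(hidden$pending))
      hidden$fs <- fs_update(hidden$fs, hidden$pending, obs, ctx)
    x <- make_input(obs, hidden$fs, ctx)
    h <- tanh(params$Wxh %*% x + params$Whh %*% hidden$h + params$bh)
    p <- softmax(params$Wp %*% h + params$bp)
    a <- if (deterministic) which.max(p) - 1L
         else sample.int(4L, 1L, prob = p) - 1L
    list(action = a,
         hidden = list(h = as.numeric(h), fs = hidden$fs, pending = a))
  }
  new_policy(act,
             init_hidden = function() list(h = numeric(H), fs = fs_init(),
                                           pending = NULL),
             name = "recurrent_ppo", deterministic = deterministic,
             params = params)
}

#' Train the recurrent policy
#'
#' Runs clipped-surrogate policy-gradient training on environments produced
#' by `make_env`. Fully seeded: the same `make_env` and configuration yield
#' bit-identical training curves.
#'
#' @param make_env Function `(episode_index) -> screening_env`; called for
#'   every new episode, so respondent draws are under the factory's control.
#' @param config A `train_config`.
#' @return A stochastic `policy` with the parameter payload in `$params` and
#'   the training curve (one row per rollout: `step`, `episodes`,
#'   `mean_reward`) in `$curve`.
#' @export
train_policy <- function(make_env, config = train_config()) {
  stopifnot(inherits(config, "train_config"), is.function(make_env))
  with_seed(config$seed, train_policy_impl(make_env, config))
}

train_policy_impl <- function(make_env, config) {
  H <- config$hidden_size
  L <- config$rollout_length
  params <- init_params(H)
  opt <- adam_init(params)
  gamma <- config$gamma
  lam <- config$gae_lambda
  clip_r <- config$clip_ratio

  ep_idx <- 1L
  env <- make_env(ep_idx)
  ctx <- policy_ctx(env$thresholds, env$instruments)
  obs <- env$reset()
  h <- numeric(H)
  fs <- fs_init()
  new_episode <- TRUE
  ep_reward <- 0
  ep_rewards <- numeric(0)
  steps_done <- 0L
  curve <- list()
  n_roll <- ceiling(config$total_steps / L)

  for (roll in seq_len(n_roll)) {
    X <- matrix(0, INPUT_DIM, L)
    Hseg <- matrix(0, H, L)
    prevdone <- logical(L)
    acts <- integer(L)
    logp_old <- numeric(L)
    vals <- numeric(L)
    rews <- numeric(L)
    dones <- logical(L)
    h0 <- h

    for (t in seq_len(L)) {
      prevdone[t] <- new_episode
      if (new_episode) {
        h <- numeric(H)
        fs <- fs_init()
      }
      x <- make_input(obs, fs, ctx)
      h <- as.numeric(tanh(params$Wxh %*% x + params$Whh %*% h + params$bh))
      p <- softmax(as.numeric(params$Wp %*% h) + params$bp)
      a <- sample.int(4L, 1L, prob = p)
      X[, t] <- x
      Hseg[, t] <- h
      acts[t] <- a
      logp_old[t] <- log(p[a])
      vals[t] <- sum(params$Wv * h) + params$bv
      out <- env$step(a - 1L)
      rews[t] <- out$reward * config$reward_scale
      dones[t] <- out$done
      ep_reward <- ep_reward + out$reward   # raw scale for logging
      new_episode <- out$done
      fs <- fs_update(fs, a - 1L, out$observation, ctx)
      if (out$done) {
        ep_rewards <- c(ep_rewards, ep_reward)
        ep_reward <- 0
        ep_idx <- ep_idx + 1L
        env <- make_env(ep_idx)
        obs <- env$reset()
      } else {
        obs <- out$observation
      }
    }
    steps_done <- steps_done + L

    # bootstrap value of the state after the segment
    v_boot <- if (dones[L]) 0 else {
      xb <- make_input(obs, fs, ctx)
      hb <- tanh(params$Wxh %*% xb + params$Whh %*% h + params$bh)
      sum(params$Wv * hb) + params$bv
    }
    adv <- numeric(L)
    gae <- 0
    v_next <- v_boot
    for (t in L:1) {
      nonterm <- if (dones[t]) 0 else 1
      delta <- rews[t] + gamma * v_next * nonterm - vals[t]
      gae <- delta + gamma * lam * nonterm * gae
      adv[t] <- gae
      v_next <- vals[t]
    }
    rets <- adv + vals
    adv_n <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)

    for (ep in seq_len(config$epochs)) {
      # forward pass over the segment with the current parameters
      Hc <- matrix(0, H, L)
      P <- matrix(0, 4L, L)
      hprev <- h0
      for (t in seq_len(L)) {
        if (prevdone[t]) hprev <- numeric(H)
        hprev <- as.numeric(tanh(params$Wxh %*% X[, t] +
                                   params$Whh %*% hprev + params$bh))
        Hc[, t] <- hprev
        P[, t] <- softmax(as.numeric(params$Wp %*% hprev) + params$bp)
      }
      v_new <- as.numeric(params$Wv %*% Hc) + params$bv
      p_a <- P[cbind(acts, seq_len(L))]
      logp_new <- log(pmax(p_a, 1e-12))
      ratio <- exp(logp_new - logp_old)
      surr1 <- ratio * adv_n
      surr2 <- clip(ratio, 1 - clip_r, 1 + clip_r) * adv_n
      use_unclipped <- surr1 <= surr2
      if (!all(is.finite(ratio)) || !all(is.finite(v_new)))
        stop("training diverged: non-finite ratio or value (rollout ", roll,
             ", epoch ", ep, ")", call. = FALSE)

      logP <- log(pmax(P, 1e-12))
      ent <- -colSums(P * logP)
      coef <- -adv_n * ratio * use_unclipped          # d(-min surr)/d logp_new
      one_hot <- matrix(0, 4L, L)
      one_hot[cbind(acts, seq_len(L))] <- 1
      dlogits <- sweep(one_hot - P, 2L, coef, `*`) +
        config$entropy_coef * P * sweep(logP, 2L, ent, `+`)
      dv <- config$value_coef * (v_new - rets)

      g <- list(Wxh = matrix(0, H, INPUT_DIM), Whh = matrix(0, H, H),
                bh = numeric(H), Wp = matrix(0, 4L, H), bp = numeric(4L),
                Wv = numeric(H), bv = 0)
      tWp <- t(params$Wp)
      tWhh <- t(params$Whh)
      carry <- numeric(H)
      for (t in L:1) {
        g_h <- as.numeric(tWp %*% dlogits[, t]) + params$Wv * dv[t] + carry
        g_a <- g_h * (1 - Hc[, t]^2)
        hp <- if (prevdone[t]) numeric(H)
              else if (t == 1L) h0 else Hc[, t - 1L]
        g$Wxh <- g$Wxh + tcrossprod(g_a, X[, t])
        g$Whh <- g$Whh + tcrossprod(g_a, hp)
        g$bh <- g$bh + g_a
        carry <- if (prevdone[t]) numeric(H) else as.numeric(tWhh %*% g_a)
      }
      g$Wp <- tcrossprod(dlogits, Hc)
      g$bp <- rowSums(dlogits)
      g$Wv <- as.numeric(Hc %*% dv)
      g$bv <- sum(dv)
      g <- lapply(g, function(x) x / L)

      gnorm <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
      if (!is.finite(gnorm))
        stop("training diverged: non-finite gradient (rollout ", roll, ")",
             call. = FALSE)
      if (gnorm > config$max_grad_norm)
        g <- lapply(g, function(x) x * config$max_grad_norm / gnorm)
      upd <- adam_update(params, g, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$opt
    }

    recent <- utils::tail(ep_rewards, 20L)
    curve[[roll]] <- data.frame(
      step = steps_done, episodes = length(ep_rewards),
      mean_reward = if (length(recent)) mean(recent) else NA_real_)
  }

  params$ctx <- ctx
  pol <- trained_policy(params, deterministic = FALSE)
  pol$curve <- do.call(rbind, curve)
  pol
}

#' Save / load a trained policy
#'
#' Checkpoints are plain JSON holding the parameter matrices.
#'
#' @param policy A trained `policy` (with `$params`).
#' @param path File path.
#' @return `write_policy` returns `path` invisibly; `read_policy` returns a
#'   `policy`.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "policy"), !is.null(policy$params))
  p <- policy$params
  jsonlite::write_json(
    list(hidden_size = length(p$bh),
         Wxh = p$Wxh, Whh = p$Whh, bh = p$bh,
         Wp = p$Wp, bp = p$bp, Wv = p$Wv, bv = p$bv,
         ctx = p$ctx),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_policy
#' @param deterministic Passed to [trained_policy()].
#' @export
read_policy <- function(path, deterministic = FALSE) {
  raw <- jsonlite::fromJSON(path)
  params <- list(Wxh = unname(raw$Wxh),
                 Whh = unname(raw$Whh),
                 bh = as.numeric(raw$bh),
                 Wp = unname(raw$Wp),
                 bp = as.numeric(raw$bp),
                 Wv = as.numeric(raw$Wv),
                 bv = as.numeric(raw$bv),
                 ctx = list(qmax = as.numeric(raw$ctx$qmax),
                            lmax = as.numeric(raw$ctx$lmax),
                            theta = lapply(raw$ctx$theta, as.numeric),
                            tau = as.numeric(raw$ctx$tau)))
  trained_policy(params, deterministic = deterministic)
}
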