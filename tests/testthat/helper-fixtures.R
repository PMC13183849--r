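# Shared fixtures and independent oracles used across the suite.

INS <- load_instruments()

# A fixed, hand-specified threshold table for scripted environment tests:
# theta grows linearly towards the final cutoff, which keeps low-severity
# scripted scores below threshold and high-severity ones above it.
fixed_thresholds <- function() {
  per_q <- lapply(INS, function(ins)
    ins$diagnostic_cutoff * seq_len(ins$item_count) / ins$item_count)
  threshold_table(per_q, lapply(INS, `[[`, "diagnostic_cutoff"), INS)
}

# Independent brute-force Youden-threshold oracle: enumerate every midpoint
# cutpoint directly from sorted distinct scores, compute sensitivity and
# specificity by counting, return the smallest maximizer of J.
brute_force_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  if (length(s) < 2L) stop("no finite cutpoint")
  cand <- (s[-length(s)] + s[-1L]) / 2
  j <- vapply(cand, function(th) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    sens + spec - 1
  }, 0)
  if (max(j) < 0) stop("sentinel-maximized")
  cand[which(j == max(j))[1L]]
}

# Streaming (one-pass Welford) re-computation of the episode summary.
streaming_summary <- function(rewards, lengths) {
  n <- 0; mr <- 0; m2r <- 0; ml <- 0; m2l <- 0
  mn <- Inf; mx <- -Inf
  for (i in seq_along(rewards)) {
    n <- n + 1
    dr <- rewards[i] - mr; mr <- mr + dr / n; m2r <- m2r + dr * (rewards[i] - mr)
    dl <- lengths[i] - ml; ml <- ml + dl / n; m2l <- m2l + dl * (lengths[i] - ml)
    mn <- min(mn, rewards[i]); mx <- max(mx, rewards[i])
  }
  list(n_episodes = n, mean_reward = mr, sd_reward = sqrt(m2r / n),
       min_reward = mn, max_reward = mx,
       mean_length = ml, sd_length = sqrt(m2l / n))
}

# From-scratch type-7 quantile (linear interpolation between order stats).
quantile_interp <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Small generator configuration for fast cohort-based tests.
small_gen_config <- function(seed = 101, n = 300, ...)
  default_generator_config(seed = seed, n = n)
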