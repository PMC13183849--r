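tab <- fixed_thresholds()

test_that("reset yields a zeroed session and an all-zero observation", {
  env <- screening_env(constant_respondent(0, 0, 0, INS), tab, INS)
  obs <- env$reset()
  expect_equal(unname(obs), c(0, 0, 0, 0))
  st <- env$state()
  expect_equal(unname(st$q), c(0L, 0L, 0L))
  expect_equal(unname(st$S), c(0, 0, 0))
  expect_false(any(st$predicted))
  expect_false(env$done())
})

test_that("each printed reward case fires in its scripted state", {
  # valid ask while items remain: -1
  env <- screening_env(constant_respondent(90, 5, 5, INS), tab, INS)
  env$reset()
  expect_equal(env$step(0)$reward, -1)
  # exhaust anxiety at high severity, then commit: +10
  for (i in 2:7) env$step(0)
  st <- env$state()
  expect_equal(st$q[["anxiety"]], 7L)
  expect_gte(st$S[["anxiety"]], tab$final$anxiety)
  out <- env$step(0)
  expect_equal(out$reward, 10)
  expect_true(env$state()$predicted[["anxiety"]])
  expect_equal(out$info$committed, "anxiety")
  # ask again after the decision is taken: -5
  expect_equal(env$step(0)$reward, -5)
  # stop with depression/stress unasked: -5, episode continues
  expect_equal(env$step(3)$reward, -5)
  expect_false(env$done())
  # one low-scoring ask each, then a valid stop: +20 and termination
  env$step(1); env$step(2)
  out <- env$step(3)
  expect_equal(out$reward, 20)
  expect_true(out$done)
  expect_equal(unname(out$info$diagnosis), c(TRUE, FALSE, FALSE))
})

test_that("stopping against a score above the current threshold is refused", {
  # stress score 100 -> S = 4 after one item, above theta_1 = 2.7
  env <- screening_env(constant_respondent(0, 0, 100, INS), tab, INS)
  env$reset()
  env$step(0); env$step(1); env$step(2)
  expect_gt(env$state()$S[["stress"]], tab$per_question$stress[1])
  out <- env$step(3)
  expect_equal(out$reward, -5)
  expect_false(out$done)
})

test_that("immediate stop on a fresh session is penalized", {
  env <- screening_env(constant_respondent(0, 0, 0, INS), tab, INS)
  env$reset()
  out <- env$step(3)
  expect_equal(out$reward, -5)
  expect_false(out$done)
})

test_that("stop predicate requires one ask per disorder and clearance or exhaustion", {
  mk <- function(q, S, predicted = c(FALSE, FALSE, FALSE)) {
    s <- list(q = stats::setNames(as.integer(q), names(INS)),
              S = stats::setNames(as.numeric(S), names(INS)),
              predicted = stats::setNames(predicted, names(INS)))
    s
  }
  expect_true(stop_ok(mk(c(1, 1, 1), c(0, 0, 0)), tab, INS))
  expect_false(stop_ok(mk(c(0, 1, 1), c(0, 0, 0)), tab, INS))
  # exhausted instrument is resolved regardless of score
  expect_true(stop_ok(mk(c(7, 1, 1), c(21, 0, 0)), tab, INS))
  # score above current threshold blocks stopping
  expect_false(stop_ok(mk(c(1, 1, 1), c(3, 0, 0)), tab, INS))
})

test_that("scripted rollouts accumulate the printed per-step rewards", {
  # 7 high anxiety asks (-7), commit (+10), 1 depression (-1), 1 stress (-1),
  # valid stop (+20): total 21
  env <- screening_env(constant_respondent(90, 5, 5, INS), tab, INS)
  env$reset()
  r <- c(vapply(1:7, function(i) env$step(0)$reward, 0),
         env$step(0)$reward, env$step(1)$reward, env$step(2)$reward,
         env$step(3)$reward)
  expect_equal(sum(r), 21)
  expect_equal(r, c(rep(-1, 7), 10, -1, -1, 20))
  # all-low path: 3 asks then a valid stop: total 17
  env2 <- screening_env(constant_respondent(0, 0, 0, INS), tab, INS)
  env2$reset()
  r2 <- c(env2$step(0)$reward, env2$step(1)$reward, env2$step(2)$reward,
          env2$step(3)$reward)
  expect_equal(sum(r2), 17)
})

test_that("episodes truncate at the safety cap without a terminal bonus", {
  env <- screening_env(constant_respondent(0, 0, 100, INS), tab, INS,
                       max_steps = 12L)
  env$reset()
  rewards <- numeric(0)
  repeat {
    out <- env$step(2)   # stress stays above threshold; never stop
    rewards <- c(rewards, out$reward)
    if (out$done) break
  }
  expect_length(rewards, 12)
  expect_true(env$state()$truncated)
  expect_false(20 %in% rewards)
  expect_error(env$step(0), "done")
})

test_that("invalid actions and mis-configured environments are rejected", {
  env <- screening_env(constant_respondent(0, 0, 0, INS), tab, INS)
  env$reset()
  expect_error(env$step(4), "0, 1, 2, 3")
  expect_error(env$step(-1), "0, 1, 2, 3")
  partial <- tab
  partial$per_question$stress <- NULL
  expect_error(screening_env(constant_respondent(0, 0, 0, INS), partial, INS),
               "cover")
  expect_error(screening_env(constant_respondent(0, 0, 0, INS), tab, INS,
                             enforce_full = "mood"), "disorders")
})

test_that("enforce_full masks stop until the named instrument is exhausted", {
  env <- screening_env(constant_respondent(0, 0, 0, INS), tab, INS,
                       enforce_full = "anxiety")
  env$reset()
  env$step(0); env$step(1); env$step(2)
  expect_equal(env$step(3)$reward, -5)    # anxiety not exhausted yet
  for (i in 2:7) env$step(0)
  expect_equal(env$step(3)$reward, 20)
})

test_that("exactly one reward case fires for fuzzed states and rewards stay bounded", {
  set.seed(1234)
  qmax <- vapply(INS, `[[`, 0L, "item_count")
  for (i in 1:1000) {
    q <- vapply(qmax, function(m) sample(0:m, 1), 0L)
    S <- stats::setNames(runif(3, 0, q * vapply(INS, `[[`, 0L, "likert_max")),
                         names(INS))
    predicted <- stats::setNames(q == qmax & runif(3) < 0.5, names(INS))
    state <- list(q = q, S = S, predicted = predicted)
    for (a in 0:3) {
      rc <- reward_case(state, a, tab, INS)
      expect_true(rc$reward %in% c(-5, -1, 10, 20))
      # the case label must match an independent recomputation of the rules
      d <- if (a < 3) names(INS)[a + 1] else NA
      expected_case <- if (a == 3) {
        if (all(q >= 1 & (q >= qmax | S <= vapply(names(INS), function(n)
          tab$per_question[[n]][max(q[[n]], 1)], 0)))) "stop_valid" else "stop_invalid"
      } else if (q[[d]] < qmax[[d]]) "ask"
        else if (!predicted[[d]] && S[[d]] >= tab$final[[d]]) "commit"
        else "already_decided"
      expect_equal(rc$case, expected_case)
    }
  }
})

test_that("final diagnosis agrees with commits plus the termination rule", {
  set.seed(99)
  cfg <- small_gen_config(seed = 77, n = 40)
  profiles <- sample_profiles(cfg, INS, n = 40)
  for (p in profiles[1:25]) {
    env <- screening_env(make_respondent(p, cfg, INS), tab, INS)
    env$reset()
    commits <- character(0)
    repeat {
      out <- env$step(sample(0:3, 1))
      if (!is.null(out$info$committed))
        commits <- c(commits, out$info$committed)
      if (out$done) break
    }
    st <- env$state()
    diag <- final_diagnosis(st, tab, INS)
    for (d in names(INS)) {
      by_rule <- d %in% commits ||
        (st$q[[d]] >= INS[[d]]$item_count && st$S[[d]] >= tab$final[[d]])
      expect_equal(unname(diag[[d]]), by_rule)
    }
  }
})

test_that("asking more questions never invalidates a previously valid stop", {
  # for a disorder whose score stays below its (monotone) threshold sequence,
  # stop_ok cannot flip from TRUE to FALSE as questions accumulate
  set.seed(5)
  for (rep in 1:20) {
    sev <- runif(3, 0, 20)
    env <- screening_env(constant_respondent(sev[1], sev[2], sev[3], INS),
                         tab, INS)
    env$reset()
    ok_seen <- FALSE
    for (step in 1:26) {
      open <- which(env$state()$q < vapply(INS, `[[`, 0L, "item_count"))
      if (!length(open)) break
      env$step(sample(open, 1) - 1L)
      ok <- stop_ok(env$state(), tab, INS)
      if (ok_seen && all(env$state()$S <= vapply(names(INS), function(n)
        tab$per_question[[n]][max(env$state()$q[[n]], 1)], 0)))
        expect_true(ok)
      ok_seen <- ok_seen || ok
    }
  }
})

test_that("episodes are reproducible given a deterministic respondent", {
  cfg <- small_gen_config(seed = 31, n = 2)
  prof <- sample_profiles(cfg, INS, n = 1)[[1]]
  replay <- function() {
    env <- screening_env(make_respondent(prof, cfg, INS), tab, INS)
    env$reset()
    acts <- c(0, 1, 2, 0, 0, 3, 1, 1, 3)
    out <- list()
    for (a in acts) {
      out[[length(out) + 1L]] <- env$step(a)[c("reward", "observation")]
      if (env$done()) break
    }
    out
  }
  expect_identical(replay(), replay())
})
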