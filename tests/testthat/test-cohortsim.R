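test_that("generator configuration validates its parameter ranges", {
  expect_s3_class(default_generator_config(), "generator_config")
  expect_error(generator_config(n = 0), "positive")
  expect_error(generator_config(prevalence = c(anxiety = 0, depression = .3,
                                               stress = .3)), "prevalence")
  expect_error(generator_config(loading_range = c(0.4, 1)), "loading_range")
  expect_error(generator_config(sigma_obs = -1), "sigma_obs")
  expect_error(generator_config(jitter_prob = 2), "jitter_prob")
})

test_that("cohorts are deterministic, schema-complete and label-consistent", {
  cfg <- small_gen_config(seed = 8, n = 150)
  a <- generate_cohort(cfg, INS)
  b <- generate_cohort(cfg, INS)
  expect_identical(a, b)
  cols <- unlist(lapply(INS, function(i) paste0(i$name, "_q", 1:i$item_count)))
  expect_true(all(c(cols, paste0(names(INS), "_label")) %in% names(a)))
  expect_equal(ncol(a), 26 + 3)
  # labels re-derivable from raw items through the instruments' own scoring
  for (d in names(INS)) {
    ins <- INS[[d]]
    totals <- apply(a[paste0(d, "_q", 1:ins$item_count)], 1, function(r)
      total_score(ins, as.integer(r)))
    expect_equal(a[[paste0(d, "_label")]], as.integer(is_positive(ins, totals)))
  }
  # truth attribute view matches the labels
  tru <- profile_truth(attr(a, "profiles"), INS)
  for (d in names(INS))
    expect_equal(as.integer(tru[[d]]), a[[paste0(d, "_label")]])
})

test_that("ordinal items follow the severity-loading-jitter construction", {
  cfg <- default_generator_config(n = 60, jitter_prob = 0, seed = 12)
  cohort <- generate_cohort(cfg, INS)
  profiles <- attr(cohort, "profiles")
  for (d in names(INS)) {
    ins <- INS[[d]]
    load <- seq(cfg$loading_range[1], cfg$loading_range[2],
                length.out = ins$item_count)
    for (i in seq_along(profiles)) {
      expected <- pmin(pmax(round(profiles[[i]]$severity[[d]] * load *
                                    ins$likert_max), 0), ins$likert_max)
      expect_equal(profiles[[i]]$items[[d]], as.integer(expected))
    }
  }
})

test_that("positive-label fractions match a Monte-Carlo reference", {
  cfg <- default_generator_config(n = 2000, seed = 3)
  cohort <- generate_cohort(cfg, INS)
  # 10x replicated reference estimate of the implied label rate
  ref_cfg <- cfg
  ref_cfg$n <- 20000L
  ref_cfg$seed <- 977L
  ref <- generate_cohort(ref_cfg, INS)
  for (d in names(INS)) {
    p_hat <- mean(cohort[[paste0(d, "_label")]])
    p_ref <- mean(ref[[paste0(d, "_label")]])
    se <- sqrt(p_ref * (1 - p_ref) / cfg$n)
    expect_lt(abs(p_hat - p_ref), 3 * se + 3 * sqrt(p_ref * (1 - p_ref) / ref_cfg$n))
  }
})

test_that("respondents answer deterministically within the instrument range", {
  cfg <- small_gen_config(seed = 14, n = 3)
  prof <- sample_profiles(cfg, INS, n = 1)[[1]]
  resp <- make_respondent(prof, cfg, INS)
  v1 <- resp$answer("anxiety", 3)
  v2 <- resp$answer("anxiety", 3)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 100))
  expect_equal(v1[["normal"]],
               100 - max(v1[c("anxiety", "depression", "stress")]))
  expect_error(resp$answer("anxiety", 8), "beyond")
  expect_error(resp$answer("stress", 11), "beyond")
})

test_that("noiseless respondents sit exactly on their ordinal item scores", {
  cfg <- default_generator_config(sigma_obs = 0, jitter_prob = 0, seed = 5)
  # hand-built saturated profile: severity 1 realizes every item at the max
  sat <- structure(list(
    present = c(anxiety = TRUE, depression = TRUE, stress = TRUE),
    severity = c(anxiety = 1, depression = 1, stress = 1),
    items = lapply(INS, function(i) rep(i$likert_max, i$item_count)),
    seed = 1L), class = "latent_profile")
  names(sat$items) <- names(INS)
  resp <- make_respondent(sat, cfg, INS)
  expect_equal(resp$answer("anxiety", 1)[["anxiety"]], 100)
  expect_equal(resp$answer("stress", 10)[["stress"]], 100)
  # healthy profile: zero severities, zero items
  healthy <- sat
  healthy$present[] <- FALSE
  healthy$severity[] <- 0
  healthy$items <- lapply(INS, function(i) rep(0L, i$item_count))
  names(healthy$items) <- names(INS)
  resp0 <- make_respondent(healthy, cfg, INS)
  expect_equal(unname(resp0$answer("depression", 4)),
               c(0, 0, 0, 100))
})

test_that("respondent fixtures serialize to JSON", {
  cfg <- small_gen_config(seed = 2, n = 4)
  profiles <- sample_profiles(cfg, INS, n = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_profiles(profiles, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(back, 4)
  expect_equal(back[[1]]$seed, profiles[[1]]$seed)
  expect_equal(unlist(back[[2]]$items$anxiety),
               as.numeric(profiles[[2]]$items$anxiety))
})
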