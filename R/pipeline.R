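#' Pipeline commands
#'
#' High-level stages tying the modules together: generate a synthetic cohort,
#' derive ROC thresholds from it, train the recurrent policy against
#' simulated respondents, evaluate policies, and replay a scripted session.
#' Each stage takes a single global seed, fans it out through [derive_seed()]
#' (stage indices: 1 generate, 2 thresholds, 3 train, 4 eval, 5 session), and
#' writes a manifest next to its outputs. A thin command-line front-end over
#' these functions ships at `system.file("cli", "adaptscreen.R", package =
#' "adaptscreen")`.
#'
#' @name pipeline
NULL

write_manifest <- function(out_dir, stage, seed, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, seed = seed,
           package_version = as.character(utils::packageVersion("adaptscreen")),
           r_version = as.character(getRversion())),
      extra),
    file.path(out_dir, paste0(stage, "-manifest.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Generate a cohort CSV (and respondent fixtures)
#'
#' @param out_dir Output directory (created if needed).
#' @param config A `generator_config`; its seed is overridden by the stage
#'   seed derived from `seed`.
#' @param seed Global seed.
#' @param instruments Instrument list.
#' @return Path of the written cohort CSV, invisibly.
#' @export
run_generate <- function(out_dir, config = default_generator_config(),
                         seed = 1L, instruments = load_instruments()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- derive_seed(seed, 1L)
  cohort <- generate_cohort(config, instruments)
  path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, path, row.names = FALSE)
  write_profiles(attr(cohort, "profiles"),
                 file.path(out_dir, "respondents.json"))
  write_manifest(out_dir, "generate", seed,
                 list(n = config$n, generator_seed = config$seed))
  invisible(path)
}

#' Derive thresholds from a cohort CSV
#'
#' @param cohort_path Path to a cohort CSV in the thresholds-module schema.
#' @param out_dir Output directory.
#' @param seed Global seed (recorded in the manifest; the derivation itself
#'   is deterministic).
#' @param instruments Instrument list.
#' @return The `threshold_table`, invisibly; writes `thresholds.json`.
#' @export
run_thresholds <- function(cohort_path, out_dir, seed = 1L,
                           instruments = load_instruments()) {
  if (!file.exists(cohort_path))
    stop("cohort file not found: ", cohort_path, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- utils::read.csv(cohort_path)
  tab <- derive_thresholds(cohort, instruments)
  write_thresholds(tab, file.path(out_dir, "thresholds.json"))
  write_manifest(out_dir, "thresholds", seed, list(cohort = cohort_path))
  invisible(tab)
}

#' Environment factory over the synthetic respondent population
#'
#' @param config A `generator_config` (its `seed` controls respondent draws:
#'   episode `i` uses `derive_seed(config$seed, i)`).
#' @param thresholds A `threshold_table`.
#' @param instruments Instrument list.
#' @param max_steps Episode safety cap.
#' @return Function `(episode_index) -> screening_env`.
#' @export
respondent_env_factory <- function(config, thresholds,
                                   instruments = load_instruments(),
                                   max_steps = 60L) {
  function(i) {
    prof <- with_seed(derive_seed(config$seed, i),
                      draw_profile(config, instruments,
                                   derive_seed(config$seed, i)))
    screening_env(make_respondent(prof, config, instruments), thresholds,
                  instruments, max_steps = max_steps)
  }
}

#' Train the recurrent policy end-to-end
#'
#' @param thresholds A `threshold_table`.
#' @param out_dir Output directory for the checkpoint and training curve.
#' @param config `train_config`.
#' @param gen_config `generator_config` for the training respondents.
#' @param seed Global seed.
#' @param instruments Instrument list.
#' @return The trained `policy`, invisibly; writes `policy.json` and
#'   `training-curve.csv`.
#' @export
run_train <- function(thresholds, out_dir, config = train_config(),
                      gen_config = default_generator_config(), seed = 1L,
                      instruments = load_instruments()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- derive_seed(seed, 3L)
  gen_config$seed <- derive_seed(seed, 31L)
  make_env <- respondent_env_factory(gen_config, thresholds, instruments)
  pol <- train_policy(make_env, config)
  write_policy(pol, file.path(out_dir, "policy.json"))
  utils::write.csv(pol$curve, file.path(out_dir, "training-curve.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "train", seed,
                 list(total_steps = config$total_steps,
                      train_seed = config$seed))
  invisible(pol)
}

#' Evaluate a policy and write summaries
#'
#' @param policy A `policy`.
#' @param thresholds A `threshold_table`.
#' @param out_dir Output directory.
#' @param gen_config Generator configuration of the evaluation population.
#' @param n_episodes Number of evaluation episodes.
#' @param seed Global seed.
#' @param instruments Instrument list.
#' @return List with `records`, `summary`, `comparison` (invisibly); writes
#'   `summary.json`, `comparison.csv` and `episodes.csv`.
#' @export
run_eval <- function(policy, thresholds, out_dir,
                     gen_config = default_generator_config(),
                     n_episodes = 200L, seed = 1L,
                     instruments = load_instruments()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- evaluate_policy(policy, thresholds, gen_config,
                             n_episodes = n_episodes,
                             seed = derive_seed(seed, 4L),
                             instruments = instruments)
  summ <- summarize_episodes(records)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  # static reference: full questionnaires of the same respondents
  eval_cfg <- gen_config
  eval_cfg$seed <- derive_seed(derive_seed(seed, 4L), 1L)
  eval_cfg$n <- as.integer(n_episodes)
  cohort <- generate_cohort(eval_cfg, instruments)
  comparison <- compare_with_static(
    stats::setNames(records[paste0(DISORDERS, "_pred")],
                    paste0(DISORDERS, "_pred")),
    cohort, instruments)
  utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(records, file.path(out_dir, "episodes.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "eval", seed,
                 list(n_episodes = n_episodes, policy = policy$name))
  invisible(list(records = records, summary = summ, comparison = comparison))
}

#' Replay a scripted session
#'
#' Runs one assessment with replies drawn from a script: every turn the
#' policy picks an action; if it asks, the next scripted reply is scored by
#' `scorer` and fed to the environment through a scripted respondent. The
#' transcript (one row per turn: question asked, reply, score vector, action,
#' reward) and the final diagnosis are returned.
#'
#' @param replies Character vector of scripted user replies (recycled if the
#'   session asks more questions than replies are provided).
#' @param policy A `policy`.
#' @param thresholds A `threshold_table`.
#' @param scorer A scorer function (default [keyword_scorer()]).
#' @param seed Seed for any policy action sampling.
#' @param instruments Instrument list.
#' @param max_steps Episode safety cap.
#' @return List with `transcript` (data frame) and `diagnosis`.
#' @export
run_session <- function(replies, policy, thresholds,
                        scorer = keyword_scorer(), seed = 1L,
                        instruments = load_instruments(), max_steps = 60L) {
  replies <- replies[nzchar(trimws(replies))]
  if (!length(replies)) stop("no non-empty replies supplied", call. = FALSE)
  k <- 0L
  answer <- function(disorder, item_index) {
    k <<- k + 1L
    reply <- replies[[(k - 1L) %% length(replies) + 1L]]
    sv <- scorer(reply)
    c(anxiety = sv[["anxiety"]], depression = sv[["depression"]],
      stress = sv[["stress"]], normal = sv[["normal"]])
  }
  respondent <- structure(list(answer = answer, profile = NULL,
                               truth = c(anxiety = NA, depression = NA,
                                         stress = NA)),
                          class = "respondent")
  env <- screening_env(respondent, thresholds, instruments,
                       max_steps = max_steps)
  rec <- with_seed(derive_seed(seed, 5L),
                   run_episode(env, policy, log_steps = TRUE))
  list(transcript = rec$steps,
       diagnosis = final_diagnosis(env$state(), thresholds, instruments),
       reward = rec$reward, length = rec$length)
}
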