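#' Synthetic cohort and respondent simulation
#'
#' The simulator plays two roles: it produces the labelled item-score cohort
#' from which ROC thresholds are derived, and it backs live respondents for
#' environment rollouts. Each respondent carries a latent profile -- presence
#' indicators and a severity in \[0, 1\] per disorder -- from which ordinal
#' Likert item responses are realized as
#' `clip(round(severity * loading_i * likert_max + jitter), 0, likert_max)`.
#' Disorder labels are `is_positive(total)` applied to the realized totals, so
#' the cohort's ground truth is exactly what the full static questionnaire
#' would conclude. A live respondent answers question i of instrument X with a
#' severity score `100 * v_i / likert_max + Normal(0, sigma_obs)` (clipped to
#' \[0, 100\]), where `v_i` is the same realized scored item value: the text
#' channel and the questionnaire channel describe one and the same respondent,
#' up to observation noise. The latent profile is constant within an episode.
#'
#' @name cohortsim
NULL

#' Generator configuration
#'
#' @param n Cohort size.
#' @param prevalence Named probabilities of disorder presence.
#' @param severity_present Beta shape parameters for severities of present
#'   disorders; severities are drawn on `[0.5, 1]`.
#' @param severity_absent Beta shape parameters for baseline severities of
#'   absent disorders, drawn on `[0, 0.3]`.
#' @param loading_range Per-item discrimination loadings are evenly spaced
#'   over this range (within `[0.6, 1]`) across each instrument's items.
#' @param sigma_obs Observation-noise standard deviation on the 0--100
#'   severity scale.
#' @param jitter_prob Probability that an ordinal item response is jittered by
#'   one Likert step (split evenly between -1 and +1).
#' @param cross_attenuation Attenuation applied to the off-instrument severity
#'   components of a live observation.
#' @param seed Integer seed; every draw in the generator flows from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 2000L,
                             prevalence = c(anxiety = 0.35, depression = 0.35,
                                            stress = 0.25),
                             severity_present = c(shape1 = 4, shape2 = 2),
                             severity_absent = c(shape1 = 2, shape2 = 5),
                             loading_range = c(0.7, 1.0),
                             sigma_obs = 4,
                             jitter_prob = 0.05,
                             cross_attenuation = 0.6,
                             seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (!all(DISORDERS %in% names(prevalence)) ||
      any(prevalence <= 0) || any(prevalence >= 1))
    stop("prevalence must name all disorders with values in (0, 1)", call. = FALSE)
  if (any(severity_present <= 0) || any(severity_absent <= 0))
    stop("Beta shape parameters must be positive", call. = FALSE)
  if (length(loading_range) != 2L || loading_range[1] > loading_range[2] ||
      loading_range[1] < 0.6 || loading_range[2] > 1)
    stop("loading_range must be within [0.6, 1]", call. = FALSE)
  if (sigma_obs < 0) stop("sigma_obs must be >= 0", call. = FALSE)
  if (jitter_prob < 0 || jitter_prob > 1)
    stop("jitter_prob must be in [0, 1]", call. = FALSE)
  structure(list(n = n, prevalence = prevalence[DISORDERS],
                 severity_present = severity_present,
                 severity_absent = severity_absent,
                 loading_range = loading_range,
                 sigma_obs = sigma_obs, jitter_prob = jitter_prob,
                 cross_attenuation = cross_attenuation,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Load the packaged default generator parameters
#'
#' @param path Path to a generator-parameter JSON file; defaults to the
#'   versioned fixture shipped with the package.
#' @param ... Named overrides of any [generator_config()] argument (e.g.
#'   `seed`, `n`, `sigma_obs`, `jitter_prob`).
#' @return A `generator_config`.
#' @export
default_generator_config <- function(path = system.file("extdata",
                                                        "generator-defaults.json",
                                                        package = "adaptscreen"),
                                     ...) {
  raw <- jsonlite::fromJSON(path)
  args <- list(n = raw$n,
               prevalence = unlist(raw$prevalence),
               severity_present = unlist(raw$severity_present),
               severity_absent = unlist(raw$severity_absent),
               loading_range = raw$loading_range,
               sigma_obs = raw$sigma_obs,
               jitter_prob = raw$jitter_prob,
               cross_attenuation = raw$cross_attenuation,
               seed = raw$seed)
  over <- list(...)
  over <- over[!vapply(over, is.null, NA)]
  args[names(over)] <- over
  do.call(generator_config, args)
}

item_loadings <- function(config, instrument) {
  if (instrument$item_count == 1L) return(mean(config$loading_range))
  seq(config$loading_range[1], config$loading_range[2],
      length.out = instrument$item_count)
}

# Draw one latent profile plus realized scored item values (RNG state is the
# caller's responsibility).
draw_profile <- function(config, instruments, respondent_seed) {
  present <- stats::runif(3L) < config$prevalence
  names(present) <- DISORDERS
  sev <- numeric(3L)
  names(sev) <- DISORDERS
  for (d in DISORDERS) {
    sev[d] <- if (present[d])
      0.5 + 0.5 * stats::rbeta(1L, config$severity_present[["shape1"]],
                               config$severity_present[["shape2"]])
    else
      0.3 * stats::rbeta(1L, config$severity_absent[["shape1"]],
                         config$severity_absent[["shape2"]])
  }
  items <- list()
  for (d in DISORDERS) {
    ins <- instruments[[d]]
    load <- item_loadings(config, ins)
    jitter <- sample(c(-1L, 0L, 1L), ins$item_count, replace = TRUE,
                     prob = c(config$jitter_prob / 2, 1 - config$jitter_prob,
                              config$jitter_prob / 2))
    items[[d]] <- as.integer(clip(round(sev[d] * load * ins$likert_max) + jitter,
                                  0L, ins$likert_max))
  }
  structure(list(present = present, severity = sev, items = items,
                 seed = respondent_seed),
            class = "latent_profile")
}

#' Sample latent respondent profiles
#'
#' @param config A `generator_config`.
#' @param instruments Instrument list.
#' @param n Number of profiles (defaults to `config$n`).
#' @return List of `latent_profile` objects.
#' @export
sample_profiles <- function(config, instruments = load_instruments(),
                            n = config$n) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("cohort size n must be a positive integer", call. = FALSE)
  with_seed(config$seed, lapply(seq_len(n), function(i)
    draw_profile(config, instruments, derive_seed(config$seed, i))))
}

#' Generate a labelled synthetic cohort
#'
#' One row per respondent with columns `<disorder>_q<i>` holding *raw* Likert
#' responses (reverse-worded PSS-10 items are stored un-reversed, so that
#' [total_score()] applies the same reverse-scoring a paper questionnaire
#' would) and `<disorder>_label` holding `is_positive(total)`. The sampled
#' profiles are attached as the `"profiles"` attribute for respondent
#' construction.
#'
#' @param config A `generator_config`.
#' @param instruments Instrument list.
#' @return Data frame in the thresholds-module cohort schema.
#' @export
generate_cohort <- function(config, instruments = load_instruments()) {
  profiles <- sample_profiles(config, instruments)
  cols <- list()
  for (d in DISORDERS) {
    ins <- instruments[[d]]
    scored <- do.call(rbind, lapply(profiles, function(p) p$items[[d]]))
    raw <- scored
    if (length(ins$reverse_items))
      raw[, ins$reverse_items] <- ins$likert_max - raw[, ins$reverse_items]
    for (i in seq_len(ins$item_count))
      cols[[paste0(d, "_q", i)]] <- as.integer(raw[, i])
  }
  for (d in DISORDERS) {
    ins <- instruments[[d]]
    totals <- vapply(profiles, function(p) sum(p$items[[d]]), 0)
    cols[[paste0(d, "_label")]] <- as.integer(is_positive(ins, totals))
  }
  out <- as.data.frame(cols)
  attr(out, "profiles") <- profiles
  out
}

#' Ground-truth labels of sampled profiles
#'
#' The full-questionnaire reading of each profile's realized responses:
#' `is_positive(total)` per disorder.
#'
#' @param profiles List of `latent_profile` objects.
#' @param instruments Instrument list.
#' @return Data frame with one logical column per disorder.
#' @export
profile_truth <- function(profiles, instruments = load_instruments()) {
  out <- lapply(DISORDERS, function(d)
    vapply(profiles, function(p)
      is_positive(instruments[[d]], sum(p$items[[d]])), NA))
  names(out) <- DISORDERS
  as.data.frame(out)
}

#' Build a live respondent from a latent profile
#'
#' The respondent answers question `i` of instrument `X` with a severity
#' vector whose `X` component is `clip(100 * v_i / likert_max + e_i, 0, 100)`
#' (`v_i` the profile's realized scored item value, `e_i` Gaussian observation
#' noise drawn once per item at construction from the profile seed), whose
#' off-instrument components are the attenuated severities of the other
#' disorders plus the same kind of noise, and whose `normal` component is
#' `100 - max` of the three. Repeated calls with the same arguments return
#' identical vectors.
#'
#' @param profile A `latent_profile`.
#' @param config The `generator_config` (for `sigma_obs` and attenuation).
#' @param instruments Instrument list.
#' @return An object of class `respondent`: list with `answer(disorder,
#'   item_index)`, the `profile`, and the truth labels.
#' @export
make_respondent <- function(profile, config, instruments = load_instruments()) {
  noise <- with_seed(profile$seed, {
    lapply(instruments, function(ins)
      matrix(stats::rnorm(4L * ins$item_count, 0, config$sigma_obs),
             nrow = 4L, ncol = ins$item_count,
             dimnames = list(c(DISORDERS, "normal"), NULL)))
  })
  truth <- vapply(DISORDERS, function(d)
    is_positive(instruments[[d]], sum(profile$items[[d]])), NA)
  answer <- function(disorder, item_index) {
    ins <- instruments[[disorder]]
    if (item_index < 1L || item_index > ins$item_count)
      stop("item index ", item_index, " beyond ", disorder, " instrument",
           call. = FALSE)
    comp <- numeric(3L)
    names(comp) <- DISORDERS
    for (d in DISORDERS) {
      base <- if (d == disorder)
        100 * profile$items[[disorder]][item_index] / ins$likert_max
      else
        100 * profile$severity[d] * config$cross_attenuation
      comp[d] <- clip(base + noise[[disorder]][d, item_index], 0, 100)
    }
    c(comp, normal = 100 - max(comp))
  }
  structure(list(answer = answer, profile = profile, truth = truth),
            class = "respondent")
}

#' Scripted respondent with constant severities
#'
#' Answers every question of every instrument with the same three severity
#' components (and `normal = 100 - max`). Used for deterministic reward-case
#' checks and worked examples.
#'
#' @param anxiety,depression,stress Constant severities in `[0, 100]`.
#' @param instruments Instrument list (for item-range validation).
#' @return A `respondent`.
#' @export
constant_respondent <- function(anxiety = 0, depression = 0, stress = 0,
                                instruments = load_instruments()) {
  comp <- c(anxiety = as.numeric(anxiety), depression = as.numeric(depression),
            stress = as.numeric(stress))
  stopifnot(all(comp >= 0), all(comp <= 100))
  answer <- function(disorder, item_index) {
    ins <- instruments[[disorder]]
    if (item_index < 1L || item_index > ins$item_count)
      stop("item index ", item_index, " beyond ", disorder, " instrument",
           call. = FALSE)
    c(comp, normal = 100 - max(comp))
  }
  structure(list(answer = answer, profile = NULL,
                 truth = c(anxiety = NA, depression = NA, stress = NA)),
            class = "respondent")
}

#' Write respondent fixtures as JSON
#'
#' @param profiles List of `latent_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  jsonlite::write_json(lapply(profiles, function(p)
    list(present = as.list(p$present), severity = as.list(p$severity),
         items = p$items, seed = p$seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
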