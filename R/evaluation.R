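#' Evaluation statistics
#'
#' Episode-level summaries (mean/sd/min/max of rewards and lengths, with
#' *population* standard deviations, i.e. divide-by-N), Tukey boxplot
#' statistics with outlier exclusion, reward histograms, descriptive
#' statistics of diagnostic outputs, and confusion-matrix agreement of the
#' adaptive diagnoses against the full static questionnaires.
#'
#' @name evaluation
NULL

#' Summarize episode records
#'
#' @param records Data frame with columns `reward` and `length` (one row per
#'   episode), e.g. from [evaluate_policy()].
#' @return List with `n_episodes`, `mean_reward`, `sd_reward` (population),
#'   `min_reward`, `max_reward`, `mean_length`, `sd_length` (population).
#' @export
summarize_episodes <- function(records) {
  if (!is.data.frame(records) || !nrow(records) ||
      !all(c("reward", "length") %in% names(records)))
    stop("records must be a non-empty data frame with reward and length",
         call. = FALSE)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  r <- records$reward
  len <- records$length
  list(n_episodes = nrow(records),
       mean_reward = mean(r), sd_reward = pop_sd(r),
       min_reward = min(r), max_reward = max(r),
       mean_length = mean(len), sd_length = pop_sd(len))
}

#' Tukey boxplot statistics
#'
#' Quartiles by linear interpolation between order statistics
#' (`quantile(type = 7)`); fences at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`;
#' values beyond the fences are outliers and are excluded from the
#' non-outlier extremes.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence`, `min_excl_outliers`, `max_excl_outliers`,
#'   `mean_excl_outliers`, `outliers`.
#' @export
boxplot_stats <- function(values) {
  if (!length(values) || any(is.na(values)))
    stop("values must be non-empty with no missing entries", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  keep <- values >= lo & values <= hi
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       lower_fence = lo, upper_fence = hi,
       min_excl_outliers = min(values[keep]),
       max_excl_outliers = max(values[keep]),
       mean_excl_outliers = mean(values[keep]),
       outliers = sort(values[!keep]))
}

#' Histogram counts over half-open bins
#'
#' Bins are `[edge, edge + bin_width)` starting at `origin` (default: the
#' bin containing the minimum); the total count is preserved.
#'
#' @param values Numeric vector.
#' @param bin_width Positive bin width.
#' @param origin Left edge of the first bin.
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
reward_histogram <- function(values, bin_width,
                             origin = floor(min(values) / bin_width) * bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (!length(values)) return(data.frame(lower = numeric(0),
                                         upper = numeric(0),
                                         count = integer(0)))
  idx <- floor((values - origin) / bin_width)
  tab <- table(idx)
  lower <- origin + as.numeric(names(tab)) * bin_width
  data.frame(lower = lower, upper = lower + bin_width,
             count = as.integer(tab))
}

metric_or_na <- function(num, den, name, disorder) {
  if (den == 0) {
    warning(name, " undefined for ", disorder, " (zero denominator)",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Compare adaptive diagnoses with the full static questionnaires
#'
#' The static reference for each disorder is `is_positive(total_score)` over
#' the cohort's complete item responses; adaptive predictions are compared to
#' it per disorder through confusion counts and the usual derived metrics.
#' Undefined ratios (zero denominators) are reported as `NA` with a warning,
#' never silently as 0.
#'
#' @param adaptive Data frame with logical/0-1 columns `<disorder>_pred`,
#'   one row per respondent, aligned with `cohort`.
#' @param cohort Cohort item table in the thresholds-module schema.
#' @param instruments Instrument list.
#' @return Data frame, one row per disorder: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `precision`, `recall`, `f1`, `specificity`.
#' @export
compare_with_static <- function(adaptive, cohort,
                                instruments = load_instruments()) {
  if (nrow(adaptive) != nrow(cohort))
    stop("adaptive predictions and cohort have different numbers of respondents",
         call. = FALSE)
  rows <- lapply(intersect(DISORDERS, names(instruments)), function(d) {
    ins <- instruments[[d]]
    cols <- cohort_item_cols(ins)
    if (!all(cols %in% names(cohort)))
      stop("cohort is missing item columns for ", d, call. = FALSE)
    pred_col <- paste0(d, "_pred")
    if (!pred_col %in% names(adaptive))
      stop("adaptive predictions are missing column ", pred_col, call. = FALSE)
    totals <- vapply(seq_len(nrow(cohort)), function(i)
      total_score(ins, as.integer(cohort[i, cols])), 0)
    ref <- is_positive(ins, totals)
    pred <- as.logical(adaptive[[pred_col]])
    tp <- sum(pred & ref); fp <- sum(pred & !ref)
    tn <- sum(!pred & !ref); fn <- sum(!pred & ref)
    precision <- metric_or_na(tp, tp + fp, "precision", d)
    recall <- metric_or_na(tp, tp + fn, "recall", d)
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
      if (!is.na(precision) && !is.na(recall))
        warning("F1 undefined for ", d, " (zero denominator)", call. = FALSE)
      NA_real_
    } else 2 * precision * recall / (precision + recall)
    data.frame(disorder = d, tp = tp, fp = fp, tn = tn, fn = fn,
               accuracy = (tp + tn) / (tp + fp + tn + fn),
               precision = precision, recall = recall, f1 = f1,
               specificity = metric_or_na(tn, tn + fp, "specificity", d))
  })
  do.call(rbind, rows)
}

#' Descriptive statistics of diagnostic outputs
#'
#' Minimum, maximum and median of the final cumulative scores among episodes
#' diagnosed positive for each disorder (the positive-only population;
#' set `positives_only = FALSE` for all episodes). Disorders with no
#' qualifying episodes are reported as absent (`NA`) rather than zero.
#'
#' @param scores Data frame with numeric columns `<disorder>_score` and
#'   logical columns `<disorder>_pred`, one row per episode.
#' @param positives_only Restrict to positively diagnosed episodes (default).
#' @return Data frame with `disorder`, `n`, `min`, `max`, `median`.
#' @export
diagnostic_output_stats <- function(scores, positives_only = TRUE) {
  rows <- lapply(DISORDERS, function(d) {
    s <- scores[[paste0(d, "_score")]]
    if (is.null(s)) stop("missing column ", d, "_score", call. = FALSE)
    if (positives_only) {
      p <- scores[[paste0(d, "_pred")]]
      if (is.null(p)) stop("missing column ", d, "_pred", call. = FALSE)
      s <- s[as.logical(p)]
    }
    if (!length(s))
      return(data.frame(disorder = d, n = 0L, min = NA_real_,
                        max = NA_real_, median = NA_real_))
    data.frame(disorder = d, n = length(s), min = min(s), max = max(s),
               median = stats::median(s))
  })
  do.call(rbind, rows)
}
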