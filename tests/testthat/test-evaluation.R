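test_that("episode summaries use population moments exactly", {
  rec <- data.frame(reward = c(-86, -100, -72), length = c(20, 30, 25))
  s <- summarize_episodes(rec)
  expect_equal(s$mean_reward, -86)
  expect_equal(s$sd_reward, sqrt(mean((rec$reward + 86)^2)))  # divide-by-N
  expect_equal(s$min_reward, -100)
  expect_equal(s$max_reward, -72)
  # degenerate single episode
  s1 <- summarize_episodes(data.frame(reward = 14, length = 27))
  expect_equal(s1$sd_reward, 0)
  expect_equal(s1$min_reward, s1$max_reward)
  expect_error(summarize_episodes(data.frame()), "non-empty")
})

test_that("summaries match an independent streaming re-computation", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(1:400, 1)
    rec <- data.frame(reward = round(rnorm(n, -90, 60)),
                      length = sample(1:60, n, replace = TRUE))
    expect_equal(summarize_episodes(rec),
                 streaming_summary(rec$reward, rec$length))
  }
})

test_that("boxplot statistics follow the Tukey convention", {
  b <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(b$outliers, 100)
  expect_equal(b$max_excl_outliers, 4)
  expect_equal(b$min_excl_outliers, 1)
  # all-equal: zero IQR, nothing flagged
  b2 <- boxplot_stats(rep(7, 10))
  expect_equal(b2$iqr, 0)
  expect_length(b2$outliers, 0)
  # symmetric data: median equals mean
  x <- c(-3, -1, 0, 1, 3)
  expect_equal(boxplot_stats(x)$median, mean(x))
  expect_error(boxplot_stats(numeric(0)), "non-empty")
})

test_that("boxplot quartiles match a from-scratch interpolation oracle", {
  set.seed(77)
  for (i in 1:40) {
    x <- rnorm(sample(5:200, 1), sample(-100:0, 1), sample(1:50, 1))
    b <- boxplot_stats(x)
    q1 <- quantile_interp(x, 0.25)
    q3 <- quantile_interp(x, 0.75)
    expect_equal(b$q1, q1)
    expect_equal(b$q3, q3)
    expect_equal(b$median, quantile_interp(x, 0.5))
    expect_equal(b$lower_fence, q1 - 1.5 * (q3 - q1))
    keep <- x >= b$lower_fence & x <= b$upper_fence
    expect_equal(b$min_excl_outliers, min(x[keep]))
    expect_equal(b$max_excl_outliers, max(x[keep]))
    expect_setequal(b$outliers, x[!keep])
  }
})

test_that("reward histograms conserve counts and match per-value binning", {
  set.seed(11)
  x <- round(rnorm(200, -80, 50))
  h <- reward_histogram(x, bin_width = 25)
  expect_equal(sum(h$count), 200)
  # brute-force per-value oracle
  for (r in seq_len(nrow(h)))
    expect_equal(h$count[r], sum(x >= h$lower[r] & x < h$upper[r]))
  h1 <- reward_histogram(5, bin_width = 10)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 1L)
  expect_error(reward_histogram(x, bin_width = 0), "positive")
})

test_that("static-baseline comparison computes confusion metrics correctly", {
  cfg <- small_gen_config(seed = 50, n = 120)
  cohort <- generate_cohort(cfg, INS)
  # perfect agreement: predictions copied from the reference labels
  preds <- data.frame(anxiety_pred = cohort$anxiety_label == 1,
                      depression_pred = cohort$depression_label == 1,
                      stress_pred = cohort$stress_label == 1)
  cmp <- compare_with_static(preds, cohort, INS)
  expect_equal(cmp$accuracy, rep(1, 3))
  expect_equal(cmp$precision, rep(1, 3))
  expect_equal(cmp$recall, rep(1, 3))
  expect_equal(cmp$f1, rep(1, 3))
  expect_equal(cmp$specificity, rep(1, 3))
  # metrics recomputed from the stored counts match exactly
  flip <- preds
  flip$anxiety_pred[1:10] <- !flip$anxiety_pred[1:10]
  cmp2 <- compare_with_static(flip, cohort, INS)
  for (r in 1:3) {
    with(cmp2[r, ], {
      expect_equal(accuracy, (tp + tn) / (tp + fp + tn + fn))
      if (!is.na(precision)) expect_equal(precision, tp / (tp + fp))
      if (!is.na(recall)) expect_equal(recall, tp / (tp + fn))
      if (!is.na(specificity)) expect_equal(specificity, tn / (tn + fp))
    })
  }
  expect_error(compare_with_static(preds[1:5, ], cohort, INS), "different")
})

test_that("confusion-metric formulas check out on a hand-built case", {
  # TP=2, FP=0, FN=1, TN=7 -> precision 1, recall 2/3, specificity 1
  ins <- INS["anxiety"]
  items <- matrix(0L, 10, 7)
  items[1:3, ] <- 3L                       # three reference positives
  cohort <- as.data.frame(items)
  names(cohort) <- paste0("anxiety_q", 1:7)
  preds <- data.frame(anxiety_pred = c(TRUE, TRUE, FALSE, rep(FALSE, 7)))
  cmp <- compare_with_static(preds, cohort, ins)
  expect_equal(cmp$tp, 2); expect_equal(cmp$fp, 0)
  expect_equal(cmp$fn, 1); expect_equal(cmp$tn, 7)
  expect_equal(cmp$precision, 1)
  expect_equal(cmp$recall, 2 / 3)
  expect_equal(cmp$specificity, 1)
  # swapping predictions and reference exchanges precision and recall
  swapped <- as.data.frame(matrix(0L, 10, 7))
  names(swapped) <- paste0("anxiety_q", 1:7)
  swapped[preds$anxiety_pred, ] <- 3L
  preds_sw <- data.frame(anxiety_pred = rowSums(items) >= 21)
  cmp_sw <- compare_with_static(preds_sw, swapped, ins)
  expect_equal(cmp_sw$precision, cmp$recall)
  expect_equal(cmp_sw$recall, cmp$precision)
})

test_that("undefined ratios warn and propagate as NA, never as zero", {
  ins <- INS["anxiety"]
  cohort <- as.data.frame(matrix(0L, 6, 7))
  names(cohort) <- paste0("anxiety_q", 1:7)   # no reference positives
  preds <- data.frame(anxiety_pred = rep(FALSE, 6))
  expect_warning(expect_warning(
    cmp <- compare_with_static(preds, cohort, ins), "recall"), "precision")
  expect_true(is.na(cmp$recall))
  expect_true(is.na(cmp$precision))
  expect_equal(cmp$specificity, 1)
})

test_that("diagnostic-output statistics summarize positive episodes only", {
  df <- data.frame(
    anxiety_score = c(16, 10, 20, 3), anxiety_pred = c(TRUE, TRUE, TRUE, FALSE),
    depression_score = c(5, 6, 7, 8), depression_pred = FALSE,
    stress_score = c(33, 1, 2, 3), stress_pred = c(TRUE, FALSE, FALSE, FALSE))
  st <- diagnostic_output_stats(df)
  anx <- st[st$disorder == "anxiety", ]
  expect_equal(anx$min, 10); expect_equal(anx$max, 20)
  expect_equal(anx$median, 16)
  # a single positive collapses min = max = median
  strs <- st[st$disorder == "stress", ]
  expect_equal(unlist(strs[c("min", "max", "median")], use.names = FALSE),
               c(33, 33, 33))
  # no positives: absent, not zero
  dep <- st[st$disorder == "depression", ]
  expect_equal(dep$n, 0L)
  expect_true(is.na(dep$median))
  # sort-based oracle over all episodes
  all_ep <- diagnostic_output_stats(df, positives_only = FALSE)
  expect_equal(all_ep$median[all_ep$disorder == "anxiety"],
               sort(df$anxiety_score)[2] / 2 + sort(df$anxiety_score)[3] / 2)
})
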