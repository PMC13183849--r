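#' ROC-derived per-question thresholds
#'
#' Adaptive screening needs to know, after each question, whether the running
#' cumulative score is already suspicious. For every disorder and every
#' question position q, a binary ROC analysis of the cohort's cumulative score
#' over the first q items against the disorder label yields a cutpoint
#' maximizing the Youden index J = sensitivity + specificity - 1; the
#' resulting sequence of per-question thresholds (made monotone by a
#' running-max pass, since cumulative scores cannot decrease) drives both the
#' stop rule and the ask rewards of the screening environment. Final
#' thresholds tau are the instruments' diagnostic cutoffs unless overridden.
#'
#' @name thresholds
NULL

#' ROC points over all candidate cutpoints
#'
#' Candidate thresholds are the midpoints between consecutive sorted distinct
#' scores plus `-Inf`/`+Inf` sentinels; classification rule is
#' `score >= threshold` is positive. TPR and FPR are therefore non-increasing
#' in the threshold.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return Data frame with columns `threshold`, `tpr`, `fpr`, one row per
#'   candidate cutpoint, ordered by increasing threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || !length(scores))
    stop("scores and labels must be non-empty and of equal length", call. = FALSE)
  if (any(is.na(scores)) || any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary with no missing values", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  tpr <- vapply(cand, function(th) sum(scores >= th & labels == 1L) / npos, 0)
  fpr <- vapply(cand, function(th) sum(scores >= th & labels == 0L) / nneg, 0)
  data.frame(threshold = cand, tpr = tpr, fpr = fpr)
}

#' Youden-optimal threshold from a ROC curve
#'
#' Returns the finite cutpoint maximizing J = tpr - fpr, ties broken toward
#' the smaller threshold (the more sensitive screen). Degenerate curves --
#' no finite cutpoint at all, or every finite cutpoint strictly worse than
#' the trivial sentinel classifiers (max finite J < 0) -- raise an error.
#'
#' @param points Data frame from [roc_points()].
#' @return The optimal threshold (numeric scalar).
#' @export
optimal_threshold <- function(points) {
  stopifnot(all(c("threshold", "tpr", "fpr") %in% names(points)))
  fin <- points[is.finite(points$threshold), , drop = FALSE]
  if (!nrow(fin))
    stop("degenerate ROC curve: no finite cutpoint", call. = FALSE)
  j <- fin$tpr - fin$fpr
  if (max(j) < 0)
    stop("degenerate ROC curve: no finite cutpoint reaches the sentinel Youden index",
         call. = FALSE)
  min(fin$threshold[j == max(j)])
}

#' Construct a threshold table
#'
#' @param per_question Named list (one entry per disorder) of numeric
#'   per-question cumulative thresholds, one value per item.
#' @param final Named numeric vector of final thresholds tau per disorder.
#' @param instruments Instrument list the table must cover.
#' @param provenance Optional list recorded alongside the table (e.g. cohort
#'   hash, seed, criterion).
#' @return An object of class `threshold_table`.
#' @export
threshold_table <- function(per_question, final, instruments = load_instruments(),
                            provenance = NULL) {
  for (nm in names(instruments)) {
    ins <- instruments[[nm]]
    th <- per_question[[nm]]
    if (is.null(th) || length(th) != ins$item_count || any(!is.finite(th)))
      stop("per_question thresholds must cover every item of ", nm, call. = FALSE)
    if (any(diff(th) < 0))
      stop("per_question thresholds for ", nm, " must be non-decreasing", call. = FALSE)
    if (any(th < 0) || any(th > seq_len(ins$item_count) * ins$likert_max))
      stop("threshold for ", nm, " outside [0, q * likert_max]", call. = FALSE)
    if (is.null(final[[nm]]) || !is.finite(final[[nm]]))
      stop("final threshold missing for ", nm, call. = FALSE)
  }
  structure(list(per_question = per_question[names(instruments)],
                 final = final[names(instruments)],
                 provenance = provenance),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat("<threshold_table>\n")
  for (nm in names(x$per_question))
    cat(sprintf("  %s: tau = %g; theta = %s\n", nm, x$final[[nm]],
                paste(signif(x$per_question[[nm]], 4), collapse = ", ")))
  invisible(x)
}

cohort_item_cols <- function(instrument)
  paste0(instrument$name, "_q", seq_len(instrument$item_count))

#' Derive a threshold table from a labelled cohort
#'
#' For each disorder X and each question position q, the cumulative
#' reverse-adjusted score of the first q items is tested against the binary
#' disorder label and the Youden-optimal cutpoint is recorded. A running-max
#' (isotonic) pass then enforces monotone non-decreasing thresholds. The
#' derivation is a pure function of its inputs: re-runs are bit-identical.
#'
#' @param cohort Data frame with columns `<disorder>_q<i>` (raw item values)
#'   and `<disorder>_label` (0/1), as written by [generate_cohort()].
#' @param instruments Instrument list.
#' @param final Optional named override of the final thresholds tau; defaults
#'   to each instrument's diagnostic cutoff.
#' @return A `threshold_table`.
#' @export
derive_thresholds <- function(cohort, instruments = load_instruments(),
                              final = NULL) {
  per_question <- list()
  fin <- list()
  for (nm in names(instruments)) {
    ins <- instruments[[nm]]
    cols <- cohort_item_cols(ins)
    lab_col <- paste0(nm, "_label")
    missing_cols <- setdiff(c(cols, lab_col), names(cohort))
    if (length(missing_cols))
      stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    labels <- as.integer(cohort[[lab_col]])
    if (length(unique(labels)) < 2L)
      stop("disorder label for ", nm, " has a single class; cannot run ROC",
           call. = FALSE)
    adj <- vapply(seq_len(ins$item_count), function(i)
      reverse_score(ins, i, cohort[[cols[i]]]), numeric(nrow(cohort)))
    cum <- t(apply(adj, 1L, cumsum))
    theta <- vapply(seq_len(ins$item_count), function(q)
      optimal_threshold(roc_points(cum[, q], labels)), 0)
    per_question[[nm]] <- cummax(theta)
    fin[[nm]] <- if (!is.null(final[[nm]])) as.numeric(final[[nm]])
                 else as.numeric(ins$diagnostic_cutoff)
  }
  threshold_table(per_question, fin, instruments,
                  provenance = list(n = nrow(cohort), criterion = "youden"))
}

#' Write / read a threshold table as JSON
#'
#' @param table A `threshold_table`.
#' @param path Output (input) file path.
#' @param instruments Instrument list used for validation on read.
#' @return `write_thresholds` returns `path` invisibly; `read_thresholds`
#'   returns a `threshold_table`.
#' @export
write_thresholds <- function(table, path) {
  stopifnot(inherits(table, "threshold_table"))
  jsonlite::write_json(
    list(per_question = table$per_question,
         final = table$final,
         provenance = table$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path, instruments = load_instruments()) {
  raw <- jsonlite::fromJSON(path)
  threshold_table(lapply(raw$per_question, as.numeric),
                  lapply(raw$final, as.numeric),
                  instruments, provenance = raw$provenance)
}
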