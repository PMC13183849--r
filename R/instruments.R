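#' Screening instruments
#'
#' The three screening questionnaires modelled by this package are the GAD-7
#' (anxiety; 7 items scored 0--3, total 0--21), the PHQ-9 (depression; 9 items
#' scored 0--3, total 0--27) and the PSS-10 (perceived stress; 10 items scored
#' 0--4 with four positively worded, reverse-scored items, total 0--40).
#' An `instrument` object records the item count, Likert range, the set of
#' reverse-scored items, the severity bands that partition the total-score
#' range, and the diagnostic cutoff at which the screen is read as positive
#' (moderate-and-above for anxiety and depression, high for stress).
#'
#' @name instruments
NULL

#' Construct an instrument definition
#'
#' @param name Disorder identifier: one of `"anxiety"`, `"depression"`,
#'   `"stress"`.
#' @param scale Human-readable scale name (e.g. `"GAD-7"`).
#' @param item_count Number of items.
#' @param likert_min,likert_max Inclusive bounds of the per-item Likert range.
#' @param reverse_items Integer vector of 1-based indices of reverse-scored
#'   items (may be empty).
#' @param severity_bands Data frame with columns `lower`, `upper`, `label`;
#'   the bands must partition `[0, item_count * likert_max]` with inclusive,
#'   non-overlapping integer bounds.
#' @param diagnostic_cutoff Total score at and above which the screen is
#'   positive; must equal the lower bound of one of the severity bands.
#' @return An object of class `instrument`.
#' @export
instrument <- function(name, scale, item_count, likert_min, likert_max,
                       reverse_items, severity_bands, diagnostic_cutoff) {
  stopifnot(is.character(name), length(name) == 1L)
  item_count <- as.integer(item_count)
  likert_min <- as.integer(likert_min)
  likert_max <- as.integer(likert_max)
  reverse_items <- as.integer(reverse_items)
  diagnostic_cutoff <- as.integer(diagnostic_cutoff)
  if (item_count < 1L)
    stop("item_count must be a positive integer", call. = FALSE)
  if (likert_min != 0L || likert_max < 1L)
    stop("Likert range must be [0, likert_max] with likert_max >= 1", call. = FALSE)
  if (length(reverse_items) &&
      (any(reverse_items < 1L) || any(reverse_items > item_count) ||
       anyDuplicated(reverse_items)))
    stop("reverse_items must be distinct indices in 1..item_count", call. = FALSE)
  bands <- as.data.frame(severity_bands)
  if (!all(c("lower", "upper", "label") %in% names(bands)))
    stop("severity_bands needs columns lower, upper, label", call. = FALSE)
  bands <- bands[order(bands$lower), , drop = FALSE]
  max_total <- item_count * likert_max
  # bands must tile [0, max_total] exactly: inclusive bounds, no gaps/overlaps
  if (bands$lower[1L] != 0L || bands$upper[nrow(bands)] != max_total ||
      any(bands$upper < bands$lower) ||
      (nrow(bands) > 1L && any(bands$lower[-1L] != bands$upper[-nrow(bands)] + 1L)))
    stop("severity_bands must partition [0, ", max_total, "] without gaps or overlaps",
         call. = FALSE)
  if (!diagnostic_cutoff %in% bands$lower)
    stop("diagnostic_cutoff must be the lower bound of a severity band", call. = FALSE)
  structure(
    list(name = name, scale = scale, item_count = item_count,
         likert_min = likert_min, likert_max = likert_max,
         reverse_items = reverse_items, severity_bands = bands,
         diagnostic_cutoff = diagnostic_cutoff),
    class = "instrument")
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf("<instrument> %s (%s): %d items, Likert %d-%d, cutoff %d\n",
              x$name, x$scale, x$item_count, x$likert_min, x$likert_max,
              x$diagnostic_cutoff))
  if (length(x$reverse_items))
    cat("  reverse-scored items:", paste(x$reverse_items, collapse = ", "), "\n")
  invisible(x)
}

#' Load the packaged instrument definitions
#'
#' Reads the GAD-7/PHQ-9/PSS-10 definitions shipped with the package (or an
#' alternative JSON document with the same schema) and validates each against
#' the `instrument()` invariants.
#'
#' @param path Path to an instruments JSON file; defaults to the packaged one.
#' @return Named list of `instrument` objects
#'   (`anxiety`, `depression`, `stress`).
#' @export
load_instruments <- function(path = system.file("extdata", "instruments.json",
                                                package = "adaptscreen")) {
  if (!nzchar(path) || !file.exists(path))
    stop("instruments file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  out <- lapply(raw, function(d) {
    instrument(d$name, d$scale, d$item_count, d$likert_min, d$likert_max,
               if (length(d$reverse_items)) d$reverse_items else integer(),
               d$severity_bands, d$diagnostic_cutoff)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

check_raw_value <- function(instrument, value) {
  if (any(is.na(value)) || any(value != as.integer(value)) ||
      any(value < instrument$likert_min) || any(value > instrument$likert_max))
    stop(sprintf("raw value out of Likert range [%d, %d] for %s",
                 instrument$likert_min, instrument$likert_max,
                 instrument$name), call. = FALSE)
  as.integer(value)
}

#' Reverse-score an item response
#'
#' Positively worded items (PSS-10 items 4, 5, 7 and 8) are mapped so that a
#' higher adjusted value always means greater distress:
#' 0 -> 4, 1 -> 3, 2 -> 2, 3 -> 1, 4 -> 0. All other items pass through
#' unchanged.
#'
#' @param instrument An `instrument`.
#' @param item_index 1-based item index.
#' @param raw_value Raw Likert response, within the instrument's range.
#' @return The scoring-adjusted integer value.
#' @export
reverse_score <- function(instrument, item_index, raw_value) {
  item_index <- as.integer(item_index)
  if (any(item_index < 1L) || any(item_index > instrument$item_count))
    stop("item_index out of range for ", instrument$name, call. = FALSE)
  raw_value <- check_raw_value(instrument, raw_value)
  n <- max(length(item_index), length(raw_value))
  item_index <- rep_len(item_index, n)
  out <- rep_len(raw_value, n)
  rev <- item_index %in% instrument$reverse_items
  out[rev] <- instrument$likert_max - out[rev]
  out
}

#' Total score of a complete response set
#'
#' Sums the reverse-adjusted item values. Exactly one response per item is
#' required.
#'
#' @param instrument An `instrument`.
#' @param raw_values Integer vector of raw responses.
#' @param item_index 1-based indices the responses belong to; defaults to
#'   `seq_along(raw_values)`.
#' @return Integer total in `[0, item_count * likert_max]`.
#' @export
total_score <- function(instrument, raw_values, item_index = seq_along(raw_values)) {
  item_index <- as.integer(item_index)
  if (length(raw_values) != instrument$item_count ||
      !setequal(item_index, seq_len(instrument$item_count)) ||
      anyDuplicated(item_index))
    stop("need exactly one response per item of ", instrument$name, call. = FALSE)
  sum(reverse_score(instrument, item_index, raw_values))
}

#' Severity band of a total score
#'
#' @param instrument An `instrument`.
#' @param total Total score within the instrument's range.
#' @return The band label (character).
#' @export
categorize <- function(instrument, total) {
  max_total <- instrument$item_count * instrument$likert_max
  if (any(is.na(total)) || any(total < 0) || any(total > max_total))
    stop("total out of range [0, ", max_total, "] for ", instrument$name,
         call. = FALSE)
  bands <- instrument$severity_bands
  idx <- vapply(total, function(t)
    which(t >= bands$lower & t <= bands$upper)[1L], integer(1))
  bands$label[idx]
}

#' Positive-screen indicator
#'
#' A respondent screens positive when the total reaches the instrument's
#' diagnostic cutoff: moderate and above for anxiety and depression (>= 10),
#' high perceived stress for the PSS-10 (>= 27).
#'
#' @param instrument An `instrument`.
#' @param total Total score within the instrument's range.
#' @return Logical.
#' @export
is_positive <- function(instrument, total) {
  max_total <- instrument$item_count * instrument$likert_max
  if (any(is.na(total)) || any(total < 0) || any(total > max_total))
    stop("total out of range [0, ", max_total, "] for ", instrument$name,
         call. = FALSE)
  total >= instrument$diagnostic_cutoff
}
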