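#' Severity score vectors and text scorers
#'
#' Every turn of an adaptive session produces a 4-dimensional observation
#' `(anxiety, depression, stress, normal)` with each component on a 0--100
#' severity scale. In a live deployment the components come from a text
#' classifier applied to the free-text reply; in simulation they come from the
#' synthetic respondent model. A *scorer* is any function `text -> score
#' vector` that is deterministic for a fixed configuration; the package ships
#' a transparent keyword scorer as the default implementation and treats
#' model-backed scorers as drop-in adapters behind the same contract.
#'
#' @name scorer
NULL

#' Construct a severity score vector
#'
#' @param anxiety,depression,stress,normal Severities in `[0, 100]`.
#' @return Named numeric vector of class `score_vector` with components
#'   `anxiety`, `depression`, `stress`, `normal`.
#' @export
score_vector <- function(anxiety, depression, stress, normal) {
  v <- c(anxiety = as.numeric(anxiety), depression = as.numeric(depression),
         stress = as.numeric(stress), normal = as.numeric(normal))
  if (any(is.na(v)) || any(v < 0) || any(v > 100))
    stop("score components must lie in [0, 100]", call. = FALSE)
  structure(v, class = "score_vector")
}

#' Rescale a 0--100 severity component to Likert units
#'
#' Cumulative questionnaire scores live in the instrument's own units, so each
#' per-turn severity is mapped linearly onto `[0, likert_max]`. The result is
#' deliberately left real-valued: rounding to integer Likert steps would
#' discard information before the comparison with the (real-valued) ROC
#' thresholds.
#'
#' @param component Severity in `[0, 100]`.
#' @param likert_max Upper end of the Likert range (>= 1).
#' @return `component / 100 * likert_max`.
#' @export
rescale_to_likert <- function(component, likert_max) {
  if (any(is.na(component)) || any(component < 0) || any(component > 100))
    stop("component must lie in [0, 100]", call. = FALSE)
  if (likert_max < 1) stop("likert_max must be >= 1", call. = FALSE)
  component / 100 * likert_max
}

#' Load the packaged keyword lexicon
#'
#' @param path Path to a lexicon JSON file (term -> disorder, weight);
#'   defaults to the packaged fixture.
#' @return Data frame with columns `term`, `disorder`, `weight`.
#' @export
load_lexicon <- function(path = system.file("extdata", "lexicon.json",
                                            package = "adaptscreen")) {
  if (!nzchar(path) || !file.exists(path))
    stop("lexicon file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path)
  data.frame(term = names(raw),
             disorder = vapply(raw, `[[`, "", "disorder"),
             weight = vapply(raw, function(e) as.numeric(e$weight), 0),
             row.names = NULL)
}

#' Keyword text scorer
#'
#' A deterministic, fully transparent scorer: the reply is lower-cased and
#' tokenized on non-letters, matched tokens add their lexicon weight to the
#' corresponding disorder component, components are clipped to `[0, 100]`,
#' and `normal` is `100 - max(anxiety, depression, stress)`. It is the
#' package's reference implementation of the scorer contract; a fine-tuned
#' transformer scorer plugs in behind the same `text -> score_vector`
#' interface.
#'
#' @param lexicon Data frame from [load_lexicon()].
#' @return A function `function(text) -> score_vector`.
#' @export
keyword_scorer <- function(lexicon = load_lexicon()) {
  stopifnot(all(c("term", "disorder", "weight") %in% names(lexicon)))
  force(lexicon)
  function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
      stop("text must be a non-empty string", call. = FALSE)
    tokens <- strsplit(tolower(text), "[^a-z]+")[[1L]]
    tokens <- tokens[nzchar(tokens)]
    hit <- lexicon[lexicon$term %in% tokens, , drop = FALSE]
    comp <- c(anxiety = 0, depression = 0, stress = 0)
    if (nrow(hit)) {
      agg <- tapply(hit$weight, hit$disorder, sum)
      comp[names(agg)] <- pmin(100, agg)
    }
    score_vector(comp[["anxiety"]], comp[["depression"]], comp[["stress"]],
                 100 - max(comp))
  }
}
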