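#' @keywords internal
"_PACKAGE"

DISORDERS <- c("anxiety", "depression", "stress")

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package internals never clobber user seeds.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage (or per-respondent) seeds through a
#' fixed linear-congruential splitter, so every pipeline stage is
#' independently reproducible from the run's single seed. Results stay below
#' 2^31.
#'
#' @param seed Integer global seed.
#' @param index Non-negative integer stage index.
#' @return Integer derived seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 11) %% 2147483647)
}
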