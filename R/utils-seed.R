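#' Derive a stage-specific random seed from a top-level seed
#'
#' The package uses one user-facing seed per analysis; every internal source
#' of randomness (sentiment draws, token draws, retweet counts, bootstrap
#' resampling, ...) runs on its own sub-stream whose seed is derived
#' deterministically from the top-level seed and a stage name. Stage-level
#' results are therefore reproducible individually without coupling the
#' random streams of unrelated stages.
#'
#' @param seed Integer top-level seed.
#' @param stage Character scalar naming the sub-stream (e.g. `"retweets/negative"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' derive_seed(1L, "bootstrap")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer(((seed %% m) + h * 2654435 + 1) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Coerce a length-3 count/probability vector to canonical sentiment order.
# Unnamed vectors are assumed already ordered (positive, negative, neutral).
as_sentiment_vector <- function(x, what = "counts") {
  if (length(x) != 3L) {
    stop(sprintf("`%s` must have length 3 (positive, negative, neutral)", what))
  }
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    if (!setequal(names(x), SENTIMENTS)) {
      stop(sprintf("`%s` names must be %s", what,
                   paste(SENTIMENTS, collapse = ", ")))
    }
    x <- x[SENTIMENTS]
  } else {
    names(x) <- SENTIMENTS
  }
  x
}
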