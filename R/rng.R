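#' Derive a reproducible substream seed from a global seed
#'
#' Every stochastic component of the toolkit (truth assignment, image
#' quality, classifier scores, grader draws, QA sampling) draws from its own
#' named substream so that, e.g., changing grader noise does not perturb the
#' cohort draw. A substream seed is a deterministic 31-bit hash of the
#' global seed and the stream name.
#'
#' @param seed Integer global seed.
#' @param stream Character stream name, e.g. `"truth"`, `"scores"`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "truth")
#' substream_seed(42, "scores")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; doubles are exact well past this
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% m
  as.integer((h * 1000003 + (abs(seed) %% m)) %% m)
}

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
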