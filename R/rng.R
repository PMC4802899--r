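#' Deterministic RNG substreams
#'
#' All randomness in drynet flows from one user-visible integer seed. A named
#' substream seed is derived by hashing the master seed together with a list
#' of string/integer labels, so that, e.g., the draws used for metabolite
#' noise are unaffected by how many genes or promoters are generated, and
#' per-pair permutation streams are independent of the order in which pairs
#' are evaluated.
#'
#' @param seed master integer seed.
#' @param ... labels (strings or integers) naming the substream.
#' @return an integer in [1, 2^31 - 2] suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  bytes <- utf8ToInt(labels)
  # 31-bit multiplicative hash; doubles stay exact (< 2^53) throughout
  h <- (abs(as.numeric(seed)) + 1) %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`, so
#' library code never disturbs the user's RNG stream.
#'
#' @param seed integer seed for the temporary stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}
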