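#' @keywords internal
"_PACKAGE"

## Rounding convention used throughout the package (memory sizes, per-class
## split counts): half away from zero, not the IEEE round-half-even of round().
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable softmax
#'
#' Maps a real vector to a probability vector via `exp(v - max(v))`
#' normalised to sum to one; the max-subtraction avoids overflow for large
#' inputs and leaves the result unchanged (softmax is shift invariant).
#'
#' @param v Numeric vector of finite scores.
#' @return Numeric vector of the same length: positive, sums to 1.
#' @examples
#' softmax(c(0, 0))          # 0.5 0.5
#' softmax(c(1000, 1000))    # no overflow
#' @export
softmax <- function(v) {
  if (length(v) == 0L) stop("empty input")
  if (!all(is.finite(v))) stop("non-finite sample")
  e <- exp(v - max(v))
  e / sum(e)
}

## Row-wise stable softmax for a score matrix.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## Evaluate a user objective while shielding the caller's RNG stream:
## objectives are free to call set.seed() internally (the CV fitness does)
## without perturbing the optimiser's own reproducible draws.
eval_shielded <- function(objective, x) {
  seed_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  val <- objective(x)
  if (!is.null(seed_state))
    assign(".Random.seed", seed_state, envir = globalenv())
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
    stop("objective returned non-finite")
  as.numeric(val)
}

## Deterministic 31-bit integer hash of a numeric vector plus salt integers,
## used to derive per-evaluation training seeds.
hash_seed <- function(..., vec = NULL) {
  acc <- 0
  for (s in c(...)) acc <- (acc * 31 + (as.numeric(s) %% 2147483647)) %% 2147483647
  if (!is.null(vec)) {
    q <- floor(abs(vec) * 1e6) %% 2147483647
    for (s in q) acc <- (acc * 131 + s) %% 2147483647
  }
  as.integer(acc %% 2147483646) + 1L
}
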