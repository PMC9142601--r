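#' Evaluate an expression under a local, fully specified RNG state
#'
#' All randomness in the package flows through this helper so that results
#' are reproducible across platforms and independent of the caller's global
#' RNG state. The RNG kind is pinned (Mersenne-Twister / Inversion /
#' Rejection) and the previous state is restored on exit.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withLocalSeed <- function(seed, expr) {
  has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has.seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Derive a child seed from a master seed and a named substream
#'
#' Deterministic, collision-resistant enough for the handful of substreams
#' the pipeline uses; result always fits in a 32-bit signed integer.
#'
#' @param seed master integer seed.
#' @param stream character substream label.
#' @param index optional integer index within the substream.
#' @return integer seed.
#' @keywords internal
deriveSeed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (as.double(seed) * 2654435.0 + h * 97.0 + as.double(index) * 7919.0)
  as.integer(val %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
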