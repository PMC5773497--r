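# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @importFrom stats runif rnorm rlnorm sd cor pchisq dgamma qnorm pnorm t.test
NULL

## Evaluate `expr` under a fixed RNG seed without clobbering the caller's
## RNG state. All user-facing stochastic operations funnel through this.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Deterministic substream seeds (kept < 2^31) so that independent stages
## of a pipeline run do not share RNG streams.
.deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) %% 65011 + 1) * 7919 +
               104729 * (as.double(offset) %% 4093)) %% 2147483587L
}

.isFlag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

.checkProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}
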