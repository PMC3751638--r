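#' @importFrom methods is new validObject slot
#' @importFrom stats median ppois pt rnorm runif rbinom sd setNames lm coef
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All simulation entry points use this
## so no global RNG state leaks between operations.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Signed fold-change convention
#'
#' Converts a linear ratio to the signed convention used in microarray tables:
#' ratios >= 1 are reported as-is, ratios < 1 as the negative reciprocal
#' (a ratio of 0.54 becomes -1.85, i.e. a 1.85-fold decrease). The magnitude
#' of a signed fold is therefore always >= 1.
#'
#' @param ratio positive numeric vector of linear ratios (B/A).
#' @return numeric vector of signed folds, `|x| >= 1`.
#' @examples
#' signedFold(c(2, 1, 0.5))
#' @export
signedFold <- function(ratio) {
  stopifnot(is.numeric(ratio), all(ratio > 0))
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' @rdname signedFold
#' @param signed numeric vector in the signed convention (`|x| >= 1`).
#' @return `unsignFold()` returns the linear ratio.
#' @export
unsignFold <- function(signed) {
  stopifnot(is.numeric(signed), all(abs(signed) >= 1 - 1e-12))
  ifelse(signed >= 0, signed, -1 / signed)
}

## scalar checks used by validity methods and argument checking
isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
isCount <- function(x) isScalarNum(x) && x >= 1 && x == floor(x)
isProportion <- function(x) isScalarNum(x) && x >= 0 && x <= 1
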