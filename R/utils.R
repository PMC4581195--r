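## Small internal helpers shared across modules.

#' @useDynLib DisorderCNF, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats runif rnorm rgamma optim setNames na.omit cor
#' @importFrom utils read.delim write.table tail head
NULL

## Run code under a temporary RNG state so library calls never disturb the
## caller's random stream.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Copy of m with every row taken from row i + l (zero where i + l falls
## outside the chain) -- the zero-padding convention of the convolutions.
shiftRowsZero <- function(m, l) {
  L <- nrow(m)
  out <- matrix(0, L, ncol(m))
  if (l >= 0L) {
    if (l < L) out[seq_len(L - l), ] <- m[(1L + l):L, , drop = FALSE]
  } else {
    k <- -l
    if (k < L) out[(k + 1L):L, ] <- m[seq_len(L - k), , drop = FALSE]
  }
  out
}

## Full-precision number formatting: doubles survive a text round trip.
formatFull <- function(x) formatC(x, format = "g", digits = 17)
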