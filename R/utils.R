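# Seed handling: evaluate code under a temporary RNG state so generators are
# deterministic under `seed` without disturbing the caller's stream.
withSeed <- function(seed, code) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed))) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-module seed from a master seed
#'
#' Stable string hash of the module name folded into the master seed, kept
#' below 2^31 so it is a valid R integer seed. Used so that one global seed
#' deterministically seeds every stochastic stage of a pipeline.
#'
#' @param master master seed (integer-valued).
#' @param module module name (character scalar).
#' @return an integer seed in [0, 2^31 - 2].
#' @examples
#' moduleSeed(1, "population")
#' @export
moduleSeed <- function(master, module) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(module))
  s <- abs(master) %% 2147483647
  for (ch in utf8ToInt(module)) s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
rowLogSumExp <- function(X) {
  m <- apply(X, 1, max)
  m + log(rowSums(exp(X - m)))
}
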