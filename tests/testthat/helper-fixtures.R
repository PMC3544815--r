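# Build RateProfiles from a plain mean-count matrix.
mkProfiles <- function(u, binWidth = 0.25, sourceId = "") {
  if (is.null(rownames(u)))
    rownames(u) <- sprintf("s%02d", seq_len(nrow(u)))
  new("RateProfiles", u = u, binWidth = binWidth, nTrials = 0,
      trialIds = integer(0), sourceId = sourceId)
}

# Random row-stochastic matrix (independent exponential rows, normalized).
randomPosterior <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  q <- matrix(rexp(n * n), n, n)
  q / rowSums(q)
}

# The full-scale recovery run is expensive; compute it once per test session
# and share it across test files.
.recoveryCache <- new.env(parent = emptyenv())
getRecoveryReport <- function() {
  if (is.null(.recoveryCache$report))
    .recoveryCache$report <- runRecovery(seed = 1)
  .recoveryCache$report
}
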