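# Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a parent seed and a stream index.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %%
               2147483647)
}

ssq <- function(x) sum(x * x)

# Column standard deviations (n-1 denominator) without per-column apply().
colSds <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  ctr <- colMeans(X)
  v <- (colSums(X * X) - n * ctr * ctr) / (n - 1)
  sqrt(pmax(v, 0))
}
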