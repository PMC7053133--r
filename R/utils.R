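#' @importFrom stats sd rexp rnorm rbinom runif quantile uniroot cor kmeans
#'   phyper wilcox.test pnorm qnorm complete.cases coef var pchisq
#' @importFrom utils head
NULL

#' @importFrom stats setNames
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific child seed below 2^31.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
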