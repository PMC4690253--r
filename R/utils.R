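#' @importFrom stats rnorm runif sd var qnorm pnorm pt plogis coef glm binomial
#'   predict t.test wilcox.test quantile setNames rpois
#' @importFrom utils read.csv write.csv head combn
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls do not perturb user code.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-unit child seeds from one master seed (counter-based
# splitting, kept below 2^31 so set.seed() accepts them).
childSeed <- function(seed, index) {
  x <- ((as.double(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((x + 1009 * (as.double(index) %% 2147483647)) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
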