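#' @import methods
#' @importFrom stats cor sd qnorm pnorm pchisq pt optim optimize rnorm runif
#'   setNames var quantile
NULL

CLASS_LEVELS <- c("idiotypic", "unimodal", "heteromodal", "paralimbic")

## Derive a deterministic sub-seed for a named operation so that every
## stage of a simulation is reproducible on its own.  Kept below 2^31.
substreamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647L)
}

withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, stream))
  force(expr)
}

zstandardize <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot z-standardize a zero-variance vector")
  (x - mean(x, na.rm = TRUE)) / s
}

## Spearman correlation that returns NA (with a warning suppressed upstream)
## for constant inputs instead of erroring.
spearmanSafe <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok], method = "spearman")
}

stopifnotScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
}
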