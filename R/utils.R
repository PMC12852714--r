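#' @import methods
#' @importFrom stats cor pt pnorm pchisq rexp rnorm runif quantile
#' @importFrom utils read.table write.table
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so seeded helpers never perturb global
## reproducibility.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Gene symbols are matched case-insensitively after upper-casing; hyphens are
## stripped (platforms disagree on e.g. SIGLEC-10 vs SIGLEC10). No alias
## expansion is performed.
normalizeSymbols <- function(x) {
  gsub("-", "", toupper(trimws(as.character(x))), fixed = TRUE)
}

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be TRUE or FALSE")
  invisible(x)
}

assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper)
    stop("'", name, "' must be a single finite number in [",
         lower, ", ", upper, "]")
  invisible(x)
}

assertCount <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower)
    stop("'", name, "' must be a single integer >= ", lower)
  invisible(as.integer(x))
}
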