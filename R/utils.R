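# classed conditions so the CLI can map failures to exit codes
stopSchema <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("erpsse_schema_error", "error")))
}

stopNumeric <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("erpsse_numeric_error", "error")))
}

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# coerce a numeric vector to a 1 x n series matrix; pass matrices through
asSeries <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.numeric(x)) return(matrix(as.double(x), nrow = 1))
  stopSchema("a series must be a numeric vector or a p x n matrix, got %s",
             class(x)[1])
}

checkSeriesPair <- function(x, y) {
  if (ncol(x) < 1L || ncol(y) < 1L)
    stopSchema("series must have length >= 1 (got %d and %d)",
               ncol(x), ncol(y))
  if (nrow(x) != nrow(y))
    stopSchema("series dimension mismatch: x is %d x %d, y is %d x %d",
               nrow(x), ncol(x), nrow(y), ncol(y))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopSchema("series entries must be finite")
  invisible(NULL)
}

matchMetric <- function(metric) {
  metric <- match.arg(metric, c("squared_euclidean", "euclidean"))
  metric
}
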