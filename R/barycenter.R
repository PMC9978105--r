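#' Soft-DTW barycenter objective
#'
#' The weighted Frechet-mean objective
#' \deqn{F(x) = \sum_{i=1}^N \frac{\lambda_i}{m_i}\,
#'   \mathrm{dtw}_\gamma(x, y_i)}
#' where \eqn{m_i} is the length of series \eqn{y_i} and the weights
#' \eqn{\lambda_i > 0} sum to 1.
#'
#' @param x candidate barycenter: numeric vector or \code{p x n} matrix.
#' @param series list of series (vectors or \code{p x m_i} matrices) sharing
#'   dimension \code{p}.
#' @param weights positive weights summing to 1; default uniform.
#' @param gamma Soft-DTW smoothing parameter, \eqn{> 0}.
#' @return scalar objective value.
#' @export
barycenterObjective <- function(x, series, weights = NULL, gamma = 1) {
  x <- asSeries(x)
  series <- lapply(series, asSeries)
  weights <- normWeights(weights, length(series))
  for (y in series) checkSeriesPair(x, y)
  if (gamma <= 0) stopSchema("gamma must be > 0, got %g", gamma)
  obj <- 0
  for (i in seq_along(series)) {
    obj <- obj + weights[i] / ncol(series[[i]]) *
      .softdtwForwardC(.costMatrixC(x, series[[i]], TRUE), gamma)$value
  }
  obj
}

normWeights <- function(weights, n) {
  if (n < 1L) stopSchema("at least one series is required")
  if (is.null(weights)) return(rep(1 / n, n))
  if (length(weights) != n)
    stopSchema("%d weights for %d series", length(weights), n)
  if (any(weights <= 0)) stopSchema("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-9)
    stopSchema("weights must sum to 1 (got %.12g)", sum(weights))
  weights
}

#' Soft-DTW barycenter by L-BFGS descent
#'
#' Minimises \code{\link{barycenterObjective}} over the candidate series
#' \code{x} using limited-memory BFGS directions with Armijo backtracking;
#' gradients come from the exact Soft-DTW backward pass. Only accepted
#' iterates are recorded, so the objective trace is monotone non-increasing.
#'
#' @inheritParams barycenterObjective
#' @param init initial series (sets the output length); commonly the anchor
#'   trial in the SSE pipeline, or the arithmetic mean of \code{series}.
#' @param maxIter maximum number of descent iterations (default 100).
#' @param tol relative objective-decrease tolerance for convergence
#'   (default 1e-5).
#' @param memory L-BFGS history size (default 6).
#' @return list with \code{x} (the barycenter, same shape as \code{init}),
#'   \code{objectiveTrace} (objective at init plus after each accepted step),
#'   \code{converged}, and \code{iterations}.
#' @examples
#' ys <- lapply(c(-2, 0, 2), function(s) dnorm(seq(-4, 4, length.out = 32), s))
#' fit <- solveBarycenter(ys, gamma = 0.1, maxIter = 25)
#' fit$objectiveTrace[1] >= fit$objectiveTrace[length(fit$objectiveTrace)]
#' @export
solveBarycenter <- function(series, weights = NULL, gamma = 1, init = NULL,
                            maxIter = 100, tol = 1e-5, memory = 6) {
  series <- lapply(series, asSeries)
  weights <- normWeights(weights, length(series))
  if (gamma <= 0) stopSchema("gamma must be > 0, got %g", gamma)
  if (is.null(init)) {
    lens <- vapply(series, ncol, 0L)
    if (length(unique(lens)) != 1L)
      stopSchema("series lengths differ; supply an explicit init")
    init <- Reduce(`+`, series) / length(series)
  }
  x <- asSeries(init)
  for (y in series) checkSeriesPair(x, y)

  objGrad <- function(x) {
    og <- .barycenterObjGradC(x, series, weights, gamma)
    if (!is.finite(og$objective))
      stopNumeric("non-finite barycenter objective")
    og
  }

  og <- objGrad(x)
  f <- og$objective; g <- og$grad
  trace <- f
  sList <- list(); yList <- list(); rhoList <- numeric()
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(maxIter)) {
    # two-loop recursion for the L-BFGS direction
    q <- g
    k <- length(sList)
    alpha <- numeric(k)
    if (k > 0) {
      for (idx in k:1) {
        alpha[idx] <- rhoList[idx] * sum(sList[[idx]] * q)
        q <- q - alpha[idx] * yList[[idx]]
      }
      gammaH <- sum(sList[[k]] * yList[[k]]) / sum(yList[[k]] * yList[[k]])
      q <- q * gammaH
      for (idx in 1:k) {
        beta <- rhoList[idx] * sum(yList[[idx]] * q)
        q <- q + (alpha[idx] - beta) * sList[[idx]]
      }
    }
    dir <- -q
    dg <- sum(dir * g)
    if (dg >= 0) { dir <- -g; dg <- -sum(g * g) }  # fall back to steepest descent
    if (-dg <= .Machine$double.eps * (1 + abs(f))) { converged <- TRUE; break }

    # Armijo backtracking
    step <- 1
    ok <- FALSE
    for (ls in 1:30) {
      xNew <- x + step * dir
      fNew <- tryCatch(objGrad(xNew), error = function(e) NULL)
      if (!is.null(fNew) && fNew$objective <= f + 1e-4 * step * dg) {
        ok <- TRUE; break
      }
      step <- step / 2
    }
    if (!ok) { converged <- TRUE; break }  # no further descent possible

    s <- xNew - x
    yv <- fNew$grad - g
    sy <- sum(s * yv)
    if (sy > 1e-12) {
      sList <- c(sList, list(s)); yList <- c(yList, list(yv))
      rhoList <- c(rhoList, 1 / sy)
      if (length(sList) > memory) {
        sList <- sList[-1]; yList <- yList[-1]; rhoList <- rhoList[-1]
      }
    }
    relDec <- (f - fNew$objective) / max(abs(f), 1e-12)
    x <- xNew; f <- fNew$objective; g <- fNew$grad
    trace <- c(trace, f)
    if (relDec < tol) { converged <- TRUE; break }
  }

  list(x = x, objectiveTrace = trace, converged = converged,
       iterations = length(trace) - 1L)
}
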