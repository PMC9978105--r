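#' Smoothed minimum (log-sum-exp soft-min)
#'
#' \eqn{\min^\gamma\{a_1,\dots,a_n\} = -\gamma \log \sum_i e^{-a_i/\gamma}}
#' for \eqn{\gamma > 0}, and the exact minimum at \eqn{\gamma = 0}. Evaluated
#' in stabilised form (the minimum is subtracted before exponentiating), so
#' it is safe for large cost ranges and small \eqn{\gamma}.
#'
#' @param values nonempty numeric vector.
#' @param gamma smoothing parameter, \eqn{\ge 0}.
#' @return scalar soft minimum; always \eqn{\le \min(values)}.
#' @examples
#' softMin(c(2, 5, 7), 0)      # exact min
#' softMin(c(4, 4, 4), 1)      # 4 - log(3)
#' @export
softMin <- function(values, gamma) {
  if (length(values) == 0L) stopSchema("softMin of an empty set is undefined")
  if (gamma < 0) stopSchema("gamma must be >= 0, got %g", gamma)
  m <- min(values)
  if (gamma == 0 || !is.finite(m)) return(m)
  m - gamma * log(sum(exp(-(values - m) / gamma)))
}

#' Soft-DTW value (forward pass)
#'
#' Dynamic program with the soft minimum in place of the hard minimum:
#' \deqn{r_{i,j} = \delta_{i,j} + \min{}^\gamma\{r_{i,j-1}, r_{i-1,j},
#'   r_{i-1,j-1}\}.}
#' The terminal entry equals
#' \eqn{-\gamma \log \sum_{A} e^{-\langle A, \Delta(x,y)\rangle/\gamma}}
#' over all monotone alignment matrices \eqn{A}; at \eqn{\gamma = 0} it
#' reduces exactly to \code{\link{dtwDistance}}. The value can be negative
#' for \eqn{\gamma > 0} (it is a soft minimum of nonnegative path costs).
#'
#' @inheritParams pairwiseCost
#' @param gamma smoothing parameter \eqn{\ge 0}.
#' @return list with \code{value} (scalar) and \code{r}, the padded
#'   \code{(n+1) x (m+1)} cost-sum table (row/column 1 is the DP boundary;
#'   entry \code{r[i+1, j+1]} is \eqn{r_{i,j}}).
#' @examples
#' softDTW(c(0, 1, 2), c(0, 1, 2), gamma = 1)$value
#' @export
softDTW <- function(x, y, gamma = 1,
                    metric = c("squared_euclidean", "euclidean")) {
  if (gamma < 0) stopSchema("gamma must be >= 0, got %g", gamma)
  delta <- pairwiseCost(x, y, metric)
  .softdtwForwardC(delta, gamma)
}

#' Soft-DTW gradient (backward pass)
#'
#' Computes the matrix \eqn{E} of partials
#' \eqn{e_{i,j} = \partial r_{n,m} / \partial r_{i,j}} by the reverse
#' dynamic program
#' \deqn{e_{i,j} = a\, e_{i+1,j} + b\, e_{i,j+1} + c\, e_{i+1,j+1}}
#' with exponential weights
#' \eqn{a = e^{(r_{i+1,j} - r_{i,j} - \delta_{i+1,j})/\gamma}} (and
#' analogously for \eqn{b, c}), then applies the chain rule
#' \eqn{\nabla_x \mathrm{dtw}_\gamma(x,y) = (\partial \Delta / \partial
#' x)^\top E} for the squared Euclidean cost. The target series \code{y} is
#' held fixed.
#'
#' @inheritParams softDTW
#' @param forward optional result of \code{softDTW} on the same
#'   \code{(x, y, gamma)}; recomputed when missing.
#' @return list with \code{value}, \code{grad} (\code{p x n} gradient with
#'   respect to \code{x}) and \code{e} (the \code{n x m} E-matrix;
#'   \code{e[n, m] == 1}, all entries in \eqn{[0, 1]}).
#' @examples
#' g <- softDTWGrad(c(0, 1, 0), c(0, 2, 0), gamma = 1)
#' g$e[3, 3]  # always 1
#' @export
softDTWGrad <- function(x, y, gamma = 1, forward = NULL) {
  if (gamma <= 0)
    stopSchema("the Soft-DTW backward pass requires gamma > 0, got %g", gamma)
  x <- asSeries(x); y <- asSeries(y)
  checkSeriesPair(x, y)
  if (is.null(forward)) return(.softdtwValueGradC(x, y, gamma))
  delta <- .costMatrixC(x, y, TRUE)
  e <- .softdtwEMatrixC(delta, forward$r, gamma)
  p <- nrow(x); n <- ncol(x)
  grad <- 2 * (x * rep(rowSums(e), each = p) - y %*% t(e))
  list(value = forward$value, grad = grad, e = e)
}
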