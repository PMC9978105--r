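#' Pairwise cost matrix between two multivariate series
#'
#' Computes the \code{n x m} matrix of pointwise costs
#' \eqn{\delta(x_i, y_j)} between the columns of two \code{p x n} /
#' \code{p x m} series. The default cost is the squared Euclidean distance,
#' which is smooth everywhere and is the metric used by the differentiable
#' Soft-DTW backward pass; plain Euclidean is available for the classic
#' distance.
#'
#' @param x,y numeric vectors (treated as 1-D series) or \code{p x length}
#'   matrices sharing the same dimension \code{p}.
#' @param metric \code{"squared_euclidean"} (default) or \code{"euclidean"}.
#' @return numeric \code{n x m} matrix of nonnegative costs.
#' @examples
#' pairwiseCost(c(1, 2), c(4, 5))
#' @export
pairwiseCost <- function(x, y, metric = c("squared_euclidean", "euclidean")) {
  metric <- matchMetric(metric)
  x <- asSeries(x); y <- asSeries(y)
  checkSeriesPair(x, y)
  .costMatrixC(x, y, metric == "squared_euclidean")
}

#' Classic dynamic time warping distance
#'
#' Evaluates the three-neighbour DTW recurrence
#' \deqn{r_{i,j} = \delta_{i,j} + \min\{r_{i,j-1}, r_{i-1,j}, r_{i-1,j-1}\}}
#' over the cost matrix of the two series and returns the terminal cost sum
#' \eqn{r_{n,m}}: the minimum of \eqn{\langle A, \Delta(x,y)\rangle} over all
#' monotone alignment paths \eqn{A}.
#'
#' @inheritParams pairwiseCost
#' @return nonnegative scalar distance; 0 when \code{x} and \code{y} are
#'   identical.
#' @seealso \code{\link{softDTW}} for the differentiable relaxation,
#'   \code{\link{dtwPath}} for the optimal alignment path.
#' @examples
#' dtwDistance(c(0, 1, 2), c(0, 0, 1, 2))
#' @export
dtwDistance <- function(x, y, metric = c("squared_euclidean", "euclidean")) {
  delta <- pairwiseCost(x, y, metric)
  .dtwFromCostC(delta)
}

#' Optimal DTW alignment path
#'
#' Backtracks one minimising monotone alignment path through the DTW table
#' (ties resolved diagonal-first). Used mainly to inspect where the soft
#' E-matrix concentrates as \eqn{\gamma \to 0}.
#'
#' @inheritParams pairwiseCost
#' @return list with \code{value} (the DTW distance) and integer vectors
#'   \code{i}, \code{j} giving the aligned index pairs from (1,1) to (n,m).
#' @export
dtwPath <- function(x, y, metric = c("squared_euclidean", "euclidean")) {
  delta <- pairwiseCost(x, y, metric)
  .dtwPathC(delta)
}

#' Summed per-channel DTW distance between two epochs
#'
#' The trial-to-trial distance of the SSE pipeline: each channel column is
#' treated as an independent univariate series and the classic DTW distances
#' are summed over channels. No multivariate joint warping is performed.
#'
#' @param a,b numeric \code{time x channel} matrices with identical shape.
#' @inheritParams pairwiseCost
#' @return nonnegative scalar; 0 for identical epochs.
#' @examples
#' a <- matrix(rnorm(32), 16, 2)
#' epochDistance(a, a)
#' @export
epochDistance <- function(a, b, metric = c("squared_euclidean", "euclidean")) {
  metric <- matchMetric(metric)
  if (!is.matrix(a) || !is.matrix(b))
    stopSchema("epochs must be time x channel matrices")
  if (ncol(a) != ncol(b))
    stopSchema("channel-count mismatch: %d vs %d channels", ncol(a), ncol(b))
  .epochDistanceC(a, b, metric == "squared_euclidean")
}
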