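# Brute-force oracles for the DTW family, independent of the package's
# dynamic programs: enumerate every monotone alignment path explicitly.

# all monotone paths from (1,1) to (n,m) with steps right/down/diagonal;
# each path is a 2-column matrix of (i, j) cells
enumeratePaths <- function(n, m) {
  out <- list()
  recur <- function(i, j, path) {
    if (i == n && j == m) {
      out[[length(out) + 1]] <<- do.call(rbind, path)
      return(invisible(NULL))
    }
    if (i < n) recur(i + 1, j, c(path, list(c(i + 1, j))))
    if (j < m) recur(i, j + 1, c(path, list(c(i, j + 1))))
    if (i < n && j < m) recur(i + 1, j + 1, c(path, list(c(i + 1, j + 1))))
  }
  recur(1, 1, list(c(1, 1)))
  out
}

pathCost <- function(path, delta) sum(delta[path])

bruteDTW <- function(delta) {
  paths <- enumeratePaths(nrow(delta), ncol(delta))
  min(vapply(paths, pathCost, 0, delta = delta))
}

bruteSoftDTW <- function(delta, gamma) {
  paths <- enumeratePaths(nrow(delta), ncol(delta))
  costs <- vapply(paths, pathCost, 0, delta = delta)
  if (gamma == 0) return(min(costs))
  m <- min(costs)
  m - gamma * log(sum(exp(-(costs - m) / gamma)))
}

randomSeries <- function(p, len) matrix(rnorm(p * len), p, len)
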