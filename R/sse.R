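#' Partition trials by (subject, label)
#'
#' Step 1 of the SSE pipeline: trials are grouped within subject and within
#' condition label, so no averaging ever mixes subjects or conditions.
#'
#' @param es an \code{\linkS4class{EpochSet}}.
#' @return named list (keys \code{"subject|label"}, sorted) of integer trial
#'   index vectors; every trial appears in exactly one group.
#' @export
groupTrials <- function(es) {
  stopifnot(is(es, "EpochSet"))
  if (nTrials(es) == 0L) return(structure(list(), names = character()))
  key <- paste(subjectIds(es), epochLabels(es), sep = "|")
  groups <- split(seq_len(nTrials(es)), key)
  groups[order(names(groups))]
}

#' DTW distance matrix within a trial group
#'
#' Step 2: the summed per-channel DTW distance (\code{\link{epochDistance}})
#' is computed for every pair of trials in the group and stored symmetric
#' with zero diagonal.
#'
#' @param es an \code{\linkS4class{EpochSet}}.
#' @param indices integer vector of trial indices forming the group.
#' @inheritParams pairwiseCost
#' @return symmetric \code{K x K} matrix with zero diagonal;
#'   \code{dimnames} carry the trial IDs.
#' @export
buildDistanceMatrix <- function(es, indices,
                                metric = c("squared_euclidean", "euclidean")) {
  metric <- matchMetric(metric)
  if (length(indices) == 0L) stopSchema("group must be nonempty")
  K <- length(indices)
  dm <- matrix(0, K, K)
  eps <- lapply(indices, function(i) epochData(es, i))
  if (K > 1) {
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      d <- .epochDistanceC(eps[[i]], eps[[j]], metric == "squared_euclidean")
      dm[i, j] <- d
      dm[j, i] <- d
    }
  }
  ids <- trialIds(es)[indices]
  dimnames(dm) <- list(ids, ids)
  dm
}

#' Similar sample group of an anchor trial
#'
#' Step 3: the \code{N} trials of the group with the smallest DTW distance
#' to the anchor, the anchor itself always included (its self-distance 0 is
#' minimal). Distance ties are broken by ascending trial index, so the
#' result is deterministic. If \code{N} exceeds the group size the whole
#' group is returned.
#'
#' @param dm distance matrix from \code{\link{buildDistanceMatrix}}.
#' @param anchor index of the anchor trial within the group (1-based row of
#'   \code{dm}).
#' @param N similar-group size, \eqn{\ge 1}.
#' @return integer vector of member indices (rows of \code{dm}), ascending
#'   distance order.
#' @export
similarGroup <- function(dm, anchor, N) {
  K <- nrow(dm)
  if (anchor < 1L || anchor > K)
    stopSchema("anchor %d out of range 1..%d", anchor, K)
  if (N < 1L) stopSchema("N must be >= 1, got %s", toString(N))
  N <- min(N, K)
  ord <- order(dm[anchor, ], seq_len(K))
  members <- ord[seq_len(N)]
  stopifnot(anchor %in% members)
  members
}

#' Single-subject short-distance ERP averaging (SSE)
#'
#' Step 4, tying the pipeline together: for every trial, each channel column
#' is replaced by the Soft-DTW barycenter (\code{\link{solveBarycenter}})
#' of that channel across the trial's similar sample group, with uniform
#' weights and the anchor's own channel as initialisation. Averaging never
#' crosses subjects, labels, or channels, and the output dataset has exactly
#' the trial count, shapes and metadata of the input. \code{N = 1} returns
#' the input verbatim.
#'
#' @param es an \code{\linkS4class{EpochSet}}.
#' @param N similar-group size (number of trials averaged per anchor, the
#'   anchor included).
#' @param gamma Soft-DTW smoothing parameter (> 0, default 1).
#' @inheritParams pairwiseCost
#' @param maxIter,tol barycenter optimizer settings (see
#'   \code{\link{solveBarycenter}}).
#' @param cacheDir optional directory; per-group distance matrices are
#'   written there as CSV with a JSON index and reused on a rerun.
#' @param verbose print per-group progress.
#' @return an \code{\linkS4class{EpochSet}} of identical dimensions and
#'   manifest.
#' @export
sseAverage <- function(es, N, gamma = 1,
                       metric = c("squared_euclidean", "euclidean"),
                       maxIter = 100, tol = 1e-5, cacheDir = NULL,
                       verbose = FALSE) {
  stopifnot(is(es, "EpochSet"))
  if (N < 1L) stopSchema("N must be >= 1")
  if (gamma <= 0) stopSchema("gamma must be > 0, got %g", gamma)
  metric <- matchMetric(metric)
  if (N == 1L) return(es)  # identity by design: exact, no gamma drift
  out <- epochArray(es)
  groups <- groupTrials(es)
  for (gk in names(groups)) {
    idx <- groups[[gk]]
    dm <- cachedDistanceMatrix(es, idx, metric, cacheDir, gk)
    if (verbose)
      message(sprintf("SSE group %s: %d trials", gk, length(idx)))
    eps <- lapply(idx, function(i) epochData(es, i))
    for (a in seq_along(idx)) {
      members <- similarGroup(dm, a, N)
      for (ch in seq_len(nChannels(es))) {
        cols <- lapply(members, function(m) matrix(eps[[m]][, ch], nrow = 1))
        fit <- tryCatch(
          solveBarycenter(cols, gamma = gamma,
                          init = matrix(eps[[a]][, ch], nrow = 1),
                          maxIter = maxIter, tol = tol),
          error = function(e) stopNumeric(
            "barycenter failed for trial %s channel %d: %s",
            trialIds(es)[idx[a]], ch, conditionMessage(e)))
        out[, ch, idx[a]] <- as.numeric(fit$x)
      }
    }
  }
  new("EpochSet", epochs = out, manifest = manifest(es),
      channelNames = channelNames(es), samplingRate = samplingRate(es))
}

# disk cache: one CSV per group plus a JSON index mapping group keys to files
cachedDistanceMatrix <- function(es, idx, metric, cacheDir, groupKey) {
  if (is.null(cacheDir))
    return(buildDistanceMatrix(es, idx, metric))
  if (!dir.exists(cacheDir)) dir.create(cacheDir, recursive = TRUE)
  indexPath <- file.path(cacheDir, "index.json")
  index <- if (file.exists(indexPath))
    jsonlite::read_json(indexPath, simplifyVector = TRUE) else list()
  ids <- trialIds(es)[idx]
  fname <- paste0("dm_", gsub("[^A-Za-z0-9_-]", "_", groupKey), ".csv")
  entry <- index[[groupKey]]
  if (!is.null(entry) && identical(as.character(entry$trial_ids), ids) &&
      identical(entry$metric, metric) &&
      file.exists(file.path(cacheDir, entry$file))) {
    dt <- data.table::fread(file.path(cacheDir, entry$file))
    dm <- as.matrix(dt[, -1])
    dimnames(dm) <- list(dt[[1]], colnames(dm))
    return(dm)
  }
  dm <- buildDistanceMatrix(es, idx, metric)
  dt <- data.table::data.table(trial_id = rownames(dm))
  for (cn in colnames(dm)) dt[[cn]] <- dm[, cn]
  data.table::fwrite(dt, file.path(cacheDir, fname))
  index[[groupKey]] <- list(file = fname, metric = metric, trial_ids = ids)
  jsonlite::write_json(index, indexPath, auto_unbox = TRUE, pretty = TRUE)
  dm
}

#' Arithmetic analogue of SSE averaging
#'
#' Identical trial grouping and similar-group construction, but each channel
#' is replaced by the plain arithmetic mean over the similar group instead
#' of a Soft-DTW barycenter. Used as the comparison condition: with latency
#' jitter, arithmetic averaging flattens the component peak.
#'
#' @inheritParams sseAverage
#' @return an \code{\linkS4class{EpochSet}} of identical dimensions.
#' @export
arithmeticAverage <- function(es, N,
                              metric = c("squared_euclidean", "euclidean"),
                              cacheDir = NULL) {
  stopifnot(is(es, "EpochSet"))
  if (N < 1L) stopSchema("N must be >= 1")
  metric <- matchMetric(metric)
  if (N == 1L) return(es)
  out <- epochArray(es)
  groups <- groupTrials(es)
  for (gk in names(groups)) {
    idx <- groups[[gk]]
    dm <- cachedDistanceMatrix(es, idx, metric, cacheDir, gk)
    for (a in seq_along(idx)) {
      members <- similarGroup(dm, a, N)
      out[, , idx[a]] <- apply(epochArray(es)[, , idx[members], drop = FALSE],
                               c(1, 2), mean)
    }
  }
  new("EpochSet", epochs = out, manifest = manifest(es),
      channelNames = channelNames(es), samplingRate = samplingRate(es))
}
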