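#' Confusion counts for the two-condition ERP task
#'
#' \code{TR}: Related trials predicted Related; \code{TU}: Unrelated
#' predicted Unrelated; \code{FR}: Unrelated predicted Related;
#' \code{FU}: Related predicted Unrelated. The four counts always sum to the
#' number of evaluated trials.
#'
#' @param predicted,truth character vectors of labels
#'   (\code{"Related"}/\code{"Unrelated"}).
#' @return named list with integer \code{TR}, \code{TU}, \code{FR},
#'   \code{FU}.
#' @export
confusionCounts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  list(TR = sum(predicted == "Related" & truth == "Related"),
       TU = sum(predicted == "Unrelated" & truth == "Unrelated"),
       FR = sum(predicted == "Related" & truth == "Unrelated"),
       FU = sum(predicted == "Unrelated" & truth == "Related"))
}

#' Accuracy, precision and recall from confusion counts
#'
#' Related is the positive class:
#' \deqn{\mathrm{Accuracy} = (TR + TU)/(TR + TU + FR + FU),\quad
#'   \mathrm{Precision} = TR/(TR + FR),\quad
#'   \mathrm{Recall} = TR/(TR + FU).}
#' A degenerate denominator yields \code{NA} (undefined), never 0.
#'
#' @param counts list/row with \code{TR}, \code{TU}, \code{FR}, \code{FU}.
#' @return named list \code{accuracy}, \code{precision}, \code{recall}.
#' @examples
#' computeMetrics(list(TR = 9, TU = 8, FR = 1, FU = 2))
#' @export
computeMetrics <- function(counts) {
  TR <- counts$TR; TU <- counts$TU; FR <- counts$FR; FU <- counts$FU
  total <- TR + TU + FR + FU
  if (total <= 0) stopSchema("no evaluated trials")
  list(
    accuracy = (TR + TU) / total,
    precision = if (TR + FR > 0) TR / (TR + FR) else NA_real_,
    recall = if (TR + FU > 0) TR / (TR + FU) else NA_real_)
}

#' Subject-wise fold assignment
#'
#' Partitions the distinct subjects into \code{k} folds whose sizes differ
#' by at most one subject. By default subjects are taken in sorted order and
#' split into contiguous blocks; with \code{shuffle = TRUE} they are
#' permuted first under \code{seed}.
#'
#' @param subjects character vector of subject IDs (repeats allowed).
#' @param k number of folds (default 5).
#' @param seed seed for the optional shuffle.
#' @param shuffle permute subjects before splitting (default FALSE).
#' @return list of \code{k} character vectors of subject IDs.
#' @export
subjectFolds <- function(subjects, k = 5, seed = 1, shuffle = FALSE) {
  subj <- sort(unique(subjects))
  if (length(subj) < k)
    stopSchema("%d subjects cannot fill %d folds", length(subj), k)
  if (shuffle) subj <- withSeed(seed, sample(subj))
  sizes <- rep(length(subj) %/% k, k)
  extra <- length(subj) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  split(subj, rep(seq_len(k), sizes))
}

#' Subject-wise k-fold cross-validation of the ERP transformer
#'
#' For each fold, the model is trained on the remaining folds' subjects and
#' evaluated on the held-out subjects after every training epoch. Per-epoch
#' confusion counts are kept for every fold; accuracy/precision/recall are
#' averaged across folds within each epoch, and the epoch with the highest
#' mean accuracy is reported as the best result. No held-out trial ever
#' enters training (assignment is by whole subjects).
#'
#' @param es a labelled \code{\linkS4class{EpochSet}} (typically
#'   SSE-averaged).
#' @param config an \code{\link{erpTransformerConfig}} matching the epoch
#'   shape.
#' @param k folds (default 5).
#' @param epochs training epochs per fold (default 100).
#' @param batch minibatch size, capped at the fold training size
#'   (default 256).
#' @param lr Adam learning rate (default 5e-4).
#' @param seed seed governing folds (if shuffled), initialisation, shuffling
#'   and dropout.
#' @param shuffleFolds permute subjects before the contiguous split.
#' @param verbose per-fold progress.
#' @return list with \code{records} (data.frame: fold, epoch, TR, TU, FR,
#'   FU, accuracy, precision, recall), \code{epochMeans} (data.frame: epoch,
#'   fold-mean accuracy/precision/recall), \code{bestEpoch},
#'   \code{bestMeanAccuracy}, and \code{folds}.
#' @export
runCV <- function(es, config, k = 5, epochs = 100, batch = 256, lr = 5e-4,
                  seed = 1, shuffleFolds = FALSE, verbose = FALSE) {
  stopifnot(is(es, "EpochSet"))
  folds <- subjectFolds(subjectIds(es), k = k, seed = seed,
                        shuffle = shuffleFolds)
  recs <- list()
  for (f in seq_len(k)) {
    testMask <- subjectIds(es) %in% folds[[f]]
    trainSet <- es[!testMask]
    testSet <- es[testMask]
    if (verbose)
      message(sprintf("fold %d: %d train / %d test trials", f,
                      nTrials(trainSet), nTrials(testSet)))
    fit <- trainModel(trainSet, config, epochs = epochs, batch = batch,
                      lr = lr, seed = seed + f, evalSet = testSet)
    cc <- fit$evalCounts
    cc$fold <- f
    cc$epoch <- seq_len(epochs)
    met <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i)
      as.data.frame(computeMetrics(cc[i, ]))))
    recs[[f]] <- cbind(cc, met)
  }
  records <- do.call(rbind, recs)
  agg <- stats::aggregate(records[c("accuracy", "precision", "recall")],
                          by = list(epoch = records$epoch), mean,
                          na.rm = TRUE)
  best <- which.max(agg$accuracy)
  list(records = records, epochMeans = agg,
       bestEpoch = agg$epoch[best], bestMeanAccuracy = agg$accuracy[best],
       folds = folds)
}
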