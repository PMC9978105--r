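#' EpochSet: an ordered collection of fixed-length multichannel ERP epochs
#'
#' Container for trial-level ERP data: a 3-D numeric array of shape
#' \code{time x channel x trial} plus a per-trial manifest with subject ID,
#' condition label and trial ID, dataset-level channel names, and the
#' sampling rate in Hz. Labels are restricted to the two-class set
#' \code{"Related"} / \code{"Unrelated"}.
#'
#' @slot epochs numeric array, \code{time x channel x trial}.
#' @slot manifest \code{data.frame} with character columns
#'   \code{trial_id}, \code{subject_id}, \code{label}; one row per trial, in
#'   trial order.
#' @slot channelNames character vector, one name per channel.
#' @slot samplingRate sampling rate in Hz (scalar).
#'
#' @seealso \code{\link{EpochSet}} (constructor), \code{\link{epochData}},
#'   \code{\link{simulateEpochs}}
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    epochs = "array",
    manifest = "data.frame",
    channelNames = "character",
    samplingRate = "numeric"
  )
)

validEpochSet <- function(object) {
  msgs <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    return("epochs must be a 3-D array (time x channel x trial)")
  man <- object@manifest
  need <- c("trial_id", "subject_id", "label")
  if (!all(need %in% names(man)))
    msgs <- c(msgs, paste("manifest must have columns",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(man) != d[3])
      msgs <- c(msgs, sprintf("manifest has %d rows but array holds %d trials",
                              nrow(man), d[3]))
    bad <- setdiff(unique(man$label), c("Related", "Unrelated"))
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown label(s): %s (allowed: Related, Unrelated)",
                              paste(bad, collapse = ", ")))
    if (anyDuplicated(man$trial_id))
      msgs <- c(msgs, "trial_id values must be unique")
  }
  if (length(object@channelNames) != d[2])
    msgs <- c(msgs, sprintf("%d channel names for %d channels",
                            length(object@channelNames), d[2]))
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a positive scalar")
  if (d[3] > 0L && !all(is.finite(object@epochs)))
    msgs <- c(msgs, "epoch data must be finite")
  if (length(msgs)) msgs else TRUE
}

setValidity("EpochSet", validEpochSet)

#' Construct an EpochSet
#'
#' @param epochs numeric array \code{time x channel x trial}, or a list of
#'   \code{time x channel} matrices.
#' @param subjectId character vector of per-trial subject IDs.
#' @param label character vector of per-trial labels
#'   (\code{"Related"}/\code{"Unrelated"}).
#' @param trialId character vector of unique per-trial IDs; generated when
#'   missing.
#' @param channelNames character vector of channel names; defaults to
#'   \code{ch1..chK}.
#' @param samplingRate sampling rate in Hz (default 256).
#' @return An \code{\linkS4class{EpochSet}}.
#' @examples
#' ep <- array(rnorm(16 * 2 * 3), c(16, 2, 3))
#' es <- EpochSet(ep, subjectId = c("s1", "s1", "s2"),
#'                label = c("Related", "Unrelated", "Related"))
#' nTrials(es)
#' @export
EpochSet <- function(epochs, subjectId, label, trialId = NULL,
                     channelNames = NULL, samplingRate = 256) {
  if (is.list(epochs)) {
    if (length(epochs) == 0L)
      epochs <- array(numeric(0), c(0L, 0L, 0L))
    else {
      d <- dim(epochs[[1]])
      epochs <- array(unlist(epochs, use.names = FALSE),
                      c(d[1], d[2], length(epochs)))
    }
  }
  nt <- dim(epochs)[3]
  if (is.null(trialId))
    trialId <- sprintf("trial_%04d", seq_len(nt))
  if (is.null(channelNames))
    channelNames <- sprintf("ch%d", seq_len(dim(epochs)[2]))
  man <- data.frame(trial_id = as.character(trialId),
                    subject_id = as.character(subjectId),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  new("EpochSet", epochs = epochs, manifest = man,
      channelNames = as.character(channelNames),
      samplingRate = as.numeric(samplingRate))
}
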