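#' Write an EpochSet to a plain-text epoch store
#'
#' The store is a directory containing \code{meta.json} (format tag,
#' sampling rate, dimensions, channel names), \code{manifest.csv} (one row
#' per trial: trial_id, subject_id, label, in trial order) and
#' \code{signals.csv} (long-by-trial wide-by-channel: columns trial_id,
#' time, then one column per channel; \code{time} is the 0-based sample
#' index). Writing the same dataset twice produces byte-identical files.
#'
#' @param es an \code{\linkS4class{EpochSet}}.
#' @param path directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readEpochs}}
#' @export
writeEpochs <- function(es, path) {
  stopifnot(is(es, "EpochSet"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopSchema("cannot create epoch store at %s", path)
  }
  meta <- list(format = "erpsse-epochs-v1",
               sampling_rate = samplingRate(es),
               n_times = nTimes(es), n_channels = nChannels(es),
               n_trials = nTrials(es), channel_names = channelNames(es))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(manifest(es), file.path(path, "manifest.csv"))
  nt <- nTrials(es); nti <- nTimes(es); nch <- nChannels(es)
  sig <- data.table::data.table(
    trial_id = rep(trialIds(es), each = nti),
    time = rep.int(seq_len(nti) - 1L, nt))
  arr <- epochArray(es)
  for (c in seq_len(nch))
    sig[[channelNames(es)[c]]] <- as.numeric(arr[, c, ])
  data.table::fwrite(sig, file.path(path, "signals.csv"))
  invisible(path)
}

#' Read an EpochSet from a plain-text epoch store
#'
#' Round-trips the format written by \code{\link{writeEpochs}}; any schema
#' violation (missing files or fields, shape mismatches, unknown labels)
#' raises an error naming the offending trial or field.
#'
#' @param path store directory.
#' @return an \code{\linkS4class{EpochSet}}.
#' @export
readEpochs <- function(path) {
  metaPath <- file.path(path, "meta.json")
  manPath <- file.path(path, "manifest.csv")
  sigPath <- file.path(path, "signals.csv")
  for (p in c(metaPath, manPath, sigPath))
    if (!file.exists(p)) stopSchema("epoch store is missing %s", basename(p))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$format, "erpsse-epochs-v1"))
    stopSchema("unknown store format: %s", toString(meta$format))
  man <- as.data.frame(data.table::fread(manPath, colClasses = "character"))
  need <- c("trial_id", "subject_id", "label")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stopSchema("manifest is missing field(s): %s", paste(miss, collapse = ", "))
  badLab <- setdiff(unique(man$label), c("Related", "Unrelated"))
  if (length(badLab)) {
    off <- man$trial_id[man$label %in% badLab][1]
    stopSchema("unknown label '%s' for trial %s", badLab[1], off)
  }
  if (nrow(man) != meta$n_trials)
    stopSchema("manifest has %d trials but meta.json declares %d",
               nrow(man), meta$n_trials)
  channels <- as.character(meta$channel_names)
  if (length(channels) != meta$n_channels)
    stopSchema("%d channel names for declared %d channels",
               length(channels), meta$n_channels)
  if (nrow(man) == 0L) {
    return(EpochSet(array(numeric(0), c(meta$n_times, meta$n_channels, 0L)),
                    subjectId = character(), label = character(),
                    trialId = character(), channelNames = channels,
                    samplingRate = meta$sampling_rate))
  }
  sig <- data.table::fread(sigPath)
  missCh <- setdiff(channels, names(sig))
  if (length(missCh))
    stopSchema("signals.csv is missing channel column(s): %s",
               paste(missCh, collapse = ", "))
  if (nrow(sig) != meta$n_trials * meta$n_times)
    stopSchema("signals.csv has %d rows, expected %d trials x %d samples",
               nrow(sig), meta$n_trials, meta$n_times)
  # preserve manifest trial order
  ord <- match(sig$trial_id, man$trial_id)
  if (anyNA(ord)) {
    off <- sig$trial_id[which(is.na(ord))[1]]
    stopSchema("signals.csv references unknown trial %s", off)
  }
  arr <- array(0, c(meta$n_times, meta$n_channels, meta$n_trials))
  sig <- sig[order(ord, sig$time), ]
  for (c in seq_len(meta$n_channels))
    arr[, c, ] <- sig[[channels[c]]]
  EpochSet(arr, subjectId = man$subject_id, label = man$label,
           trialId = man$trial_id, channelNames = channels,
           samplingRate = meta$sampling_rate)
}

#' Save / load a trained classifier checkpoint
#'
#' Checkpoints are RDS files holding the model object (config, parameters,
#' positional-encoding table and normalisation statistics).
#'
#' @param model a trained model (\code{trainModel(...)$model}).
#' @param path file path (conventionally \code{.rds}).
#' @return \code{saveCheckpoint}: \code{path}, invisibly;
#'   \code{loadCheckpoint}: the model.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(inherits(model, "erpTransformer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "erpTransformer"))
    stopSchema("%s is not an erpTransformer checkpoint", path)
  m
}
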