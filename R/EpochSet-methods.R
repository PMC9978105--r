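#' @name EpochSet-accessors
#' @title Accessors for EpochSet objects
#' @description Retrieve dimensions, metadata and per-trial data from an
#'   \code{\linkS4class{EpochSet}}.
#' @param x,object an \code{EpochSet}.
#' @param i trial index (integer) for \code{epochData}; for \code{[}, any
#'   trial subscript (integer, logical or trial-ID character vector).
#' @return \code{epochData} returns the \code{time x channel} matrix of one
#'   trial; \code{epochArray} the full 3-D array; the remaining accessors
#'   return vectors or scalars.
NULL

#' @rdname EpochSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("nTimes", function(x) standardGeneric("nTimes"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochData", function(x, i) standardGeneric("epochData"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))
#' @rdname EpochSet-accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname EpochSet-accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@epochs)[3])
#' @rdname EpochSet-accessors
setMethod("nTimes", "EpochSet", function(x) dim(x@epochs)[1])
#' @rdname EpochSet-accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@epochs)[2])
#' @rdname EpochSet-accessors
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname EpochSet-accessors
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname EpochSet-accessors
setMethod("subjectIds", "EpochSet", function(x) x@manifest$subject_id)
#' @rdname EpochSet-accessors
setMethod("trialIds", "EpochSet", function(x) x@manifest$trial_id)
#' @rdname EpochSet-accessors
setMethod("epochLabels", "EpochSet", function(x) x@manifest$label)
#' @rdname EpochSet-accessors
setMethod("manifest", "EpochSet", function(x) x@manifest)

#' @rdname EpochSet-accessors
setMethod("epochData", "EpochSet", function(x, i) {
  if (length(i) != 1L || i < 1L || i > nTrials(x))
    stopSchema("trial index %s out of range 1..%d", toString(i), nTrials(x))
  m <- x@epochs[, , i, drop = FALSE]
  dim(m) <- dim(x@epochs)[1:2]
  colnames(m) <- x@channelNames
  m
})

#' @rdname EpochSet-accessors
setMethod("epochArray", "EpochSet", function(x) x@epochs)

#' @rdname EpochSet-accessors
#' @param j,drop,... ignored (trial subsetting only).
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, trialIds(x))
  if (is.logical(i)) i <- which(i)
  if (anyNA(i) || any(i < 1L) || any(i > nTrials(x)))
    stopSchema("trial subscript out of range")
  new("EpochSet",
      epochs = x@epochs[, , i, drop = FALSE],
      manifest = x@manifest[i, , drop = FALSE],
      channelNames = x@channelNames,
      samplingRate = x@samplingRate)
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d trials x %d samples x %d channels @ %g Hz\n",
              nTrials(object), nTimes(object), nChannels(object),
              samplingRate(object)))
  if (nTrials(object) > 0) {
    tab <- table(subject = subjectIds(object), label = epochLabels(object))
    cat(sprintf("subjects: %d  labels: %s\n",
                nrow(tab), paste(sprintf("%s=%d", colnames(tab),
                                         colSums(tab)), collapse = " ")))
  }
  invisible(NULL)
})
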