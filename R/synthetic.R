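# 35-channel montage retained after N400 preprocessing (10-20 names plus
# EOG derivatives); topography weights peak over centro-parietal sites where
# the N400 is maximal and are near zero on the ocular channels.
n400Channels <- c(
  "FP1", "F3", "F7", "FC3", "C3", "C5", "P3", "P7", "PO7", "PO3", "O1",
  "Oz", "Pz", "CPz", "FP2", "Fz", "F4", "F8", "FC4", "FCz", "Cz", "C4",
  "C6", "P4", "P8", "PO8", "PO4", "O2", "HEOG_left", "HEOG_right",
  "VEOG_lower", "HEOG_corr", "VEOG_corr", "HEOG_uncorr", "VEOG_uncorr")

n400Topography <- c(
  FP1 = 0.25, F3 = 0.35, F7 = 0.30, FC3 = 0.55, C3 = 0.70, C5 = 0.60,
  P3 = 0.80, P7 = 0.60, PO7 = 0.50, PO3 = 0.60, O1 = 0.40, Oz = 0.45,
  Pz = 0.95, CPz = 1.00, FP2 = 0.25, Fz = 0.50, F4 = 0.35, F8 = 0.30,
  FC4 = 0.55, FCz = 0.65, Cz = 0.90, C4 = 0.70, C6 = 0.60, P4 = 0.80,
  P8 = 0.60, PO8 = 0.50, PO4 = 0.60, O2 = 0.40, HEOG_left = 0.05,
  HEOG_right = 0.05, VEOG_lower = 0.05, HEOG_corr = 0.05, VEOG_corr = 0.05,
  HEOG_uncorr = 0.05, VEOG_uncorr = 0.05)

#' Configuration for the synthetic N400 epoch generator
#'
#' Defines the statistical structure the SSE method assumes: a negative
#' Gaussian-bump deflection centred near 400 ms post-stimulus, larger in
#' amplitude for Related-condition trials, with non-phase-locked latency
#' jitter across trials, a per-subject amplitude factor, a fixed scalp
#' topography, and additive white noise. Amplitudes are in microvolts
#' (negative = the N400 deflection); times in milliseconds. The epoch window
#' is [0, seqLen/samplingRate) seconds post-stimulus with 0-based sample
#' indexing, so 400 ms maps to sample \code{floor(0.4 * samplingRate)}.
#'
#' @param nSubjects number of subjects (default 40).
#' @param trialsPerLabel trials per subject per label (default 30).
#' @param seqLen samples per epoch (default 256).
#' @param nChannels channels per epoch (default 35); for fewer than 35 the
#'   montage is subsampled evenly across the 35-name list.
#' @param samplingRate Hz; defaults to \code{seqLen} so that an epoch always
#'   spans the 1-second post-stimulus window and the 400 ms component stays
#'   inside it at any temporal scale (256 Hz at the full 256-sample scale).
#' @param amplitudeRelated,amplitudeUnrelated peak N400 amplitude in uV for
#'   the two conditions; both negative, Related larger in magnitude
#'   (defaults -8 and -4).
#' @param center bump centre in ms post-stimulus (default 400).
#' @param width bump standard deviation in ms (default 50).
#' @param jitterSd per-trial latency jitter standard deviation in ms
#'   (default 40): the non-phase-locking that defeats arithmetic averaging.
#' @param subjectAmplitudeSd standard deviation of the per-subject
#'   multiplicative amplitude factor around 1 (default 0.2).
#' @param noiseSd additive white-noise standard deviation in uV
#'   (default 1.3).
#' @param topography named per-channel weight vector in [0, 1]; defaults to
#'   a centro-parietal-maximal map over the 35-channel montage.
#' @param seed RNG seed making generation deterministic.
#' @return a \code{syntheticConfig} list.
#' @export
syntheticConfig <- function(nSubjects = 40, trialsPerLabel = 30,
                            seqLen = 256, nChannels = 35,
                            samplingRate = seqLen,
                            amplitudeRelated = -8, amplitudeUnrelated = -4,
                            center = 400, width = 50, jitterSd = 40,
                            subjectAmplitudeSd = 0.2, noiseSd = 1.3,
                            topography = NULL, seed = 1) {
  if (abs(amplitudeRelated) <= abs(amplitudeUnrelated))
    stopSchema("|amplitudeRelated| must exceed |amplitudeUnrelated|")
  if (jitterSd < 0 || noiseSd < 0 || subjectAmplitudeSd < 0)
    stopSchema("standard deviations must be >= 0")
  # reduced montages span the scalp the way real sparse EEG montages do:
  # channels at evenly spaced ranks of the topography, so the montage always
  # includes the component maximum (CPz) and heterogeneous weaker sites
  channels <- if (nChannels == 35L) n400Channels
    else {
      if (nChannels > 35L)
        stopSchema("at most 35 channels are available, got %d", nChannels)
      ranked <- names(sort(n400Topography, decreasing = TRUE))
      keep <- ranked[round(seq(1, 35, length.out = nChannels))]
      n400Channels[n400Channels %in% keep]
    }
  if (is.null(topography)) topography <- n400Topography[channels]
  if (length(topography) != nChannels)
    stopSchema("%d topography weights for %d channels",
               length(topography), nChannels)
  structure(list(
    nSubjects = nSubjects, trialsPerLabel = trialsPerLabel, seqLen = seqLen,
    nChannels = nChannels, samplingRate = samplingRate,
    amplitudeRelated = amplitudeRelated,
    amplitudeUnrelated = amplitudeUnrelated,
    center = center, width = width, jitterSd = jitterSd,
    subjectAmplitudeSd = subjectAmplitudeSd, noiseSd = noiseSd,
    channels = channels, topography = topography, seed = seed),
    class = "syntheticConfig")
}

#' Generate a synthetic N400-like epoch dataset
#'
#' Each trial is \code{topography (outer) bump + noise}, where the bump is a
#' negative Gaussian deflection of per-condition amplitude scaled by a
#' per-subject factor, centred at \code{floor(0.4 * samplingRate)} samples
#' plus a per-trial latency jitter. Labels are balanced per subject.
#' Deterministic for a fixed \code{config$seed}.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return an \code{\linkS4class{EpochSet}} with
#'   \code{nSubjects * 2 * trialsPerLabel} trials.
#' @examples
#' es <- simulateEpochs(syntheticConfig(nSubjects = 2, trialsPerLabel = 3,
#'                                      seqLen = 64, nChannels = 8))
#' nTrials(es)
#' @export
simulateEpochs <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  withSeed(config$seed, {
    fs <- config$samplingRate
    centerSample <- floor(config$center / 1000 * fs)  # 0-based
    widthSamples <- config$width / 1000 * fs
    s <- seq_len(config$seqLen) - 1
    nPer <- 2L * config$trialsPerLabel
    nTot <- config$nSubjects * nPer
    arr <- array(0, c(config$seqLen, config$nChannels, nTot))
    subj <- character(nTot); lab <- character(nTot); tid <- character(nTot)
    k <- 0L
    for (si in seq_len(config$nSubjects)) {
      sFactor <- max(0.2, rnorm(1, 1, config$subjectAmplitudeSd))
      for (label in c("Related", "Unrelated")) {
        amp <- if (label == "Related") config$amplitudeRelated
               else config$amplitudeUnrelated
        for (ti in seq_len(config$trialsPerLabel)) {
          k <- k + 1L
          jit <- if (config$jitterSd > 0)
            rnorm(1, 0, config$jitterSd) / 1000 * fs else 0
          bump <- amp * sFactor *
            exp(-((s - centerSample - jit)^2) / (2 * widthSamples^2))
          trial <- outer(bump, as.numeric(config$topography))
          if (config$noiseSd > 0)
            trial <- trial + matrix(rnorm(length(trial), 0, config$noiseSd),
                                    nrow = config$seqLen)
          arr[, , k] <- trial
          subj[k] <- sprintf("S%02d", si)
          lab[k] <- label
          tid[k] <- sprintf("S%02d_%s_%03d", si, label, ti)
        }
      }
    }
    EpochSet(arr, subjectId = subj, label = lab, trialId = tid,
             channelNames = config$channels, samplingRate = fs)
  })
}

#' Shifted-bump fixture for barycenter tests
#'
#' Generates \code{nCopies} identical unimodal (Gaussian) bumps with random
#' integer latency shifts — the minimal model of a non-phase-locked ERP
#' component. The arithmetic mean of such copies has a flattened peak; a
#' DTW-based barycenter should preserve it.
#'
#' @param nCopies number of copies (\eqn{\ge 2}).
#' @param shiftSd standard deviation of the integer shifts, in samples.
#' @param seed RNG seed.
#' @param len series length (default 128).
#' @param center bump centre in samples (default \code{len / 2}).
#' @param width bump standard deviation in samples (default \code{len / 16}).
#' @param amplitude bump peak (default -5, an N400-like deflection).
#' @return list of \code{1 x len} series matrices.
#' @export
bumpSeries <- function(nCopies, shiftSd, seed = 1, len = 128,
                       center = len / 2, width = len / 16, amplitude = -5) {
  if (nCopies < 2) stopSchema("nCopies must be >= 2")
  withSeed(seed, {
    s <- seq_len(len) - 1
    lapply(seq_len(nCopies), function(i) {
      shift <- if (shiftSd > 0) round(rnorm(1, 0, shiftSd)) else 0
      matrix(amplitude * exp(-((s - center - shift)^2) / (2 * width^2)),
             nrow = 1)
    })
  })
}
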