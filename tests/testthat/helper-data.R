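# small EpochSet builders used across test files

smallEpochSet <- function(nSubjects = 2, trialsPerLabel = 3, seqLen = 16,
                          nChannels = 3, noiseSd = 1, seed = 42) {
  simulateEpochs(syntheticConfig(
    nSubjects = nSubjects, trialsPerLabel = trialsPerLabel, seqLen = seqLen,
    nChannels = nChannels, noiseSd = noiseSd, jitterSd = 20, seed = seed))
}

tinyModelConfig <- function(seqLen = 6, inputDim = 4, dropoutP = 0) {
  erpTransformerConfig(seqLen = seqLen, inputDim = inputDim,
                       numEncoders = 2, numHeads = 2, headDim = 3,
                       dropoutP = dropoutP, ffnHidden = 5)
}
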