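test_that("metrics reproduce hand-computed values, including degenerate denominators", {
  m <- computeMetrics(list(TR = 5, TU = 5, FR = 0, FU = 0))
  expect_equal(m, list(accuracy = 1, precision = 1, recall = 1))
  m <- computeMetrics(list(TR = 9, TU = 8, FR = 1, FU = 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11)
  m <- computeMetrics(list(TR = 0, TU = 10, FR = 0, FU = 5))
  expect_equal(m$accuracy, 10 / 15)
  expect_true(is.na(m$precision))   # undefined, not 0
  expect_equal(m$recall, 0)
  m <- computeMetrics(list(TR = 0, TU = 3, FR = 2, FU = 0))
  expect_true(is.na(m$recall))
  expect_error(computeMetrics(list(TR = 0, TU = 0, FR = 0, FU = 0)),
               "no evaluated trials")
})

test_that("confusion counts partition the evaluated trials", {
  set.seed(12)
  truth <- sample(c("Related", "Unrelated"), 50, replace = TRUE)
  pred <- sample(c("Related", "Unrelated"), 50, replace = TRUE)
  cc <- confusionCounts(pred, truth)
  expect_equal(cc$TR + cc$TU + cc$FR + cc$FU, 50)
  expect_equal(cc$TR + cc$FU, sum(truth == "Related"))
  expect_equal(cc$TR + cc$FR, sum(pred == "Related"))
})

test_that("subject folds are disjoint, exhaustive and balanced", {
  subj <- sprintf("S%02d", 1:40)
  f <- subjectFolds(rep(subj, each = 3), k = 5)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 8))
  expect_setequal(unlist(f), subj)
  expect_equal(anyDuplicated(unlist(f)), 0L)
  # uneven split differs by at most one
  f7 <- subjectFolds(sprintf("S%d", 1:7), k = 3)
  expect_true(max(lengths(f7)) - min(lengths(f7)) <= 1)
  # seeded shuffle is reproducible and differs from sorted blocks
  fs1 <- subjectFolds(subj, k = 5, seed = 7, shuffle = TRUE)
  fs2 <- subjectFolds(subj, k = 5, seed = 7, shuffle = TRUE)
  expect_identical(fs1, fs2)
  expect_error(subjectFolds(c("a", "b"), k = 5), "cannot fill")
})

test_that("cross-validation isolates held-out subjects and tracks the best epoch", {
  es <- smallEpochSet(nSubjects = 5, trialsPerLabel = 3, seqLen = 8,
                      nChannels = 3)
  cfg <- erpTransformerConfig(seqLen = 8, inputDim = 3, numEncoders = 1,
                              numHeads = 2, headDim = 3, ffnHidden = 4,
                              dropoutP = 0.25)
  cv <- runCV(es, cfg, k = 5, epochs = 3, batch = 8, seed = 2)
  expect_equal(nrow(cv$records), 5 * 3)
  expect_equal(nrow(cv$epochMeans), 3)
  expect_equal(cv$bestEpoch,
               cv$epochMeans$epoch[which.max(cv$epochMeans$accuracy)])
  expect_equal(cv$bestMeanAccuracy, max(cv$epochMeans$accuracy))
  # each fold evaluates exactly its held-out subject's trials
  for (f in 1:5) {
    nHeld <- sum(subjectIds(es) %in% cv$folds[[f]])
    rec <- cv$records[cv$records$fold == f, ]
    expect_true(all(rec$TR + rec$TU + rec$FR + rec$FU == nHeld))
  }
  # fold subject sets are disjoint
  expect_equal(anyDuplicated(unlist(cv$folds)), 0L)
})
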