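test_that("positional encoding matches the generating function cell by cell", {
  pe <- positionalEncoding(10, 6)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(pe[1, ], c(0, 1, 0, 1, 0, 1))
  for (t in 0:9) for (i0 in 0:5) {
    k <- i0 %/% 2
    omega <- 1 / 10000^(2 * k / 6)
    expected <- if (i0 %% 2 == 0) sin(omega * t) else cos(omega * t)
    expect_equal(pe[t + 1, i0 + 1], expected)
  }
})

test_that("configured encoder and head counts are instantiated", {
  cfg <- erpTransformerConfig(seqLen = 8, inputDim = 4, numEncoders = 3,
                              numHeads = 5, headDim = 4)
  m <- erpTransformer(cfg, seed = 1)
  expect_length(m$params$encoders, 3)
  expect_length(m$params$encoders[[1]]$WQ, 5)
  expect_equal(dim(m$params$Wc), c(8 * 4, 2))
  expect_equal(cfg$attnScale, 5^-0.5)
})

test_that("forward pass conserves shape and yields normalised probabilities", {
  cfg <- tinyModelConfig()
  m <- erpTransformer(cfg, seed = 2)
  set.seed(1)
  batch <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  out <- modelForward(m, batch)
  expect_equal(dim(out$probs), c(4, 2))
  expect_equal(rowSums(out$probs), rep(1, 4), tolerance = 1e-12)
  # eval mode is deterministic
  out2 <- modelForward(m, batch)
  expect_identical(out$logits, out2$logits)
  expect_error(modelForward(m, matrix(0, 5, 4)), "\\(6, 4\\)")
})

test_that("attention softmax rows sum to 1 and constant input gives constant output", {
  cfg <- tinyModelConfig()
  m <- erpTransformer(cfg, seed = 3)
  X <- matrix(rep(rnorm(4), each = 6), 6, 4)  # constant in time
  fw <- erpsse:::forwardSample(m, X, train = TRUE, usePE = FALSE)
  for (e in 1:2) for (a in 1:2) {
    P <- fw$cache$encoders[[e]]$heads[[a]]$P
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12)
  }
  lastRowDiffs <- apply(fw$cache$encoders[[2]]$ln2$out, 2,
                        function(col) max(col) - min(col))
  expect_true(all(lastRowDiffs < 1e-8))
})

test_that("without positional encoding the stack is permutation-equivariant; with it, not", {
  cfg <- tinyModelConfig()
  m <- erpTransformer(cfg, seed = 4)
  set.seed(2)
  X <- matrix(rnorm(24), 6, 4)
  perm <- c(3, 1, 6, 2, 5, 4)
  encOut <- function(X, usePE) {
    fw <- erpsse:::forwardSample(m, X, train = TRUE, usePE = usePE)
    fw$cache$encoders[[2]]$ln2$out
  }
  expect_equal(encOut(X[perm, ], usePE = FALSE),
               encOut(X, usePE = FALSE)[perm, ], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(encOut(X[perm, ], usePE = TRUE),
                                encOut(X, usePE = TRUE)[perm, ])))
})

test_that("layer-normalised rows have near-zero mean and unit variance", {
  cfg <- tinyModelConfig()
  m <- erpTransformer(cfg, seed = 5)
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  fw <- erpsse:::forwardSample(m, X, train = TRUE)
  zhat <- fw$cache$encoders[[1]]$ln1$Zhat
  expect_equal(rowMeans(zhat), rep(0, 6), tolerance = 1e-10)
  expect_equal(rowMeans(zhat^2), rep(1, 6), tolerance = 1e-3)
})

test_that("parameter gradients agree with central finite differences", {
  cfg <- tinyModelConfig(dropoutP = 0)
  m <- erpTransformer(cfg, seed = 6)
  set.seed(4)
  X <- matrix(rnorm(24), 6, 4)
  y <- 2L
  fw <- erpsse:::forwardSample(m, X, train = TRUE)
  dl <- fw$probs; dl[y] <- dl[y] - 1
  g <- erpsse:::backwardSample(m, fw$cache, dl)
  lossAt <- function(params) {
    m2 <- m; m2$params <- params
    -log(erpsse:::forwardSample(m2, X, train = FALSE)$probs[y])
  }
  h <- 1e-5
  checkLeaf <- function(getter, setter, gleaf) {
    vals <- getter(m$params)
    idx <- sample(seq_along(vals), min(3, length(vals)))
    for (i in idx) {
      pp <- m$params; pm <- m$params
      pp <- setter(pp, i, vals[i] + h)
      pm <- setter(pm, i, vals[i] - h)
      num <- (lossAt(pp) - lossAt(pm)) / (2 * h)
      expect_equal(gleaf[i], num, tolerance = 1e-4)
    }
  }
  checkLeaf(function(p) p$encoders[[1]]$L1$W,
            function(p, i, v) { p$encoders[[1]]$L1$W[i] <- v; p },
            g$encoders[[1]]$L1$W)
  checkLeaf(function(p) p$encoders[[2]]$WQ[[1]],
            function(p, i, v) { p$encoders[[2]]$WQ[[1]][i] <- v; p },
            g$encoders[[2]]$WQ[[1]])
  checkLeaf(function(p) p$encoders[[1]]$WO,
            function(p, i, v) { p$encoders[[1]]$WO[i] <- v; p },
            g$encoders[[1]]$WO)
  checkLeaf(function(p) p$encoders[[2]]$ln1g,
            function(p, i, v) { p$encoders[[2]]$ln1g[i] <- v; p },
            g$encoders[[2]]$ln1g)
  checkLeaf(function(p) p$encoders[[1]]$W1,
            function(p, i, v) { p$encoders[[1]]$W1[i] <- v; p },
            g$encoders[[1]]$W1)
  checkLeaf(function(p) p$Wc,
            function(p, i, v) { p$Wc[i] <- v; p },
            g$Wc)
})

test_that("training is seed-reproducible and untrained accuracy is near chance", {
  cfg <- tinyModelConfig(dropoutP = 0.5)
  es <- smallEpochSet(nSubjects = 2, trialsPerLabel = 4, seqLen = 6,
                      nChannels = 4)
  f1 <- trainModel(es, cfg, epochs = 2, batch = 4, seed = 9)
  f2 <- trainModel(es, cfg, epochs = 2, batch = 4, seed = 9)
  expect_identical(f1$losses, f2$losses)
  expect_identical(f1$model$params, f2$model$params)
  # untrained model on balanced random inputs: accuracy ~ chance
  m <- erpTransformer(cfg, seed = 10)
  m$norm <- list(mu = 0, sd = 1)
  set.seed(11)
  n <- 400
  xs <- array(rnorm(6 * 4 * n), c(6, 4, n))
  truth <- rep(c("Related", "Unrelated"), n / 2)
  pred <- predictEpochs(m, xs)
  acc <- mean(pred == truth)
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})
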