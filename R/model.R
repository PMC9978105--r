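#' Sinusoidal positional encoding
#'
#' The standard geometric-frequency sin/cos table added elementwise to the
#' input epoch before the encoder stack: with 0-based position \eqn{t} and
#' 0-based dimension index \eqn{i}, entry \eqn{(t, i)} is
#' \eqn{\sin(\omega_k t)} for \eqn{i = 2k} and \eqn{\cos(\omega_k t)} for
#' \eqn{i = 2k + 1}, with \eqn{\omega_k = 1/10000^{2k/\mathrm{dim}}}.
#'
#' @param seqLen number of time steps.
#' @param dim input dimension (channels).
#' @return \code{seqLen x dim} matrix with entries in \eqn{[-1, 1]}; row
#'   \eqn{t = 0} is 0 at even and 1 at odd (0-based) indices.
#' @export
positionalEncoding <- function(seqLen, dim) {
  stopifnot(seqLen >= 1, dim >= 1)
  t <- seq_len(seqLen) - 1
  pe <- matrix(0, seqLen, dim)
  for (i0 in 0:(dim - 1)) {
    k <- i0 %/% 2
    omega <- 1 / 10000^(2 * k / dim)
    pe[, i0 + 1] <- if (i0 %% 2 == 0) sin(omega * t) else cos(omega * t)
  }
  pe
}

#' Configuration of the ERP transformer classifier
#'
#' A decoder-free transformer for fixed-length multichannel epochs: additive
#' sinusoidal positional encoding and dropout, \code{numEncoders} identical
#' encoder blocks (multi-head self-attention with per-head dimension
#' \code{headDim}, residual connections and layer normalisation, a two-layer
#' position-wise feedforward), then a flatten and a single linear layer to
#' \code{numClasses} logits with softmax. Heads project from the shared
#' \code{inputDim}-wide Q/K/V maps to \code{headDim} each; head outputs are
#' concatenated and projected back to \code{inputDim}. Attention scores are
#' multiplied by \code{attnScale} (default \eqn{\mathrm{numHeads}^{-1/2}};
#' set \code{headDim^-0.5} for the conventional scaling).
#'
#' @param seqLen epoch length in samples (default 256).
#' @param inputDim channels per sample (default 35).
#' @param numEncoders encoder blocks (default 3).
#' @param numHeads attention heads per block (default 5).
#' @param headDim per-head dimension (default \code{inputDim}).
#' @param dropoutP dropout probability in \eqn{[0, 1)} (default 0.5).
#' @param ffnHidden hidden width of the feedforward sub-block (default 64).
#' @param attnScale multiplier on raw attention scores.
#' @param numClasses output classes (default 2).
#' @return an \code{erpTransformerConfig} list.
#' @export
erpTransformerConfig <- function(seqLen = 256, inputDim = 35,
                                 numEncoders = 3, numHeads = 5,
                                 headDim = inputDim, dropoutP = 0.5,
                                 ffnHidden = 64,
                                 attnScale = numHeads^-0.5,
                                 numClasses = 2) {
  stopifnot(numHeads >= 1, dropoutP >= 0, dropoutP < 1, seqLen >= 1,
            inputDim >= 1, numEncoders >= 1, ffnHidden >= 1)
  structure(list(seqLen = seqLen, inputDim = inputDim,
                 numEncoders = numEncoders, numHeads = numHeads,
                 headDim = headDim, dropoutP = dropoutP,
                 ffnHidden = ffnHidden, attnScale = attnScale,
                 numClasses = numClasses),
            class = "erpTransformerConfig")
}

glorot <- function(fin, fout) {
  a <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -a, a), fin, fout)
}

#' Initialise an ERP transformer
#'
#' Glorot-uniform weight initialisation, zero biases, unit layer-norm gains.
#' Deterministic for a fixed seed.
#'
#' @param config an \code{\link{erpTransformerConfig}}.
#' @param seed RNG seed for the initial weights.
#' @return an \code{erpTransformer} object (config + parameter list).
#' @export
erpTransformer <- function(config, seed = 1) {
  stopifnot(inherits(config, "erpTransformerConfig"))
  d <- config$inputDim; hd <- config$headDim; H <- config$numHeads
  Fh <- config$ffnHidden
  params <- withSeed(seed, {
    encoders <- lapply(seq_len(config$numEncoders), function(e) {
      list(
        L1 = list(W = glorot(d, d), b = numeric(d)),
        L2 = list(W = glorot(d, d), b = numeric(d)),
        L3 = list(W = glorot(d, d), b = numeric(d)),
        WQ = lapply(seq_len(H), function(a) glorot(d, hd)),
        WK = lapply(seq_len(H), function(a) glorot(d, hd)),
        WV = lapply(seq_len(H), function(a) glorot(d, hd)),
        WO = glorot(H * hd, d), bO = numeric(d),
        ln1g = rep(1, d), ln1b = numeric(d),
        W1 = glorot(d, Fh), b1 = numeric(Fh),
        W2 = glorot(Fh, d), b2 = numeric(d),
        ln2g = rep(1, d), ln2b = numeric(d))
    })
    list(encoders = encoders,
         Wc = glorot(config$seqLen * d, config$numClasses),
         bc = numeric(config$numClasses))
  })
  structure(list(config = config, params = params,
                 pe = positionalEncoding(config$seqLen, d)),
            class = "erpTransformer")
}

# add a row vector to every row / scale columns, via column-major recycling
addRow <- function(X, b) X + rep(b, each = nrow(X))
mulRow <- function(X, g) X * rep(g, each = nrow(X))

layerNormForward <- function(Z, g, b, eps = 1e-5) {
  mu <- rowMeans(Z)
  Zc <- Z - mu
  v <- rowMeans(Zc^2)
  inv <- 1 / sqrt(v + eps)
  Zhat <- Zc * inv
  out <- addRow(mulRow(Zhat, g), b)
  list(out = out, Zhat = Zhat, inv = inv)
}

layerNormBackward <- function(dOut, cache, g) {
  dZhat <- mulRow(dOut, g)
  m1 <- rowMeans(dZhat)
  m2 <- rowMeans(dZhat * cache$Zhat)
  dZ <- (dZhat - m1 - cache$Zhat * m2) * cache$inv
  list(dZ = dZ,
       dg = colSums(dOut * cache$Zhat),
       db = colSums(dOut))
}

dropoutForward <- function(X, p, train) {
  if (!train || p == 0) return(list(out = X, mask = NULL))
  mask <- matrix(runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(out = X * mask, mask = mask)
}

dropoutBackward <- function(dOut, mask) {
  if (is.null(mask)) dOut else dOut * mask
}

rowSoftmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# forward pass on one sample (seq x d matrix); returns logits, probs and,
# when train = TRUE, the cache needed by the backward pass
forwardSample <- function(model, X, train = FALSE, usePE = TRUE) {
  cfg <- model$config; P <- model$params
  if (!is.matrix(X) || nrow(X) != cfg$seqLen || ncol(X) != cfg$inputDim)
    stopSchema("epoch shape %s does not match the expected (%d, %d)",
               paste(dim(X), collapse = " x "), cfg$seqLen, cfg$inputDim)
  cache <- list(encoders = vector("list", cfg$numEncoders))
  X0 <- if (usePE) X + model$pe else X
  d0 <- dropoutForward(X0, cfg$dropoutP, train)
  cache$mask0 <- d0$mask
  A <- d0$out
  for (e in seq_len(cfg$numEncoders)) {
    pe <- P$encoders[[e]]
    ec <- list(Ain = A)
    Q0 <- addRow(A %*% pe$L1$W, pe$L1$b)
    K0 <- addRow(A %*% pe$L2$W, pe$L2$b)
    V0 <- addRow(A %*% pe$L3$W, pe$L3$b)
    ec$Q0 <- Q0; ec$K0 <- K0; ec$V0 <- V0
    heads <- vector("list", cfg$numHeads)
    Hcat <- matrix(0, cfg$seqLen, cfg$numHeads * cfg$headDim)
    for (a in seq_len(cfg$numHeads)) {
      Qa <- Q0 %*% pe$WQ[[a]]
      Ka <- K0 %*% pe$WK[[a]]
      Va <- V0 %*% pe$WV[[a]]
      Pm <- rowSoftmax(tcrossprod(Qa, Ka) * cfg$attnScale)
      Ha <- Pm %*% Va
      heads[[a]] <- list(Qa = Qa, Ka = Ka, Va = Va, P = Pm)
      Hcat[, ((a - 1) * cfg$headDim + 1):(a * cfg$headDim)] <- Ha
    }
    ec$heads <- heads; ec$Hcat <- Hcat
    O <- addRow(Hcat %*% pe$WO, pe$bO)
    dO <- dropoutForward(O, cfg$dropoutP, train)
    ec$maskO <- dO$mask
    R1 <- A + dO$out
    ln1 <- layerNormForward(R1, pe$ln1g, pe$ln1b)
    ec$ln1 <- ln1
    N1 <- ln1$out
    Z1 <- addRow(N1 %*% pe$W1, pe$b1)
    ec$reluMask <- Z1 > 0
    F1 <- Z1 * ec$reluMask
    ec$F1 <- F1
    F2 <- addRow(F1 %*% pe$W2, pe$b2)
    dF <- dropoutForward(F2, cfg$dropoutP, train)
    ec$maskF <- dF$mask
    R2 <- N1 + dF$out
    ln2 <- layerNormForward(R2, pe$ln2g, pe$ln2b)
    ec$ln2 <- ln2
    ec$N1 <- N1
    A <- ln2$out
    cache$encoders[[e]] <- ec
  }
  z <- as.numeric(A)
  logits <- as.numeric(z %*% P$Wc + P$bc)
  m <- max(logits)
  probs <- exp(logits - m); probs <- probs / sum(probs)
  cache$z <- z
  list(logits = logits, probs = probs, cache = if (train) cache else NULL)
}

# backward pass for one sample given its forward cache and dlogits;
# returns gradients with the same nesting as model$params
backwardSample <- function(model, cache, dlogits) {
  cfg <- model$config; P <- model$params
  g <- list(encoders = vector("list", cfg$numEncoders))
  g$Wc <- outer(cache$z, dlogits)
  g$bc <- dlogits
  dz <- as.numeric(P$Wc %*% dlogits)
  dA <- matrix(dz, cfg$seqLen, cfg$inputDim)
  for (e in rev(seq_len(cfg$numEncoders))) {
    pe <- P$encoders[[e]]
    ec <- cache$encoders[[e]]
    ge <- list()
    ln2b <- layerNormBackward(dA, ec$ln2, pe$ln2g)
    ge$ln2g <- ln2b$dg; ge$ln2b <- ln2b$db
    dR2 <- ln2b$dZ
    dN1 <- dR2
    dF2 <- dropoutBackward(dR2, ec$maskF)
    ge$W2 <- crossprod(ec$F1, dF2)
    ge$b2 <- colSums(dF2)
    dF1 <- tcrossprod(dF2, pe$W2) * ec$reluMask
    ge$W1 <- crossprod(ec$ln1$out, dF1)
    ge$b1 <- colSums(dF1)
    dN1 <- dN1 + tcrossprod(dF1, pe$W1)
    ln1b <- layerNormBackward(dN1, ec$ln1, pe$ln1g)
    ge$ln1g <- ln1b$dg; ge$ln1b <- ln1b$db
    dR1 <- ln1b$dZ
    dAin <- dR1                       # residual branch
    dOdrop <- dropoutBackward(dR1, ec$maskO)
    ge$WO <- crossprod(ec$Hcat, dOdrop)
    ge$bO <- colSums(dOdrop)
    dHcat <- tcrossprod(dOdrop, pe$WO)
    dQ0 <- matrix(0, cfg$seqLen, cfg$inputDim)
    dK0 <- dQ0; dV0 <- dQ0
    ge$WQ <- vector("list", cfg$numHeads)
    ge$WK <- vector("list", cfg$numHeads)
    ge$WV <- vector("list", cfg$numHeads)
    for (a in seq_len(cfg$numHeads)) {
      hc <- ec$heads[[a]]
      dHa <- dHcat[, ((a - 1) * cfg$headDim + 1):(a * cfg$headDim),
                   drop = FALSE]
      dP <- tcrossprod(dHa, hc$Va)
      dVa <- crossprod(hc$P, dHa)
      dS <- hc$P * (dP - rowSums(dP * hc$P))
      dQa <- cfg$attnScale * (dS %*% hc$Ka)
      dKa <- cfg$attnScale * crossprod(dS, hc$Qa)
      ge$WQ[[a]] <- crossprod(ec$Q0, dQa)
      ge$WK[[a]] <- crossprod(ec$K0, dKa)
      ge$WV[[a]] <- crossprod(ec$V0, dVa)
      dQ0 <- dQ0 + tcrossprod(dQa, pe$WQ[[a]])
      dK0 <- dK0 + tcrossprod(dKa, pe$WK[[a]])
      dV0 <- dV0 + tcrossprod(dVa, pe$WV[[a]])
    }
    ge$L1 <- list(W = crossprod(ec$Ain, dQ0), b = colSums(dQ0))
    ge$L2 <- list(W = crossprod(ec$Ain, dK0), b = colSums(dK0))
    ge$L3 <- list(W = crossprod(ec$Ain, dV0), b = colSums(dV0))
    dAin <- dAin + tcrossprod(dQ0, pe$L1$W) + tcrossprod(dK0, pe$L2$W) +
      tcrossprod(dV0, pe$L3$W)
    g$encoders[[e]] <- ge
    dA <- dAin
  }
  # gradient w.r.t. the input (through dropout + PE) is discarded
  g
}

#' Forward pass of the ERP transformer
#'
#' Runs a batch of epochs through the network in evaluation mode (dropout
#' off) and returns class scores.
#'
#' @param model an \code{\link{erpTransformer}}.
#' @param x a single \code{seqLen x inputDim} matrix, a
#'   \code{time x channel x trial} array, or an
#'   \code{\linkS4class{EpochSet}}.
#' @param usePE include the positional encoding (default TRUE; disabling it
#'   exposes the permutation-equivariance of pure self-attention).
#' @return list with \code{logits} and \code{probs}, each
#'   \code{batch x numClasses}; softmax rows sum to 1.
#' @export
modelForward <- function(model, x, usePE = TRUE) {
  stopifnot(inherits(model, "erpTransformer"))
  xs <- asEpochList(x)
  n <- length(xs)
  logits <- matrix(0, n, model$config$numClasses)
  probs <- logits
  for (i in seq_len(n)) {
    fw <- forwardSample(model, xs[[i]], train = FALSE, usePE = usePE)
    logits[i, ] <- fw$logits
    probs[i, ] <- fw$probs
  }
  list(logits = logits, probs = probs)
}

asEpochList <- function(x) {
  if (is(x, "EpochSet"))
    return(lapply(seq_len(nTrials(x)), function(i) epochData(x, i)))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3]), function(i) {
      m <- x[, , i, drop = FALSE]; dim(m) <- dim(x)[1:2]; m
    }))
  if (is.matrix(x)) return(list(x))
  stopSchema("x must be a matrix, 3-D array, or EpochSet")
}

# elementwise recursion over two parameter trees; the second tree is
# indexed by name where names exist, so field order never matters
mapParams <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (is.null(b)) NULL
            else if (!is.null(nm) && nzchar(nm[i])) b[[nm[i]]]
            else b[[i]]
      out[[i]] <- mapParams(f, a[[i]], bi)
    }
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

zeroLike <- function(p) mapParams(function(x) x * 0, p)

adamStep <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- mapParams(function(m, gr) beta1 * m + (1 - beta1) * gr,
                       state$m, g)
  state$v <- mapParams(function(v, gr) beta2 * v + (1 - beta2) * gr^2,
                       state$v, g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- mapParams(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  p <- mapParams(function(w, u) w - lr * u, p, upd)
  list(params = p, state = state)
}

# mean cross-entropy loss and summed parameter gradients over a minibatch;
# labels are 1-based class indices
batchLossGrad <- function(model, xs, yIdx) {
  n <- length(xs)
  loss <- 0
  gTot <- NULL
  for (i in seq_len(n)) {
    fw <- forwardSample(model, xs[[i]], train = TRUE)
    pr <- fw$probs
    loss <- loss - log(max(pr[yIdx[i]], 1e-12))
    dlogits <- pr
    dlogits[yIdx[i]] <- dlogits[yIdx[i]] - 1
    gi <- backwardSample(model, fw$cache, dlogits / n)
    gTot <- if (is.null(gTot)) gi else mapParams(`+`, gTot, gi)
  }
  if (!is.finite(loss)) stopNumeric("non-finite training loss")
  list(loss = loss / n, grad = gTot)
}

classLevels <- c("Related", "Unrelated")

#' Train the ERP transformer on labelled epochs
#'
#' Minibatch Adam on softmax cross-entropy. When \code{evalSet} is given the
#' model is evaluated on it after every epoch and the per-epoch confusion
#' counts are recorded.
#'
#' @param es training \code{\linkS4class{EpochSet}}.
#' @param config an \code{\link{erpTransformerConfig}}.
#' @param epochs training epochs (default 100).
#' @param batch minibatch size; capped at the training-set size
#'   (default 256).
#' @param lr Adam learning rate (default 5e-4).
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @param evalSet optional held-out \code{EpochSet}.
#' @param normalize standardise inputs with training-set mean/sd
#'   (default TRUE); the statistics are stored in the returned model and
#'   applied to evaluation inputs.
#' @param verbose print per-epoch loss.
#' @return list with \code{model} (including normalisation stats),
#'   \code{losses} (per epoch) and, when \code{evalSet} is given,
#'   \code{evalCounts}: one \code{\link{confusionCounts}} row per epoch.
#' @export
trainModel <- function(es, config, epochs = 100, batch = 256, lr = 5e-4,
                       seed = 1, evalSet = NULL, normalize = TRUE,
                       verbose = FALSE) {
  stopifnot(is(es, "EpochSet"))
  xs <- asEpochList(es)
  yIdx <- match(epochLabels(es), classLevels)
  if (anyNA(yIdx)) stopSchema("labels must be Related/Unrelated")
  norm <- list(mu = 0, sd = 1)
  if (normalize) {
    v <- unlist(xs, use.names = FALSE)
    norm <- list(mu = mean(v), sd = max(stats::sd(v), 1e-12))
  }
  xs <- lapply(xs, function(m) (m - norm$mu) / norm$sd)
  evalXs <- NULL
  if (!is.null(evalSet)) {
    evalXs <- lapply(asEpochList(evalSet),
                     function(m) (m - norm$mu) / norm$sd)
    evalY <- epochLabels(evalSet)
  }
  model <- erpTransformer(config, seed = seed)
  model$norm <- norm
  n <- length(xs)
  batch <- min(batch, n)
  state <- list(t = 0, m = zeroLike(model$params),
                v = zeroLike(model$params))
  losses <- numeric(epochs)
  counts <- vector("list", epochs)
  withSeed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        lg <- batchLossGrad(model, xs[idx], yIdx[idx])
        st <- adamStep(model$params, lg$grad, state, lr)
        model$params <- st$params
        state <- st$state
        epLoss <- epLoss + lg$loss; nb <- nb + 1
      }
      losses[ep] <- epLoss / nb
      if (verbose) message(sprintf("epoch %d loss %.4f", ep, losses[ep]))
      if (!is.null(evalXs)) {
        pred <- predictLabels(model, evalXs)
        counts[[ep]] <- confusionCounts(pred, evalY)
      }
    }
  })
  out <- list(model = model, losses = losses)
  if (!is.null(evalXs))
    out$evalCounts <- do.call(rbind, lapply(counts, as.data.frame))
  out
}

# eval-mode argmax labels for a list of (already normalised) epoch matrices
predictLabels <- function(model, xs) {
  vapply(xs, function(m) {
    fw <- forwardSample(model, m, train = FALSE)
    classLevels[which.max(fw$probs)]
  }, "")
}

#' Predict condition labels for epochs
#'
#' @param model a trained model (\code{trainModel(...)$model}).
#' @param es an \code{\linkS4class{EpochSet}} (or array/matrix).
#' @return character vector of predicted labels.
#' @export
predictEpochs <- function(model, es) {
  norm <- model$norm %||% list(mu = 0, sd = 1)
  xs <- lapply(asEpochList(es), function(m) (m - norm$mu) / norm$sd)
  predictLabels(model, xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
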