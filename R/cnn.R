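#' CNN architecture specification
#'
#' Architecture of the correlogram-to-connectivity network: a 1-D
#' convolution (kernel 10, 5 output channels, stride 1, tanh, no padding),
#' average pooling (window 2, stride 1), one fully connected hidden layer
#' of 100 ReLU nodes, and a two-unit output head (logistic connection
#' probability `z`, linear PSP in mV).  With a 100-bin input this totals
#' about 45k trainable parameters; pooling geometry is configurable.
#'
#' @param inputLength correlogram length: 100 untrimmed, 96 shadow-trimmed
#'   (the default, matching the end-to-end pipeline).
#' @param kernelSize convolution kernel length, bins.
#' @param channels number of convolution output channels.
#' @param stride convolution stride (only 1 supported).
#' @param poolWidth,poolStride average-pooling window and stride (stride 1
#'   supported).
#' @param hidden hidden fully connected layer width.
#' @return a validated spec list.
#' @export
cnnModelSpec <- function(inputLength = 96L, kernelSize = 10L, channels = 5L,
                         stride = 1L, poolWidth = 2L, poolStride = 1L,
                         hidden = 100L) {
    stopifnot(stride == 1L, poolStride == 1L, kernelSize >= 1L,
              channels >= 1L, poolWidth >= 1L, hidden >= 1L)
    convLen <- inputLength - kernelSize + 1L
    poolLen <- convLen - poolWidth + 1L
    if (convLen < 2L || poolLen < 1L)
        stop("inconsistent architecture: non-positive layer length")
    list(inputLength = as.integer(inputLength),
         kernelSize = as.integer(kernelSize),
         channels = as.integer(channels), stride = 1L,
         poolWidth = as.integer(poolWidth), poolStride = 1L,
         hidden = as.integer(hidden),
         convLen = as.integer(convLen), poolLen = as.integer(poolLen))
}

#' Build an (untrained) CNN estimator
#'
#' Glorot-uniform initialization, deterministic under the given seed.
#'
#' @param spec a [cnnModelSpec()].
#' @param seed integer RNG seed for the initial weights.
#' @return a [CnnConnect-class].
#' @export
buildCnnModel <- function(spec = cnnModelSpec(), seed = 1L) {
    set.seed(seed)
    glorot <- function(nr, nc, fanIn, fanOut) {
        lim <- sqrt(6 / (fanIn + fanOut))
        matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
    nFlat <- spec$channels * spec$poolLen
    # convolution weights start small: inputs are raw integer counts (tens
    # to hundreds per bin), and a Glorot-scale kernel would saturate the
    # tanh from the first step
    weights <- list(
        Wc = matrix(runif(spec$kernelSize * spec$channels, -0.01, 0.01),
                    spec$kernelSize, spec$channels),
        bc = numeric(spec$channels),
        W1 = glorot(nFlat, spec$hidden, nFlat, spec$hidden),
        b1 = numeric(spec$hidden),
        W2 = glorot(spec$hidden, 2L, spec$hidden, 2L),
        b2 = numeric(2L))
    new("CnnConnect", spec = spec, weights = weights,
        history = data.frame(), seed = as.numeric(seed), trained = FALSE)
}

# forward pass; X is n x inputLength. Returns output list and, optionally,
# the intermediate activations needed for backprop.
.cnnForward <- function(w, X, spec, cache = FALSE) {
    n <- nrow(X)
    K <- spec$kernelSize; C <- spec$channels
    m1 <- spec$convLen; m2 <- spec$poolLen; pw <- spec$poolWidth
    conv <- vector("list", C)
    for (c in seq_len(C)) {
        A <- matrix(w$bc[c], n, m1)
        for (k in seq_len(K))
            A <- A + X[, k:(k + m1 - 1L), drop = FALSE] * w$Wc[k, c]
        conv[[c]] <- tanh(A)
    }
    pool <- vector("list", C)
    for (c in seq_len(C)) {
        P <- conv[[c]][, 1:m2, drop = FALSE]
        if (pw > 1L)
            for (q in 2:pw) P <- P + conv[[c]][, q:(q + m2 - 1L), drop = FALSE]
        pool[[c]] <- P / pw
    }
    H <- do.call(cbind, pool)
    A1pre <- sweep(H %*% w$W1, 2L, w$b1, `+`)
    A1 <- pmax(A1pre, 0)
    O <- sweep(A1 %*% w$W2, 2L, w$b2, `+`)
    out <- list(logit = O[, 1L], z = stats::plogis(O[, 1L]), psp = O[, 2L])
    if (cache) out <- c(out, list(conv = conv, H = H, A1 = A1))
    out
}

# composite loss: wConn * binary cross-entropy + wPsp * squared PSP error,
# averaged over examples.  Stable BCE from the logit.
.cnnLoss <- function(fwd, z, psp, wConn, wPsp) {
    o <- fwd$logit
    bce <- pmax(o, 0) - z * o + log1p(exp(-abs(o)))
    mse <- (fwd$psp - psp)^2
    c(total = mean(wConn * bce + wPsp * mse),
      conn = mean(bce), psp = mean(mse))
}

.cnnBackward <- function(w, X, fwd, z, psp, spec, wConn, wPsp) {
    n <- nrow(X)
    K <- spec$kernelSize; C <- spec$channels
    m1 <- spec$convLen; m2 <- spec$poolLen; pw <- spec$poolWidth
    dO <- cbind(wConn * (fwd$z - z), wPsp * 2 * (fwd$psp - psp)) / n
    dW2 <- crossprod(fwd$A1, dO)
    db2 <- colSums(dO)
    dA1 <- tcrossprod(dO, w$W2) * (fwd$A1 > 0)
    dW1 <- crossprod(fwd$H, dA1)
    db1 <- colSums(dA1)
    dH <- tcrossprod(dA1, w$W1)
    dWc <- matrix(0, K, C)
    dbc <- numeric(C)
    for (c in seq_len(C)) {
        dP <- dH[, (c - 1L) * m2 + seq_len(m2), drop = FALSE] / pw
        dZ <- matrix(0, n, m1)
        for (q in seq_len(pw))
            dZ[, q:(q + m2 - 1L)] <- dZ[, q:(q + m2 - 1L)] + dP
        dZ <- dZ * (1 - fwd$conv[[c]]^2)
        for (k in seq_len(K))
            dWc[k, c] <- sum(X[, k:(k + m1 - 1L), drop = FALSE] * dZ)
        dbc[c] <- sum(dZ)
    }
    list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Training configuration
#'
#' Adam hyperparameters and the composite loss weights: equal halves of
#' binary cross-entropy (connection presence) and mean squared error (PSP
#' amplitude in mV).
#'
#' @param learningRate,beta1,beta2 Adam parameters.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed RNG seed for minibatch shuffling.
#' @param lossWeightConn,lossWeightPsp loss weights (sum to 1).
#' @return a config list.
#' @export
trainConfig <- function(learningRate = 0.001, beta1 = 0.9, beta2 = 0.999,
                        epochs = 20L, batchSize = 256L, seed = 1L,
                        lossWeightConn = 0.5, lossWeightPsp = 0.5) {
    stopifnot(abs(lossWeightConn + lossWeightPsp - 1) < 1e-9)
    list(learningRate = learningRate, beta1 = beta1, beta2 = beta2,
         epochs = as.integer(epochs), batchSize = as.integer(batchSize),
         seed = as.integer(seed), lossWeightConn = lossWeightConn,
         lossWeightPsp = lossWeightPsp)
}

#' Build the labeled training set from simulated recordings
#'
#' For every unordered unit pair one correlogram is computed and presented
#' in both orientations (original and lag-reversed), so each pair yields
#' two examples whose positive-lag half carries the candidate causal
#' direction.  Teaching signals come from the ground-truth network: `z = 1`
#' and the signed PSP (mV) when the oriented connection exists, `z = 0` and
#' 0 mV otherwise.  Time-rescaled copies of the spike trains
#' ([rescaleAugment()]) are added per `augmentFactors`; labels are
#' unchanged by augmentation.
#'
#' @param spikes a [SpikeTrainSet-class] of recorded units.
#' @param truth the matching [GroundTruthNetwork-class] (same unit
#'   numbering).
#' @param augmentFactors time-rescaling factors.
#' @param trim logical; shadow-trim the correlograms (96-bin inputs).
#' @param window,binWidth correlogram geometry, ms.
#' @return list with `x` (example-by-bin count matrix), `z`, `psp`, and
#'   `meta` (pre, post, factor per example).
#' @export
makeTrainingSet <- function(spikes, truth, augmentFactors = c(1, 2, 4),
                            trim = TRUE, window = 50, binWidth = 1) {
    n <- nUnits(spikes)
    if (nUnits(truth) != n)
        stop("spike trains and ground truth cover different unit sets")
    syn <- truth@synapses
    zmat <- matrix(0, n, n)
    pmat <- matrix(0, n, n)
    if (nrow(syn)) {
        idx <- cbind(syn$pre, syn$post)
        zmat[idx] <- 1
        pmat[idx] <- syn$psp
    }
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    npair <- nrow(pairs)
    M <- round(2 * window / binWidth)
    len <- if (trim) M - 4L else M
    nex <- 2L * npair * length(augmentFactors)
    X <- matrix(0L, nex, len)
    z <- numeric(nex); psp <- numeric(nex)
    meta <- data.frame(pre = integer(nex), post = integer(nex),
                       factor = numeric(nex))
    drop <- .shadowBins(window, binWidth)
    row <- 0L
    for (f in augmentFactors) {
        sp <- rescaleAugment(spikes, f)
        for (p in seq_len(npair)) {
            i <- pairs[p, 1L]; j <- pairs[p, 2L]
            cnt <- .ccgCountCpp(sp@spikes[[i]], sp@spikes[[j]],
                                window / 1000, binWidth / 1000)
            if (trim) cnt <- cnt[!drop]
            X[row + 1L, ] <- cnt
            X[row + 2L, ] <- rev(cnt)
            z[row + 1L] <- zmat[i, j]; psp[row + 1L] <- pmat[i, j]
            z[row + 2L] <- zmat[j, i]; psp[row + 2L] <- pmat[j, i]
            meta$pre[row + 1L] <- i; meta$post[row + 1L] <- j
            meta$pre[row + 2L] <- j; meta$post[row + 2L] <- i
            meta$factor[row + (1:2)] <- f
            row <- row + 2L
        }
    }
    list(x = X, z = z, psp = psp, meta = meta)
}

#' Train the CNN estimator
#'
#' Minimizes the composite loss with Adam for `config$epochs` epochs over
#' shuffled minibatches.  Deterministic under fixed model seed and
#' `config$seed`.
#'
#' @param model a [CnnConnect-class] from [buildCnnModel()].
#' @param data a training set from [makeTrainingSet()] (or any list with
#'   `x`, `z`, `psp`).
#' @param config a [trainConfig()].
#' @return the trained [CnnConnect-class] with per-epoch losses in
#'   `trainingHistory()`.
#' @export
trainCnn <- function(model, data, config = trainConfig()) {
    spec <- model@spec
    X <- data$x
    storage.mode(X) <- "double"
    if (ncol(X) != spec$inputLength)
        stop(sprintf("input length %d does not match model input %d",
                     ncol(X), spec$inputLength))
    n <- nrow(X)
    if (n == 0L) stop("empty training set")
    w <- model@weights
    mom <- lapply(w, function(p) p * 0)  # zero, same shape and attributes
    vel <- mom
    set.seed(config$seed)
    lr <- config$learningRate; b1 <- config$beta1; b2 <- config$beta2
    eps <- 1e-8
    t <- 0L
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       loss_conn = numeric(), loss_psp = numeric())
    for (epoch in seq_len(config$epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = config$batchSize)
        tot <- con <- ps <- 0
        for (s in starts) {
            take <- ord[s:min(s + config$batchSize - 1L, n)]
            Xb <- X[take, , drop = FALSE]
            fwd <- .cnnForward(w, Xb, spec, cache = TRUE)
            l <- .cnnLoss(fwd, data$z[take], data$psp[take],
                          config$lossWeightConn, config$lossWeightPsp)
            if (!is.finite(l[["total"]]))
                stop(sprintf("non-finite loss at epoch %d", epoch))
            g <- .cnnBackward(w, Xb, fwd, data$z[take], data$psp[take],
                              spec, config$lossWeightConn, config$lossWeightPsp)
            t <- t + 1L
            for (nm in names(w)) {
                mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
                vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
                mhat <- mom[[nm]] / (1 - b1^t)
                vhat <- vel[[nm]] / (1 - b2^t)
                w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
            }
            wt <- length(take) / n
            tot <- tot + wt * l[["total"]]
            con <- con + wt * l[["conn"]]
            ps <- ps + wt * l[["psp"]]
        }
        hist <- rbind(hist, data.frame(epoch = epoch, loss = tot,
                                       loss_conn = con, loss_psp = ps))
    }
    initialize(model, weights = w, history = hist, trained = TRUE)
}

#' Predict connectivity from correlograms
#'
#' @param model a trained [CnnConnect-class].
#' @param cc a [Correlogram-class], a count vector, or a matrix with one
#'   correlogram per row; lengths must match the model input length.
#' @param theta detection threshold on `z` (default 0.5).
#' @return data.frame with columns `z`, `connected` (`z > theta`),
#'   `psp_mV` (0 when not connected) and `sign` ("E", "I" or NA).
#' @export
predictCnn <- function(model, cc, theta = 0.5) {
    X <- if (is(cc, "Correlogram")) matrix(as.numeric(counts(cc)), 1L)
         else if (is.matrix(cc)) cc
         else matrix(as.numeric(cc), 1L)
    storage.mode(X) <- "double"
    if (ncol(X) != model@spec$inputLength)
        stop(sprintf("correlogram length %d does not match model input %d",
                     ncol(X), model@spec$inputLength))
    fwd <- .cnnForward(model@weights, X, model@spec)
    connected <- fwd$z > theta
    psp <- ifelse(connected, fwd$psp, 0)
    data.frame(z = fwd$z, connected = connected, psp_mV = psp,
               sign = ifelse(!connected, NA_character_,
                             ifelse(fwd$psp > 0, "E", "I")))
}

# raw per-ordered-pair outputs (z and unthresholded PSP); one correlogram
# per unordered pair evaluated in both orientations.
.cnnEstimateRaw <- function(model, spikes, window = 50, binWidth = 1) {
    n <- nUnits(spikes)
    if (n < 2L) stop("need at least 2 units")
    spec <- model@spec
    M <- round(2 * window / binWidth)
    trim <- spec$inputLength == M - 4L
    if (!trim && spec$inputLength != M)
        stop("model input length incompatible with correlogram geometry")
    drop <- .shadowBins(window, binWidth)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    npair <- nrow(pairs)
    X <- matrix(0, 2L * npair, spec$inputLength)
    for (p in seq_len(npair)) {
        cnt <- .ccgCountCpp(spikes@spikes[[pairs[p, 1L]]],
                            spikes@spikes[[pairs[p, 2L]]],
                            window / 1000, binWidth / 1000)
        if (trim) cnt <- cnt[!drop]
        X[2L * p - 1L, ] <- cnt
        X[2L * p, ] <- rev(cnt)
    }
    fwd <- .cnnForward(model@weights, X, spec)
    data.frame(pre = as.vector(rbind(pairs[, 1L], pairs[, 2L])),
               post = as.vector(rbind(pairs[, 2L], pairs[, 1L])),
               z = fwd$z, psp_raw = fwd$psp)
}

#' Estimate the full directed connection matrix
#'
#' Computes one correlogram per unordered unit pair, evaluates the model in
#' both orientations, and reports a [predictCnn()] estimate for every
#' ordered pair (diagonal excluded).
#'
#' @param model a trained [CnnConnect-class].
#' @param spikes a [SpikeTrainSet-class] (at least 2 units).
#' @param theta detection threshold on `z`.
#' @param window,binWidth correlogram geometry, ms.
#' @return data.frame with columns `pre`, `post`, `z`, `connected`,
#'   `psp_mV` (0 for undetected pairs).
#' @export
estimateMatrix <- function(model, spikes, theta = 0.5, window = 50,
                           binWidth = 1) {
    raw <- .cnnEstimateRaw(model, spikes, window, binWidth)
    connected <- raw$z > theta
    data.frame(pre = raw$pre, post = raw$post, z = raw$z,
               connected = connected,
               psp_mV = ifelse(connected, raw$psp_raw, 0))
}
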