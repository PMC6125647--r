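#' Logistic (sigmoid) activation
#'
#' `beta = 1 / (1 + exp(-alpha))`, applied elementwise. This is the
#' activation applied to convolved feature maps by default and always to
#' the single output unit.
#'
#' @param alpha finite numeric input.
#' @return Values in (0, 1).
#' @examples
#' sigmoidActivation(0)        # 0.5
#' sigmoidActivation(log(3))   # 0.75
#' @export
sigmoidActivation <- function(alpha) 1 / (1 + exp(-alpha))

.actFun <- function(name) {
    switch(name,
        sigmoid = list(f = sigmoidActivation,
                       df = function(a, y) y * (1 - y)),
        relu = list(f = function(a) pmax(a, 0),
                    df = function(a, y) as.numeric(a > 0)),
        stop("unknown activation: ", name))
}

#' Trace the per-layer output shapes of an architecture
#'
#' Valid-padding convolution maps a spatial size s to `s - k + 1`; pooling
#' to `floor(s / poolSize)`. The default architecture traces
#' 128 -> 119 -> 110 -> 55 -> 48 -> 45 -> 22, giving (22, 22, 32) feature
#' maps and a flatten length of 15488.
#'
#' @param spec a [CnnSpec-class].
#' @return data.frame with columns layer, outH, outW, channels, units.
#' @examples
#' tr <- shapeTrace(cnnSpec())
#' tr[tr$layer == "flatten", "units"]   # 15488
#' @export
shapeTrace <- function(spec) {
    validObject(spec)
    h <- spec@inputShape[1L]; w <- spec@inputShape[2L]
    ch <- spec@inputShape[3L]
    rows <- list(data.frame(layer = "input", outH = h, outW = w,
                            channels = ch, units = NA_integer_))
    for (i in seq_len(nrow(spec@convLayers))) {
        k <- spec@convLayers[i, "kernelSize"]
        h <- h - k + 1L; w <- w - k + 1L
        ch <- spec@convLayers[i, "nKernels"]
        if (h < 1L || w < 1L)
            stop("conv layer ", i, " produces non-positive spatial size")
        rows[[length(rows) + 1L]] <-
            data.frame(layer = sprintf("conv%d(%dx%d)", i, k, k),
                       outH = h, outW = w, channels = ch,
                       units = NA_integer_)
        if (i %in% spec@poolAfter) {
            h <- h %/% spec@poolSize; w <- w %/% spec@poolSize
            if (h < 1L || w < 1L)
                stop("pooling after conv ", i, " empties the feature map")
            rows[[length(rows) + 1L]] <-
                data.frame(layer = sprintf("%spool%d", spec@poolType,
                                           match(i, spec@poolAfter)),
                           outH = h, outW = w, channels = ch,
                           units = NA_integer_)
        }
    }
    units <- h * w * ch
    rows[[length(rows) + 1L]] <-
        data.frame(layer = "flatten", outH = NA_integer_, outW = NA_integer_,
                   channels = NA_integer_, units = units)
    for (j in seq_along(spec@fcNeurons)) {
        units <- spec@fcNeurons[j]
        rows[[length(rows) + 1L]] <-
            data.frame(layer = sprintf("fc%d", j), outH = NA_integer_,
                       outW = NA_integer_, channels = NA_integer_,
                       units = units)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.glorot <- function(dims, fanIn, fanOut) {
    lim <- sqrt(6 / (fanIn + fanOut))
    array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build an untrained CNN from an architecture specification
#'
#' Constructs the layer sequence
#' conv, conv, pool, dropout, conv, conv, pool, dropout, flatten, fc,
#' dropout, fc(1, sigmoid) for the default spec (pool positions and layer
#' counts follow `spec`), with Glorot-uniform weight initialization.
#'
#' @param spec a [CnnSpec-class].
#' @param seed integer seed for the weight initialization.
#' @return A [CnnModel-class]; its `trace` slot holds the shape trace.
#' @export
buildModel <- function(spec = cnnSpec(), seed = 1L) {
    trace <- shapeTrace(spec)      # also validates spatial sizes
    set.seed(seed)
    layers <- list()
    ch <- spec@inputShape[3L]
    h <- spec@inputShape[1L]; w <- spec@inputShape[2L]
    dropI <- 1L
    for (i in seq_len(nrow(spec@convLayers))) {
        k <- spec@convLayers[i, "kernelSize"]
        f <- spec@convLayers[i, "nKernels"]
        layers[[length(layers) + 1L]] <- list(
            type = "conv",
            w = .glorot(c(k, k, ch, f), k * k * ch, k * k * f),
            b = numeric(f), act = spec@convActivation)
        ch <- f; h <- h - k + 1L; w <- w - k + 1L
        if (i %in% spec@poolAfter) {
            layers[[length(layers) + 1L]] <-
                list(type = "pool", p = spec@poolSize,
                     maxPool = spec@poolType == "max")
            h <- h %/% spec@poolSize; w <- w %/% spec@poolSize
            layers[[length(layers) + 1L]] <-
                list(type = "dropout", rate = spec@dropoutRates[dropI])
            dropI <- dropI + 1L
        }
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    nIn <- h * w * ch
    nFc <- length(spec@fcNeurons)
    for (j in seq_len(nFc)) {
        nOut <- spec@fcNeurons[j]
        last <- j == nFc
        layers[[length(layers) + 1L]] <- list(
            type = "fc",
            w = matrix(.glorot(c(nIn, nOut), nIn, nOut), nIn, nOut),
            b = numeric(nOut),
            act = if (last) "sigmoid" else spec@convActivation)
        if (!last && j == nFc - 1L) {
            layers[[length(layers) + 1L]] <-
                list(type = "dropout",
                     rate = spec@dropoutRates[length(spec@dropoutRates)])
        }
        nIn <- nOut
    }
    new("CnnModel", spec = spec, layers = layers, trace = trace,
        history = data.frame())
}

# forward pass; when training, caches per-layer inputs/outputs for backprop
# and samples dropout masks from the current RNG stream
.forward <- function(layers, x, training = FALSE) {
    cache <- vector("list", length(layers))
    B <- dim(x)[length(dim(x))]
    for (i in seq_along(layers)) {
        ly <- layers[[i]]
        cache[[i]] <- list(x = x)
        if (ly$type == "conv") {
            a <- .convForward(x, ly$w, ly$b)
            act <- .actFun(ly$act)
            y <- act$f(a)
            cache[[i]]$a <- a
            x <- y
        } else if (ly$type == "pool") {
            pf <- .poolForward(x, ly$p, ly$maxPool)
            cache[[i]]$idx <- pf$idx
            cache[[i]]$inDim <- dim(x)
            x <- pf$y
        } else if (ly$type == "dropout") {
            if (training && ly$rate > 0) {
                mask <- array(runif(length(x)) >= ly$rate, dim = dim(x)) /
                    (1 - ly$rate)
                cache[[i]]$mask <- mask
                x <- x * mask
            }
        } else if (ly$type == "flatten") {
            cache[[i]]$inDim <- dim(x)
            x <- matrix(x, ncol = B)            # units x B
        } else if (ly$type == "fc") {
            a <- crossprod(ly$w, x) + ly$b      # nOut x B
            act <- .actFun(ly$act)
            cache[[i]]$a <- a
            x <- act$f(a)
        }
        cache[[i]]$y <- x
    }
    list(out = x, cache = cache)
}

# backward pass from d(loss)/d(pre-sigmoid output); returns gradient list
.backward <- function(layers, cache, dOut) {
    grads <- vector("list", length(layers))
    d <- dOut   # gradient w.r.t. the final PRE-activation (BCE + sigmoid)
    for (i in rev(seq_along(layers))) {
        ly <- layers[[i]]
        cc <- cache[[i]]
        if (ly$type == "fc") {
            if (i < length(layers)) {   # hidden fc: d arrives post-act
                act <- .actFun(ly$act)
                d <- d * act$df(cc$a, cc$y)
            }
            grads[[i]] <- list(dw = cc$x %*% t(d), db = rowSums(d))
            d <- ly$w %*% d
        } else if (ly$type == "flatten") {
            d <- array(d, dim = cc$inDim)
        } else if (ly$type == "dropout") {
            if (!is.null(cc$mask)) d <- d * cc$mask
        } else if (ly$type == "pool") {
            d <- .poolBackward(d, cc$idx, cc$inDim, ly$p, ly$maxPool)
        } else if (ly$type == "conv") {
            act <- .actFun(ly$act)
            d <- d * act$df(cc$a, cc$y)
            bw <- .convBackward(cc$x, ly$w, d)
            grads[[i]] <- list(dw = bw$dw, db = bw$db)
            d <- bw$dx
        }
    }
    grads
}

.tensorBatch <- function(tensors, idx) {
    d <- dim(tensors[[idx[1L]]]@tensor)
    x <- array(0, dim = c(d, length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- tensors[[idx[j]]]@tensor
    x
}

.binaryTargets <- function(tensors) {
    vapply(tensors, function(tt) as.numeric(tt@label == "AF"), 1)
}

#' Train a CNN by stochastic gradient descent with momentum
#'
#' Minimizes binary cross-entropy on the sigmoid output with SGD using the
#' configured learning rate, momentum coefficient and L2 weight decay.
#' Shuffling, dropout and initialization all draw from the seeded RNG, so a
#' fixed seed reproduces training exactly (single-threaded BLAS assumed).
#'
#' @param model an untrained (or previously trained) [CnnModel-class].
#' @param tensors list of [InstanceTensor-class] training instances; both
#'   classes must be present (>= 2 instances each).
#' @param config a [TrainConfig-class].
#' @param verbose print one line per epoch.
#' @return The trained [CnnModel-class]; `trainingHistory()` gives
#'   per-epoch loss and training accuracy.
#' @export
trainModel <- function(model, tensors, config = trainConfig(),
                       verbose = FALSE) {
    validObject(config)
    y <- .binaryTargets(tensors)
    if (length(y) < 4L || min(table(factor(y, c(0, 1)))) < 2L)
        stop("training set must contain >= 2 instances of each class")
    layers <- model@layers
    vel <- lapply(layers, function(ly)
        if (ly$type %in% c("conv", "fc"))
            list(w = ly$w * 0, b = ly$b * 0) else NULL)
    set.seed(config@seed)
    n <- length(tensors)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       accuracy = numeric())
    eps <- 1e-12
    for (ep in seq_len(config@epochs)) {
        ord <- sample.int(n)
        lossSum <- 0; correct <- 0L
        for (bStart in seq.int(1L, n, by = config@batchSize)) {
            idx <- ord[bStart:min(bStart + config@batchSize - 1L, n)]
            x <- .tensorBatch(tensors, idx)
            yy <- y[idx]
            fw <- .forward(layers, x, training = TRUE)
            p <- as.numeric(fw$out)
            pC <- pmin(pmax(p, eps), 1 - eps)
            loss <- -mean(yy * log(pC) + (1 - yy) * log(1 - pC))
            if (!is.finite(loss))
                stop("non-finite loss at epoch ", ep)
            lossSum <- lossSum + loss * length(idx)
            correct <- correct + sum((p >= config@decisionThreshold) == yy)
            # BCE + sigmoid: gradient at the pre-activation is (p - y)/B
            dOut <- matrix((p - yy) / length(idx), nrow = 1L)
            grads <- .backward(layers, fw$cache, dOut)
            for (i in seq_along(layers)) {
                if (is.null(grads[[i]])) next
                lr <- config@learningRate
                vel[[i]]$w <- config@momentum * vel[[i]]$w -
                    lr * (grads[[i]]$dw + config@weightDecay * layers[[i]]$w)
                vel[[i]]$b <- config@momentum * vel[[i]]$b -
                    lr * grads[[i]]$db
                layers[[i]]$w <- layers[[i]]$w + vel[[i]]$w
                layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
            }
        }
        hist <- rbind(hist, data.frame(epoch = ep, loss = lossSum / n,
                                       accuracy = correct / n))
        if (verbose)
            message(sprintf("epoch %d: loss %.4f, accuracy %.4f", ep,
                            lossSum / n, correct / n))
    }
    model@layers <- layers
    model@history <- hist
    model
}

#' Predict AF probabilities for instance tensors
#'
#' Runs the forward pass in evaluation mode (dropout inactive). Batched and
#' one-by-one prediction give identical probabilities.
#'
#' @param model a [CnnModel-class].
#' @param tensors list of [InstanceTensor-class] objects.
#' @param batchSize prediction batch size.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictProbs <- function(model, tensors, batchSize = 64L) {
    n <- length(tensors)
    d <- dim(tensors[[1L]]@tensor)
    if (!identical(as.integer(d), model@spec@inputShape))
        stop("tensor shape ", paste(d, collapse = "x"),
             " does not match the model input shape")
    p <- numeric(n)
    for (bStart in seq.int(1L, n, by = batchSize)) {
        idx <- bStart:min(bStart + batchSize - 1L, n)
        x <- .tensorBatch(tensors, idx)
        p[idx] <- as.numeric(.forward(model@layers, x)$out)
    }
    p
}

#' Threshold probabilities into binary labels
#'
#' A probability greater than or equal to the threshold is called AF (ties
#' go to AF).
#'
#' @param probs numeric probabilities.
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @return Character vector of `"AF"` / `"non-AF"`.
#' @export
classifyProbs <- function(probs, threshold = 0.5) {
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie in (0, 1)")
    ifelse(probs >= threshold, "AF", "non-AF")
}
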