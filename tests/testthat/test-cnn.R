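test_that("the logistic activation matches its closed forms", {
    expect_identical(sigmoidActivation(0), 0.5)
    expect_equal(sigmoidActivation(log(3)), 0.75, tolerance = 1e-12)
    expect_equal(sigmoidActivation(1e4), 1)
    expect_equal(sigmoidActivation(-1e4), 0)
})

test_that("the default architecture traces to the published sizes", {
    tr <- shapeTrace(cnnSpec())
    spatial <- tr$outH[!is.na(tr$outH)]
    expect_identical(spatial, c(128L, 119L, 110L, 55L, 48L, 45L, 22L))
    pool2 <- tr[tr$layer == "maxpool2", ]
    expect_identical(c(pool2$outH, pool2$outW, pool2$channels),
                     c(22L, 22L, 32L))
    expect_identical(tr$units[tr$layer == "flatten"], 15488L)
    expect_identical(tail(tr$units, 1L), 1L)
})

test_that("the first fully connected layer dominates the parameter count", {
    m <- buildModel(cnnSpec(), seed = 1)
    fc1 <- Filter(function(l) l$type == "fc", m@layers)[[1]]
    expect_identical(length(fc1$w) + length(fc1$b),
                     15488L * 256L + 256L)
    nConv <- sum(vapply(m@layers, function(l)
        if (l$type == "conv") length(l$w) + length(l$b) else 0L, 1L))
    expect_gt(length(fc1$w), nConv)
})

test_that("specs tracing to non-positive sizes are rejected", {
    bad <- cnnSpec(inputShape = c(16L, 16L, 5L),
                   convLayers = list(c(8L, 10L), c(8L, 10L)),
                   poolAfter = 2L)
    expect_error(buildModel(bad), "non-positive")
    expect_error(cnnSpec(fcNeurons = c(256L, 2L)), "exactly 1 unit")
})

test_that("training solves a linearly separable toy task", {
    tens <- toyTask(50)
    m <- buildModel(toySpec(), seed = 2)
    cfg <- trainConfig(learningRate = 0.05, epochs = 20, batchSize = 16,
                       seed = 3)
    m2 <- trainModel(m, tens, cfg)
    hist <- trainingHistory(m2)
    expect_identical(nrow(hist), 20L)
    expect_gte(tail(hist$accuracy, 1), 0.99)
    # loss is non-increasing up to small epoch-to-epoch noise
    expect_true(all(diff(hist$loss) <= 0.05 * head(hist$loss, -1)))
})

test_that("training is deterministic and inert at zero learning rate", {
    tens <- toyTask(10)
    m <- buildModel(toySpec(), seed = 2)
    cfg <- trainConfig(learningRate = 0.05, epochs = 3, batchSize = 8,
                       seed = 5)
    a <- trainModel(m, tens, cfg)
    b <- trainModel(m, tens, cfg)
    expect_identical(tail(trainingHistory(a)$loss, 1),
                     tail(trainingHistory(b)$loss, 1))
    frozen <- trainModel(m, tens, trainConfig(learningRate = 0,
                                              epochs = 2, batchSize = 8,
                                              seed = 5))
    for (i in seq_along(m@layers))
        if (!is.null(m@layers[[i]]$w))
            expect_identical(frozen@layers[[i]]$w, m@layers[[i]]$w)
})

test_that("prediction is a probability, batch-invariant, threshold >= AF", {
    tens <- toyTask(10)
    m <- trainModel(buildModel(toySpec(), seed = 2), tens,
                    trainConfig(learningRate = 0.05, epochs = 3,
                                batchSize = 8, seed = 5))
    p <- predictProbs(m, tens)
    expect_true(all(p > 0 & p < 1))
    single <- vapply(tens, function(tt) predictProbs(m, list(tt)), 1)
    expect_lt(max(abs(p - single)), 1e-6)
    expect_identical(classifyProbs(c(0.5, 0.49)), c("AF", "non-AF"))
    expect_error(classifyProbs(0.5, threshold = 1), "threshold")
})

test_that("degenerate training sets and shapes are rejected", {
    oneClass <- toyTask(10)[1:10]
    expect_error(trainModel(buildModel(toySpec(), 1), oneClass,
                            trainConfig(epochs = 1)), "each class")
    expect_error(trainConfig(epochs = 0), "epochs")
    m <- buildModel(toySpec(), 1)
    expect_error(predictProbs(m, list(toyTensor(0.5, "AF", side = 16L))),
                 "shape")
})
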