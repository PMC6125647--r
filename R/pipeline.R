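#' Assemble a pipeline configuration
#'
#' One nested configuration object drives [runPipeline()] end to end:
#' synthesis, denoising, segmentation, scalogram construction, splitting
#' and training. It round-trips losslessly through YAML via
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param nRecords number of synthetic records.
#' @param classBalance fraction of AF records.
#' @param duration per-record duration, s.
#' @param fs sampling rate, Hz.
#' @param rhythmNSR,rhythmAF [RhythmParams-class] per class.
#' @param noise a [NoiseSpec-class].
#' @param denoiseJ dyadic scales for denoising.
#' @param zeroScales detail scales zeroed by the denoiser.
#' @param denoiseWavelet analysis wavelet for denoising.
#' @param windowL window length in samples (NA: `round(1.2 * fs)`).
#' @param nBeats beats per instance.
#' @param policy instance grouping policy, "block" or "sliding".
#' @param cwt a [CwtConfig-class].
#' @param cnn a [CnnSpec-class].
#' @param train a [TrainConfig-class].
#' @param split a [SplitSpec-class].
#' @param seed master seed; stage seeds are derived from it.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nRecords = 10L, classBalance = 0.5,
                           duration = 60, fs = 250,
                           rhythmNSR = rhythmParams("NSR"),
                           rhythmAF = rhythmParams("AF"),
                           noise = noiseSpec(),
                           denoiseJ = 7L, zeroScales = 1:3,
                           denoiseWavelet = "db4",
                           windowL = NA_integer_, nBeats = 5L,
                           policy = "block",
                           cwt = cwtConfig(), cnn = cnnSpec(),
                           train = trainConfig(), split = splitSpec(),
                           seed = 1L) {
    cfg <- list(nRecords = as.integer(nRecords),
                classBalance = classBalance, duration = duration, fs = fs,
                rhythmNSR = rhythmNSR, rhythmAF = rhythmAF, noise = noise,
                denoiseJ = as.integer(denoiseJ),
                zeroScales = as.integer(zeroScales),
                denoiseWavelet = denoiseWavelet,
                windowL = as.integer(windowL), nBeats = as.integer(nBeats),
                policy = policy, cwt = cwt, cnn = cnn, train = train,
                split = split, seed = as.integer(seed))
    for (s4 in c("rhythmNSR", "rhythmAF", "noise", "cwt", "cnn", "train",
                 "split"))
        validObject(cfg[[s4]])
    if (cfg$train@epochs < 1L) stop("epochs must be >= 1")
    class(cfg) <- "PipelineConfig"
    cfg
}

.s4ToList <- function(obj) {
    out <- lapply(slotNames(class(obj)), function(s) {
        v <- slot(obj, s)
        if (is.matrix(v)) as.vector(v) else v
    })
    names(out) <- slotNames(class(obj))
    out
}

.listToS4 <- function(lst, cls) {
    known <- slotNames(cls)
    extra <- setdiff(names(lst), known)
    if (length(extra))
        stop("unknown keys for ", cls, ": ", paste(extra, collapse = ", "))
    proto <- new(cls)
    args <- lapply(names(lst), function(s) {
        v <- lst[[s]]
        tmpl <- slot(proto, s)
        if (is.matrix(tmpl))
            matrix(as.integer(v), ncol = ncol(tmpl),
                   dimnames = dimnames(tmpl))
        else if (is.integer(tmpl)) as.integer(v)
        else if (is.numeric(tmpl)) as.numeric(v)
        else v
    })
    names(args) <- names(lst)
    do.call(new, c(cls, args))
}

.CFG_S4 <- c(rhythmNSR = "RhythmParams", rhythmAF = "RhythmParams",
             noise = "NoiseSpec", cwt = "CwtConfig", cnn = "CnnSpec",
             train = "TrainConfig", split = "SplitSpec")

#' Write / read a pipeline configuration as YAML
#'
#' Unknown keys in a configuration file are rejected rather than ignored.
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()]).
#' @param path file path.
#' @export
writePipelineConfig <- function(config, path) {
    flat <- lapply(seq_along(config), function(i) {
        nm <- names(config)[i]
        if (nm %in% names(.CFG_S4)) .s4ToList(config[[i]]) else config[[i]]
    })
    names(flat) <- names(config)
    yaml::write_yaml(flat, path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    lst <- yaml::read_yaml(path)
    template <- pipelineConfig()
    extra <- setdiff(names(lst), names(template))
    if (length(extra))
        stop("unknown configuration keys: ", paste(extra, collapse = ", "))
    args <- lapply(names(lst), function(nm) {
        if (nm %in% names(.CFG_S4)) .listToS4(lst[[nm]], .CFG_S4[[nm]])
        else lst[[nm]]
    })
    names(args) <- names(lst)
    do.call(pipelineConfig, args)
}

#' Run the full AF detection pipeline on synthetic data
#'
#' Executes simulate, denoise, segment, scalogram, split, train and
#' evaluate in sequence, seeded end to end: generates the configured
#' two-class dataset, denoises every record, cuts five-beat instances,
#' builds the stacked scalogram tensors for the balanced record-disjoint
#' split, trains the CNN on the training side and reports confusion
#' metrics on the held-out records.
#'
#' @param config a `PipelineConfig`.
#' @param verbose log stage sizes as messages.
#' @return List with `metrics` (a [ConfusionMetrics-class]), `history`
#'   (per-epoch training loss/accuracy), `probs`, `truth`, `split` sizes
#'   and the trained `model`.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(nRecords = 6, duration = 30,
#'                       cnn = cnnSpec(inputShape = c(32L, 32L, 5L),
#'                                     convLayers = list(c(4L, 5L),
#'                                                       c(4L, 3L)),
#'                                     poolAfter = c(1L, 2L),
#'                                     fcNeurons = c(8L, 1L),
#'                                     convActivation = "relu"),
#'                       cwt = cwtConfig(nScales = 32,
#'                                       outSize = c(32L, 32L)),
#'                       train = trainConfig(epochs = 2, batchSize = 16),
#'                       split = splitSpec(total = 40), seed = 1)
#' res <- runPipeline(cfg)
#' res$metrics
#' }
#' @export
runPipeline <- function(config, verbose = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    say <- function(...) if (verbose) message(sprintf(...))
    stage <- function(what, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", what, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    records <- stage("simulate", makeDataset(
        config$nRecords, config$classBalance,
        paramsGrid = list(NSR = config$rhythmNSR, AF = config$rhythmAF),
        noise = config$noise, duration = config$duration, fs = config$fs,
        seed = config$seed))
    say("simulate: %d records, %.0f s each", length(records),
        config$duration)

    instances <- stage("denoise+segment", {
        out <- list()
        for (rec in records) {
            den <- denoiseEcg(rec@samples, fs = config$fs,
                              J = config$denoiseJ,
                              zeroScales = config$zeroScales,
                              waveletName = config$denoiseWavelet)
            L <- if (is.na(config$windowL)) NULL else config$windowL
            wins <- segmentRecord(rec, L = L, signal = den)
            out <- c(out, makeInstances(wins, nBeats = config$nBeats,
                                        policy = config$policy))
        }
        out
    })
    say("segment: %d candidate instances", length(instances))

    labels <- vapply(instances, function(i) i@label, "")
    recIds <- vapply(instances, function(i) i@recordId, "")
    sp <- stage("split", balancedSplit(labels, recIds, config$split))
    say("split: %d train / %d test instances (%d / %d records)",
        length(sp$train), length(sp$test), length(sp$trainRecords),
        length(sp$testRecords))

    used <- c(sp$train, sp$test)
    tensors <- stage("scalogram",
        instanceTensors(instances[used], fs = config$fs, config = config$cwt,
                        nBeats = config$nBeats, verbose = verbose))
    trainT <- tensors[seq_along(sp$train)]
    testT <- tensors[length(sp$train) + seq_along(sp$test)]
    say("scalogram: %d tensors of %s", length(tensors),
        paste(dim(tensors[[1L]]@tensor), collapse = "x"))

    model <- stage("train", {
        m <- buildModel(config$cnn, seed = config$seed)
        trainModel(m, trainT, config$train, verbose = verbose)
    })

    res <- stage("evaluate", {
        probs <- predictProbs(model, testT)
        truth <- vapply(testT, function(tt) tt@label, "")
        pred <- classifyProbs(probs, config$train@decisionThreshold)
        list(metrics = confusionCounts(pred, truth), probs = probs,
             truth = truth)
    })
    say("evaluate: Acc %.2f%%", res$metrics@acc)

    list(metrics = res$metrics, history = model@history, probs = res$probs,
         truth = res$truth,
         split = list(nTrain = length(sp$train), nTest = length(sp$test),
                      trainRecords = sp$trainRecords,
                      testRecords = sp$testRecords),
         model = model)
}

#' Reference synthetic study configuration
#'
#' The configuration used by the package's own end-to-end evaluation:
#' 50 synthetic subjects (25 NSR at 70 bpm, 25 AF at 95 bpm with
#' coefficient of RR variation 0.2), 200 s per record at 250 Hz with the
#' default noise mix; 2000 balanced five-beat instances split 4:1 by
#' record. To keep a complete run in the minutes range on a single core
#' the study uses 64 x 64 scalogram patterns (64 scales over the same
#' 0.5--30 Hz band) and a width-reduced network -- 6 kernels per
#' convolutional layer, 64 first fully connected neurons, relu hidden
#' activations -- trained for a few epochs. The full-width (128, 128, 5)
#' architecture with 32 kernels per layer remains the package default via
#' [cnnSpec()] and [cwtConfig()].
#'
#' @param seed master seed.
#' @param epochs training epochs.
#' @return A `PipelineConfig`.
#' @export
afStudyConfig <- function(seed = 1L, epochs = 8L) {
    pipelineConfig(
        nRecords = 50L, classBalance = 0.5, duration = 200, fs = 250,
        cwt = cwtConfig(nScales = 64L, outSize = c(64L, 64L)),
        cnn = cnnSpec(inputShape = c(64L, 64L, 5L),
                      convLayers = cbind(nKernels = c(6L, 6L, 6L, 6L),
                                         kernelSize = c(10L, 10L, 8L, 4L)),
                      fcNeurons = c(64L, 1L), convActivation = "relu",
                      dropoutRates = c(0.1, 0.1, 0.25)),
        train = trainConfig(learningRate = 0.01, momentum = 0.8,
                            weightDecay = 1e-6, epochs = epochs,
                            batchSize = 32L, seed = seed),
        split = splitSpec(total = 2000L, seed = seed),
        seed = seed)
}
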