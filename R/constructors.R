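#' Construct rhythm parameters
#'
#' Convenience constructor with per-class defaults. `rhythmParams("NSR")`
#' gives a 70 bpm sinus rhythm with low RR variability and a P wave;
#' `rhythmParams("AF")` gives a 95 bpm rhythm with high RR variability
#' (coefficient of variation 0.2), no P wave and 4--10 Hz f-waves.
#'
#' @param rhythmClass "NSR" or "AF".
#' @param ... slot overrides, e.g. `meanHr = 80`.
#' @return A [RhythmParams-class] object.
#' @examples
#' rhythmParams("AF", meanHr = 110)
#' @export
rhythmParams <- function(rhythmClass = c("NSR", "AF"), ...) {
    rhythmClass <- match.arg(rhythmClass)
    defaults <- if (rhythmClass == "AF") {
        list(rhythmClass = "AF", meanHr = 95, rrCv = 0.2, pAmp = 0,
             fWaveAmp = 0.08)
    } else {
        list(rhythmClass = "NSR", meanHr = 70, rrCv = 0.04, pAmp = 0.15,
             fWaveAmp = 0)
    }
    args <- modifyList(defaults, list(...))
    do.call(new, c("RhythmParams", args))
}

#' Construct a noise specification
#'
#' Defaults exercise the denoiser: 0.2 mV baseline wander at 0.3 Hz, 0.05 mV
#' white noise and 0.03 mV mains interference at 50 Hz.
#'
#' @param ... slot overrides; `noiseSpec(hfNoiseSd = 0)` etc.
#' @return A [NoiseSpec-class] object.
#' @examples
#' noiseSpec()                      # default noise mix
#' noiseSpec(baselineWanderAmp = 0, hfNoiseSd = 0, powerlineAmp = 0)
#' @export
noiseSpec <- function(...) new("NoiseSpec", ...)

#' Construct an annotated ECG record
#'
#' @param samples signal, mV.
#' @param fs sampling rate, Hz.
#' @param rPeaks 0-based R-peak sample indices, strictly increasing.
#' @param beatLabels one rhythm label per R peak.
#' @param recordId identifier used as the subject key in splits.
#' @param seed generating seed, or NA for real data.
#' @return An [EcgRecord-class] object.
#' @export
ecgRecord <- function(samples, fs = 250, rPeaks = integer(),
                      beatLabels = character(), recordId = "rec",
                      seed = NA_integer_) {
    new("EcgRecord", samples = as.numeric(samples), fs = fs,
        rPeaks = as.integer(rPeaks), beatLabels = as.character(beatLabels),
        recordId = as.character(recordId), seed = as.integer(seed))
}

#' Construct a CWT configuration
#'
#' @param waveletName mother wavelet (default "db5").
#' @param nScales number of log-spaced scale rows (default 128).
#' @param freqMin,freqMax covered frequency band, Hz (default 0.5--30).
#' @param outSize output pattern size, `(rows, cols)`.
#' @param normalization per-pattern min-max normalization.
#' @return A [CwtConfig-class] object.
#' @export
cwtConfig <- function(waveletName = "db5", nScales = 128L, freqMin = 0.5,
                      freqMax = 30, outSize = c(128L, 128L),
                      normalization = "per_pattern_minmax") {
    new("CwtConfig", waveletName = waveletName, nScales = as.integer(nScales),
        freqMin = freqMin, freqMax = freqMax, outSize = as.integer(outSize),
        normalization = normalization)
}

#' Construct a CNN architecture specification
#'
#' @param inputShape `(rows, cols, channels)`, default `c(128, 128, 5)`.
#' @param convLayers matrix (or list of pairs) of `(nKernels, kernelSize)`
#'   per convolutional layer.
#' @param poolAfter conv-layer positions followed by pooling.
#' @param poolSize square pooling window, default 2.
#' @param poolType "max" or "avg".
#' @param dropoutRates three dropout fractions.
#' @param fcNeurons fully connected layer sizes, ending in 1.
#' @param convActivation "sigmoid" or "relu" for hidden layers.
#' @return A [CnnSpec-class] object.
#' @examples
#' spec <- cnnSpec()
#' shapeTrace(spec)
#' @export
cnnSpec <- function(inputShape = c(128L, 128L, 5L),
                    convLayers = cbind(nKernels = c(32L, 32L, 32L, 32L),
                                       kernelSize = c(10L, 10L, 8L, 4L)),
                    poolAfter = c(2L, 4L), poolSize = 2L, poolType = "max",
                    dropoutRates = c(0.25, 0.25, 0.5),
                    fcNeurons = c(256L, 1L), convActivation = "sigmoid") {
    if (is.list(convLayers))
        convLayers <- do.call(rbind, convLayers)
    convLayers <- matrix(as.integer(convLayers), ncol = 2L,
                         dimnames = list(NULL, c("nKernels", "kernelSize")))
    new("CnnSpec", inputShape = as.integer(inputShape),
        convLayers = convLayers, poolAfter = as.integer(poolAfter),
        poolSize = as.integer(poolSize), poolType = poolType,
        dropoutRates = dropoutRates, fcNeurons = as.integer(fcNeurons),
        convActivation = convActivation, padding = "valid")
}

#' Construct a training configuration
#'
#' @param learningRate initial learning rate (default 0.001).
#' @param momentum momentum coefficient (default 0.8).
#' @param weightDecay L2 decay rate (default 1e-6).
#' @param epochs training epochs (default 50).
#' @param batchSize mini-batch size (default 128).
#' @param seed RNG seed.
#' @param decisionThreshold AF decision threshold (default 0.5).
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(learningRate = 0.001, momentum = 0.8,
                        weightDecay = 1e-6, epochs = 50L, batchSize = 128L,
                        seed = 1L, decisionThreshold = 0.5) {
    new("TrainConfig", learningRate = learningRate, momentum = momentum,
        weightDecay = weightDecay, epochs = as.integer(epochs),
        batchSize = as.integer(batchSize), seed = as.integer(seed),
        decisionThreshold = decisionThreshold)
}

#' Construct a split specification
#'
#' @param total number of instances to select overall (even).
#' @param trainFraction training share, default 0.8 (4:1).
#' @param seed RNG seed.
#' @return A [SplitSpec-class] object.
#' @export
splitSpec <- function(total = 100000L, trainFraction = 0.8, seed = 1L) {
    new("SplitSpec", total = as.integer(total), trainFraction = trainFraction,
        balance = "equal_classes", seed = as.integer(seed))
}
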