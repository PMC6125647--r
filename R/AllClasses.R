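#' @import methods
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rlnorm runif approx fft mvfft nextn sd quantile
#' @importFrom utils head tail read.csv write.csv modifyList
#' @useDynLib fibriwave, .registration = TRUE
NULL

RHYTHM_CLASSES <- c("NSR", "AF")
BINARY_LABELS <- c("non-AF", "AF")

#' Rhythm parameter set for the synthetic ECG generator
#'
#' Describes one rhythm class in terms of heart rate, RR-interval
#' variability and waveform morphology. Normal sinus rhythm (NSR) carries a
#' P wave and no fibrillatory waves; atrial fibrillation (AF) has no P wave
#' and a continuous low-amplitude f-wave component in the 4--10 Hz band.
#'
#' @slot rhythmClass `"NSR"` or `"AF"`.
#' @slot meanHr mean heart rate, beats/min.
#' @slot rrCv coefficient of variation of the RR interval (dimensionless).
#' @slot pAmp P-wave amplitude, mV (must be 0 for AF).
#' @slot fWaveAmp f-wave amplitude, mV (must be 0 for NSR, > 0 for AF).
#' @slot fWaveFreqRange two-element frequency range of f-waves, Hz.
#' @slot qrsAmp R-wave amplitude, mV.
#' @slot tAmp T-wave amplitude, mV.
#' @exportClass RhythmParams
setClass("RhythmParams",
    representation(
        rhythmClass = "character",
        meanHr = "numeric",
        rrCv = "numeric",
        pAmp = "numeric",
        fWaveAmp = "numeric",
        fWaveFreqRange = "numeric",
        qrsAmp = "numeric",
        tAmp = "numeric"
    ),
    prototype(
        rhythmClass = "NSR", meanHr = 70, rrCv = 0.04, pAmp = 0.15,
        fWaveAmp = 0, fWaveFreqRange = c(4, 10), qrsAmp = 1.0, tAmp = 0.3
    )
)

setValidity("RhythmParams", function(object) {
    msg <- character()
    if (!(object@rhythmClass %in% RHYTHM_CLASSES))
        msg <- c(msg, "rhythmClass must be 'NSR' or 'AF'")
    if (length(object@meanHr) != 1L || !is.finite(object@meanHr) ||
        object@meanHr <= 0)
        msg <- c(msg, "meanHr must be a single positive number")
    if (object@rrCv < 0) msg <- c(msg, "rrCv must be >= 0")
    if (length(object@fWaveFreqRange) != 2L ||
        diff(object@fWaveFreqRange) <= 0)
        msg <- c(msg, "fWaveFreqRange must be an increasing pair (Hz)")
    if (object@rhythmClass == "AF") {
        if (object@pAmp != 0)
            msg <- c(msg, "AF implies pAmp == 0 (no P wave)")
        if (object@fWaveAmp <= 0)
            msg <- c(msg, "AF implies fWaveAmp > 0")
    } else {
        if (object@fWaveAmp != 0)
            msg <- c(msg, "NSR implies fWaveAmp == 0")
    }
    if (length(msg)) msg else TRUE
})

#' Additive noise specification for synthetic ECG
#'
#' Baseline wander, broadband high-frequency noise and mains interference
#' added on top of the clean synthetic signal.
#'
#' @slot baselineWanderAmp amplitude of the baseline wander sinusoid, mV.
#' @slot baselineWanderFreq baseline wander frequency, Hz.
#' @slot hfNoiseSd standard deviation of additive white noise, mV.
#' @slot powerlineAmp mains interference amplitude, mV.
#' @slot powerlineFreq mains frequency, Hz.
#' @exportClass NoiseSpec
setClass("NoiseSpec",
    representation(
        baselineWanderAmp = "numeric",
        baselineWanderFreq = "numeric",
        hfNoiseSd = "numeric",
        powerlineAmp = "numeric",
        powerlineFreq = "numeric"
    ),
    prototype(
        baselineWanderAmp = 0.2, baselineWanderFreq = 0.3,
        hfNoiseSd = 0.05, powerlineAmp = 0.03, powerlineFreq = 50
    )
)

setValidity("NoiseSpec", function(object) {
    amps <- c(object@baselineWanderAmp, object@hfNoiseSd, object@powerlineAmp)
    if (any(amps < 0)) "all noise amplitudes must be >= 0" else TRUE
})

#' Annotated single-lead ECG record
#'
#' A sampled ECG signal together with its R-peak annotations and one rhythm
#' label per beat. Sample indices (`rPeaks`, and window starts derived from
#' them) are 0-based offsets into the signal, the convention of WFDB-style
#' annotation files; accessor code converts when subscripting R vectors.
#'
#' @slot samples signal, mV.
#' @slot fs sampling rate, Hz.
#' @slot rPeaks strictly increasing 0-based sample indices of R peaks.
#' @slot beatLabels rhythm label per R peak ("NSR", "AF", or other codes).
#' @slot recordId opaque identifier; acts as the subject key for
#'   record-disjoint splitting.
#' @slot seed integer seed the record was generated from (NA for real data).
#' @exportClass EcgRecord
setClass("EcgRecord",
    representation(
        samples = "numeric",
        fs = "numeric",
        rPeaks = "integer",
        beatLabels = "character",
        recordId = "character",
        seed = "integer"
    ),
    prototype(fs = 250, seed = NA_integer_)
)

setValidity("EcgRecord", function(object) {
    msg <- character()
    if (length(object@fs) != 1L || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (length(object@rPeaks) > 1L && any(diff(object@rPeaks) <= 0))
        msg <- c(msg, "rPeaks must be strictly increasing")
    if (length(object@rPeaks) != length(object@beatLabels))
        msg <- c(msg, "one beatLabel per rPeak required")
    if (length(object@rPeaks) &&
        (min(object@rPeaks) < 0L ||
         max(object@rPeaks) >= length(object@samples)))
        msg <- c(msg, "rPeaks must lie inside [0, length(samples))")
    if (length(msg)) msg else TRUE
})

#' Analysis/synthesis filter pair for the dyadic wavelet transform
#'
#' `h` is the low-pass (scaling) filter feeding the approximations and `g`
#' the high-pass (wavelet) filter feeding the details, both in the
#' orthonormal convention (sum of `h` equals sqrt(2)).
#'
#' @slot h low-pass filter coefficients.
#' @slot g high-pass filter coefficients.
#' @slot waveletName identifier, e.g. `"db4"`.
#' @exportClass FilterPair
setClass("FilterPair",
    representation(h = "numeric", g = "numeric", waveletName = "character"))

setValidity("FilterPair", function(object) {
    if (!length(object@h) || !length(object@g) ||
        any(!is.finite(object@h)) || any(!is.finite(object@g)))
        "filter coefficients must be nonempty and finite" else TRUE
})

#' Undecimated dyadic wavelet decomposition
#'
#' Holds the per-scale smooth approximations S_j and detail series W_j of
#' the translation-invariant (a trous) transform; every stored series has
#' the input length.
#'
#' @slot approximations list of J numeric series S_1..S_J.
#' @slot details list of J numeric series W_1..W_J.
#' @slot J number of scales.
#' @slot fs sampling rate of the decomposed signal, Hz.
#' @slot filters the [FilterPair-class] used.
#' @exportClass DyadicDecomposition
setClass("DyadicDecomposition",
    representation(
        approximations = "list",
        details = "list",
        J = "integer",
        fs = "numeric",
        filters = "FilterPair"
    )
)

setValidity("DyadicDecomposition", function(object) {
    msg <- character()
    if (object@J < 1L) msg <- c(msg, "J must be >= 1")
    if (length(object@approximations) != object@J ||
        length(object@details) != object@J)
        msg <- c(msg, "need one approximation and one detail per scale")
    n <- unique(c(lengths(object@approximations), lengths(object@details)))
    if (length(n) > 1L)
        msg <- c(msg, "all stored series must share the input length")
    if (length(msg)) msg else TRUE
})

#' One fixed-length beat window
#'
#' A window of `L` samples (default 300, i.e. 1.2 s at 250 Hz) anchored at
#' one R peak and positioned by the 2/3-RR rule. Indices are 0-based.
#'
#' @slot samples the window signal, mV; exactly L samples.
#' @slot startIndex 0-based start sample in the parent record.
#' @slot rIndex 0-based sample index of the anchoring R peak.
#' @slot label rhythm label of the anchoring beat.
#' @exportClass BeatWindow
setClass("BeatWindow",
    representation(
        samples = "numeric",
        startIndex = "integer",
        rIndex = "integer",
        label = "character"
    )
)

setValidity("BeatWindow", function(object) {
    if (object@startIndex < 0L) "startIndex must be >= 0" else TRUE
})

#' A labeled group of consecutive beat windows
#'
#' Five (by default) consecutive beat windows from one record whose beat
#' labels agree, carrying the binary instance label.
#'
#' @slot windows list of [BeatWindow-class] objects, consecutive beats.
#' @slot label `"AF"` or `"non-AF"`.
#' @slot recordId provenance record identifier.
#' @exportClass EcgInstance
setClass("EcgInstance",
    representation(windows = "list", label = "character",
                   recordId = "character"))

setValidity("EcgInstance", function(object) {
    msg <- character()
    if (!(object@label %in% BINARY_LABELS))
        msg <- c(msg, "label must be 'AF' or 'non-AF'")
    if (!all(vapply(object@windows, is, logical(1), "BeatWindow")))
        msg <- c(msg, "windows must all be BeatWindow objects")
    if (length(msg)) msg else TRUE
})

#' Continuous wavelet transform configuration
#'
#' @slot waveletName mother wavelet identifier (default `"db5"`).
#' @slot nScales number of scale rows (default 128).
#' @slot freqMin,freqMax frequency band covered by the log-spaced scale
#'   grid, Hz.
#' @slot outSize output pattern size `(rows, cols)` (default c(128, 128)).
#' @slot normalization `"per_pattern_minmax"`.
#' @exportClass CwtConfig
setClass("CwtConfig",
    representation(
        waveletName = "character",
        nScales = "integer",
        freqMin = "numeric",
        freqMax = "numeric",
        outSize = "integer",
        normalization = "character"
    ),
    prototype(
        waveletName = "db5", nScales = 128L, freqMin = 0.5, freqMax = 30,
        outSize = c(128L, 128L), normalization = "per_pattern_minmax"
    )
)

setValidity("CwtConfig", function(object) {
    msg <- character()
    if (!(object@freqMin > 0 && object@freqMin < object@freqMax))
        msg <- c(msg, "need 0 < freqMin < freqMax")
    if (object@nScales < 2L) msg <- c(msg, "nScales must be >= 2")
    if (length(object@outSize) != 2L || any(object@outSize < 1L))
        msg <- c(msg, "outSize must be two positive integers")
    if (!(object@normalization %in% "per_pattern_minmax"))
        msg <- c(msg, "unknown normalization")
    if (length(msg)) msg else TRUE
})

#' Normalized CWT magnitude pattern
#'
#' @slot pattern matrix of magnitudes min-max normalized to [0, 1]; rows are
#'   scales (ascending center frequency), columns time.
#' @slot scaleAxis per-row center frequency, Hz (strictly monotone).
#' @slot timeAxis per-column time, s.
#' @exportClass Scalogram
setClass("Scalogram",
    representation(pattern = "matrix", scaleAxis = "numeric",
                   timeAxis = "numeric"))

setValidity("Scalogram", function(object) {
    msg <- character()
    rng <- range(object@pattern)
    if (rng[1] < 0 || rng[2] > 1)
        msg <- c(msg, "pattern entries must lie in [0, 1]")
    if (nrow(object@pattern) != length(object@scaleAxis))
        msg <- c(msg, "one scaleAxis entry per pattern row required")
    d <- diff(object@scaleAxis)
    if (length(d) && !(all(d > 0) || all(d < 0)))
        msg <- c(msg, "scaleAxis must be strictly monotone")
    if (length(msg)) msg else TRUE
})

#' Stacked five-beat scalogram tensor
#'
#' The network input: one normalized pattern per beat, stacked along the
#' third dimension in beat order, with the binary instance label.
#'
#' @slot tensor numeric array `(rows, cols, nBeats)`, entries in [0, 1].
#' @slot label `"AF"` or `"non-AF"`.
#' @slot recordId provenance record identifier.
#' @slot beatIndices 0-based R-peak indices of the stacked beats.
#' @exportClass InstanceTensor
setClass("InstanceTensor",
    representation(tensor = "array", label = "character",
                   recordId = "character", beatIndices = "integer"))

setValidity("InstanceTensor", function(object) {
    msg <- character()
    if (length(dim(object@tensor)) != 3L)
        msg <- c(msg, "tensor must be a 3D array")
    if (min(object@tensor) < 0 || max(object@tensor) > 1)
        msg <- c(msg, "tensor entries must lie in [0, 1]")
    if (!(object@label %in% BINARY_LABELS))
        msg <- c(msg, "label must be 'AF' or 'non-AF'")
    if (length(msg)) msg else TRUE
})

#' 2D CNN architecture specification
#'
#' Default architecture: four valid-padding, stride-1 convolutional layers
#' of 32 kernels each (sizes 10, 10, 8, 4), 2x2 max-pooling after the 2nd
#' and 4th convolutions, three dropout layers, a flatten layer and two fully
#' connected layers of 256 and 1 neurons, the last with a sigmoid output.
#' With a (128, 128, 5) input this traces to (22, 22, 32) feature maps and a
#' flatten length of 15488.
#'
#' @slot inputShape `(rows, cols, channels)`.
#' @slot convLayers integer matrix with columns `nKernels`, `kernelSize`,
#'   one row per convolutional layer.
#' @slot poolAfter 1-based positions of conv layers followed by pooling.
#' @slot poolSize pooling window (square), default 2.
#' @slot poolType `"max"` (default) or `"avg"`.
#' @slot dropoutRates three dropout fractions (post-pool1, post-pool2,
#'   pre-output).
#' @slot fcNeurons sizes of the fully connected layers, last must be 1.
#' @slot convActivation `"sigmoid"` (default) or `"relu"` for the hidden
#'   layers; the output unit is always sigmoid.
#' @slot padding `"valid"` only.
#' @exportClass CnnSpec
setClass("CnnSpec",
    representation(
        inputShape = "integer",
        convLayers = "matrix",
        poolAfter = "integer",
        poolSize = "integer",
        poolType = "character",
        dropoutRates = "numeric",
        fcNeurons = "integer",
        convActivation = "character",
        padding = "character"
    ),
    prototype(
        inputShape = c(128L, 128L, 5L),
        convLayers = cbind(nKernels = c(32L, 32L, 32L, 32L),
                           kernelSize = c(10L, 10L, 8L, 4L)),
        poolAfter = c(2L, 4L),
        poolSize = 2L,
        poolType = "max",
        dropoutRates = c(0.25, 0.25, 0.5),
        fcNeurons = c(256L, 1L),
        convActivation = "sigmoid",
        padding = "valid"
    )
)

setValidity("CnnSpec", function(object) {
    msg <- character()
    if (length(object@inputShape) != 3L || any(object@inputShape < 1L))
        msg <- c(msg, "inputShape must be three positive integers")
    if (ncol(object@convLayers) != 2L || any(object@convLayers < 1L))
        msg <- c(msg, "convLayers must be an (nKernels, kernelSize) matrix")
    if (any(object@poolAfter < 1L) ||
        any(object@poolAfter > nrow(object@convLayers)))
        msg <- c(msg, "poolAfter positions must index conv layers")
    if (!(object@poolType %in% c("max", "avg")))
        msg <- c(msg, "poolType must be 'max' or 'avg'")
    if (any(object@dropoutRates < 0) || any(object@dropoutRates >= 1))
        msg <- c(msg, "dropoutRates must lie in [0, 1)")
    if (tail(object@fcNeurons, 1L) != 1L)
        msg <- c(msg, "final fully connected layer must have exactly 1 unit")
    if (!(object@convActivation %in% c("sigmoid", "relu")))
        msg <- c(msg, "convActivation must be 'sigmoid' or 'relu'")
    if (!identical(object@padding, "valid"))
        msg <- c(msg, "only valid padding is supported")
    if (length(msg)) msg else TRUE
})

#' Training configuration for the CNN
#'
#' Defaults follow the reference hyperparameter set: stochastic gradient
#' descent with learning rate 0.001, momentum 0.8, weight decay 1e-6 and 50
#' epochs, binary cross-entropy loss on the sigmoid output.
#'
#' @slot learningRate initial learning rate.
#' @slot momentum momentum coefficient.
#' @slot weightDecay L2 weight decay rate.
#' @slot epochs number of passes over the training set.
#' @slot batchSize mini-batch size.
#' @slot loss `"binary_cross_entropy"`.
#' @slot optimizer `"sgd"`.
#' @slot seed integer RNG seed for initialization, shuffling and dropout.
#' @slot decisionThreshold probability threshold for the AF call; a
#'   probability >= threshold is labeled AF.
#' @exportClass TrainConfig
setClass("TrainConfig",
    representation(
        learningRate = "numeric",
        momentum = "numeric",
        weightDecay = "numeric",
        epochs = "integer",
        batchSize = "integer",
        loss = "character",
        optimizer = "character",
        seed = "integer",
        decisionThreshold = "numeric"
    ),
    prototype(
        learningRate = 0.001, momentum = 0.8, weightDecay = 1e-6,
        epochs = 50L, batchSize = 128L, loss = "binary_cross_entropy",
        optimizer = "sgd", seed = 1L, decisionThreshold = 0.5
    )
)

setValidity("TrainConfig", function(object) {
    msg <- character()
    if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (!(object@decisionThreshold > 0 && object@decisionThreshold < 1))
        msg <- c(msg, "decisionThreshold must lie in (0, 1)")
    if (!identical(object@loss, "binary_cross_entropy"))
        msg <- c(msg, "only binary_cross_entropy loss is supported")
    if (!identical(object@optimizer, "sgd"))
        msg <- c(msg, "only sgd is supported")
    if (length(msg)) msg else TRUE
})

#' A constructed (possibly trained) CNN model
#'
#' @slot spec the [CnnSpec-class] the model was built from.
#' @slot layers internal layer list with weight arrays.
#' @slot trace data.frame of per-layer output shapes.
#' @slot history per-epoch training loss and accuracy (empty until trained).
#' @exportClass CnnModel
setClass("CnnModel",
    representation(spec = "CnnSpec", layers = "list", trace = "data.frame",
                   history = "data.frame"))

#' Balanced record-disjoint split specification
#'
#' @slot total number of instances to select (equal class counts).
#' @slot trainFraction fraction assigned to training (default 0.8, i.e. 4:1).
#' @slot balance `"equal_classes"`.
#' @slot seed RNG seed for subsampling and record shuffling.
#' @exportClass SplitSpec
setClass("SplitSpec",
    representation(total = "integer", trainFraction = "numeric",
                   balance = "character", seed = "integer"),
    prototype(total = 100000L, trainFraction = 0.8,
              balance = "equal_classes", seed = 1L)
)

setValidity("SplitSpec", function(object) {
    msg <- character()
    if (!(object@trainFraction > 0 && object@trainFraction < 1))
        msg <- c(msg, "trainFraction must lie in (0, 1)")
    if (!identical(object@balance, "equal_classes"))
        msg <- c(msg, "only equal_classes balancing is supported")
    if (object@total %% 2L != 0L)
        msg <- c(msg, "total must be even under equal_classes")
    if (length(msg)) msg else TRUE
})

#' Binary confusion counts and derived metrics
#'
#' Sensitivity Se = TP/(TP+FN), specificity Sp = TN/(TN+FP), positive
#' predictive value PPV = TP/(TP+FP) and accuracy
#' Acc = (TP+TN)/(TP+FP+TN+FN), each times 100%. A metric whose denominator
#' is zero is reported as NA (undefined), never coerced to 0 or 100.
#'
#' @slot tp,fn,tn,fp confusion counts (AF is the positive class).
#' @slot se,sp,ppv,acc percentages in [0, 100], or NA when undefined.
#' @exportClass ConfusionMetrics
setClass("ConfusionMetrics",
    representation(tp = "integer", fn = "integer", tn = "integer",
                   fp = "integer", se = "numeric", sp = "numeric",
                   ppv = "numeric", acc = "numeric"))

setValidity("ConfusionMetrics", function(object) {
    counts <- c(object@tp, object@fn, object@tn, object@fp)
    msg <- character()
    if (any(counts < 0L)) msg <- c(msg, "counts must be >= 0")
    pct <- c(object@se, object@sp, object@ppv, object@acc)
    if (any(pct < -1e-9 | pct > 100 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "percentages must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})
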