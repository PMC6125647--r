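# shared fixture builders; everything is generated in code

cleanNoise <- function() {
    noiseSpec(baselineWanderAmp = 0, hfNoiseSd = 0, powerlineAmp = 0)
}

# a labeled beat window without a parent record
makeWindow <- function(label, L = 300L) {
    new("BeatWindow", samples = numeric(L), startIndex = 0L, rIndex = 0L,
        label = label)
}

windowList <- function(labels, L = 300L, recordId = "rec") {
    out <- lapply(labels, makeWindow, L = L)
    attr(out, "recordId") <- recordId
    out
}

# constant-intensity toy tensor for classifier tests (small spatial size)
toyTensor <- function(value, label, side = 32L, id = "toy") {
    new("InstanceTensor", tensor = array(value, c(side, side, 5L)),
        label = label, recordId = id, beatIndices = 0:4)
}

# linearly separable toy task: two intensity clusters
toyTask <- function(nPerClass = 50L, side = 32L, seed = 1L) {
    set.seed(seed)
    c(lapply(runif(nPerClass, 0.15, 0.25), toyTensor, label = "non-AF",
             side = side),
      lapply(runif(nPerClass, 0.75, 0.85), toyTensor, label = "AF",
             side = side))
}

# small CNN spec matched to the toy tensors
toySpec <- function(side = 32L) {
    cnnSpec(inputShape = c(side, side, 5L),
            convLayers = list(c(4L, 5L), c(4L, 3L)),
            poolAfter = c(1L, 2L), fcNeurons = c(16L, 1L),
            convActivation = "relu", dropoutRates = c(0, 0, 0))
}

rms <- function(x) sqrt(mean(x^2))

relL2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

toneAt <- function(freq, n = 2048L, fs = 250) {
    sin(2 * pi * freq * (seq_len(n) - 1L) / fs)
}
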