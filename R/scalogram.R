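.fibriCache <- new.env(parent = emptyenv())

#' Sample a Daubechies mother wavelet by cascade refinement
#'
#' Runs the cascade algorithm: a delta is passed once through the high-pass
#' synthesis step and then repeatedly through the upsampled low-pass
#' refinement, converging to the mother wavelet sampled on a dyadic grid
#' over its compact support (length 2N-1 time units for dbN). The samples
#' are mean-subtracted and L2-normalized (`sum(psi^2) * dt == 1`). The
#' center frequency is the dominant frequency of the sampled wavelet's
#' spectrum (zero-padded for sub-bin resolution), in cycles per unit scale.
#'
#' @param waveletName `"db4"` or `"db5"`.
#' @param resolution samples per unit support, rounded up to a power of two
#'   (default 1024, minimum 256).
#' @return List with `grid` (time points), `values` (wavelet samples) and
#'   `centerFreq` (Hz times scale unit).
#' @examples
#' mw <- sampleMotherWavelet("db5")
#' max(mw$grid)      # 9 time units: support 2N-1 for N = 5
#' mw$centerFreq     # ~0.667
#' @export
sampleMotherWavelet <- function(waveletName = "db5", resolution = 1024L) {
    if (resolution < 256) stop("resolution must be >= 256 points per unit")
    level <- ceiling(log2(resolution))
    key <- sprintf("mw_%s_%d", waveletName, level)
    if (!is.null(.fibriCache[[key]])) return(.fibriCache[[key]])
    fp <- waveletFilters(waveletName)
    upsample2 <- function(x) {
        out <- numeric(2L * length(x) - 1L)
        out[seq(1L, length(out), by = 2L)] <- x
        out
    }
    # delta -> g once, then refine with h; sqrt(2) keeps dyadic scaling
    psi <- fp@g * sqrt(2)
    for (i in seq_len(level - 1L))
        psi <- convolve(upsample2(psi), rev(fp@h * sqrt(2)), type = "open")
    dt <- 2^-(level)
    grid <- (seq_along(psi) - 1L) * dt
    psi <- psi - mean(psi)
    psi <- psi / sqrt(sum(psi^2) * dt)
    # center frequency: peak response under the transform's 1/sqrt(a)
    # amplitude normalization, i.e. argmax of sqrt(f)*|psi_hat(f)| -- this
    # calibration makes the scale-to-frequency map unbiased for tones.
    # Zero-padded 16x for sub-bin precision.
    nPad <- 16L * length(psi)
    spec <- Mod(fft(c(psi, numeric(nPad - length(psi)))))
    half <- seq_len(nPad %/% 2L)
    fAxis <- (half - 1L) / (nPad * dt)
    centerFreq <- fAxis[which.max(sqrt(fAxis) * spec[half])]
    out <- list(grid = grid, values = psi, centerFreq = centerFreq)
    .fibriCache[[key]] <- out
    out
}

# FFT correlation plan for a fixed (window length, fs, config): discretized
# 1/sqrt(a)-normalized kernels at every scale, pre-transformed
.cwtPlan <- function(n, fs, config) {
    key <- sprintf("plan_%d_%g_%s_%d_%g_%g", n, fs, config@waveletName,
                   config@nScales, config@freqMin, config@freqMax)
    if (!is.null(.fibriCache[[key]])) return(.fibriCache[[key]])
    mw <- sampleMotherWavelet(config@waveletName)
    freqs <- exp(seq(log(config@freqMin), log(config@freqMax),
                     length.out = config@nScales))
    scales <- mw$centerFreq * fs / freqs        # in samples
    support <- max(mw$grid)
    lens <- pmax(3L, as.integer(floor(support * scales)) + 1L)
    pad <- max(lens %/% 2L)
    nExt <- n + 2L * pad
    N <- nextn(nExt + max(lens) - 1L, c(2L, 3L, 5L))
    kernFft <- matrix(0 + 0i, nrow = N, ncol = config@nScales)
    offsets <- integer(config@nScales)
    for (r in seq_len(config@nScales)) {
        a <- scales[r]
        k <- seq_len(lens[r]) - 1L
        vals <- approx(mw$grid, mw$values, xout = k / a, rule = 2)$y /
            sqrt(a)
        offsets[r] <- lens[r] %/% 2L
        kernFft[, r] <- fft(c(rev(vals), numeric(N - lens[r])))
    }
    # symmetric (tiled reflection) extension indices for the window:
    # position p in 1-pad .. n+pad maps into 1..n via the period-2n
    # half-sample-symmetric reflection sequence
    refl <- c(seq_len(n), rev(seq_len(n)))
    extIdx <- refl[(((1L - pad):(n + pad)) - 1L) %% (2L * n) + 1L]
    # conv index of correlation output position b (1-based slice start)
    sliceStart <- pad - offsets + lens - 1L + 1L
    out <- list(N = N, pad = pad, nExt = nExt, extIdx = extIdx,
                kernFft = kernFft, lens = lens, sliceStart = sliceStart,
                freqs = freqs, scales = scales, n = n, fs = fs)
    .fibriCache[[key]] <- out
    out
}

#' Continuous wavelet transform of a beat window
#'
#' Correlates the window with the 1/sqrt(a)-normalized mother wavelet at
#' every sample shift, for scales derived from `nScales` log-spaced center
#' frequencies between `freqMin` and `freqMax`
#' (`a = centerFreq * fs / f`). FFT-based, same-length output, symmetric
#' boundary extension. Returns coefficient magnitudes; row r corresponds to
#' `scaleAxis[r]` Hz, ascending.
#'
#' @param window finite numeric series (>= 8 samples).
#' @param fs sampling rate, Hz.
#' @param config a [CwtConfig-class].
#' @return List with `magnitude` (`nScales` x `length(window)` matrix) and
#'   `scaleAxis` (center frequency per row, Hz).
#' @examples
#' x <- sin(2 * pi * 8 * seq(0, 1.2, length.out = 300))
#' cc <- cwtCoeffs(x, 250, cwtConfig())
#' cc$scaleAxis[which.max(rowMeans(cc$magnitude))]  # ~8 Hz
#' @export
cwtCoeffs <- function(window, fs, config = cwtConfig()) {
    if (length(window) < 8L) stop("window must have >= 8 samples")
    if (any(!is.finite(window))) stop("window contains non-finite samples")
    if (config@freqMax > fs / 2)
        stop("freqMax must not exceed the Nyquist frequency")
    plan <- .cwtPlan(length(window), fs, config)
    mag <- .cwtApply(matrix(window, ncol = 1L), plan)[, , 1L]
    list(magnitude = mag, scaleAxis = plan$freqs, fs = fs)
}

# batched CWT magnitude: xMat is n x B, returns nScales x n x B
.cwtApply <- function(xMat, plan) {
    n <- plan$n
    B <- ncol(xMat)
    nS <- ncol(plan$kernFft)
    out <- array(0, dim = c(nS, n, B))
    for (b in seq_len(B)) {
        ext <- xMat[plan$extIdx, b]
        fx <- fft(c(ext, numeric(plan$N - plan$nExt)))
        conv <- mvfft(plan$kernFft * fx, inverse = TRUE) / plan$N
        for (r in seq_len(nS))
            out[r, , b] <- Mod(conv[plan$sliceStart[r]:
                                    (plan$sliceStart[r] + n - 1L), r])
    }
    out
}

#' Convert CWT magnitudes to a normalized fixed-size pattern
#'
#' The time axis is resized from the window length to `outSize[2]` columns
#' by linear interpolation, then the whole pattern is min-max normalized to
#' `[0, 1]`. An all-constant matrix maps to all zeros.
#'
#' @param coeffs output of [cwtCoeffs()] (or a magnitude matrix plus a
#'   `scaleAxis` attribute).
#' @param config a [CwtConfig-class]; `outSize` gives the pattern shape.
#' @return A [Scalogram-class] object.
#' @export
asScalogram <- function(coeffs, config = cwtConfig()) {
    mag <- coeffs$magnitude
    if (nrow(mag) != config@outSize[1L])
        stop("coeffs rows must equal outSize[1]; set nScales accordingly")
    nOut <- config@outSize[2L]
    resized <- .resizeCols(mag, nOut)
    rng <- range(resized)
    patt <- if (rng[2] > rng[1]) {
        (resized - rng[1]) / (rng[2] - rng[1])
    } else {
        matrix(0, nrow(resized), ncol(resized))   # degenerate: constant
    }
    fs <- if (is.null(coeffs$fs)) 1 else coeffs$fs
    new("Scalogram", pattern = patt, scaleAxis = coeffs$scaleAxis,
        timeAxis = seq(0, (ncol(mag) - 1L) / fs, length.out = nOut))
}

# linear interpolation of matrix columns to nOut columns
.resizeCols <- function(M, nOut) {
    nIn <- ncol(M)
    if (nIn == nOut) return(M)
    pos <- seq(1, nIn, length.out = nOut)
    lo <- pmin(floor(pos), nIn - 1L)
    w <- pos - lo
    M[, lo, drop = FALSE] * rep(1 - w, each = nrow(M)) +
        M[, lo + 1L, drop = FALSE] * rep(w, each = nrow(M))
}

#' Build the stacked scalogram tensor for one instance
#'
#' Applies [cwtCoeffs()] and [asScalogram()] to each of the instance's beat
#' windows and stacks the patterns in beat order into a
#' `(outSize[1], outSize[2], nBeats)` array.
#'
#' @param instance an [EcgInstance-class] with exactly `nBeats` windows.
#' @param fs sampling rate, Hz.
#' @param config a [CwtConfig-class].
#' @param nBeats required number of windows (default 5).
#' @return An [InstanceTensor-class].
#' @export
instanceTensor <- function(instance, fs, config = cwtConfig(),
                           nBeats = 5L) {
    if (length(instance@windows) != nBeats)
        stop("instance must have exactly ", nBeats, " windows")
    pats <- lapply(instance@windows, function(w) {
        pattern(asScalogram(cwtCoeffs(w@samples, fs, config), config))
    })
    tens <- array(unlist(pats),
                  dim = c(config@outSize[1L], config@outSize[2L], nBeats))
    new("InstanceTensor", tensor = tens, label = instance@label,
        recordId = instance@recordId,
        beatIndices = vapply(instance@windows, function(w) w@rIndex, 1L))
}

#' Batched tensor construction for a list of instances
#'
#' Equivalent to `lapply(instances, instanceTensor, ...)` but shares the
#' FFT plan and batches windows through the transform, which is
#' substantially faster for large datasets.
#'
#' @param instances list of [EcgInstance-class] objects.
#' @param fs sampling rate, Hz.
#' @param config a [CwtConfig-class].
#' @param nBeats windows per instance.
#' @param verbose print progress every 500 instances.
#' @return List of [InstanceTensor-class] objects.
#' @export
instanceTensors <- function(instances, fs, config = cwtConfig(),
                            nBeats = 5L, verbose = FALSE) {
    if (!length(instances)) return(list())
    n <- length(instances[[1L]]@windows[[1L]]@samples)
    plan <- .cwtPlan(n, fs, config)
    nOut <- config@outSize
    out <- vector("list", length(instances))
    for (i in seq_along(instances)) {
        inst <- instances[[i]]
        if (length(inst@windows) != nBeats)
            stop("instance ", i, " does not have ", nBeats, " windows")
        xMat <- vapply(inst@windows, function(w) w@samples, numeric(n))
        mags <- .cwtApply(xMat, plan)
        tens <- array(0, dim = c(nOut[1L], nOut[2L], nBeats))
        for (b in seq_len(nBeats)) {
            resized <- .resizeCols(mags[, , b], nOut[2L])
            rng <- range(resized)
            tens[, , b] <- if (rng[2] > rng[1])
                (resized - rng[1]) / (rng[2] - rng[1]) else 0
        }
        out[[i]] <- new("InstanceTensor", tensor = tens, label = inst@label,
                        recordId = inst@recordId,
                        beatIndices = vapply(inst@windows,
                                             function(w) w@rIndex, 1L))
        if (verbose && i %% 500L == 0L)
            message("  tensors: ", i, "/", length(instances))
    }
    out
}
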