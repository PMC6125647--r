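# Gaussian-bump beat morphology (amplitude mV, width sigma s, center offset
# from the R peak in s). P amplitude and R amplitude come from RhythmParams.
.BUMPS <- list(
    P = list(sigma = 0.025, center = -0.160),
    Q = list(amp = -0.1, sigma = 0.008, center = -0.025),
    R = list(sigma = 0.012, center = 0),
    S = list(amp = -0.1, sigma = 0.008, center = 0.025),
    T = list(sigma = 0.060, center = 0.300)
)

.drawRr <- function(n, params) {
    meanRr <- 60 / params@meanHr
    if (params@rrCv <= 0) return(rep(meanRr, n))
    if (params@rhythmClass == "AF") {
        # long-tailed irregularity: lognormal with the stated mean and CV
        sdlog <- sqrt(log(1 + params@rrCv^2))
        rr <- rlnorm(n, meanlog = log(meanRr) - sdlog^2 / 2, sdlog = sdlog)
    } else {
        rr <- rnorm(n, mean = meanRr, sd = params@rrCv * meanRr)
    }
    pmax(rr, 0.25 * meanRr)   # refractory floor
}

#' Generate one synthetic annotated ECG record
#'
#' Builds a two-class test signal with known ground truth. Each beat is a
#' sum of Gaussian bumps (P, Q, R, S, T) placed relative to its R peak; RR
#' intervals are Gaussian for NSR and lognormal (long-tailed, with the
#' stated coefficient of variation) for AF. AF records omit the P bump and
#' carry a continuous f-wave component: three sinusoids with frequencies
#' drawn uniformly from `fWaveFreqRange` and slowly drifting random phases.
#' Baseline wander, white noise and mains interference are added per the
#' [NoiseSpec-class]. Output is a pure function of the arguments: the same
#' seed reproduces the record bit for bit.
#'
#' @param params a [RhythmParams-class].
#' @param noise a [NoiseSpec-class].
#' @param duration record length, s (must allow at least ~10 beats).
#' @param fs sampling rate, Hz (>= 100).
#' @param seed integer seed.
#' @param recordId identifier stored in the record.
#' @return An [EcgRecord-class] with 0-based `rPeaks` and per-beat labels.
#' @examples
#' rec <- generateRecord(rhythmParams("NSR"), noiseSpec(), duration = 30,
#'                       seed = 1)
#' rec
#' @export
generateRecord <- function(params, noise = noiseSpec(), duration = 60,
                           fs = 250, seed = 1L,
                           recordId = sprintf("sim-%s-%d",
                                              params@rhythmClass, seed)) {
    validObject(params)
    validObject(noise)
    if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
    if (fs < 100) stop("fs must be >= 100 Hz")
    if (duration < 10 * 60 / params@meanHr)
        stop("duration too short: need room for at least ~10 beats")
    if (params@rhythmClass == "AF" && params@pAmp > 0)
        stop("AF parameters must have pAmp == 0")

    n <- as.integer(round(duration * fs))
    tGrid <- (seq_len(n) - 1L) / fs
    sig <- numeric(n)

    set.seed(seed)

    # R-peak times: start half a mean RR in, walk RR draws to the end
    meanRr <- 60 / params@meanHr
    maxBeats <- ceiling(duration / meanRr * (1 + 6 * params@rrCv)) + 10L
    rr <- .drawRr(maxBeats, params)
    rTimes <- 0.5 * meanRr + cumsum(c(0, rr))
    rTimes <- rTimes[rTimes < duration - 1 / fs]
    rIdx <- as.integer(round(rTimes * fs))        # 0-based sample indices
    rIdx <- rIdx[rIdx < n]
    rTimesSnapped <- rIdx / fs                    # bump centers on-grid

    addBump <- function(center, amp, sigma) {
        lo <- max(1L, floor((center - 5 * sigma) * fs) + 1L)
        hi <- min(n, ceiling((center + 5 * sigma) * fs) + 1L)
        if (lo > hi) return(invisible())
        idx <- lo:hi
        sig[idx] <<- sig[idx] +
            amp * exp(-((tGrid[idx] - center)^2) / (2 * sigma^2))
    }
    for (rt in rTimesSnapped) {
        if (params@pAmp > 0)
            addBump(rt + .BUMPS$P$center, params@pAmp, .BUMPS$P$sigma)
        addBump(rt + .BUMPS$Q$center, .BUMPS$Q$amp, .BUMPS$Q$sigma)
        addBump(rt, params@qrsAmp, .BUMPS$R$sigma)
        addBump(rt + .BUMPS$S$center, .BUMPS$S$amp, .BUMPS$S$sigma)
        addBump(rt + .BUMPS$T$center, params@tAmp, .BUMPS$T$sigma)
    }

    if (params@fWaveAmp > 0) {
        fr <- runif(3, params@fWaveFreqRange[1L], params@fWaveFreqRange[2L])
        for (f in fr) {
            # slow random phase drift makes the f-waves irregular
            drift <- cumsum(rnorm(n, sd = 0.02))
            sig <- sig + params@fWaveAmp *
                sin(2 * pi * f * tGrid + runif(1, 0, 2 * pi) + drift)
        }
    }

    if (noise@baselineWanderAmp > 0)
        sig <- sig + noise@baselineWanderAmp *
            sin(2 * pi * noise@baselineWanderFreq * tGrid +
                runif(1, 0, 2 * pi))
    if (noise@powerlineAmp > 0)
        sig <- sig + noise@powerlineAmp *
            sin(2 * pi * noise@powerlineFreq * tGrid + runif(1, 0, 2 * pi))
    if (noise@hfNoiseSd > 0)
        sig <- sig + rnorm(n, sd = noise@hfNoiseSd)

    ecgRecord(sig, fs = fs, rPeaks = rIdx,
              beatLabels = rep(params@rhythmClass, length(rIdx)),
              recordId = recordId, seed = seed)
}

#' Generate a labeled two-class dataset of synthetic records
#'
#' Produces `nRecords` records with unique record ids; a fraction
#' `classBalance` of them are AF and the rest NSR. Per-record seeds are
#' derived deterministically from the master seed, so the whole dataset is
#' reproducible.
#'
#' @param nRecords number of records (>= 2).
#' @param classBalance fraction of AF records, in (0, 1).
#' @param paramsGrid named list with elements `NSR` and `AF` giving the
#'   [RhythmParams-class] for each class.
#' @param noise a [NoiseSpec-class] shared by all records.
#' @param duration per-record duration, s.
#' @param fs sampling rate, Hz.
#' @param seed master seed.
#' @return List of [EcgRecord-class] objects.
#' @examples
#' ds <- makeDataset(4, 0.5, duration = 20, seed = 7)
#' table(vapply(ds, function(r) beatLabels(r)[1], ""))
#' @export
makeDataset <- function(nRecords, classBalance = 0.5,
                        paramsGrid = list(NSR = rhythmParams("NSR"),
                                          AF = rhythmParams("AF")),
                        noise = noiseSpec(), duration = 60, fs = 250,
                        seed = 1L) {
    if (nRecords < 2) stop("nRecords must be >= 2")
    if (classBalance <= 0 || classBalance >= 1)
        stop("classBalance must lie in (0, 1)")
    nAf <- round(nRecords * classBalance)
    classes <- rep(c("AF", "NSR"), c(nAf, nRecords - nAf))
    lapply(seq_len(nRecords), function(i) {
        cls <- classes[i]
        # derived per-record seed, kept within 32-bit integer range
        recSeed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %%
                              .Machine$integer.max)
        generateRecord(paramsGrid[[cls]], noise = noise,
                       duration = duration, fs = fs, seed = recSeed,
                       recordId = sprintf("sim-%03d-%s", i, cls))
    })
}
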