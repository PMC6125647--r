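test_that("NSR generation hits the requested rate and variability", {
    rec <- generateRecord(rhythmParams("NSR", meanHr = 60, rrCv = 0.03),
                          noiseSpec(), duration = 60, fs = 250, seed = 1)
    expect_s4_class(rec, "EcgRecord")
    nBeats <- length(rPeaks(rec))
    expect_gte(nBeats, 58)
    expect_lte(nBeats, 62)
    rr <- diff(rPeaks(rec))
    expect_lt(sd(rr) / mean(rr), 0.1)
    expect_true(all(rPeaks(rec) >= 0 &
                    rPeaks(rec) < length(samples(rec))))
    expect_identical(length(beatLabels(rec)), nBeats)
})

test_that("generation is a pure function of its seed", {
    a <- generateRecord(rhythmParams("AF"), noiseSpec(), 30, seed = 11)
    b <- generateRecord(rhythmParams("AF"), noiseSpec(), 30, seed = 11)
    expect_identical(samples(a), samples(b))
    expect_identical(rPeaks(a), rPeaks(b))
    c <- generateRecord(rhythmParams("AF"), noiseSpec(), 30, seed = 12)
    expect_false(identical(samples(a), samples(c)))
})

test_that("AF records carry f-wave energy and RR irregularity", {
    nsr <- generateRecord(rhythmParams("NSR", meanHr = 60, rrCv = 0.03),
                          cleanNoise(), 60, seed = 1)
    af <- generateRecord(rhythmParams("AF", meanHr = 90, rrCv = 0.2),
                         cleanNoise(), 60, seed = 2)
    interBeat <- function(rec) {
        mask <- rep(TRUE, length(samples(rec)))
        for (r in rPeaks(rec)) {
            lo <- max(1L, r - 24L)
            hi <- min(length(mask), r + 91L)
            mask[lo:hi] <- FALSE
        }
        samples(rec)[mask]
    }
    bandEnergy <- function(x) {
        sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
        f <- sp$freq * 250
        sum(sp$spec[f >= 4 & f <= 10])
    }
    expect_gte(bandEnergy(interBeat(af)) / bandEnergy(interBeat(nsr)), 2)
    cv <- function(rec) {
        rr <- diff(rPeaks(rec))
        sd(rr) / mean(rr)
    }
    expect_gt(cv(af), cv(nsr))
})

test_that("annotated R peaks sit on the true R bump centers", {
    for (cls in c("NSR", "AF")) {
        rec <- generateRecord(rhythmParams(cls), cleanNoise(), 40,
                              seed = 3)
        hits <- vapply(rPeaks(rec), function(r) {
            win <- samples(rec)[(r - 2):(r + 6)]   # r is 0-based
            abs(which.max(win) - 3L) <= 2L
        }, TRUE)
        expect_true(all(hits))
    }
})

test_that("a 4-10 Hz spectral discriminator separates the classes", {
    ds <- makeDataset(20, 0.5, noise = cleanNoise(), duration = 30,
                      seed = 5)
    hasFwaves <- vapply(ds, function(rec) {
        # mask out the QRS-T complexes: f-waves live between beats
        mask <- rep(TRUE, length(samples(rec)))
        for (r in rPeaks(rec)) {
            lo <- max(1L, r - 24L)
            hi <- min(length(mask), r + 91L)
            mask[lo:hi] <- FALSE
        }
        sp <- stats::spec.pgram(samples(rec)[mask], plot = FALSE,
                                taper = 0, spans = 5)
        f <- sp$freq * samplingRate(rec)
        inBand <- mean(sp$spec[f >= 4 & f <= 10])
        outBand <- mean(sp$spec[f > 10 & f <= 20])
        inBand > 2.5 * outBand
    }, TRUE)
    truth <- vapply(ds, function(rec) beatLabels(rec)[1L] == "AF", TRUE)
    expect_identical(hasFwaves, truth)
})

test_that("dataset construction balances classes deterministically", {
    ds <- makeDataset(10, 0.5, duration = 20, seed = 7)
    classes <- vapply(ds, function(r) beatLabels(r)[1L], "")
    expect_identical(sum(classes == "AF"), 5L)
    expect_identical(sum(classes == "NSR"), 5L)
    ids <- vapply(ds, recordId, "")
    expect_identical(anyDuplicated(ids), 0L)
    ds2 <- makeDataset(2, 0.5, duration = 20, seed = 7)
    expect_identical(samples(ds2[[1L]]), samples(ds[[1L]]))
})

test_that("generator rejects inconsistent arguments", {
    expect_error(generateRecord(rhythmParams("NSR"), noiseSpec(),
                                duration = -5), "positive")
    expect_error(generateRecord(rhythmParams("NSR"), noiseSpec(),
                                duration = 2), "too short")
    expect_error(rhythmParams("AF", pAmp = 0.2), "pAmp")
    expect_error(rhythmParams("NSR", fWaveAmp = 0.1), "fWaveAmp")
    expect_error(makeDataset(10, 1.5), "classBalance")
    expect_error(makeDataset(1, 0.5), "nRecords")
})
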