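test_that("cascade refinement yields a normalized compact-support db5", {
    mw <- sampleMotherWavelet("db5")
    expect_equal(max(mw$grid), 9, tolerance = 0.02)   # 2N-1 for N = 5
    expect_lt(abs(mean(mw$values)), 1e-6)
    dt <- mw$grid[2] - mw$grid[1]
    expect_equal(sum(mw$values^2) * dt, 1, tolerance = 1e-6)
    expect_gt(mw$centerFreq, 0)
    mw2 <- sampleMotherWavelet("db5", resolution = 2048)
    expect_lt(abs(mw2$centerFreq - mw$centerFreq) / mw$centerFreq, 0.01)
    expect_error(sampleMotherWavelet("sym9"), "unknown wavelet")
    expect_error(sampleMotherWavelet("db5", resolution = 16), "resolution")
})

test_that("the transform is linear and zero maps to zero", {
    cfg <- cwtConfig()
    z <- cwtCoeffs(numeric(300), 250, cfg)
    expect_identical(max(z$magnitude), 0)
    set.seed(3)
    x <- rnorm(300)
    c1 <- cwtCoeffs(x, 250, cfg)
    c2 <- cwtCoeffs(2 * x, 250, cfg)
    expect_lt(max(abs(c2$magnitude - 2 * c1$magnitude)), 1e-9)
    expect_true(all(diff(c1$scaleAxis) > 0))
    expect_error(cwtCoeffs(numeric(4), 250, cfg), ">= 8 samples")
})

test_that("tones localize to the matching scale row", {
    cfg <- cwtConfig()
    # short beat-window case from the worked example
    cc <- cwtCoeffs(toneAt(8, n = 300), 250, cfg)
    best <- which.max(rowMeans(cc$magnitude))
    nearest <- which.min(abs(cc$scaleAxis - 8))
    expect_lte(abs(best - nearest), 1L)
    # across the band, with enough cycles for the low frequencies
    for (freq in c(2, 4, 8, 16)) {
        cc <- cwtCoeffs(toneAt(freq, n = 1024), 250, cfg)
        best <- which.max(rowMeans(cc$magnitude))
        nearest <- which.min(abs(cc$scaleAxis - freq))
        expect_lte(abs(best - nearest), 1L)
    }
})

test_that("patterns are 128x128, min-max normalized, degenerate-safe", {
    cfg <- cwtConfig()
    cc <- cwtCoeffs(rnorm(300), 250, cfg)
    sg <- asScalogram(cc, cfg)
    expect_identical(dim(pattern(sg)), c(128L, 128L))
    expect_identical(range(pattern(sg)), c(0, 1))
    flat <- asScalogram(list(magnitude = matrix(5, 128, 300),
                             scaleAxis = cc$scaleAxis, fs = 250), cfg)
    expect_true(all(pattern(flat) == 0))
})

test_that("instance tensors stack five patterns in beat order", {
    rec <- generateRecord(rhythmParams("AF"), noiseSpec(), 30, seed = 2)
    inst <- makeInstances(segmentRecord(rec))[[1]]
    tt <- instanceTensor(inst, 250, cwtConfig())
    expect_identical(dim(tensorArray(tt)), c(128L, 128L, 5L))
    expect_gte(min(tensorArray(tt)), 0)
    expect_lte(max(tensorArray(tt)), 1)
    expect_identical(instanceLabel(tt), "AF")
    # permuting the beats permutes the slices identically
    perm <- inst
    perm@windows <- inst@windows[c(3, 1, 2, 5, 4)]
    tp <- instanceTensor(perm, 250, cwtConfig())
    expect_equal(tensorArray(tp)[, , 1], tensorArray(tt)[, , 3])
    expect_equal(tensorArray(tp)[, , 4], tensorArray(tt)[, , 5])
    short <- inst
    short@windows <- inst@windows[1:4]
    expect_error(instanceTensor(short, 250, cwtConfig()), "exactly 5")
})

test_that("batched and per-instance tensor construction agree", {
    rec <- generateRecord(rhythmParams("NSR"), noiseSpec(), 30, seed = 6)
    inst <- makeInstances(segmentRecord(rec))[1:2]
    cfg <- cwtConfig(nScales = 32L, outSize = c(32L, 32L))
    one <- lapply(inst, instanceTensor, fs = 250, config = cfg)
    batch <- instanceTensors(inst, 250, cfg)
    expect_equal(tensorArray(batch[[1]]), tensorArray(one[[1]]),
                 tolerance = 1e-12)
    expect_equal(tensorArray(batch[[2]]), tensorArray(one[[2]]),
                 tolerance = 1e-12)
})

test_that("AF instances carry more f-wave-band pattern energy than NSR", {
    cfg <- cwtConfig(nScales = 64L, outSize = c(64L, 64L))
    ds <- makeDataset(10, 0.5, noise = cleanNoise(), duration = 40,
                      seed = 21)
    bandMean <- function(rec) {
        inst <- makeInstances(segmentRecord(rec))
        tens <- instanceTensors(inst, 250, cfg)
        freqs <- exp(seq(log(0.5), log(30), length.out = 64))
        rows <- which(freqs >= 4 & freqs <= 10)
        mean(vapply(tens, function(tt)
            mean(tensorArray(tt)[rows, , ]), 1))
    }
    means <- vapply(ds, bandMean, 1)
    isAf <- vapply(ds, function(r) beatLabels(r)[1] == "AF", TRUE)
    expect_gt(min(means[isAf]), max(means[!isAf]) * 0.9)
    expect_gt(mean(means[isAf]), mean(means[!isAf]))
})
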