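test_that("db4 filter pair is orthonormal and quadrature-mirrored", {
    fp <- waveletFilters("db4")
    expect_length(fp@h, 8L)
    expect_equal(sum(fp@h), sqrt(2), tolerance = 1e-12)
    expect_equal(sum(fp@h^2), 1, tolerance = 1e-12)
    expect_equal(sum(fp@g), 0, tolerance = 1e-12)
    expect_equal(sum(fp@h * fp@g), 0, tolerance = 1e-12)
    expect_error(waveletFilters("haar9"), "unknown wavelet")
})

test_that("band edges reproduce the dyadic octave table", {
    expect_equal(unname(bandEdges(1, 250)), c(62.5, 125))
    expect_equal(unname(bandEdges(4, 250)), c(7.8125, 15.625))
    expect_equal(unname(bandEdges(1, 2)), c(0.5, 1))
    # adjacent octaves share an edge exactly
    for (j in 1:6)
        expect_identical(bandEdges(j, 250)[["low"]],
                         bandEdges(j + 1, 250)[["high"]])
    expect_error(bandEdges(0, 250), "scaleJ")
    expect_error(bandEdges(1, -1), "fs")
})

test_that("decomposition of a constant has vanishing details", {
    dec <- dyadicDecompose(rep(3, 1024), J = 7)
    for (j in 1:7)
        expect_lt(max(abs(details(dec)[[j]])), 1e-10 * 3)
})

test_that("decompose/reconstruct is a perfect-reconstruction pair", {
    set.seed(42)
    x <- rnorm(2048)
    dec <- dyadicDecompose(x, J = 7)
    expect_lt(relL2(reconstructSignal(dec), x), 1e-8)
    # components telescope: approximation j = approximation j+1 + detail j+1
    for (j in 1:6)
        expect_equal(approximations(dec)[[j]],
                     approximations(dec)[[j + 1]] + details(dec)[[j + 1]],
                     tolerance = 1e-12)
    # zeroing every scale leaves exactly the deepest smooth
    expect_lt(relL2(reconstructSignal(dec, 1:7),
                    approximations(dec)[[7]]), 1e-8)
})

test_that("detail energy concentrates in the band holding a pure tone", {
    for (freq in c(100, 80, 20, 5)) {
        dec <- dyadicDecompose(toneAt(freq), J = 7)
        en <- vapply(details(dec), function(w) sum(w^2), 1)
        inBand <- which(vapply(1:7, function(j) {
            b <- bandEdges(j, 250)
            freq > b[["low"]] && freq <= b[["high"]]
        }, TRUE))
        expect_gte(en[inBand] / sum(en), 0.8)
    }
    # the worked case: 80 Hz lives in scale 1 (62.5-125 Hz)
    dec80 <- dyadicDecompose(toneAt(80), J = 7)
    en80 <- vapply(details(dec80), function(w) sum(w^2), 1)
    expect_gte(en80[1] / sum(en80), 0.9)
})

test_that("zeroing the three finest scales suppresses the 15.6-125 Hz band", {
    tone80 <- toneAt(80)
    dec <- dyadicDecompose(tone80, J = 7)
    out <- reconstructSignal(dec, 1:3)
    expect_lt(rms(out) / rms(tone80), 0.01)   # >= 40 dB attenuation
    tone5 <- toneAt(5)
    kept <- denoiseEcg(tone5, fs = 250)
    expect_lt(abs(rms(kept) / rms(tone5) - 1), 0.1)
})

test_that("denoising is linear and improves SNR on noisy synthetic ECG", {
    set.seed(7)
    x <- rnorm(2048)
    y <- rnorm(2048)
    expect_lt(max(abs(denoiseEcg(2 * x + 3 * y) -
                      (2 * denoiseEcg(x) + 3 * denoiseEcg(y)))), 1e-8)
    # zeroing scales 1-3 also discards the clean QRS energy above 15.6 Hz
    # (~0.05 mV RMS for the 12 ms R bump), which bounds the achievable
    # error; the broadband noise must dominate that floor for denoising
    # to pay off against the clean reference
    params <- rhythmParams("NSR")
    clean <- generateRecord(params, cleanNoise(), 30, seed = 9)
    noisy <- generateRecord(params,
                            noiseSpec(baselineWanderAmp = 0,
                                      powerlineAmp = 0, hfNoiseSd = 0.1),
                            30, seed = 9)
    den <- denoiseEcg(samples(noisy), fs = 250)
    rmseIn <- rms(samples(noisy) - samples(clean))
    rmseOut <- rms(den - samples(clean))
    expect_lt(rmseOut, rmseIn)
    # and the suppressed noise itself is mostly gone: the residual of
    # denoising pure noise keeps only the sub-15.6 Hz eighth of its power
    set.seed(10)
    noise <- rnorm(4096, sd = 0.1)
    expect_lt(rms(denoiseEcg(noise)), 0.6 * rms(noise))
})

test_that("invalid decomposition inputs are rejected", {
    expect_error(dyadicDecompose(rnorm(100), J = 7), "shorter")
    expect_error(dyadicDecompose(c(rnorm(1023), NA), J = 7), "non-finite")
    dec <- dyadicDecompose(rnorm(1024), J = 7)
    expect_error(reconstructSignal(dec, 8), "subset")
})
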