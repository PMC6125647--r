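test_that("the 2/3-RR start rule matches its integer arithmetic", {
    expect_identical(windowStart(0, 300), 200L)
    expect_identical(windowStart(100, 350), 266L)
    expect_identical(windowStart(10, 11), 10L)
    expect_error(windowStart(300, 300), "exceed")
})

test_that("a hand-traced record segments to the expected windows", {
    rec <- ecgRecord(seq_len(1100), fs = 250,
                     rPeaks = c(0, 250, 500, 750),
                     beatLabels = rep("NSR", 4))
    w <- segmentRecord(rec, L = 300)
    expect_length(w, 3L)
    expect_identical(vapply(w, function(x) x@startIndex, 1L),
                     c(166L, 416L, 666L))
    expect_true(all(vapply(w, function(x) length(samples(x)), 1L) == 300L))
    # windows slice the record where they claim to: 0-based [start, start+L)
    expect_identical(samples(w[[1]]), rec@samples[167:466])
})

test_that("windows that would overrun the record are dropped", {
    rec <- ecgRecord(numeric(400), fs = 250, rPeaks = c(0, 250),
                     beatLabels = rep("NSR", 2))
    expect_length(segmentRecord(rec, L = 300), 0L)
})

test_that("segmentation respects the record geometry invariants", {
    rec <- generateRecord(rhythmParams("AF"), noiseSpec(), 60, seed = 13)
    w <- segmentRecord(rec)
    expect_lte(length(w), length(rPeaks(rec)) - 1L)
    n <- length(samples(rec))
    for (x in w) {
        expect_identical(length(samples(x)), 300L)
        expect_gte(x@startIndex, 0L)
        expect_lte(x@startIndex + 300L, n)
    }
    # pure function of the annotations
    w2 <- segmentRecord(rec)
    expect_identical(vapply(w, function(x) x@startIndex, 1L),
                     vapply(w2, function(x) x@startIndex, 1L))
})

test_that("fixed-length windows overlap when RR is shorter than 1.2 s", {
    rec <- generateRecord(rhythmParams("NSR", meanHr = 60, rrCv = 0.02),
                          cleanNoise(), 40, seed = 4)
    w <- segmentRecord(rec)
    starts <- vapply(w, function(x) x@startIndex, 1L)
    expect_true(any(diff(starts) < 300L))
})

test_that("instance grouping follows the block and unanimity policy", {
    expect_length(makeInstances(windowList(rep("AF", 12))), 2L)
    expect_length(makeInstances(windowList(c("AF", "AF", "NSR", "AF",
                                             "AF"))), 0L)
    ii <- makeInstances(windowList(rep(c("AF", "NSR"), each = 5)))
    expect_identical(vapply(ii, instanceLabel, ""), c("AF", "non-AF"))
    expect_length(makeInstances(list()), 0L)
    # rhythms outside the binary task are excluded
    expect_length(makeInstances(windowList(rep("AFL", 5))), 0L)
    # sliding policy emits one instance per position
    expect_length(makeInstances(windowList(rep("AF", 12)),
                                policy = "sliding"), 8L)
})

test_that("degenerate segmentation inputs are rejected", {
    rec <- ecgRecord(numeric(500), fs = 250, rPeaks = 100L,
                     beatLabels = "NSR")
    expect_error(segmentRecord(rec), ">= 2 R peaks")
    rec2 <- ecgRecord(numeric(500), fs = 250, rPeaks = c(0L, 250L),
                      beatLabels = c("NSR", "NSR"))
    expect_error(segmentRecord(rec2, L = 0), "positive")
})
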