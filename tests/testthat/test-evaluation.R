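test_that("confusion counting matches exhaustive enumeration", {
    cm <- confusionCounts(rep(c("AF", "non-AF"), each = 10),
                          rep(c("AF", "non-AF"), each = 10))
    expect_identical(c(cm@tp, cm@tn, cm@fp, cm@fn), c(10L, 10L, 0L, 0L))
    flipped <- confusionCounts(rep(c("non-AF", "AF"), each = 10),
                               rep(c("AF", "non-AF"), each = 10))
    expect_identical(c(flipped@tp, flipped@tn), c(0L, 0L))
    allAf <- confusionCounts(rep("AF", 10),
                             rep(c("AF", "non-AF"), c(3, 7)))
    expect_identical(c(allAf@tp, allAf@fp, allAf@tn, allAf@fn),
                     c(3L, 7L, 0L, 0L))
    expect_error(confusionCounts("AF", c("AF", "AF")), "equal length")
    expect_error(confusionCounts("AFIB", "AF"), "labels")
})

test_that("metric formulas agree with a brute-force label-level oracle", {
    set.seed(99)
    for (i in 1:50) {
        n <- sample(10:200, 1)
        truth <- sample(c("AF", "non-AF"), n, replace = TRUE)
        pred <- sample(c("AF", "non-AF"), n, replace = TRUE)
        cm <- suppressWarnings(confusionCounts(pred, truth))
        # oracle: count every instance individually
        tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
        for (k in seq_len(n)) {
            if (pred[k] == "AF" && truth[k] == "AF") tp <- tp + 1L
            if (pred[k] == "AF" && truth[k] == "non-AF") fp <- fp + 1L
            if (pred[k] == "non-AF" && truth[k] == "non-AF") tn <- tn + 1L
            if (pred[k] == "non-AF" && truth[k] == "AF") fn <- fn + 1L
        }
        expect_identical(c(cm@tp, cm@fp, cm@tn, cm@fn), c(tp, fp, tn, fn))
        expect_identical(tp + fp + tn + fn, n)
        if (tp + fn > 0) expect_equal(cm@se, 100 * tp / (tp + fn))
        if (tn + fp > 0) expect_equal(cm@sp, 100 * tn / (tn + fp))
        if (tp + fp > 0) expect_equal(cm@ppv, 100 * tp / (tp + fp))
        expect_equal(cm@acc, 100 * (tp + tn) / n)
    }
})

test_that("worked metric examples compute exactly", {
    perfect <- confusionMetrics(tp = 1, fn = 0, tn = 1, fp = 0)
    expect_identical(c(perfect@se, perfect@sp, perfect@ppv, perfect@acc),
                     rep(100, 4))
    m <- confusionMetrics(tp = 50, fn = 50, tn = 80, fp = 20)
    expect_equal(m@se, 50)
    expect_equal(m@sp, 80)
    expect_equal(m@ppv, 100 * 50 / 70)
    expect_equal(m@acc, 65)
})

test_that("balanced tables satisfy Acc == (Se + Sp) / 2", {
    set.seed(17)
    for (i in 1:20) {
        npos <- sample(5:50, 1)
        tp <- sample(0:npos, 1)
        tn <- sample(0:npos, 1)
        m <- confusionMetrics(tp = tp, fn = npos - tp, tn = tn,
                              fp = npos - tn)
        expect_equal(m@acc, (m@se + m@sp) / 2, tolerance = 1e-12)
    }
})

test_that("zero denominators are undefined, never coerced", {
    expect_warning(m <- confusionMetrics(tp = 0, fn = 0, tn = 5, fp = 5),
                   "Se undefined")
    expect_true(is.na(m@se))
    expect_false(is.na(m@sp))
    expect_warning(m2 <- confusionMetrics(tp = 0, fn = 5, tn = 5, fp = 0),
                   "PPV undefined")
    expect_identical(m2@se, 0)
})

test_that("the balanced split is record-disjoint and reproducible", {
    set.seed(1)
    labs <- rep(c("AF", "non-AF"), each = 300)
    recs <- c(paste0("a", rep(1:20, each = 15)),
              paste0("n", rep(1:20, each = 15)))
    sp <- balancedSplit(labs, recs, splitSpec(total = 400, seed = 3))
    expect_length(intersect(sp$trainRecords, sp$testRecords), 0L)
    # class counts per side are equal up to record granularity (records
    # here hold ~10 selected instances each and are packed whole)
    maxRec <- max(table(recs))
    trainCounts <- as.integer(table(labs[sp$train]))
    testCounts <- as.integer(table(labs[sp$test]))
    expect_lte(abs(diff(trainCounts)), maxRec)
    expect_lte(abs(diff(testCounts)), maxRec)
    # the selection itself is exactly balanced
    expect_identical(as.integer(table(labs[c(sp$train, sp$test)])),
                     c(200L, 200L))
    expect_identical(length(sp$train) + length(sp$test), 400L)
    # proportion approached at record granularity
    expect_lt(abs(length(sp$train) / 400 - 0.8), 0.1)
    sp2 <- balancedSplit(labs, recs, splitSpec(total = 400, seed = 3))
    expect_identical(sp, sp2)
    sp3 <- balancedSplit(labs, recs, splitSpec(total = 400, seed = 4))
    expect_false(identical(sp$train, sp3$train))
})

test_that("infeasible pools are rejected", {
    labs <- rep(c("AF", "non-AF"), each = 10)
    recs <- rep(c("r1", "r2"), each = 10)   # one record per class
    expect_error(balancedSplit(labs, recs, splitSpec(total = 20)),
                 ">= 2 records")
    expect_error(balancedSplit(labs, paste0("r", 1:20),
                               splitSpec(total = 100)),
                 "balance")
})
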