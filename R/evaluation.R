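#' Balanced, record-disjoint train/test split
#'
#' Selects `spec@total` instances with equal class counts by seeded random
#' subsampling, then partitions *records* (never individual instances)
#' into train and test so that no record contributes to both sets and the
#' instance counts approach the configured proportion (exactly 4:1 when
#' every record holds one instance). Records are packed greedily per class
#' in seeded random order until the training quota is reached.
#'
#' @param labels character vector of instance labels ("AF" / "non-AF").
#' @param recordIds record identifier per instance.
#' @param spec a [SplitSpec-class].
#' @return List with integer index vectors `train` and `test` (into the
#'   input), each class-balanced, and `trainRecords` / `testRecords`.
#' @examples
#' labs <- rep(c("AF", "non-AF"), each = 50)
#' recs <- paste0("r", rep(1:20, each = 5))
#' sp <- balancedSplit(labs, recs, splitSpec(total = 60, seed = 1))
#' intersect(sp$trainRecords, sp$testRecords)  # empty
#' @export
balancedSplit <- function(labels, recordIds, spec = splitSpec()) {
    validObject(spec)
    if (length(labels) != length(recordIds))
        stop("labels and recordIds must have equal length")
    perClass <- spec@total %/% 2L
    idxAf <- which(labels == "AF")
    idxN <- which(labels == "non-AF")
    if (length(idxAf) < perClass || length(idxN) < perClass)
        stop("pool cannot satisfy the balance: need ", perClass,
             " instances per class")
    if (length(unique(recordIds[idxAf])) < 2L ||
        length(unique(recordIds[idxN])) < 2L)
        stop("need >= 2 records per class for a record-disjoint split")
    set.seed(spec@seed)
    keepAf <- sort(sample(idxAf, perClass))
    keepN <- sort(sample(idxN, perClass))

    packClass <- function(keep) {
        recs <- recordIds[keep]
        uRecs <- sample(unique(recs))            # seeded random order
        counts <- as.integer(table(factor(recs, levels = uRecs)))
        target <- spec@trainFraction * length(keep)
        cum <- cumsum(counts)
        # stop at the record count whose cumulative size is closest to the
        # quota (greedy packing at record granularity)
        nTrainRecs <- which.min(abs(cum - target))
        trainRecs <- uRecs[seq_len(nTrainRecs)]
        list(train = keep[recs %in% trainRecs],
             test = keep[!(recs %in% trainRecs)],
             trainRecs = trainRecs,
             testRecs = setdiff(uRecs, trainRecs))
    }
    pAf <- packClass(keepAf)
    pN <- packClass(keepN)
    shared <- intersect(c(pAf$trainRecs, pN$trainRecs),
                        c(pAf$testRecs, pN$testRecs))
    if (length(shared))
        stop("records ", paste(shared, collapse = ", "),
             " hold instances of both classes on opposite sides; ",
             "cannot build a record-disjoint split")
    list(train = sort(c(pAf$train, pN$train)),
         test = sort(c(pAf$test, pN$test)),
         trainRecords = unique(c(pAf$trainRecs, pN$trainRecs)),
         testRecords = unique(c(pAf$testRecs, pN$testRecs)))
}

#' Confusion counts for binary AF classification
#'
#' AF is the positive class: TP counts instances predicted AF that truly
#' are AF, FP predicted AF but truly non-AF, and so on;
#' `tp + fp + tn + fn` equals the number of instances.
#'
#' @param predicted,truth equal-length character vectors of
#'   "AF" / "non-AF" labels.
#' @return A [ConfusionMetrics-class] with counts filled in and the four
#'   derived metrics computed (see [confusionMetrics()]).
#' @examples
#' confusionCounts(rep("AF", 10), rep(c("AF", "non-AF"), each = 5))
#' @export
confusionCounts <- function(predicted, truth) {
    if (length(predicted) != length(truth))
        stop("predicted and truth must have equal length")
    bad <- setdiff(unique(c(predicted, truth)), BINARY_LABELS)
    if (length(bad))
        stop("labels must be 'AF' or 'non-AF'; got: ",
             paste(bad, collapse = ", "))
    tp <- sum(predicted == "AF" & truth == "AF")
    fp <- sum(predicted == "AF" & truth == "non-AF")
    tn <- sum(predicted == "non-AF" & truth == "non-AF")
    fn <- sum(predicted == "non-AF" & truth == "AF")
    confusionMetrics(tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Classification metrics from confusion counts
#'
#' Computes, in percent: sensitivity `Se = TP/(TP+FN) * 100`, specificity
#' `Sp = TN/(TN+FP) * 100`, positive predictive value
#' `PPV = TP/(TP+FP) * 100` and accuracy
#' `Acc = (TP+TN)/(TP+FP+TN+FN) * 100`. A metric with a zero denominator
#' is reported as NA with a warning (undefined, not 0 or 100).
#'
#' @param tp,fn,tn,fp non-negative counts.
#' @return A [ConfusionMetrics-class].
#' @examples
#' confusionMetrics(tp = 50, fn = 50, tn = 80, fp = 20)  # Se 50, Sp 80
#' @export
confusionMetrics <- function(tp, fn, tn, fp) {
    ratio <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined: zero denominator", call. = FALSE)
            return(NA_real_)
        }
        100 * num / den
    }
    new("ConfusionMetrics",
        tp = as.integer(tp), fn = as.integer(fn), tn = as.integer(tn),
        fp = as.integer(fp),
        se = ratio(tp, tp + fn, "Se"),
        sp = ratio(tn, tn + fp, "Sp"),
        ppv = ratio(tp, tp + fp, "PPV"),
        acc = ratio(tp + tn, tp + fp + tn + fn, "Acc"))
}
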