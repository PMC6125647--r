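#' Window start position from the 2/3-RR rule
#'
#' A beat's analysis window starts at two thirds of the previous RR
#' interval: `r_prev + floor(2 * (r_curr - r_prev) / 3)`. Flooring keeps the
#' start on the sample grid.
#'
#' @param rPrev,rCurr 0-based sample indices of the previous and current
#'   R peaks, `rCurr > rPrev`.
#' @return 0-based start sample index.
#' @examples
#' windowStart(0, 300)    # 200
#' windowStart(100, 350)  # 266
#' @export
windowStart <- function(rPrev, rCurr) {
    if (any(rCurr <= rPrev)) stop("rCurr must exceed rPrev")
    as.integer(rPrev + (2L * (as.integer(rCurr) - as.integer(rPrev))) %/% 3L)
}

#' Segment an annotated record into fixed-length beat windows
#'
#' Emits one window per beat from the second onward (the first has no
#' previous RR interval to position from), starting at
#' [windowStart()] of the preceding RR interval and spanning exactly `L`
#' samples (default `round(1.2 * fs)`, i.e. 300 at 250 Hz). Windows that
#' would run past the end of the record are dropped. Because `L` is fixed
#' while RR varies, consecutive windows may overlap (short RR) or leave
#' gaps (long RR); both are intended.
#'
#' @param record an [EcgRecord-class] with >= 2 R peaks.
#' @param L window length in samples; default `round(1.2 * fs)`.
#' @param fs sampling rate override (defaults to the record's).
#' @param signal optional replacement sample series of the record's length
#'   (e.g. the denoised signal); annotations stay those of `record`.
#' @return List of [BeatWindow-class] objects.
#' @examples
#' rec <- generateRecord(rhythmParams("NSR"), noiseSpec(), 30, seed = 1)
#' length(segmentRecord(rec))
#' @export
segmentRecord <- function(record, L = NULL, fs = NULL, signal = NULL) {
    fs <- if (is.null(fs)) record@fs else fs
    if (is.null(L)) L <- as.integer(round(1.2 * fs))
    L <- as.integer(L)
    if (L <= 0L) stop("L must be positive")
    r <- record@rPeaks
    if (length(r) < 2L) stop("record must have >= 2 R peaks")
    x <- if (is.null(signal)) record@samples else signal
    if (length(x) != length(record@samples))
        stop("replacement signal must match the record length")
    n <- length(x)
    out <- vector("list", length(r) - 1L)
    kept <- 0L
    for (i in 2L:length(r)) {
        start <- windowStart(r[i - 1L], r[i])
        if (start + L > n) next               # would overrun the record
        kept <- kept + 1L
        out[[kept]] <- new("BeatWindow",
            samples = x[(start + 1L):(start + L)],
            startIndex = start, rIndex = r[i],
            label = record@beatLabels[i])
    }
    out <- out[seq_len(kept)]
    attr(out, "recordId") <- record@recordId
    out
}

#' Group consecutive beat windows into labeled instances
#'
#' Default policy cuts the window sequence into non-overlapping blocks of
#' `nBeats` consecutive windows. A block is kept only when all its beat
#' labels are unanimous and map to the binary task: "AF" becomes an AF
#' instance, "NSR"/"N" a non-AF instance; blocks containing any other
#' rhythm code, or mixed labels, are discarded. `policy = "sliding"`
#' emits one (stride-1) block per position instead, for data augmentation.
#'
#' @param windows list of [BeatWindow-class] objects (as returned by
#'   [segmentRecord()]); the `recordId` attribute is carried through.
#' @param nBeats windows per instance (default 5).
#' @param policy `"block"` (default, non-overlapping) or `"sliding"`.
#' @return List of [EcgInstance-class] objects (possibly empty).
#' @examples
#' rec <- generateRecord(rhythmParams("AF"), noiseSpec(), 30, seed = 2)
#' length(makeInstances(segmentRecord(rec)))
#' @export
makeInstances <- function(windows, nBeats = 5L,
                          policy = c("block", "sliding")) {
    policy <- match.arg(policy)
    nBeats <- as.integer(nBeats)
    if (nBeats < 1L) stop("nBeats must be >= 1")
    recId <- attr(windows, "recordId")
    if (is.null(recId)) recId <- "unknown"
    nW <- length(windows)
    if (nW < nBeats) return(list())
    starts <- if (policy == "block") {
        seq.int(1L, nW - nBeats + 1L, by = nBeats)
    } else {
        seq.int(1L, nW - nBeats + 1L, by = 1L)
    }
    out <- list()
    for (s in starts) {
        block <- windows[s:(s + nBeats - 1L)]
        labs <- vapply(block, function(w) w@label, "")
        if (length(unique(labs)) != 1L) next        # mixed rhythm: discard
        lab <- labs[1L]
        binary <- if (lab == "AF") "AF"
                  else if (lab %in% c("NSR", "N")) "non-AF"
                  else next                         # other rhythms excluded
        out[[length(out) + 1L]] <- new("EcgInstance", windows = block,
                                       label = binary, recordId = recId)
    }
    out
}
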