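# rhythm-code mapping applied when reading annotation files; extensible by
# the caller. Codes mapping to NA are excluded downstream.
.DEFAULT_RHYTHM_MAP <- c(AFIB = "AF", AF = "AF", N = "NSR", NSR = "NSR")

#' Read / write an ECG signal as CSV
#'
#' The CSV dialect has a header line `time,mV`; the sampling rate is taken
#' from the time column (median step) unless given. Values are written with
#' 17 significant digits so a write/read round trip is exact.
#'
#' @param path file path.
#' @param fs sampling rate override, Hz.
#' @return `readSignal`: an [EcgRecord-class] without annotations.
#' @export
readSignal <- function(path, fs = NULL) {
    df <- read.csv(path)
    if (!all(c("time", "mV") %in% names(df)))
        stop("signal CSV must have columns time,mV")
    if (is.null(fs)) {
        if (nrow(df) < 2L) stop("cannot infer fs from fewer than 2 samples")
        fs <- 1 / stats::median(diff(df$time))
    }
    ecgRecord(df$mV, fs = fs,
              recordId = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname readSignal
#' @param record an [EcgRecord-class].
#' @export
writeSignal <- function(record, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time,mV", con)
    tGrid <- (seq_along(record@samples) - 1L) / record@fs
    writeLines(sprintf("%.17g,%.17g", tGrid, record@samples), con)
    invisible(path)
}

#' Read / write beat annotations as CSV
#'
#' Annotation CSVs have columns `sample_index` (0-based R-peak positions)
#' and `label`. On reading, rhythm codes are translated through `rhythmMap`
#' (default: AFIB and AF to "AF", N and NSR to "NSR"); unknown codes are
#' kept verbatim with a warning and are excluded when instances are formed.
#'
#' @param path file path.
#' @param rhythmMap named character vector mapping file codes to package
#'   labels.
#' @return `readAnnotations`: list with `rPeaks` (0-based integer) and
#'   `labels` (character).
#' @export
readAnnotations <- function(path, rhythmMap = .DEFAULT_RHYTHM_MAP) {
    df <- read.csv(path)
    if (!all(c("sample_index", "label") %in% names(df)))
        stop("annotation CSV must have columns sample_index,label")
    labs <- as.character(df$label)
    known <- labs %in% names(rhythmMap)
    if (any(!known))
        warning("unknown rhythm codes kept verbatim (will be excluded): ",
                paste(unique(labs[!known]), collapse = ", "))
    labs[known] <- unname(rhythmMap[labs[known]])
    list(rPeaks = as.integer(df$sample_index), labels = labs)
}

#' @rdname readAnnotations
#' @param record an [EcgRecord-class] whose annotations are written.
#' @export
writeAnnotations <- function(record, path) {
    write.csv(data.frame(sample_index = record@rPeaks,
                         label = record@beatLabels),
              path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Attach annotations to a signal record
#'
#' @param record an [EcgRecord-class] (e.g. from [readSignal()]).
#' @param annotations list with `rPeaks` and `labels` (from
#'   [readAnnotations()]).
#' @return The annotated [EcgRecord-class].
#' @export
annotateRecord <- function(record, annotations) {
    ecgRecord(record@samples, fs = record@fs, rPeaks = annotations$rPeaks,
              beatLabels = annotations$labels, recordId = record@recordId,
              seed = record@seed)
}
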