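#' @name accessors
#' @title Accessors for fibriwave data classes
#' @description Slot accessors for the core classes; user code should use
#'   these rather than `@`.
#' @param object an object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "EcgRecord", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("samples", "BeatWindow", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EcgRecord", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("rPeaks", function(object) standardGeneric("rPeaks"))
#' @rdname accessors
#' @export
setMethod("rPeaks", "EcgRecord", function(object) object@rPeaks)

#' @rdname accessors
#' @export
setGeneric("beatLabels", function(object) standardGeneric("beatLabels"))
#' @rdname accessors
#' @export
setMethod("beatLabels", "EcgRecord", function(object) object@beatLabels)

#' @rdname accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
#' @rdname accessors
#' @export
setMethod("recordId", "EcgRecord", function(object) object@recordId)
#' @rdname accessors
#' @export
setMethod("recordId", "EcgInstance", function(object) object@recordId)
#' @rdname accessors
#' @export
setMethod("recordId", "InstanceTensor", function(object) object@recordId)

#' @rdname accessors
#' @export
setGeneric("instanceLabel", function(object) standardGeneric("instanceLabel"))
#' @rdname accessors
#' @export
setMethod("instanceLabel", "EcgInstance", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("instanceLabel", "InstanceTensor", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("instanceLabel", "BeatWindow", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("windows", function(object) standardGeneric("windows"))
#' @rdname accessors
#' @export
setMethod("windows", "EcgInstance", function(object) object@windows)

#' @rdname accessors
#' @export
setGeneric("pattern", function(object) standardGeneric("pattern"))
#' @rdname accessors
#' @export
setMethod("pattern", "Scalogram", function(object) object@pattern)

#' @rdname accessors
#' @export
setGeneric("scaleAxis", function(object) standardGeneric("scaleAxis"))
#' @rdname accessors
#' @export
setMethod("scaleAxis", "Scalogram", function(object) object@scaleAxis)

#' @rdname accessors
#' @export
setGeneric("tensorArray", function(object) standardGeneric("tensorArray"))
#' @rdname accessors
#' @export
setMethod("tensorArray", "InstanceTensor", function(object) object@tensor)

#' @rdname accessors
#' @export
setGeneric("approximations",
           function(object) standardGeneric("approximations"))
#' @rdname accessors
#' @export
setMethod("approximations", "DyadicDecomposition",
          function(object) object@approximations)

#' @rdname accessors
#' @export
setGeneric("details", function(object) standardGeneric("details"))
#' @rdname accessors
#' @export
setMethod("details", "DyadicDecomposition", function(object) object@details)

#' @rdname accessors
#' @export
setGeneric("nScales", function(object) standardGeneric("nScales"))
#' @rdname accessors
#' @export
setMethod("nScales", "DyadicDecomposition", function(object) object@J)

#' @rdname accessors
#' @export
setGeneric("trainingHistory",
           function(object) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "CnnModel", function(object) object@history)

#' Confusion metrics as a named list
#'
#' @param object a [ConfusionMetrics-class] object.
#' @return Named list with tp, fn, tn, fp, se, sp, ppv, acc.
#' @export
setGeneric("metricsList", function(object) standardGeneric("metricsList"))
#' @rdname metricsList
#' @export
setMethod("metricsList", "ConfusionMetrics", function(object) {
    list(tp = object@tp, fn = object@fn, tn = object@tn, fp = object@fp,
         se = object@se, sp = object@sp, ppv = object@ppv, acc = object@acc)
})

setMethod("show", "EcgRecord", function(object) {
    cat(sprintf(
        "EcgRecord '%s': %d samples at %g Hz (%.1f s), %d beats (%s)\n",
        object@recordId, length(object@samples), object@fs,
        length(object@samples) / object@fs, length(object@rPeaks),
        paste(sprintf("%s: %d", names(table(object@beatLabels)),
                      as.integer(table(object@beatLabels))),
              collapse = ", ")))
})

setMethod("show", "DyadicDecomposition", function(object) {
    cat(sprintf(
        "DyadicDecomposition (%s): %d scales, series length %d, fs %g Hz\n",
        object@filters@waveletName, object@J,
        length(object@approximations[[1L]]), object@fs))
    for (j in seq_len(object@J)) {
        be <- bandEdges(j, object@fs)
        cat(sprintf("  W_%d: %.2f-%.2f Hz\n", j, be[1L], be[2L]))
    }
})

setMethod("show", "EcgInstance", function(object) {
    cat(sprintf("EcgInstance (%s) from '%s': %d beat windows\n",
                object@label, object@recordId, length(object@windows)))
})

setMethod("show", "Scalogram", function(object) {
    cat(sprintf("Scalogram: %d x %d pattern, %.2f-%.2f Hz\n",
                nrow(object@pattern), ncol(object@pattern),
                min(object@scaleAxis), max(object@scaleAxis)))
})

setMethod("show", "InstanceTensor", function(object) {
    d <- dim(object@tensor)
    cat(sprintf("InstanceTensor (%s) from '%s': %d x %d x %d\n",
                object@label, object@recordId, d[1L], d[2L], d[3L]))
})

setMethod("show", "CnnSpec", function(object) {
    cat("CnnSpec:\n")
    print(shapeTrace(object))
})

setMethod("show", "CnnModel", function(object) {
    cat(sprintf("CnnModel (%s conv activation), %s\n",
                object@spec@convActivation,
                if (nrow(object@history)) {
                    sprintf("trained %d epochs (final loss %.4f)",
                            nrow(object@history),
                            tail(object@history$loss, 1L))
                } else "untrained"))
})

setMethod("show", "ConfusionMetrics", function(object) {
    cat(sprintf("ConfusionMetrics: TP %d  FN %d  TN %d  FP %d\n",
                object@tp, object@fn, object@tn, object@fp))
    fmt <- function(x) if (is.na(x)) "undefined" else sprintf("%.2f%%", x)
    cat(sprintf("  Se %s  Sp %s  PPV %s  Acc %s\n", fmt(object@se),
                fmt(object@sp), fmt(object@ppv), fmt(object@acc)))
})
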