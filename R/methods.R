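#' @describeIn SpikeTrainSet number of units
#' @param x,i,object see generic.
#' @export
setMethod("nUnits", "SpikeTrainSet", function(x) length(x@spikes))

#' @describeIn SpikeTrainSet spike times of unit `i` (seconds)
#' @export
setMethod("spikeTimes", "SpikeTrainSet", function(x, i) {
    stopifnot(i >= 1L, i <= length(x@spikes))
    x@spikes[[i]]
})

#' @describeIn SpikeTrainSet recording duration (seconds)
#' @export
setMethod("recordingDuration", "SpikeTrainSet", function(x) x@duration)

#' @describeIn SpikeTrainSet unit metadata table
#' @export
setMethod("unitMeta", "SpikeTrainSet", function(x) x@unitMeta)

#' @export
setMethod("length", "SpikeTrainSet", function(x) length(x@spikes))

#' Subset a SpikeTrainSet by unit index
#'
#' @param x a [SpikeTrainSet-class].
#' @param i integer or logical index over units.
#' @param j,drop,... ignored.
#' @return a [SpikeTrainSet-class] with the selected units (positions are
#'   renumbered; original labels remain in `unitMeta(x)$unit_id`).
#' @export
setMethod("[", "SpikeTrainSet", function(x, i, j, ..., drop = FALSE) {
    meta <- x@unitMeta[i, , drop = FALSE]
    rownames(meta) <- NULL
    new("SpikeTrainSet", spikes = x@spikes[i], duration = x@duration,
        unitMeta = meta)
})

setMethod("show", "SpikeTrainSet", function(object) {
    n <- length(object@spikes)
    tot <- sum(vapply(object@spikes, length, integer(1)))
    cls <- table(factor(object@unitMeta$class, levels = c("E", "I")))
    cat(sprintf("SpikeTrainSet: %d units, %d spikes, %.1f s", n, tot,
                object@duration))
    if (sum(cls) > 0)
        cat(sprintf(" (%d E / %d I)", cls[["E"]], cls[["I"]]))
    cat("\n")
    if (n > 0 && object@duration > 0)
        cat(sprintf("  mean rate %.2f Hz\n", tot / n / object@duration))
})

#' @describeIn GroundTruthNetwork number of neurons
#' @param x,object see generic.
#' @export
setMethod("nUnits", "GroundTruthNetwork", function(x) nrow(x@neurons))

#' @describeIn GroundTruthNetwork synapse table
#' @export
setMethod("synapses", "GroundTruthNetwork", function(x) x@synapses)

#' @describeIn GroundTruthNetwork neuron parameter table
#' @export
setMethod("neuronTable", "GroundTruthNetwork", function(x) x@neurons)

setMethod("show", "GroundTruthNetwork", function(object) {
    syn <- object@synapses
    cat(sprintf("GroundTruthNetwork: %d neurons (%d E / %d I), %d synapses\n",
                nrow(object@neurons),
                sum(object@neurons$class == "E"),
                sum(object@neurons$class == "I"), nrow(syn)))
    if (nrow(syn))
        cat(sprintf("  |PSP| median %.3f mV (E), %.3f mV (I)\n",
                    stats::median(abs(syn$psp[syn$sign == "E"])),
                    stats::median(abs(syn$psp[syn$sign == "I"]))))
})

#' @describeIn Correlogram bin counts
#' @param x,object see generic.
#' @export
setMethod("counts", "Correlogram", function(x) x@counts)

#' @describeIn Correlogram bin width (ms)
#' @export
setMethod("binWidth", "Correlogram", function(x) x@binWidth)

#' @describeIn Correlogram half-window (ms)
#' @export
setMethod("lagWindow", "Correlogram", function(x) x@window)

#' @describeIn Correlogram TRUE after shadow trimming
#' @export
setMethod("isTrimmed", "Correlogram", function(x) x@trimmed)

#' @describeIn Correlogram lag bin centers (ms)
#' @export
setMethod("lagCenters", "Correlogram", function(x) {
    M <- round(2 * x@window / x@binWidth)
    centers <- -x@window + (seq_len(M) - 0.5) * x@binWidth
    if (x@trimmed) centers <- centers[!.shadowBins(x@window, x@binWidth)]
    centers
})

setMethod("show", "Correlogram", function(object) {
    cat(sprintf("Correlogram: %d bins of %.1f ms over [-%g, %g] ms%s\n",
                length(object@counts), object@binWidth, object@window,
                object@window, if (object@trimmed) " (shadow-trimmed)" else ""))
    cat(sprintf("  pair (%s -> %s), %d reference spikes, %d pair counts\n",
                object@pair[1L], object@pair[2L], object@nRef,
                sum(object@counts)))
})

#' @describeIn CnnConnect total trainable parameter count
#' @param x,object see generic.
#' @export
setMethod("nParameters", "CnnConnect", function(x) {
    sum(vapply(x@weights, length, integer(1)))
})

#' @describeIn CnnConnect per-epoch training losses
#' @export
setMethod("trainingHistory", "CnnConnect", function(x) x@history)

setMethod("show", "CnnConnect", function(object) {
    s <- object@spec
    cat(sprintf(paste0("CnnConnect: input %d, conv(kernel %d, %d ch, tanh), ",
                       "avg-pool %d, dense %d ReLU -> (z, PSP)\n"),
                s$inputLength, s$kernelSize, s$channels, s$poolWidth, s$hidden))
    cat(sprintf("  %d parameters, %s\n", nParameters(object),
                if (object@trained) "trained" else "untrained"))
})

#' @describeIn GlmccFit fitted couplings
#' @param x,object see generic.
#' @export
setMethod("couplings", "GlmccFit", function(x) x@J)

#' @describeIn GlmccFit chosen delays (ms)
#' @export
setMethod("delays", "GlmccFit", function(x) x@delay)

#' @describeIn GlmccFit log likelihood-ratio statistics
#' @export
setMethod("lrStatistics", "GlmccFit", function(x) x@D)

#' @describeIn GlmccFit significance flags
#' @export
setMethod("isSignificant", "GlmccFit", function(x) x@significant)

#' @describeIn GlmccFit fitted baseline (log expected counts per bin)
#' @export
setMethod("baseline", "GlmccFit", function(x) x@a)

setMethod("show", "GlmccFit", function(object) {
    cat("GlmccFit\n")
    cat(sprintf("  J12 = %.3f (d = %g ms, 2D = %.2f%s)\n", object@J[["J12"]],
                object@delay[["d12"]], 2 * object@D[["D12"]],
                if (object@significant[["sig12"]]) ", significant" else ""))
    cat(sprintf("  J21 = %.3f (d = %g ms, 2D = %.2f%s)\n", object@J[["J21"]],
                object@delay[["d21"]], 2 * object@D[["D21"]],
                if (object@significant[["sig21"]]) ", significant" else ""))
})
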