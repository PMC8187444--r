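#' Number of units in a container
#' @param x a [SpikeTrainSet-class] or [GroundTruthNetwork-class].
#' @return integer scalar.
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Spike times of one unit
#' @param x a [SpikeTrainSet-class].
#' @param i unit index.
#' @return numeric vector of spike times in seconds.
#' @export
setGeneric("spikeTimes", function(x, i) standardGeneric("spikeTimes"))

#' Recording duration in seconds
#' @param x a [SpikeTrainSet-class].
#' @return numeric scalar.
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' Unit metadata table
#' @param x a [SpikeTrainSet-class].
#' @return data.frame with columns `unit_id`, `class`, `group`.
#' @export
setGeneric("unitMeta", function(x) standardGeneric("unitMeta"))

#' Synapse table of a ground-truth network
#' @param x a [GroundTruthNetwork-class].
#' @return data.frame (pre, post, sign, G, delay, psp).
#' @export
setGeneric("synapses", function(x) standardGeneric("synapses"))

#' Per-neuron parameter table of a ground-truth network
#' @param x a [GroundTruthNetwork-class].
#' @return data.frame.
#' @export
setGeneric("neuronTable", function(x) standardGeneric("neuronTable"))

#' Bin counts of a correlogram
#' @param x a [Correlogram-class].
#' @return integer vector.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' Bin width of a correlogram (ms)
#' @param x a [Correlogram-class].
#' @return numeric scalar.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Half-window of a correlogram (ms)
#' @param x a [Correlogram-class].
#' @return numeric scalar.
#' @export
setGeneric("lagWindow", function(x) standardGeneric("lagWindow"))

#' Has the shadow region been trimmed?
#' @param x a [Correlogram-class].
#' @return logical scalar.
#' @export
setGeneric("isTrimmed", function(x) standardGeneric("isTrimmed"))

#' Lag bin centers of a correlogram (ms)
#' @param x a [Correlogram-class].
#' @return numeric vector (same length as `counts(x)`).
#' @export
setGeneric("lagCenters", function(x) standardGeneric("lagCenters"))

#' Number of trainable parameters of a model
#' @param x a [CnnConnect-class].
#' @return integer scalar.
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

#' Per-epoch training history
#' @param x a [CnnConnect-class].
#' @return data.frame of per-epoch losses.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Fitted couplings of a GLMCC fit
#' @param x a [GlmccFit-class].
#' @return named numeric `c(J12, J21)`.
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))

#' Chosen transmission delays of a GLMCC fit (ms)
#' @param x a [GlmccFit-class].
#' @return named numeric `c(d12, d21)`.
#' @export
setGeneric("delays", function(x) standardGeneric("delays"))

#' Log likelihood-ratio statistics of a GLMCC fit
#' @param x a [GlmccFit-class].
#' @return named numeric `c(D12, D21)`.
#' @export
setGeneric("lrStatistics", function(x) standardGeneric("lrStatistics"))

#' Per-direction significance flags of a GLMCC fit
#' @param x a [GlmccFit-class].
#' @return named logical `c(sig12, sig21)`.
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' Fitted baseline of a GLMCC fit
#' @param x a [GlmccFit-class].
#' @return numeric vector `a(t)` in log expected counts per bin.
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))
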