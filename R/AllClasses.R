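#' @useDynLib connectr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rlnorm qchisq sd cor optim rpois
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

#' SpikeTrainSet: parallel spike trains with recording metadata
#'
#' Container for per-unit sorted spike times (seconds) recorded (or
#' simulated) over a common duration, together with optional unit metadata
#' (true excitatory/inhibitory class and background-oscillation group for
#' simulated data).
#'
#' @slot spikes list of numeric vectors, one per unit; spike times in
#'   seconds, strictly increasing, within `[0, duration]`.
#' @slot duration recording duration in seconds.
#' @slot unitMeta data.frame with one row per unit: `unit_id` (original
#'   label), `class` ("E", "I" or NA) and `group` (oscillation group index,
#'   0 when none).
#' @export
setClass("SpikeTrainSet",
         representation(spikes = "list", duration = "numeric",
                        unitMeta = "data.frame"))

setValidity("SpikeTrainSet", function(object) {
    msgs <- character()
    if (length(object@duration) != 1L || object@duration < 0)
        msgs <- c(msgs, "duration must be a single non-negative number")
    if (nrow(object@unitMeta) != length(object@spikes))
        msgs <- c(msgs, "unitMeta must have one row per unit")
    for (i in seq_along(object@spikes)) {
        st <- object@spikes[[i]]
        if (length(st) == 0L) next
        if (is.unsorted(st, strictly = TRUE)) {
            msgs <- c(msgs, sprintf("spike times of unit %d are not strictly increasing", i))
            break
        }
        if (st[1L] < 0 || st[length(st)] > object@duration + 1e-9) {
            msgs <- c(msgs, sprintf("spike times of unit %d outside [0, duration]", i))
            break
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a SpikeTrainSet
#'
#' @param spikes list of numeric vectors of spike times in seconds.
#' @param duration recording duration in seconds; defaults to the latest
#'   spike time.
#' @param unitMeta optional data.frame with columns `unit_id`, `class`,
#'   `group`.
#' @return A [SpikeTrainSet-class] object.
#' @export
SpikeTrainSet <- function(spikes, duration = NULL, unitMeta = NULL) {
    spikes <- lapply(spikes, as.numeric)
    if (is.null(duration))
        duration <- if (length(spikes)) max(0, unlist(spikes, use.names = FALSE)) else 0
    if (is.null(unitMeta))
        unitMeta <- data.frame(unit_id = seq_along(spikes),
                               class = rep(NA_character_, length(spikes)),
                               group = rep(0L, length(spikes)))
    new("SpikeTrainSet", spikes = spikes, duration = as.numeric(duration),
        unitMeta = unitMeta)
}

#' GroundTruthNetwork: known synaptic wiring of a simulated circuit
#'
#' Ordered-pair synapse table of a simulated network, plus the per-neuron
#' parameters drawn at construction (adaptive-threshold jump `alpha1`,
#' oscillation-group assignment, phase and amplitude), so that a simulation
#' is fully reproducible from the object and a seed.
#'
#' @slot synapses data.frame with columns `pre`, `post` (1-based unit
#'   indices), `sign` ("E"/"I"), `G` (peak conductance, mS/cm^2), `delay`
#'   (transmission delay, ms) and `psp` (signed single-spike postsynaptic
#'   potential amplitude, mV).
#' @slot neurons data.frame with one row per neuron: `id`, `class`,
#'   `tau_m`, `omega_rest`, `alpha1`, `alpha2`, `osc_group`, `osc_freq`,
#'   `osc_A`, `osc_delta`.
#' @slot config the resolved simulation configuration used to build the
#'   network (list, see [simConfig()]).
#' @export
setClass("GroundTruthNetwork",
         representation(synapses = "data.frame", neurons = "data.frame",
                        config = "list"))

setValidity("GroundTruthNetwork", function(object) {
    syn <- object@synapses
    msgs <- character()
    need <- c("pre", "post", "sign", "G", "delay", "psp")
    if (!all(need %in% names(syn)))
        return(paste("synapse table must have columns", paste(need, collapse = ", ")))
    if (nrow(syn)) {
        if (any(syn$pre == syn$post)) msgs <- c(msgs, "self-connections are not allowed")
        if (any(syn$G <= 0)) msgs <- c(msgs, "conductances must be positive")
        bad <- (syn$sign == "E" & syn$psp < 0) | (syn$sign == "I" & syn$psp > 0)
        if (any(bad)) msgs <- c(msgs, "PSP sign must match synapse sign")
        n <- nrow(object@neurons)
        if (any(syn$pre < 1 | syn$pre > n | syn$post < 1 | syn$post > n))
            msgs <- c(msgs, "synapse endpoints outside neuron table")
    }
    if (length(msgs)) msgs else TRUE
})

#' Correlogram: binned cross-correlation histogram of a spike-train pair
#'
#' Integer spike-pair counts over lags `t_target - t_reference` in
#' `[-window, window]` ms; bin k covers the half-open interval
#' `[-W + (k-1) * delta, -W + k * delta)`.  A causal (pre -> post) synaptic
#' effect of the reference unit on the target appears in the positive-lag
#' half.  Trimmed correlograms have the four central bins (the +/- 2 ms
#' spike-sorting shadow region) removed and the flanks concatenated.
#'
#' @slot counts integer bin counts (length `2 * window / binWidth`, minus 4
#'   when trimmed).
#' @slot binWidth bin width, ms.
#' @slot window half-window, ms.
#' @slot trimmed logical; TRUE after shadow trimming.
#' @slot nRef number of reference-unit spikes.
#' @slot pair integer vector (reference unit, target unit); NA when unknown.
#' @export
setClass("Correlogram",
         representation(counts = "integer", binWidth = "numeric",
                        window = "numeric", trimmed = "logical",
                        nRef = "integer", pair = "integer"))

setValidity("Correlogram", function(object) {
    M <- round(2 * object@window / object@binWidth)
    expected <- if (object@trimmed) M - 4L else M
    if (length(object@counts) != expected)
        return(sprintf("counts has length %d, expected %d", length(object@counts), expected))
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
})

#' CnnConnect: convolutional network estimator for correlogram pairs
#'
#' A small one-dimensional convolutional network that maps a
#' cross-correlogram to a connection probability `z` in `[0, 1]` and a PSP
#' amplitude in mV.  Architecture: one convolution layer (kernel 10, 5
#' output channels, stride 1, tanh), average pooling (window 2, stride 1),
#' a fully connected hidden layer of 100 ReLU nodes, and a two-unit output
#' (logistic `z`, linear PSP).
#'
#' @slot spec architecture description (see [cnnModelSpec()]).
#' @slot weights named list of weight arrays.
#' @slot history per-epoch training losses (data.frame; empty before
#'   training).
#' @slot seed RNG seed used for weight initialization.
#' @slot trained logical.
#' @export
setClass("CnnConnect",
         representation(spec = "list", weights = "list",
                        history = "data.frame", seed = "numeric",
                        trained = "logical"))

#' GlmccFit: GLM fit to a cross-correlogram with likelihood-ratio tests
#'
#' MAP fit of the intensity
#' `lambda(t) = exp(a(t) + J12 f(t) + J21 f(-t))` to a correlogram, where
#' `a(t)` is a smoothness-penalized baseline and `f` an exponential synaptic
#' kernel with transmission delay `d` and timescale `tau`.  Holds the fitted
#' baseline, both couplings and delays, and the per-direction log
#' likelihood-ratio statistics `D` with their significance flags
#' (`2 D >` upper-alpha chi-square(1) quantile).
#'
#' @slot a fitted baseline vector (log expected counts per bin).
#' @slot J named couplings `c(J12, J21)` (dimensionless log-intensity).
#' @slot delay named chosen delays, ms.
#' @slot D named log likelihood-ratio statistics per direction.
#' @slot significant named logical flags per direction.
#' @slot logPost log posterior at the optimum.
#' @slot logLik log likelihood at the optimum.
#' @slot converged logical.
#' @slot hyper hyperparameters used (see [glmccHyper()]).
#' @slot counts the (untrimmed-length) counts the fit saw; masked bins NA.
#' @export
setClass("GlmccFit",
         representation(a = "numeric", J = "numeric", delay = "numeric",
                        D = "numeric", significant = "logical",
                        logPost = "numeric", logLik = "numeric",
                        converged = "logical", hyper = "list",
                        counts = "numeric"))
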