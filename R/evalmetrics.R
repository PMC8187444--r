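# Matthews correlation coefficient, guarded to 0 when any marginal is zero
.mcc <- function(tp, fp, tn, fn) {
    m <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    if (any(m == 0)) return(0)
    (tp * tn - fp * fn) / sqrt(prod(as.numeric(m)))
}

# normalize an estimate table to (pre, post, detected, est_sign in {-1,0,1})
.normalizeEstimates <- function(est) {
    if (all(c("connected", "psp_mV") %in% names(est))) {
        data.frame(pre = est$pre, post = est$post,
                   detected = est$connected,
                   est_sign = sign(est$psp_mV))
    } else if (all(c("significant", "J") %in% names(est))) {
        data.frame(pre = est$pre, post = est$post,
                   detected = est$significant,
                   est_sign = sign(est$J))
    } else stop("unrecognized estimate table columns")
}

#' Confusion summary against ground truth
#'
#' Scores a directed estimate table (from [estimateMatrix()] or
#' [glmccEstimateMatrix()]) against a [GroundTruthNetwork-class] with
#' one-vs-rest categories: excitatory (detected with positive PSP/coupling
#' vs a true excitatory connection) and inhibitory likewise.  True
#' excitatory connections weaker than `pspThreshold` (mV) are too small to
#' be visible at realistic durations and are excluded from the excitatory
#' tally: they are neither counted as misses nor do their detections count
#' as false positives.  The inhibitory tally is unchanged by the threshold.
#'
#' Rates follow the discovery/omission reading:
#' `FPR = FP / (FP + TP)` and `FNR = FN / (FN + TP)`; set
#' `rates = "classic"` for `FP / (FP + TN)` and `FN / (FN + TP)`.
#'
#' @param est directed estimate data.frame.
#' @param truth the matching [GroundTruthNetwork-class] (same unit
#'   numbering).
#' @param pspThreshold visibility threshold for excitatory PSPs, mV.
#' @param rates "discovery" (default) or "classic" denominators.
#' @return list with per-category counts/rates/MCC (`E`, `I`), `macroMcc`,
#'   and the threshold used.
#' @export
confusion <- function(est, truth, pspThreshold = 0.1,
                      rates = c("discovery", "classic")) {
    rates <- match.arg(rates)
    nr <- nUnits(truth)
    ids <- sort(unique(c(est$pre, est$post)))
    if (any(ids < 1 | ids > nr))
        stop("estimate table refers to units outside the ground truth")
    ne <- .normalizeEstimates(est)
    syn <- truth@synapses
    key <- function(p, q) (p - 1) * nr + q
    trueSign <- integer(nr * nr)
    truePsp <- numeric(nr * nr)
    if (nrow(syn)) {
        trueSign[key(syn$pre, syn$post)] <- ifelse(syn$sign == "E", 1L, -1L)
        truePsp[key(syn$pre, syn$post)] <- syn$psp
    }
    k <- key(ne$pre, ne$post)
    ts <- trueSign[k]
    tp_ <- truePsp[k]

    tally <- function(category) {
        s <- if (category == "E") 1L else -1L
        keep <- rep(TRUE, nrow(ne))
        if (category == "E")
            keep <- !(ts == 1L & abs(tp_) < pspThreshold)
        truePos <- ts[keep] == s
        estPos <- ne$detected[keep] & ne$est_sign[keep] == s
        TP <- sum(truePos & estPos); FP <- sum(!truePos & estPos)
        FN <- sum(truePos & !estPos); TN <- sum(!truePos & !estPos)
        fpr <- if (rates == "discovery") {
            if (FP + TP > 0) FP / (FP + TP) else 0
        } else {
            if (FP + TN > 0) FP / (FP + TN) else 0
        }
        fnr <- if (FN + TP > 0) FN / (FN + TP) else 0
        list(TP = TP, FP = FP, TN = TN, FN = FN,
             MCC = .mcc(TP, FP, TN, FN), FPR = fpr, FNR = fnr)
    }
    E <- tally("E"); I <- tally("I")
    list(E = E, I = I, macroMcc = (E$MCC + I$MCC) / 2,
         pspThreshold = pspThreshold, rates = rates)
}

#' Macro-averaged Matthews correlation coefficient
#'
#' Arithmetic mean of the excitatory and inhibitory one-vs-rest MCCs,
#' giving equal importance to both categories.
#'
#' @param summary a [confusion()] result.
#' @return scalar macro MCC.
#' @export
macroMcc <- function(summary) {
    (summary$E$MCC + summary$I$MCC) / 2
}

#' Macro MCC as a function of the detection threshold
#'
#' Evaluates the CNN once per pair and sweeps the threshold `theta` applied
#' to the connection-probability output `z`.
#'
#' @param model a trained [CnnConnect-class].
#' @param spikes validation [SpikeTrainSet-class].
#' @param truth matching [GroundTruthNetwork-class].
#' @param thetas threshold grid in (0, 1].
#' @param pspThreshold excitatory visibility threshold, mV.
#' @return data.frame with `theta`, `macro_mcc`, `n_detected`.
#' @export
thresholdSweep <- function(model, spikes, truth,
                           thetas = seq(0.05, 0.95, by = 0.05),
                           pspThreshold = 0.1) {
    raw <- .cnnEstimateRaw(model, spikes)
    out <- lapply(thetas, function(th) {
        connected <- raw$z > th
        est <- data.frame(pre = raw$pre, post = raw$post, z = raw$z,
                          connected = connected,
                          psp_mV = ifelse(connected, raw$psp_raw, 0))
        data.frame(theta = th,
                   macro_mcc = confusion(est, truth, pspThreshold)$macroMcc,
                   n_detected = sum(connected))
    })
    do.call(rbind, out)
}

#' Excitatory-inhibitory dominance index
#'
#' For each unit, `d_ei = (n_e - n_i) / (n_e + n_i)` over its detected
#' outgoing connections (`n_e` excitatory, `n_i` inhibitory).  Units with
#' positive index are putative excitatory, negative putative inhibitory,
#' zero or no detections undetermined.
#'
#' @param est directed estimate data.frame.
#' @param units optional vector of unit ids to report (defaults to all ids
#'   appearing in `est`).
#' @return data.frame with `unit`, `n_e`, `n_i`, `d_ei` (NA when
#'   undetermined) and `class` ("E", "I" or "undetermined").
#' @export
eiDominance <- function(est, units = NULL) {
    ne <- .normalizeEstimates(est)
    if (is.null(units)) units <- sort(unique(c(ne$pre, ne$post)))
    out <- lapply(units, function(u) {
        rows <- ne$pre == u & ne$detected
        n_e <- sum(rows & ne$est_sign == 1L)
        n_i <- sum(rows & ne$est_sign == -1L)
        d <- if (n_e + n_i > 0) (n_e - n_i) / (n_e + n_i) else NA_real_
        cls <- if (is.na(d) || d == 0) "undetermined"
               else if (d > 0) "E" else "I"
        data.frame(unit = u, n_e = n_e, n_i = n_i, d_ei = d, class = cls)
    })
    do.call(rbind, out)
}

#' Truncate a recording to its first `T` seconds
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param T new duration, seconds (must not exceed the recording).
#' @return the truncated [SpikeTrainSet-class].
#' @export
truncateRecording <- function(spikes, T) {
    if (T <= 0) stop("duration must be positive")
    if (T > spikes@duration + 1e-9)
        stop("requested duration exceeds the recording")
    new("SpikeTrainSet",
        spikes = lapply(spikes@spikes, function(st) st[st <= T]),
        duration = T, unitMeta = spikes@unitMeta)
}

#' Split a recording in half
#'
#' First half keeps its time axis; the second half is shifted to start at
#' zero.  Used by the split-half stability analysis.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @return list of two [SpikeTrainSet-class] objects.
#' @export
splitRecording <- function(spikes) {
    h <- spikes@duration / 2
    first <- truncateRecording(spikes, h)
    second <- new("SpikeTrainSet",
                  spikes = lapply(spikes@spikes,
                                  function(st) st[st > h] - h),
                  duration = h, unitMeta = spikes@unitMeta)
    list(first = first, second = second)
}

#' False-positive / false-negative counts across recording durations
#'
#' Runs an estimator on truncated copies of a recording and tabulates
#' per-category FP/FN/TP/TN counts; longer recordings reveal weaker
#' connections, so excitatory misses should fall with duration while
#' spurious detections stay roughly flat.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param truth matching [GroundTruthNetwork-class].
#' @param estimator function mapping a [SpikeTrainSet-class] to a directed
#'   estimate table (e.g. `function(s) estimateMatrix(model, s)`).
#' @param durations durations in seconds (default 10, 30, 120 minutes),
#'   each within the recording.
#' @param pspThreshold excitatory visibility threshold, mV.
#' @return data.frame with one row per duration and category.
#' @export
durationCurve <- function(spikes, truth, estimator,
                          durations = c(600, 1800, 7200),
                          pspThreshold = 0.1) {
    out <- lapply(durations, function(T) {
        cf <- confusion(estimator(truncateRecording(spikes, T)), truth,
                        pspThreshold)
        do.call(rbind, lapply(c("E", "I"), function(cat) {
            x <- cf[[cat]]
            data.frame(duration = T, category = cat, FP = x$FP, FN = x$FN,
                       TP = x$TP, TN = x$TN, MCC = x$MCC)
        }))
    })
    do.call(rbind, out)
}
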