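# which bins of an untrimmed correlogram fall in the +/- shadow region
.shadowBins <- function(window, binWidth, half = 2) {
    M <- round(2 * window / binWidth)
    lower <- -window + (seq_len(M) - 1) * binWidth
    lower >= -half & lower < half
}

#' Cross-correlogram of a spike-train pair
#'
#' Counts spike pairs by lag `t_target - t_reference` over
#' `[-window, window]` ms in half-open bins of `binWidth` ms (lower edge
#' inclusive, so an exact coincidence falls in the first positive-lag bin).
#' With the defaults this yields 100 integer counts over +/- 50 ms at 1 ms
#' resolution.  A causal effect of the reference unit on the target appears
#' in the positive-lag half.
#'
#' @param ref,tgt sorted spike-time vectors, seconds.
#' @param window half-window, ms.
#' @param binWidth bin width, ms; `window` must be a multiple.
#' @param pair optional integer pair of unit indices for bookkeeping.
#' @return a [Correlogram-class].
#' @export
computeCorrelogram <- function(ref, tgt, window = 50, binWidth = 1,
                               pair = c(NA_integer_, NA_integer_)) {
    stopifnot(window > 0, binWidth > 0,
              abs(window / binWidth - round(window / binWidth)) < 1e-9)
    if (is.unsorted(ref) || is.unsorted(tgt))
        stop("spike trains must be sorted")
    if (length(ref) == 0L || length(tgt) == 0L) {
        warning("empty spike train; returning all-zero correlogram")
        cnt <- integer(round(2 * window / binWidth))
    } else {
        cnt <- .ccgCountCpp(as.numeric(ref), as.numeric(tgt),
                            window / 1000, binWidth / 1000)
    }
    new("Correlogram", counts = cnt, binWidth = binWidth, window = window,
        trimmed = FALSE, nRef = length(ref), pair = as.integer(pair))
}

#' Remove the spike-sorting shadow region from a correlogram
#'
#' Spike sorting can miss near-synchronous spikes, carving a spurious notch
#' around lag zero (the shadowing effect).  This drops the four 1 ms bins
#' covering lags -2 to +2 ms and concatenates the remaining left and right
#' flanks, leaving 96 bins at the default geometry.
#'
#' @param cc an untrimmed [Correlogram-class].
#' @return the trimmed [Correlogram-class].
#' @export
shadowTrim <- function(cc) {
    if (isTrimmed(cc)) stop("correlogram is already trimmed")
    drop <- .shadowBins(cc@window, cc@binWidth)
    new("Correlogram", counts = cc@counts[!drop], binWidth = cc@binWidth,
        window = cc@window, trimmed = TRUE, nRef = cc@nRef, pair = cc@pair)
}

#' Time-rescaling augmentation of spike trains
#'
#' Multiplies all spike times (and the duration) by `factor`, dilating time
#' so every unit's firing rate scales by `1/factor` while spike counts,
#' ordering and any ground-truth labels are unchanged.  Recomputing
#' correlograms after rescaling moves pair-interaction features from lag
#' `tau` to lag `factor * tau`; the training pipeline uses factors 1, 2 and
#' 4 to expose the network to lower-rate statistics.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param factor positive rescaling factor.
#' @return the rescaled [SpikeTrainSet-class].
#' @export
rescaleAugment <- function(spikes, factor) {
    stopifnot(factor > 0)
    if (factor == 1) return(spikes)
    new("SpikeTrainSet", spikes = lapply(spikes@spikes, `*`, factor),
        duration = spikes@duration * factor, unitMeta = spikes@unitMeta)
}

#' Firing rate of a spike train
#'
#' @param train numeric vector of spike times.
#' @param T recording duration, seconds.
#' @return rate in Hz (`length(train) / T`).
#' @export
firingRate <- function(train, T) {
    stopifnot(T > 0)
    length(train) / T
}

#' Firing rates of all units
#'
#' @param spikes a [SpikeTrainSet-class].
#' @return numeric vector of per-unit rates, Hz.
#' @export
firingRates <- function(spikes) {
    vapply(spikes@spikes, length, integer(1)) / spikes@duration
}

#' Local variation of the interspike intervals (Lv)
#'
#' Spiking-irregularity statistic over consecutive interspike-interval
#' pairs: `Lv = 3/(n-1) * sum(((I_k - I_{k+1}) / (I_k + I_{k+1}))^2)` with
#' `n` the number of intervals.  0 for a perfectly regular train, about 1
#' for a Poisson train.
#'
#' @param train numeric vector of spike times (at least 3 spikes).
#' @return Lv, or `NA_real_` for fewer than 3 spikes.
#' @export
localVariation <- function(train) {
    if (length(train) < 3L) return(NA_real_)
    isi <- diff(train)
    n <- length(isi)
    r <- (isi[-n] - isi[-1]) / (isi[-n] + isi[-1])
    3 * sum(r^2) / (n - 1)
}

#' Remove low-firing units
#'
#' Units firing at or below `minRate` are dropped (strictly-greater
#' retained); applied before connectivity estimation because low-rate units
#' carry too little evidence.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param minRate rate threshold, Hz.
#' @return the filtered [SpikeTrainSet-class].
#' @export
filterLowRateUnits <- function(spikes, minRate = 1) {
    stopifnot(minRate >= 0)
    spikes[firingRates(spikes) > minRate]
}

#' Per-unit summary statistics
#'
#' @param spikes a [SpikeTrainSet-class].
#' @return data.frame with per-unit `unit_id`, `class`, `n_spikes`,
#'   `rate` (Hz) and `lv`.
#' @export
unitStats <- function(spikes) {
    data.frame(unit_id = spikes@unitMeta$unit_id,
               class = spikes@unitMeta$class,
               n_spikes = vapply(spikes@spikes, length, integer(1)),
               rate = firingRates(spikes),
               lv = vapply(spikes@spikes, localVariation, numeric(1)))
}
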