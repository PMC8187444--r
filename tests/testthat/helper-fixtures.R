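# homogeneous Poisson spike train on [0, T] seconds
poissonTrain <- function(rate, T) {
    sort(runif(rpois(1L, rate * T), 0, T))
}

# pair of trains where the target carries an injected excitatory
# monosynaptic effect: after each reference spike, with probability p an
# extra target spike at lag ~ Uniform(3, 5) ms
bumpPair <- function(rateRef = 5, rateTgt = 5, T = 1800, p = 0.2) {
    ref <- poissonTrain(rateRef, T)
    extra <- ref[runif(length(ref)) < p]
    extra <- extra + runif(length(extra), 0.003, 0.005)
    tgt <- sort(c(poissonTrain(rateTgt, T), extra))
    list(ref = ref, tgt = unique(tgt))
}

# pair of trains with an inhibitory effect: target spikes within (2, 6] ms
# after a reference spike are deleted with probability p
dipPair <- function(rateRef = 8, rateTgt = 8, T = 1800, p = 0.8) {
    ref <- poissonTrain(rateRef, T)
    tgt <- poissonTrain(rateTgt, T)
    lagPrev <- tgt - ref[pmax(findInterval(tgt, ref), 1L)]
    inWin <- findInterval(tgt, ref) > 0 & lagPrev > 0.002 & lagPrev <= 0.006
    drop <- inWin & runif(length(tgt)) < p
    list(ref = ref, tgt = tgt[!drop])
}

# trimmed-correlogram classification toy set: flat Poisson counts vs counts
# with an exponential bump (amplitude far above counting noise) at short
# positive latencies
separableToySet <- function(nPer = 1200, len = 96L, base = 30) {
    X <- matrix(rpois(2L * nPer * len, base), 2L * nPer, len)
    z <- rep(c(0, 1), each = nPer)
    psp <- rep(c(0, 1), each = nPer)
    posStart <- len / 2L + 1L  # first positive-lag bin
    kernel <- round(25 * exp(-(0:5) / 2))
    for (r in (nPer + 1L):(2L * nPer))
        X[r, posStart + 1L + (0:5)] <- X[r, posStart + 1L + (0:5)] + kernel
    list(x = X, z = z, psp = psp)
}

# a tiny deterministic SpikeTrainSet for label/IO tests
tinySpikeSet <- function() {
    SpikeTrainSet(list(c(0.1, 0.5, 0.9), c(0.104, 0.504, 0.93),
                       c(0.2, 0.6)),
                  duration = 1,
                  unitMeta = data.frame(unit_id = 1:3,
                                        class = c("E", "E", "I"),
                                        group = c(0L, 0L, 0L)))
}

# minimal hand-built ground truth over n units with the given synapses
handTruth <- function(n, pre, post, sign, psp) {
    syn <- data.frame(pre = pre, post = post, sign = sign,
                      G = abs(psp) / 50, delay = ifelse(sign == "E", 4, 3),
                      psp = psp)
    neurons <- data.frame(id = seq_len(n),
                          class = rep(c("E", "I"), length.out = n),
                          tau_m = 20, omega_rest = -55, alpha1 = 1.5,
                          alpha2 = 0.5, osc_group = 0L, osc_freq = 0,
                          osc_A = 0, osc_delta = 0)
    new("GroundTruthNetwork", synapses = syn, neurons = neurons,
        config = list())
}
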