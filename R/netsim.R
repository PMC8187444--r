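#' MAT neuron parameters
#'
#' Default parameters of the multi-timescale adaptive threshold (MAT) model
#' neurons used by the network simulator.  Excitatory cells have a 20 ms
#' membrane time constant, resting threshold -55 mV and per-neuron
#' threshold-jump weight `alpha1` drawn from Gauss(1.5, 0.25) mV at network
#' construction; inhibitory cells have tau_m 10 ms, resting threshold -57 mV
#' and fixed `alpha1 = 3`, `alpha2 = 0`.  Threshold decay timescales are 10
#' and 200 ms; reversal potentials (leak, excitatory, inhibitory) are -70, 0
#' and -80 mV; synaptic conductance time constants are 1 ms (excitatory) and
#' 2 ms (inhibitory).
#'
#' @return a list of neuron-model constants.
#' @export
matNeuronParams <- function() {
    list(V_L = -70, V_E = 0, V_I = -80,
         tau_s_e = 1, tau_s_i = 2,
         tau_1 = 10, tau_2 = 200,
         E = list(tau_m = 20, omega_rest = -55,
                  alpha1_mean = 1.5, alpha1_sd = 0.25, alpha2 = 0.5),
         I = list(tau_m = 10, omega_rest = -57,
                  alpha1 = 3, alpha2 = 0))
}

#' Background-input parameters
#'
#' Ornstein-Uhlenbeck background conductance parameters (means, stationary
#' SDs, time constants, reversal potentials) and the oscillatory modulation:
#' three disjoint subgroups of neurons receive a variance-modulating term
#' `A sin(2 pi f t + delta) xi(t)` on the excitatory background conductance
#' at 7, 10 and 20 Hz, with per-neuron phase uniform on `[0, 2 pi)` and
#' amplitude uniform on `[A_tilde / 2, 3 A_tilde / 2]`.
#'
#' @return a list of background-input constants (conductances in mS/cm^2,
#'   times in ms, potentials in mV).
#' @export
backgroundParams <- function() {
    list(g_e0 = 0.123, g_i0 = 0.322,
         E_e = 0, E_i = -80,
         sigma_e = 0.0163, sigma_i = 0.0265,
         tau_e = 2.7, tau_i = 10.5,
         A_tilde = 0.015, osc_freqs = c(7, 10, 20))
}

#' Simulation configuration
#'
#' Resolved configuration for building and simulating a MAT network.  The
#' defaults are the reference conditions: 1000 neurons (800 excitatory, 200
#' inhibitory), each receiving exactly 100 excitatory and 50 inhibitory
#' presynaptic partners (per-pair connection probabilities 12.5 % and 25 %),
#' 0.1 ms integration step, 7200 s of activity, 2 ms absolute refractory
#' period, and three oscillation groups each holding a tenth of the
#' population (80 % excitatory, 20 % inhibitory members).  Scaled-down
#' configurations keep the connection probabilities by scaling in-degrees as
#' `round(nExc / 8)` and `round(nInh / 4)`.
#'
#' @param nExc,nInh numbers of excitatory and inhibitory neurons.
#' @param duration biological time to simulate, seconds.
#' @param dt integration step, ms.
#' @param seed integer seed for the simulation noise stream.
#' @param refractory absolute refractory period, ms.
#' @param inDegreeExc,inDegreeInh per-neuron in-degrees; defaults preserve
#'   the 12.5 % / 25 % per-pair probabilities.
#' @param oscGroupSize neurons per oscillation group; default one tenth of
#'   the population.
#' @param neuron neuron-model constants, see [matNeuronParams()].
#' @param background background-input constants, see [backgroundParams()].
#' @param noise logical; FALSE turns off all background input (used for
#'   deterministic limit checks).
#' @param bgUpdateEvery advance the background OU conductances every this
#'   many membrane steps (exact discretization, value held in between);
#'   the default 0.5 ms stays well below the shortest background time
#'   constant.
#' @return a list with class-checked fields; the same object is written
#'   next to every simulation output for provenance.
#' @export
simConfig <- function(nExc = 800L, nInh = 200L, duration = 7200, dt = 0.1,
                      seed = 1L, refractory = 2,
                      inDegreeExc = NULL, inDegreeInh = NULL,
                      oscGroupSize = NULL,
                      neuron = matNeuronParams(),
                      background = backgroundParams(),
                      noise = TRUE, bgUpdateEvery = 5L) {
    nExc <- as.integer(nExc); nInh <- as.integer(nInh)
    if (is.null(inDegreeExc)) inDegreeExc <- as.integer(round(nExc / 8))
    if (is.null(inDegreeInh)) inDegreeInh <- as.integer(round(nInh / 4))
    if (is.null(oscGroupSize)) oscGroupSize <- as.integer(round((nExc + nInh) / 10))
    stopifnot(dt > 0, duration > 0, nExc >= 1, nInh >= 1)
    if (nExc < inDegreeExc + 1L || nInh < inDegreeInh + 1L)
        stop("in-degree exceeds available presynaptic pool")
    cfg <- list(nExc = nExc, nInh = nInh, N = nExc + nInh,
                duration = duration, dt = dt, seed = as.integer(seed),
                refractory = refractory,
                inDegreeExc = as.integer(inDegreeExc),
                inDegreeInh = as.integer(inDegreeInh),
                oscGroupSize = as.integer(oscGroupSize),
                neuron = neuron, background = background, noise = noise,
                bgUpdateEvery = as.integer(bgUpdateEvery))
    class(cfg) <- "simConfig"
    cfg
}

#' Sample synaptic peak conductances
#'
#' Excitatory conductances are log-normal with ln-mean -5.543 and ln-SD
#' 1.30; inhibitory conductances are normal with mean 0.0217 and SD 0.00171
#' mS/cm^2, with non-positive draws resampled so all conductances are
#' strictly positive.
#'
#' @param sign "E" or "I".
#' @param n number of draws.
#' @return numeric vector of conductances (mS/cm^2); uses the session RNG.
#' @export
sampleConductance <- function(sign = c("E", "I"), n) {
    sign <- match.arg(sign)
    stopifnot(n >= 1)
    if (sign == "E") {
        rlnorm(n, meanlog = -5.543, sdlog = 1.30)
    } else {
        g <- rnorm(n, mean = 0.0217, sd = 0.00171)
        while (any(bad <- g <= 0))
            g[bad] <- rnorm(sum(bad), mean = 0.0217, sd = 0.00171)
        g
    }
}

#' One step of the background Ornstein-Uhlenbeck conductance
#'
#' Exact discretization of `dg = -(g - mean)/tau dt + sigma sqrt(2/tau) dW`:
#' `g' = mean + (g - mean) exp(-dt/tau) + sigma sqrt(1 - exp(-2 dt/tau)) n`,
#' preserving the stationary mean and SD at any step size.  This is the
#' identical update rule the compiled network simulator applies per step.
#'
#' @param g current conductance(s).
#' @param mean stationary mean.
#' @param sd stationary standard deviation.
#' @param tau relaxation time, ms.
#' @param dt step, ms.
#' @param n standard-normal deviate(s); drawn from the session RNG when
#'   missing.
#' @return updated conductance(s).
#' @export
ouUpdate <- function(g, mean, sd, tau, dt, n = rnorm(length(g))) {
    stopifnot(dt > 0, tau > 0)
    phi <- exp(-dt / tau)
    mean + (g - mean) * phi + sd * sqrt(1 - phi^2) * n
}

#' One step of the oscillation-modulated background conductance
#'
#' The [ouUpdate()] step plus the variance-modulating oscillation term
#' `A sin(2 pi f t + delta) xi(t)`, discretized as
#' `A sin(2 pi f t/1000 + delta) sqrt(dt) n2` (t in ms, f in Hz).  The
#' sinusoid multiplies white noise, so it modulates the noise variance at
#' period `1/(2 f)` rather than adding a sinusoid to the mean; with `A = 0`
#' the trajectory is identical to [ouUpdate()] given the same noise stream.
#'
#' @inheritParams ouUpdate
#' @param A oscillation amplitude (0 disables the term).
#' @param freq oscillation frequency, Hz.
#' @param delta phase, radians.
#' @param t current time, ms.
#' @param n2 standard-normal deviate(s) for the oscillation term.
#' @return updated conductance(s).
#' @export
ouUpdateOscillatory <- function(g, mean, sd, tau, A, freq, delta, t, dt,
                                n = rnorm(length(g)),
                                n2 = rnorm(length(g))) {
    base <- ouUpdate(g, mean, sd, tau, dt, n)
    base + A * sin(2 * pi * freq * t / 1000 + delta) * sqrt(dt) * n2
}

#' Build a ground-truth network
#'
#' Draws the synaptic wiring (each neuron receives exactly `inDegreeExc`
#' excitatory and `inDegreeInh` inhibitory presynaptic partners, sampled
#' without replacement and excluding self-connections), conductances via
#' [sampleConductance()], transmission delays (uniform 3-5 ms excitatory,
#' 2-4 ms inhibitory), the per-neuron threshold-jump weights, and the
#' oscillation-group assignment with per-neuron phases and amplitudes.  The
#' signed single-spike PSP amplitude of every synapse is computed with
#' [computeTruePsp()] and stored in the synapse table.
#'
#' Uses the session RNG; call `set.seed()` first for reproducibility.
#'
#' @param config a [simConfig()].
#' @return a [GroundTruthNetwork-class].
#' @export
buildNetwork <- function(config = simConfig()) {
    nE <- config$nExc; nI <- config$nInh; N <- config$N
    np <- config$neuron
    excIds <- seq_len(nE)
    inhIds <- nE + seq_len(nI)

    neurons <- data.frame(
        id = seq_len(N),
        class = c(rep("E", nE), rep("I", nI)),
        tau_m = c(rep(np$E$tau_m, nE), rep(np$I$tau_m, nI)),
        omega_rest = c(rep(np$E$omega_rest, nE), rep(np$I$omega_rest, nI)),
        alpha1 = c(rnorm(nE, np$E$alpha1_mean, np$E$alpha1_sd),
                   rep(np$I$alpha1, nI)),
        alpha2 = c(rep(np$E$alpha2, nE), rep(np$I$alpha2, nI)),
        osc_group = 0L, osc_freq = 0, osc_A = 0, osc_delta = 0)

    # oscillation groups: disjoint, 80 % E / 20 % I members each
    bg <- config$background
    gsz <- config$oscGroupSize
    if (gsz > 0) {
        nGE <- round(0.8 * gsz); nGI <- gsz - nGE
        freqs <- bg$osc_freqs
        if (length(freqs) * nGE > nE || length(freqs) * nGI > nI)
            stop("oscillation groups exceed the population")
        freeE <- sample(excIds); freeI <- sample(inhIds)
        for (k in seq_along(freqs)) {
            members <- c(freeE[(k - 1) * nGE + seq_len(nGE)],
                         freeI[(k - 1) * nGI + seq_len(nGI)])
            neurons$osc_group[members] <- k
            neurons$osc_freq[members] <- freqs[k]
            neurons$osc_A[members] <- runif(length(members),
                                            bg$A_tilde / 2, 1.5 * bg$A_tilde)
            neurons$osc_delta[members] <- runif(length(members), 0, 2 * pi)
        }
    }

    kE <- config$inDegreeExc; kI <- config$inDegreeInh
    preE <- matrix(0L, nrow = kE, ncol = N)
    preI <- matrix(0L, nrow = kI, ncol = N)
    for (post in seq_len(N)) {
        poolE <- if (post <= nE) excIds[-post] else excIds
        poolI <- if (post > nE) inhIds[-(post - nE)] else inhIds
        preE[, post] <- sample(poolE, kE)
        preI[, post] <- sample(poolI, kI)
    }
    syn <- data.frame(
        pre = c(as.vector(preE), as.vector(preI)),
        post = c(rep(seq_len(N), each = kE), rep(seq_len(N), each = kI)),
        sign = c(rep("E", kE * N), rep("I", kI * N)))
    syn$G <- numeric(nrow(syn))
    syn$delay <- numeric(nrow(syn))
    if (kE > 0) syn$G[syn$sign == "E"] <- sampleConductance("E", kE * N)
    if (kI > 0) syn$G[syn$sign == "I"] <- sampleConductance("I", kI * N)
    if (kE > 0) syn$delay[syn$sign == "E"] <- runif(kE * N, 3, 5)
    if (kI > 0) syn$delay[syn$sign == "I"] <- runif(kI * N, 2, 4)
    syn$psp <- pspAmplitude(syn$G, syn$sign == "E",
                            neurons$tau_m[syn$post], neuron = np)
    new("GroundTruthNetwork", synapses = syn, neurons = neurons,
        config = unclass(config))
}

#' Single-synapse PSP amplitude
#'
#' Signed peak deflection (mV) of a passive membrane from the leak
#' potential in response to one presynaptic spike: the membrane equation is
#' integrated with only the leak and the single synaptic conductance
#' transient `G exp(-t / tau_s)` (no background, no other inputs).
#' Positive for excitatory synapses, negative for inhibitory ones, and
#' strictly increasing in magnitude with `G`.
#'
#' @param G peak conductance(s), mS/cm^2.
#' @param exc logical; TRUE for excitatory synapses.
#' @param tauMPost membrane time constant(s) of the postsynaptic neuron, ms.
#' @param neuron neuron-model constants, see [matNeuronParams()].
#' @param dt integration step, ms.
#' @return signed PSP amplitude(s), mV.
#' @export
pspAmplitude <- function(G, exc, tauMPost, neuron = matNeuronParams(),
                         dt = 0.02) {
    stopifnot(length(exc) %in% c(1L, length(G)))
    if (length(exc) == 1L) exc <- rep(exc, length(G))
    if (length(tauMPost) == 1L) tauMPost <- rep(tauMPost, length(G))
    .pspPeakCpp(as.numeric(G), as.logical(exc), as.numeric(tauMPost),
                neuron$V_L, neuron$V_E, neuron$V_I,
                neuron$tau_s_e, neuron$tau_s_i, dt, 120)
}

#' Ground-truth PSP of one connection
#'
#' @param network a [GroundTruthNetwork-class].
#' @param pre,post unit indices of an existing connection.
#' @return signed PSP amplitude in mV (as stored in the synapse table).
#' @export
computeTruePsp <- function(network, pre, post) {
    syn <- network@synapses
    hit <- which(syn$pre == pre & syn$post == post)
    if (!length(hit)) stop(sprintf("no synapse %d -> %d in network", pre, post))
    sum(syn$psp[hit])
}

#' Simulate a MAT network
#'
#' Runs the compiled forward-Euler simulation of the network at step
#' `config$dt` ms for `config$duration` s: exponential synaptic conductance
#' decay with delayed jumps, Ornstein-Uhlenbeck background conductances
#' with per-neuron oscillatory variance modulation, adaptive two-timescale
#' threshold with no voltage reset, and an absolute refractory period.
#' Identical `network`, `config` and `seed` give bit-identical spike trains.
#'
#' @param network a [GroundTruthNetwork-class] from [buildNetwork()].
#' @param config a [simConfig()]; defaults to the configuration stored in
#'   the network.
#' @param seed integer seed for the noise stream; defaults to
#'   `config$seed`.
#' @return a [SpikeTrainSet-class] with unit classes and oscillation-group
#'   tags in its metadata.
#' @export
simulateNetwork <- function(network, config = NULL, seed = NULL) {
    if (is.null(config)) config <- network@config
    config <- unclass(config)
    if (is.null(seed)) seed <- config$seed
    nrn <- network@neurons
    syn <- network@synapses
    np <- config$neuron
    bg <- config$background
    res <- .simulateMatCpp(
        src = as.integer(syn$pre - 1L), dst = as.integer(syn$post - 1L),
        G = syn$G, delay_ms = syn$delay, src_exc = syn$sign == "E",
        tau_m = nrn$tau_m, omega_rest = nrn$omega_rest,
        alpha1 = nrn$alpha1, alpha2 = nrn$alpha2,
        osc_A = nrn$osc_A, osc_freq_hz = nrn$osc_freq,
        osc_delta = nrn$osc_delta,
        constants = list(V_L = np$V_L, V_E = np$V_E, V_I = np$V_I,
                         tau_s_e = np$tau_s_e, tau_s_i = np$tau_s_i,
                         tau_1 = np$tau_1, tau_2 = np$tau_2),
        background = list(g_e0 = bg$g_e0, g_i0 = bg$g_i0,
                          E_e = bg$E_e, E_i = bg$E_i,
                          sigma_e = bg$sigma_e, sigma_i = bg$sigma_i,
                          tau_e = bg$tau_e, tau_i = bg$tau_i),
        dt = config$dt, duration_ms = config$duration * 1000,
        refr_steps = as.integer(round(config$refractory / config$dt)),
        seed = as.numeric(seed), noise_on = isTRUE(config$noise),
        bg_every = if (is.null(config$bgUpdateEvery)) 5L else config$bgUpdateEvery)
    SpikeTrainSet(res$spikes, duration = config$duration,
                  unitMeta = data.frame(unit_id = nrn$id, class = nrn$class,
                                        group = nrn$osc_group))
}

# low-level entry used by tests that need membrane/threshold traces
.simulateWithTraces <- function(network, config, seed, every = 1L) {
    nrn <- network@neurons
    syn <- network@synapses
    np <- config$neuron
    bg <- config$background
    .simulateMatCpp(
        src = as.integer(syn$pre - 1L), dst = as.integer(syn$post - 1L),
        G = syn$G, delay_ms = syn$delay, src_exc = syn$sign == "E",
        tau_m = nrn$tau_m, omega_rest = nrn$omega_rest,
        alpha1 = nrn$alpha1, alpha2 = nrn$alpha2,
        osc_A = nrn$osc_A, osc_freq_hz = nrn$osc_freq,
        osc_delta = nrn$osc_delta,
        constants = list(V_L = np$V_L, V_E = np$V_E, V_I = np$V_I,
                         tau_s_e = np$tau_s_e, tau_s_i = np$tau_s_i,
                         tau_1 = np$tau_1, tau_2 = np$tau_2),
        background = list(g_e0 = bg$g_e0, g_i0 = bg$g_i0,
                          E_e = bg$E_e, E_i = bg$E_i,
                          sigma_e = bg$sigma_e, sigma_i = bg$sigma_i,
                          tau_e = bg$tau_e, tau_i = bg$tau_i),
        dt = config$dt, duration_ms = config$duration * 1000,
        refr_steps = as.integer(round(config$refractory / config$dt)),
        seed = as.numeric(seed), noise_on = isTRUE(config$noise),
        bg_every = if (is.null(config$bgUpdateEvery)) 5L else config$bgUpdateEvery,
        record_state_every = as.integer(every))
}

#' Sample a recorded subset of units
#'
#' Emulates extracellular recording of a subset of the simulated
#' population: selects `nExc` excitatory and `nInh` inhibitory units at
#' random, renumbers them, and restricts the ground-truth network to the
#' selected units.
#'
#' @param spikes a [SpikeTrainSet-class] covering the whole population.
#' @param network the matching [GroundTruthNetwork-class].
#' @param nExc,nInh numbers of excitatory / inhibitory units to keep.
#' @return list with elements `spikes` (subset, renumbered) and `network`
#'   (restricted ground truth with renumbered indices); original labels
#'   remain in the unit metadata.
#' @export
sampleRecordedUnits <- function(spikes, network, nExc, nInh) {
    meta <- spikes@unitMeta
    excPool <- which(meta$class == "E")
    inhPool <- which(meta$class == "I")
    if (nExc > length(excPool) || nInh > length(inhPool))
        stop("requested more units than available in a class")
    keep <- sort(c(sample(excPool, nExc), sample(inhPool, nInh)))
    sub <- spikes[keep]
    remap <- integer(nUnits(spikes)); remap[keep] <- seq_along(keep)
    syn <- network@synapses
    syn <- syn[syn$pre %in% keep & syn$post %in% keep, , drop = FALSE]
    syn$pre <- remap[syn$pre]; syn$post <- remap[syn$post]
    rownames(syn) <- NULL
    nrn <- network@neurons[keep, , drop = FALSE]
    nrn$id <- seq_along(keep)
    rownames(nrn) <- NULL
    list(spikes = sub,
         network = new("GroundTruthNetwork", synapses = syn, neurons = nrn,
                       config = network@config))
}
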