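test_that("toy network wiring has exact in-degrees and no self-connections", {
    set.seed(1)
    cfg <- simConfig(nExc = 8, nInh = 2, inDegreeExc = 2, inDegreeInh = 1,
                     duration = 1, oscGroupSize = 0)
    net <- buildNetwork(cfg)
    syn <- synapses(net)
    expect_true(all(syn$pre != syn$post))
    inE <- table(factor(syn$post[syn$sign == "E"], levels = 1:10))
    inI <- table(factor(syn$post[syn$sign == "I"], levels = 1:10))
    expect_true(all(inE == 2))
    expect_true(all(inI == 1))
    expect_true(all(syn$G > 0))
    expect_true(all(syn$delay[syn$sign == "E"] >= 3 &
                    syn$delay[syn$sign == "E"] <= 5))
    expect_true(all(syn$delay[syn$sign == "I"] >= 2 &
                    syn$delay[syn$sign == "I"] <= 4))
    expect_error(simConfig(nExc = 8, nInh = 2, inDegreeExc = 8,
                           inDegreeInh = 1),
                 "in-degree exceeds")
})

test_that("conductance sampler recovers its moments and stays positive", {
    set.seed(2)
    gE <- sampleConductance("E", 2e5)
    expect_equal(mean(log(gE)), -5.543, tolerance = 0.01 / 5.543)
    expect_equal(sd(log(gE)), 1.30, tolerance = 0.01)
    gI <- sampleConductance("I", 2e5)
    expect_true(all(gI > 0))
    expect_equal(mean(gI), 0.0217, tolerance = 3 * 0.00171 / sqrt(2e5) / 0.0217)
})

test_that("OU update preserves stationary moments and relaxation time", {
    set.seed(3)
    bg <- backgroundParams()
    nst <- 5e5
    dt <- 0.1
    g <- numeric(nst)
    gc <- bg$g_e0
    nvec <- rnorm(nst)
    phi <- exp(-dt / bg$tau_e)
    for (i in seq_len(nst)) {
        gc <- bg$g_e0 + (gc - bg$g_e0) * phi +
            bg$sigma_e * sqrt(1 - phi^2) * nvec[i]
        g[i] <- gc
    }
    expect_equal(mean(g), bg$g_e0, tolerance = 0.05)
    expect_equal(sd(g), bg$sigma_e, tolerance = 0.05 * bg$sigma_e / bg$sigma_e)
    expect_lt(abs(sd(g) / bg$sigma_e - 1), 0.05)
    # autocorrelation time: rho(k) = exp(-k dt / tau)
    k <- round(bg$tau_e / dt)
    rho <- cor(g[-(1:k)], g[1:(nst - k)])
    tauHat <- -k * dt / log(rho)
    expect_lt(abs(tauHat / bg$tau_e - 1), 0.10)
    # inhibitory stationary mean
    set.seed(4)
    gi <- Reduce(function(gc, n) ouUpdate(gc, bg$g_i0, bg$sigma_i, bg$tau_i,
                                          0.5, n),
                 rnorm(2e5), accumulate = TRUE, init = bg$g_i0)
    expect_equal(mean(gi), bg$g_i0, tolerance = 0.05 * bg$g_i0 / bg$g_i0)
    expect_lt(abs(mean(gi) / bg$g_i0 - 1), 0.05)
})

test_that("noiseless OU relaxes exponentially to its mean and stays", {
    g <- 1
    for (i in 1:200) g <- ouUpdate(g, 0.123, 0, 2.7, 1, n = 0)
    expect_equal(g, 0.123, tolerance = 1e-9)
    expect_equal(ouUpdate(0.5, 0.123, 0, 2.7, 1, n = 0),
                 0.123 + (0.5 - 0.123) * exp(-1 / 2.7))
})

test_that("oscillatory term modulates the noise variance at twice the frequency", {
    # oracle: direct Euler-Maruyama of the modulated OU equation; the
    # sinusoid multiplies white noise, so the spectral signature appears in
    # the squared centred conductance at 2 f, not in the conductance itself
    bg <- backgroundParams()
    dt <- 0.1
    nst <- 2^20
    freq <- 10
    simOne <- function(A) {
        g <- numeric(nst)
        gc <- bg$g_e0
        phi <- exp(-dt / bg$tau_e)
        s <- bg$sigma_e * sqrt(1 - phi^2)
        tvec <- (seq_len(nst) - 1) * dt
        n1 <- rnorm(nst)
        n2 <- rnorm(nst)
        for (i in seq_len(nst)) {
            gc <- bg$g_e0 + (gc - bg$g_e0) * phi + s * n1[i] +
                A * sin(2 * pi * freq * tvec[i] / 1000) * sqrt(dt) * n2[i]
            g[i] <- gc
        }
        g
    }
    set.seed(5)
    gOn <- simOne(0.0225)
    gOff <- simOne(0)
    pgram <- function(x) {
        x <- x - mean(x)
        Mod(fft(x))^2 / length(x)
    }
    fr <- (seq_len(nst) - 1) / (nst * dt / 1000)
    band <- function(p, f0) mean(p[fr > f0 - 1 & fr < f0 + 1])
    sqOn <- pgram((gOn - mean(gOn))^2)
    sqOff <- pgram((gOff - mean(gOff))^2)
    peak <- band(sqOn, 2 * freq)
    flank <- mean(c(band(sqOn, 2 * freq - 8), band(sqOn, 2 * freq + 8)))
    expect_gt(peak / flank, 5)
    flankOff <- mean(c(band(sqOff, 2 * freq - 8), band(sqOff, 2 * freq + 8)))
    expect_lt(band(sqOff, 2 * freq) / flankOff, 2)
    # A = 0 path equals the plain OU update given the same noise stream
    set.seed(6)
    n1 <- rnorm(10); n2 <- rnorm(10)
    g1 <- 0.1; g2 <- 0.1
    for (i in 1:10) {
        g1 <- ouUpdate(g1, bg$g_e0, bg$sigma_e, bg$tau_e, 0.1, n1[i])
        g2 <- ouUpdateOscillatory(g2, bg$g_e0, bg$sigma_e, bg$tau_e, 0,
                                  freq, 1, i * 0.1, 0.1, n1[i], n2[i])
    }
    expect_identical(g1, g2)
    # amplitudes drawn at network construction stay in [A/2, 3A/2]
    set.seed(7)
    net <- buildNetwork(simConfig(nExc = 80, nInh = 20, duration = 1))
    A <- neuronTable(net)$osc_A
    A <- A[A > 0]
    expect_true(all(A >= 0.0075 & A <= 0.0225))
    grp <- neuronTable(net)$osc_group
    expect_equal(sort(unique(grp)), 0:3)
})

test_that("silent network with no input sits at the leak potential", {
    cfg <- simConfig(nExc = 2, nInh = 1, duration = 1, inDegreeExc = 0,
                     inDegreeInh = 0, oscGroupSize = 0, noise = FALSE)
    cfg$background$g_e0 <- 0
    cfg$background$g_i0 <- 0
    set.seed(8)
    net <- buildNetwork(cfg)
    res <- connectr:::.simulateWithTraces(net, cfg, seed = 1, every = 100L)
    expect_true(all(abs(res$v - (-70)) < 1e-9))
    expect_true(all(lengths(res$spikes) == 0))
})

test_that("threshold jumps by alpha1 + alpha2 right after a spike", {
    cfg <- simConfig(nExc = 1, nInh = 1, duration = 2, inDegreeExc = 0,
                     inDegreeInh = 0, oscGroupSize = 0)
    cfg$background <- list(g_e0 = 0.02, g_i0 = 0, E_e = 0, E_i = -80,
                           sigma_e = 0, sigma_i = 0, tau_e = 2.7,
                           tau_i = 10.5, A_tilde = 0, osc_freqs = c(7, 10, 20))
    net <- new("GroundTruthNetwork",
               synapses = data.frame(pre = integer(), post = integer(),
                                     sign = character(), G = numeric(),
                                     delay = numeric(), psp = numeric()),
               neurons = data.frame(id = 1:2, class = c("E", "I"),
                                    tau_m = c(20, 10),
                                    omega_rest = c(-55, -57),
                                    alpha1 = c(1.5, 3), alpha2 = c(0.5, 0),
                                    osc_group = 0L, osc_freq = 0,
                                    osc_A = 0, osc_delta = 0),
               config = unclass(cfg))
    res <- connectr:::.simulateWithTraces(net, cfg, seed = 1, every = 1L)
    expect_gt(length(res$spikes[[1]]), 2)
    jump <- max(diff(res$theta[1, ]))
    expect_equal(jump, 1.5 + 0.5, tolerance = 0.03)
})

test_that("simulated rate under constant drive matches an event-driven oracle", {
    # oracle: between spikes the membrane has a closed form under constant
    # conductance; threshold crossings found by bracketing + uniroot
    gConst <- 0.02; tau <- 20; VL <- -70; om <- -55
    a1 <- 1.5; a2 <- 0.5; t1 <- 10; t2 <- 200; refr <- 2
    aCoef <- 1 / tau + gConst
    vInf <- (VL / tau) / aCoef
    vAt <- function(v0, s) vInf + (v0 - vInf) * exp(-aCoef * s)
    oracleSpikes <- function(T_ms) {
        tNow <- 0; v <- VL; th1 <- 0; th2 <- 0; spk <- numeric()
        repeat {
            h <- function(s) vAt(v, s) -
                (om + th1 * exp(-s / t1) + th2 * exp(-s / t2))
            lo <- if (length(spk)) refr else 0
            grid <- seq(lo, 2000, by = 0.01)
            hv <- h(grid)
            ix <- which(hv >= 0)[1]
            if (is.na(ix)) break
            s <- if (ix == 1) grid[1] else
                uniroot(h, c(grid[ix - 1], grid[ix]), tol = 1e-10)$root
            s <- max(s, lo)
            tNow <- tNow + s
            if (tNow > T_ms) break
            spk <- c(spk, tNow)
            th1 <- th1 * exp(-s / t1) + a1
            th2 <- th2 * exp(-s / t2) + a2
            v <- vAt(v, s)
        }
        spk
    }
    rateOracle <- sum(oracleSpikes(10000) > 2000) / 8
    cfg <- simConfig(nExc = 1, nInh = 1, duration = 10, inDegreeExc = 0,
                     inDegreeInh = 0, oscGroupSize = 0)
    cfg$background <- list(g_e0 = gConst, g_i0 = 0, E_e = 0, E_i = -80,
                           sigma_e = 0, sigma_i = 0, tau_e = 2.7,
                           tau_i = 10.5, A_tilde = 0, osc_freqs = c(7, 10, 20))
    net <- new("GroundTruthNetwork",
               synapses = data.frame(pre = integer(), post = integer(),
                                     sign = character(), G = numeric(),
                                     delay = numeric(), psp = numeric()),
               neurons = data.frame(id = 1:2, class = c("E", "I"),
                                    tau_m = c(20, 10),
                                    omega_rest = c(-55, -57),
                                    alpha1 = c(1.5, 3), alpha2 = c(0.5, 0),
                                    osc_group = 0L, osc_freq = 0,
                                    osc_A = 0, osc_delta = 0),
               config = unclass(cfg))
    sp <- simulateNetwork(net, cfg, seed = 3)
    rateSim <- sum(spikeTimes(sp, 1) > 2) / 8
    expect_lt(abs(rateSim / rateOracle - 1), 0.02)
})

test_that("PSP amplitude is zero at G = 0, monotone in G, and matches the
           linearized closed form for small G", {
    np <- matNeuronParams()
    expect_equal(pspAmplitude(0, TRUE, 20), 0)
    g <- seq(0.001, 0.05, length.out = 15)
    expect_true(all(diff(pspAmplitude(g, TRUE, 20)) > 0))
    expect_true(all(diff(abs(pspAmplitude(g, FALSE, 20))) > 0))
    expect_true(all(pspAmplitude(g, FALSE, 10) < 0))
    # difference-of-exponentials peak of the linearized response
    G <- 1e-5; taum <- 20; taus <- np$tau_s_e
    tstar <- log(taum / taus) * taum * taus / (taum - taus)
    analytic <- G * taum * (np$V_E - np$V_L) * taus / (taum - taus) *
        (exp(-tstar / taum) - exp(-tstar / taus))
    expect_equal(pspAmplitude(G, TRUE, taum), analytic,
                 tolerance = 0.01)
    # lookup of a stored connection
    set.seed(9)
    net <- buildNetwork(simConfig(nExc = 8, nInh = 2, inDegreeExc = 2,
                                  inDegreeInh = 1, duration = 1,
                                  oscGroupSize = 0))
    syn <- synapses(net)
    expect_equal(computeTruePsp(net, syn$pre[1], syn$post[1]), syn$psp[1])
    expect_error(computeTruePsp(net, syn$post[1], syn$post[1]), "no synapse")
})

test_that("population statistics show faster, more regular inhibitory firing", {
    cfg <- simConfig(nExc = 80, nInh = 20, duration = 60, seed = 21)
    set.seed(21)
    net <- buildNetwork(cfg)
    sp <- simulateNetwork(net, cfg)
    r <- firingRates(sp)
    cls <- unitMeta(sp)$class
    expect_gt(mean(r[cls == "I"]), mean(r[cls == "E"]))
    st <- unitStats(sp)
    expect_gt(median(st$lv, na.rm = TRUE), 0.7)
    expect_lt(median(st$lv, na.rm = TRUE), 1.6)
    # refractoriness: no ISI below 2 ms
    isi <- unlist(lapply(sp@spikes, diff))
    expect_true(all(isi >= 0.002 - 1e-9))
})

test_that("recorded-unit subsampling restricts the ground truth consistently", {
    cfg <- simConfig(nExc = 80, nInh = 20, duration = 1, seed = 22)
    set.seed(22)
    net <- buildNetwork(cfg)
    sp <- simulateNetwork(net, cfg)
    set.seed(23)
    sub <- sampleRecordedUnits(sp, net, 40, 10)
    expect_equal(nUnits(sub$spikes), 50)
    expect_equal(sum(unitMeta(sub$spikes)$class == "E"), 40)
    expect_equal(50 * 49, 2450)  # ordered pairs of the recorded subset
    syn <- synapses(sub$network)
    expect_true(all(syn$pre >= 1 & syn$pre <= 50))
    # spikes travel with their units
    src <- unitMeta(sub$spikes)$unit_id[1]
    expect_identical(spikeTimes(sub$spikes, 1), spikeTimes(sp, src))
    # identity subset keeps everything
    set.seed(24)
    all_ <- sampleRecordedUnits(sp, net, 80, 20)
    expect_equal(nrow(synapses(all_$network)), nrow(synapses(net)))
    expect_error(sampleRecordedUnits(sp, net, 81, 10), "more units")
})

test_that("simulation is bit-reproducible under a fixed seed", {
    cfg <- simConfig(nExc = 20, nInh = 5, duration = 20, seed = 31,
                     oscGroupSize = 2)
    set.seed(31)
    net <- buildNetwork(cfg)
    s1 <- simulateNetwork(net, cfg)
    s2 <- simulateNetwork(net, cfg)
    expect_identical(s1@spikes, s2@spikes)
    set.seed(31)
    net2 <- buildNetwork(cfg)
    expect_identical(synapses(net), synapses(net2))
    s3 <- simulateNetwork(net, cfg, seed = 99)
    expect_false(identical(s1@spikes, s3@spikes))
})
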