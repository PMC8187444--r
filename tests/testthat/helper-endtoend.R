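# Shared end-to-end fixture, computed once per test session: a training
# network simulated for 30 min, an independent validation network simulated
# for 60 min (both 100 neurons, 80 E / 20 I, in-degrees 10 / 5), the CNN
# trained on all training-network pairs with {1, 2, 4} time-rescaling
# augmentation, and the estimated validation connection matrix.
.e2eEnv <- new.env(parent = emptyenv())

e2eFixture <- function() {
    if (!is.null(.e2eEnv$fix)) return(.e2eEnv$fix)
    cfgT <- simConfig(nExc = 80, nInh = 20, duration = 1800, seed = 101)
    set.seed(101)
    netT <- buildNetwork(cfgT)
    spT <- simulateNetwork(netT, cfgT)
    cfgV <- simConfig(nExc = 80, nInh = 20, duration = 3600, seed = 202)
    set.seed(202)
    netV <- buildNetwork(cfgV)
    spV <- simulateNetwork(netV, cfgV)
    train <- makeTrainingSet(spT, netT)
    model <- buildCnnModel(cnnModelSpec(inputLength = ncol(train$x)),
                           seed = 7)
    model <- trainCnn(model, train, trainConfig(epochs = 20, seed = 7))
    est <- estimateMatrix(model, spV)
    .e2eEnv$fix <- list(netT = netT, spT = spT, netV = netV, spV = spV,
                        model = model, est = est)
    .e2eEnv$fix
}

# true signed PSP for every ordered pair as a lookup matrix
truePspMatrix <- function(network) {
    n <- nUnits(network)
    syn <- synapses(network)
    m <- matrix(0, n, n)
    if (nrow(syn)) m[cbind(syn$pre, syn$post)] <- syn$psp
    m
}
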