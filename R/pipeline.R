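#' End-to-end pipeline on synthetic data
#'
#' Builds a scaled network, simulates it, trains the CNN estimator on all
#' pairs, estimates the full connection matrix, and scores it against the
#' ground truth.  All randomness is derived from `seed` (one sub-seed per
#' stage); identical inputs give byte-identical outputs.
#'
#' @param seed integer master seed.
#' @param nNeurons total network size (80 % excitatory).
#' @param duration simulated biological time, seconds.
#' @param epochs CNN training epochs.
#' @param augmentFactors time-rescaling factors for training.
#' @param theta detection threshold.
#' @param pspThreshold excitatory visibility threshold for scoring, mV.
#' @param outDir optional directory; when given, writes spike trains,
#'   ground truth, model checkpoint, estimate table, evaluation summary
#'   and the resolved configuration.
#' @return list with `config`, `network`, `spikes`, `model`, `estimates`
#'   and `confusion`.
#' @export
runPipeline <- function(seed = 1L, nNeurons = 100L, duration = 600,
                        epochs = 20L, augmentFactors = c(1, 2, 4),
                        theta = 0.5, pspThreshold = 0.1, outDir = NULL) {
    nExc <- as.integer(round(0.8 * nNeurons))
    nInh <- as.integer(nNeurons - nExc)
    cfg <- simConfig(nExc = nExc, nInh = nInh, duration = duration,
                     seed = seed)
    set.seed(seed)
    network <- buildNetwork(cfg)
    spikes <- simulateNetwork(network, cfg, seed = seed)
    train <- makeTrainingSet(spikes, network, augmentFactors = augmentFactors)
    model <- buildCnnModel(cnnModelSpec(inputLength = ncol(train$x)),
                           seed = seed)
    model <- trainCnn(model, train,
                      trainConfig(epochs = epochs, seed = seed))
    est <- estimateMatrix(model, spikes, theta = theta)
    cf <- confusion(est, network, pspThreshold = pspThreshold)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeSpikeTrains(spikes, file.path(outDir, "spikes.tsv"))
        writeGroundTruth(network, file.path(outDir, "truth.csv"))
        saveCnnModel(model, file.path(outDir, "model.json"))
        writeEstimates(est, file.path(outDir, "estimates.csv"))
        writeRunConfig(c(unclass(cfg),
                         list(epochs = epochs, theta = theta,
                              pspThreshold = pspThreshold,
                              augmentFactors = augmentFactors)),
                       file.path(outDir, "config.yaml"))
        summaryLines <- c(
            sprintf("units: %d, duration: %g s", nNeurons, duration),
            sprintf("E: TP %d FP %d FN %d TN %d MCC %.3f",
                    cf$E$TP, cf$E$FP, cf$E$FN, cf$E$TN, cf$E$MCC),
            sprintf("I: TP %d FP %d FN %d TN %d MCC %.3f",
                    cf$I$TP, cf$I$FP, cf$I$FN, cf$I$TN, cf$I$MCC),
            sprintf("macro MCC: %.3f", cf$macroMcc))
        writeLines(summaryLines, file.path(outDir, "evaluation.txt"))
    }
    list(config = cfg, network = network, spikes = spikes, model = model,
         estimates = est, confusion = cf)
}
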