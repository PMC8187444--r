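#' Write spike trains to plain text
#'
#' Two-column tab-separated file (`unit_id`, `spike_time_seconds`, sorted
#' within unit) plus a metadata sidecar carrying the recording duration and
#' per-unit class/group.
#'
#' @param spikes a [SpikeTrainSet-class].
#' @param path output path for the spike table.
#' @param metaPath sidecar path (default `paste0(path, ".meta")`).
#' @return `path`, invisibly.
#' @export
writeSpikeTrains <- function(spikes, path, metaPath = paste0(path, ".meta")) {
    n <- vapply(spikes@spikes, length, integer(1))
    df <- data.frame(unit_id = rep(spikes@unitMeta$unit_id, n),
                     time_s = unlist(spikes@spikes, use.names = FALSE))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    con <- file(metaPath, "w")
    writeLines(sprintf("# duration_s=%.10g", spikes@duration), con)
    write.table(spikes@unitMeta, con, sep = "\t", row.names = FALSE,
                quote = FALSE)
    close(con)
    invisible(path)
}

#' Read spike trains from plain text
#'
#' Validates the two-column format: a negative or out-of-order timestamp
#' within a unit raises an error naming the offending line.  The duration
#' is taken from the metadata sidecar when present, otherwise from the
#' latest spike.
#'
#' @param path spike-table path (tab-separated `unit_id`, `time_s`).
#' @param metaPath sidecar path; read when the file exists.
#' @return a [SpikeTrainSet-class].
#' @export
readSpikeTrains <- function(path, metaPath = paste0(path, ".meta")) {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    df <- read.delim(path)
    if (nrow(df) == 0L) {
        warning("empty spike-train file")
        return(SpikeTrainSet(list(), duration = 0))
    }
    if (!all(c("unit_id", "time_s") %in% names(df)))
        stop("expected columns unit_id, time_s")
    last <- new.env()
    for (r in seq_len(nrow(df))) {
        u <- as.character(df$unit_id[r]); tm <- df$time_s[r]
        if (tm < 0)
            stop(sprintf("negative spike time at line %d", r + 1L))
        prev <- mget(u, envir = last, ifnotfound = -Inf)[[1L]]
        if (tm <= prev)
            stop(sprintf("out-of-order spike time at line %d", r + 1L))
        assign(u, tm, envir = last)
    }
    duration <- NULL
    meta <- NULL
    if (file.exists(metaPath)) {
        first <- readLines(metaPath, n = 1L)
        if (grepl("^# duration_s=", first))
            duration <- as.numeric(sub("^# duration_s=", "", first))
        meta <- read.delim(metaPath, comment.char = "#")
    }
    ids <- if (!is.null(meta)) meta$unit_id else sort(unique(df$unit_id))
    spikes <- lapply(ids, function(u) df$time_s[df$unit_id == u])
    if (is.null(meta))
        meta <- data.frame(unit_id = ids, class = NA_character_, group = 0L)
    SpikeTrainSet(spikes, duration = duration, unitMeta = meta)
}

#' Write a ground-truth synapse table to CSV
#'
#' Columns `pre,post,sign,G_mScm2,delay_ms,psp_mV` with 0-based unit
#' indices.
#'
#' @param network a [GroundTruthNetwork-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(network, path) {
    syn <- network@synapses
    out <- data.frame(pre = syn$pre - 1L, post = syn$post - 1L,
                      sign = syn$sign, G_mScm2 = syn$G,
                      delay_ms = syn$delay, psp_mV = syn$psp)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a ground-truth synapse table from CSV
#'
#' @param path CSV written by [writeGroundTruth()].
#' @param nUnits number of neurons; defaults to the largest index + 1.
#' @return a [GroundTruthNetwork-class] (neuron table reduced to ids and
#'   classes inferred from outgoing synapse signs).
#' @export
readGroundTruth <- function(path, nUnits = NULL) {
    df <- read.csv(path)
    need <- c("pre", "post", "sign", "G_mScm2", "delay_ms", "psp_mV")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("ground-truth CSV missing columns: %s",
                     paste(miss, collapse = ", ")))
    syn <- data.frame(pre = df$pre + 1L, post = df$post + 1L,
                      sign = df$sign, G = df$G_mScm2,
                      delay = df$delay_ms, psp = df$psp_mV)
    if (is.null(nUnits)) nUnits <- max(syn$pre, syn$post)
    cls <- rep(NA_character_, nUnits)
    cls[unique(syn$pre[syn$sign == "E"])] <- "E"
    cls[unique(syn$pre[syn$sign == "I"])] <- "I"
    neurons <- data.frame(id = seq_len(nUnits), class = cls,
                          tau_m = NA_real_, omega_rest = NA_real_,
                          alpha1 = NA_real_, alpha2 = NA_real_,
                          osc_group = 0L, osc_freq = 0, osc_A = 0,
                          osc_delta = 0)
    new("GroundTruthNetwork", synapses = syn, neurons = neurons,
        config = list())
}

#' Write / read a directed estimate table
#'
#' CSV with the fixed column order `pre,post,z,connected,psp_mV` (CNN
#' estimates) or `pre,post,J,delay_ms,two_D,significant` (GLMCC).
#'
#' @param est estimate data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeEstimates <- function(est, path) {
    cnnCols <- c("pre", "post", "z", "connected", "psp_mV")
    glmCols <- c("pre", "post", "J", "delay_ms", "two_D", "significant")
    cols <- if (all(cnnCols %in% names(est))) cnnCols
            else if (all(glmCols %in% names(est))) glmCols
            else stop("unrecognized estimate table columns")
    write.csv(est[, cols], path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeEstimates
#' @export
readEstimates <- function(path) {
    read.csv(path)
}

#' Write / read a correlogram store
#'
#' One row per pair: `ref, tgt, window_ms, bin_ms, trimmed, n_ref` followed
#' by the count columns.
#'
#' @param ccs list of [Correlogram-class] objects (same geometry).
#' @param path CSV path.
#' @return `path` (write) or a list of [Correlogram-class] (read).
#' @export
writeCorrelograms <- function(ccs, path) {
    stopifnot(length(ccs) > 0)
    lens <- vapply(ccs, function(x) length(x@counts), integer(1))
    if (length(unique(lens)) != 1L)
        stop("all correlograms must share one geometry")
    head <- do.call(rbind, lapply(ccs, function(x)
        data.frame(ref = x@pair[1L], tgt = x@pair[2L], window_ms = x@window,
                   bin_ms = x@binWidth, trimmed = x@trimmed, n_ref = x@nRef)))
    cnt <- do.call(rbind, lapply(ccs, function(x) as.integer(x@counts)))
    colnames(cnt) <- paste0("c", seq_len(ncol(cnt)))
    write.csv(cbind(head, cnt), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCorrelograms
#' @export
readCorrelograms <- function(path) {
    df <- read.csv(path)
    cntCols <- grep("^c[0-9]+$", names(df))
    lapply(seq_len(nrow(df)), function(r)
        new("Correlogram", counts = as.integer(df[r, cntCols]),
            binWidth = df$bin_ms[r], window = df$window_ms[r],
            trimmed = df$trimmed[r], nRef = as.integer(df$n_ref[r]),
            pair = as.integer(c(df$ref[r], df$tgt[r]))))
}

#' Save / load a CNN model checkpoint
#'
#' Single-file JSON checkpoint embedding the architecture spec, all weight
#' arrays at full precision, the initialization seed and the training
#' history, so that a reloaded model reproduces predictions bit-for-bit.
#'
#' @param model a [CnnConnect-class].
#' @param path checkpoint path (.json).
#' @return `path` (save) or the [CnnConnect-class] (load).
#' @export
saveCnnModel <- function(model, path) {
    payload <- list(
        format = "connectr-cnn-1",
        spec = model@spec,
        weights = lapply(model@weights, function(p)
            if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
            else list(dim = length(p), data = as.numeric(p))),
        seed = model@seed,
        trained = model@trained,
        history = model@history)
    writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE),
               path)
    invisible(path)
}

#' @rdname saveCnnModel
#' @export
loadCnnModel <- function(path) {
    if (!file.exists(path)) stop(sprintf("no such checkpoint: %s", path))
    p <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
    if (is.null(p$format) || p$format != "connectr-cnn-1")
        stop("not a connectr CNN checkpoint")
    weights <- lapply(p$weights, function(w) {
        if (length(w$dim) == 2L) matrix(w$data, w$dim[1L], w$dim[2L])
        else as.numeric(w$data)
    })
    hist <- if (length(p$history)) as.data.frame(p$history) else data.frame()
    new("CnnConnect", spec = lapply(p$spec, function(v)
            if (is.numeric(v) && v == round(v)) as.integer(v) else v),
        weights = weights, history = hist,
        seed = as.numeric(p$seed), trained = isTRUE(p$trained))
}

#' Write a resolved run configuration (YAML)
#'
#' Every pipeline stage writes its resolved configuration and seed next to
#' its outputs for provenance.
#'
#' @param config a named list (e.g. a [simConfig()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    cfg <- unclass(config)
    cfg$package_version <- as.character(utils::packageVersion("connectr"))
    yaml::write_yaml(cfg, path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    yaml::read_yaml(path)
}
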