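#' GLMCC hyperparameters
#'
#' @param window correlogram half-window W, ms.
#' @param binWidth discretization step Delta, ms.
#' @param tau synaptic interaction timescale, ms.
#' @param delays candidate transmission delays, ms.
#' @param gamma baseline smoothness hyperparameter, 1/ms (smaller = flatter
#'   baseline; the prior penalty per adjacent bin pair is
#'   `(a[k+1] - a[k])^2 / (gamma * Delta)`).
#' @param alpha significance level of the likelihood-ratio test.
#' @param tol gradient max-norm convergence tolerance of the Newton
#'   optimizer.
#' @param maxit maximum Newton iterations.
#' @return a hyperparameter list; `M = 2 * window / binWidth` bins.
#' @export
glmccHyper <- function(window = 50, binWidth = 1, tau = 4, delays = 1:4,
                       gamma = 2e-4, alpha = 1e-4, tol = 1e-6,
                       maxit = 1000L) {
    stopifnot(window > 0, binWidth > 0, tau > 0, gamma > 0,
              alpha > 0, alpha < 1, all(delays > 0))
    list(window = window, binWidth = binWidth,
         M = as.integer(round(2 * window / binWidth)),
         tau = tau, delays = delays, gamma = gamma, alpha = alpha,
         tol = tol, maxit = as.integer(maxit))
}

#' Exponential synaptic interaction kernel
#'
#' `f(t) = exp(-(t - d) / tau)` for `t > d`, 0 otherwise: the temporal
#' profile of a monosynaptic effect with transmission delay `d` and decay
#' timescale `tau`.
#'
#' @param t lag(s), ms.
#' @param d transmission delay, ms.
#' @param tau decay timescale, ms.
#' @return kernel value(s).
#' @export
synapticKernel <- function(t, d, tau = 4) {
    stopifnot(tau > 0)
    ifelse(t > d, exp(-(t - d) / tau), 0)
}

# counts on the full (untrimmed) lag grid plus a mask of bins that enter
# the likelihood.  Trimmed correlograms keep their true lag alignment: the
# four shadow bins are masked out, not concatenated.
.glmccCountsMask <- function(cc, hyper) {
    if (is(cc, "Correlogram")) {
        if (abs(cc@window - hyper$window) > 1e-9 ||
            abs(cc@binWidth - hyper$binWidth) > 1e-9)
            stop("correlogram geometry does not match hyperparameters")
        if (isTrimmed(cc)) {
            drop <- .shadowBins(cc@window, cc@binWidth)
            counts <- numeric(hyper$M)
            counts[!drop] <- cc@counts
            list(counts = counts, mask = !drop)
        } else {
            list(counts = as.numeric(cc@counts), mask = rep(TRUE, hyper$M))
        }
    } else {
        counts <- as.numeric(cc)
        if (length(counts) == hyper$M)
            list(counts = counts, mask = rep(TRUE, hyper$M))
        else if (length(counts) == hyper$M - 4L) {
            drop <- .shadowBins(hyper$window, hyper$binWidth)
            full <- numeric(hyper$M)
            full[!drop] <- counts
            list(counts = full, mask = !drop)
        } else stop("counts length matches neither M nor M - 4")
    }
}

.lagCentersFull <- function(hyper) {
    -hyper$window + (seq_len(hyper$M) - 0.5) * hyper$binWidth
}

# log posterior, gradient and (optionally) Hessian of the GLM
#   lambda_k = exp(a_k + J1 f1_k + J2 f2_k)   [counts per bin width]
# against observed counts; quadratic smoothness prior on a.
.glmccParts <- function(a, J1, J2, counts, mask, f1, f2, hyper,
                        hessian = FALSE) {
    delta <- hyper$binWidth
    beta <- 1 / (hyper$gamma * delta)
    eta <- a + J1 * f1 + J2 * f2
    lam <- exp(eta)
    ll <- sum((counts * eta - delta * lam)[mask])
    d <- diff(a)
    pen <- beta * sum(d^2)
    r <- (counts - delta * lam) * mask
    ga <- r - 2 * beta * (c(0, d) - c(d, 0))
    out <- list(lp = ll - pen, ll = ll,
                grad = c(ga, J1 = sum(r * f1), J2 = sum(r * f2)))
    if (hessian) {
        M <- length(a)
        W <- (delta * lam) * mask
        lap <- diag(c(1, rep(2, M - 2), 1))
        lap[cbind(1:(M - 1), 2:M)] <- -1
        lap[cbind(2:M, 1:(M - 1))] <- -1
        Haa <- -diag(W) - 2 * beta * lap
        out$H <- rbind(cbind(Haa, -W * f1, -W * f2),
                       c(-W * f1, -sum(W * f1^2), -sum(W * f1 * f2)),
                       c(-W * f2, -sum(W * f1 * f2), -sum(W * f2^2)))
    }
    out
}

#' GLMCC log posterior
#'
#' Log posterior of the correlogram GLM
#' `lambda(t) = exp(a(t) + J12 f(t) + J21 f(-t))`: the binned Poisson log
#' likelihood `sum_k c_k eta_k - Delta exp(eta_k)` plus the smoothness
#' prior `-sum_k (a[k+1] - a[k])^2 / (gamma Delta)` (additive constants
#' dropped).  `a` is in log expected counts per bin; divide `exp(a)` by
#' `binWidth * nRef` for an intensity per reference spike per ms.
#'
#' @param a baseline vector of length `M`.
#' @param J couplings `c(J12, J21)`.
#' @param delay delays `c(d12, d21)`, ms.
#' @param cc a [Correlogram-class] (untrimmed or trimmed; trimmed bins are
#'   masked out of the likelihood, keeping the kernel's lag alignment) or a
#'   count vector.
#' @param hyper a [glmccHyper()].
#' @return log posterior (scalar).
#' @export
glmccLogPosterior <- function(a, J, delay, cc, hyper = glmccHyper()) {
    cm <- .glmccCountsMask(cc, hyper)
    tk <- .lagCentersFull(hyper)
    f1 <- synapticKernel(tk, delay[1L], hyper$tau)
    f2 <- synapticKernel(-tk, delay[2L], hyper$tau)
    .glmccParts(a, J[1L], J[2L], cm$counts, cm$mask, f1, f2, hyper)$lp
}

# damped Newton ascent on the strictly concave log posterior.  J1fix/J2fix
# pin a coupling to a constant (NULL = free).  Returns the optimum.
.glmccNewton <- function(counts, mask, f1, f2, hyper,
                         J1fix = NULL, J2fix = NULL,
                         a0 = NULL, J0 = c(0, 0)) {
    M <- hyper$M
    if (is.null(a0))
        a0 <- rep(log(max(mean(counts[mask]), 1e-3)), M)
    a <- a0
    J1 <- if (is.null(J1fix)) J0[1L] else J1fix
    J2 <- if (is.null(J2fix)) J0[2L] else J2fix
    freeJ <- c(is.null(J1fix), is.null(J2fix))
    sel <- c(rep(TRUE, M), freeJ)
    converged <- FALSE
    parts <- .glmccParts(a, J1, J2, counts, mask, f1, f2, hyper, hessian = TRUE)
    for (it in seq_len(hyper$maxit)) {
        g <- parts$grad[sel]
        if (max(abs(g)) < hyper$tol) { converged <- TRUE; break }
        H <- parts$H[sel, sel, drop = FALSE]
        step <- tryCatch(solve(-H + diag(1e-9, nrow(H)), g),
                         error = function(e) g * 1e-3)
        t <- 1
        repeat {
            a2 <- a + t * step[seq_len(M)]
            jstep <- step[-seq_len(M)]
            J1n <- J1; J2n <- J2
            if (freeJ[1L]) { J1n <- J1 + t * jstep[1L]; jstep <- jstep[-1L] }
            if (freeJ[2L]) J2n <- J2 + t * jstep[1L]
            p2 <- .glmccParts(a2, J1n, J2n, counts, mask, f1, f2, hyper,
                              hessian = TRUE)
            if (is.finite(p2$lp) && p2$lp >= parts$lp - 1e-12) break
            t <- t / 2
            if (t < 1e-10) break
        }
        if (t < 1e-10) break
        a <- a2; J1 <- J1n; J2 <- J2n; parts <- p2
    }
    list(a = a, J1 = J1, J2 = J2, lp = parts$lp, ll = parts$ll,
         converged = converged)
}

#' MAP fit of the GLM to a correlogram with likelihood-ratio tests
#'
#' Fits `lambda(t) = exp(a(t) + J12 f(t) + J21 f(-t))` by maximum a
#' posteriori estimation with a damped-Newton optimizer (the log posterior
#' is strictly concave).  The transmission delay of each direction is
#' selected independently from the candidate set by maximal penalized
#' posterior; the final joint fit frees both couplings at the chosen
#' delays.  Each direction is then tested by the likelihood ratio
#' `D = logL(J = Jhat) - logL(J = 0)`, where both likelihoods are profiled
#' over all remaining parameters; the null is rejected when `2 D` exceeds
#' the upper-`alpha` chi-square(1) quantile (Wilks).
#'
#' @param cc a [Correlogram-class] (trimmed or untrimmed) or count vector.
#' @param hyper a [glmccHyper()].
#' @return a [GlmccFit-class].
#' @export
glmccFit <- function(cc, hyper = glmccHyper()) {
    cm <- .glmccCountsMask(cc, hyper)
    counts <- cm$counts; mask <- cm$mask
    tk <- .lagCentersFull(hyper)
    kern1 <- lapply(hyper$delays, function(d) synapticKernel(tk, d, hyper$tau))
    kern2 <- lapply(hyper$delays, function(d) synapticKernel(-tk, d, hyper$tau))

    pickDelay <- function(kerns, direction) {
        best <- NULL
        for (k in seq_along(kerns)) {
            fit <- if (direction == 1L)
                .glmccNewton(counts, mask, kerns[[k]], numeric(hyper$M),
                             hyper, J2fix = 0)
            else
                .glmccNewton(counts, mask, numeric(hyper$M), kerns[[k]],
                             hyper, J1fix = 0)
            if (is.null(best) || fit$lp > best$lp)
                best <- c(fit, list(idx = k))
        }
        best
    }
    s1 <- pickDelay(kern1, 1L)
    s2 <- pickDelay(kern2, 2L)
    f1 <- kern1[[s1$idx]]; f2 <- kern2[[s2$idx]]

    full <- .glmccNewton(counts, mask, f1, f2, hyper,
                         a0 = s1$a, J0 = c(s1$J1, s2$J2))
    c12 <- .glmccNewton(counts, mask, f1, f2, hyper, J1fix = 0,
                        a0 = full$a, J0 = c(0, full$J2))
    c21 <- .glmccNewton(counts, mask, f1, f2, hyper, J2fix = 0,
                        a0 = full$a, J0 = c(full$J1, 0))
    D12 <- max(full$ll - c12$ll, 0)
    D21 <- max(full$ll - c21$ll, 0)
    zcrit <- qchisq(1 - hyper$alpha, df = 1)
    new("GlmccFit",
        a = full$a,
        J = c(J12 = full$J1, J21 = full$J2),
        delay = c(d12 = hyper$delays[s1$idx], d21 = hyper$delays[s2$idx]),
        D = c(D12 = D12, D21 = D21),
        significant = c(sig12 = 2 * D12 > zcrit, sig21 = 2 * D21 > zcrit),
        logPost = full$lp, logLik = full$ll,
        converged = full$converged && c12$converged && c21$converged,
        hyper = hyper,
        counts = ifelse(mask, counts, NA_real_))
}

#' Calibrate GLMCC couplings to a PSP scale (simulator-based utility)
#'
#' The coupling `J` is a log-intensity factor with no physical unit; this
#' helper regresses the known signed PSP amplitudes of a simulated ground
#' truth on the fitted couplings of significant pairs, giving an ad-hoc
#' linear mapping `psp ~ slope * J`.  Purely a convenience for comparing
#' the two estimators on synthetic data; the calibration is not part of
#' the GLMCC method itself.
#'
#' @param est a [glmccEstimateMatrix()] table.
#' @param truth the matching [GroundTruthNetwork-class].
#' @return list with `slope` (mV per unit J, zero-intercept fit) and the
#'   fitted `psp_mV` vector aligned with `est` rows (0 where not
#'   significant).
#' @export
glmccPspCalibration <- function(est, truth) {
    syn <- truth@synapses
    n <- nUnits(truth)
    tp <- matrix(0, n, n)
    if (nrow(syn)) tp[cbind(syn$pre, syn$post)] <- syn$psp
    y <- tp[cbind(est$pre, est$post)]
    use <- est$significant & y != 0
    if (sum(use) < 3) stop("too few significant true pairs to calibrate")
    slope <- sum(y[use] * est$J[use]) / sum(est$J[use]^2)
    list(slope = slope,
         psp_mV = ifelse(est$significant, slope * est$J, 0))
}

#' Likelihood-ratio test of one coupling direction
#'
#' @param cc a [Correlogram-class] or count vector.
#' @param hyper a [glmccHyper()].
#' @param direction "12" (reference drives target; positive lags) or "21".
#' @return list with `D`, `twoD`, `significant` and the fitted `J`.
#' @export
likelihoodRatioTest <- function(cc, hyper = glmccHyper(),
                                direction = c("12", "21")) {
    direction <- match.arg(direction)
    fit <- glmccFit(cc, hyper)
    i <- if (direction == "12") 1L else 2L
    list(D = unname(fit@D[i]), twoD = unname(2 * fit@D[i]),
         significant = unname(fit@significant[i]), J = unname(fit@J[i]))
}

#' GLMCC estimates for all ordered unit pairs
#'
#' Fits the correlogram GLM to every unordered pair and reports, for each
#' ordered pair, the fitted coupling, chosen delay, likelihood-ratio
#' statistic and significance flag.  The orientation contract guarantees
#' that the (i, j) row equals the reverse coupling of the (j, i)
#' correlogram.
#'
#' @param spikes a [SpikeTrainSet-class] (at least 2 units).
#' @param hyper a [glmccHyper()].
#' @param trim logical; shadow-trim correlograms before fitting (masked
#'   bins, see [glmccFit()]).
#' @param fits logical; also return the list of [GlmccFit-class] objects
#'   (for plotting fitted curves).
#' @return data.frame with columns `pre`, `post`, `J`, `delay_ms`,
#'   `two_D`, `significant` (plus attribute `"fits"` when requested).
#' @export
glmccEstimateMatrix <- function(spikes, hyper = glmccHyper(), trim = TRUE,
                                fits = FALSE) {
    n <- nUnits(spikes)
    if (n < 2L) stop("need at least 2 units")
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    rows <- vector("list", 2L * nrow(pairs))
    fitList <- if (fits) vector("list", nrow(pairs)) else NULL
    for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1L]; j <- pairs[p, 2L]
        cc <- computeCorrelogram(spikeTimes(spikes, i), spikeTimes(spikes, j),
                                 hyper$window, hyper$binWidth, pair = c(i, j))
        if (trim) cc <- shadowTrim(cc)
        fit <- glmccFit(cc, hyper)
        rows[[2L * p - 1L]] <- data.frame(
            pre = i, post = j, J = unname(fit@J["J12"]),
            delay_ms = unname(fit@delay["d12"]),
            two_D = unname(2 * fit@D["D12"]),
            significant = unname(fit@significant["sig12"]))
        rows[[2L * p]] <- data.frame(
            pre = j, post = i, J = unname(fit@J["J21"]),
            delay_ms = unname(fit@delay["d21"]),
            two_D = unname(2 * fit@D["D21"]),
            significant = unname(fit@significant["sig21"]))
        if (fits) fitList[[p]] <- fit
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (fits) attr(out, "fits") <- fitList
    out
}
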