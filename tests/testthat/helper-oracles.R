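# Independent oracles used to freeze expected values.

# Drift covariance by direct enumeration of all configurations, assembling
# the per-branch sharing matrices explicitly (independent of the vectorized
# inclusion-matrix path used by driftCovariance).
bruteCovariance <- function(graph, c, w) {
    M <- numPopulations(graph)
    K <- numBranches(graph)
    I <- numMigrationEdges(graph)
    configs <- if (I == 0) matrix(integer(), 1, 0) else
        as.matrix(expand.grid(rep(list(0:1), I)))
    p <- matrix(0, M, K)
    for (r in seq_len(nrow(configs))) {
        b <- as.integer(configs[r, ])
        wb <- configurationProbability(w, b)
        paths <- resolveConfiguration(graph, b)
        for (m in seq_len(M)) {
            for (br in paths[[m]]) {
                k <- match(br, graph@branchChild)
                p[m, k] <- p[m, k] + wb
            }
        }
    }
    W <- matrix(0, M, M)
    for (k in seq_len(K)) W <- W + c[k] * outer(p[, k], p[, k])
    W
}

# Log-likelihood and per-locus posteriors by exhaustive enumeration of all
# hidden state paths (tiny L and state counts only).
pathEnumOracle <- function(logE, Plist, init, segStart = NULL, group = NULL) {
    L <- nrow(logE); S <- ncol(logE)
    if (is.matrix(Plist)) Plist <- list(Plist)
    if (is.null(segStart)) segStart <- c(TRUE, rep(FALSE, L - 1))
    if (is.null(group)) group <- rep(1L, L)
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
    lik <- numeric(nrow(paths))
    for (r in seq_len(nrow(paths))) {
        z <- paths[r, ]
        lp <- 0
        for (l in seq_len(L)) {
            lp <- lp + logE[l, z[l]] +
                if (segStart[l]) log(init[z[l]])
                else log(Plist[[group[l]]][z[l - 1], z[l]])
        }
        lik[r] <- exp(lp)
    }
    tot <- sum(lik)
    gamma <- matrix(0, L, S)
    for (l in seq_len(L))
        for (s in seq_len(S))
            gamma[l, s] <- sum(lik[paths[, l] == s]) / tot
    list(loglik = log(tot), gamma = gamma)
}

# Dense-inverse Gaussian log density (checks the Cholesky path)
denseGaussLogDens <- function(d, mu, S) {
    M <- length(d)
    r <- d - mu
    as.numeric(-0.5 * (M * log(2 * pi) + determinant(S)$modulus +
        t(r) %*% solve(S) %*% r))
}

# Finite-difference gradient of a scalar function
fdGradient <- function(f, x, h = 1e-6) {
    vapply(seq_along(x), function(k) {
        xp <- x; xp[k] <- xp[k] + h
        xm <- x; xm[k] <- xm[k] - h
        (f(xp) - f(xm)) / (2 * h)
    }, numeric(1))
}

simulateToy <- function(graph, L = 200, mode = "peaks", peakWidth = NULL,
                        N = 100, mu = -0.5, sigma2 = 0.3, seed = 1, ...) {
    if (mode == "peaks" && is.null(peakWidth)) {
        stopifnot(L %% 10 == 0)
        divs <- which((L / 10) %% seq_len(10) == 0)
        peakWidth <- max(divs)
    }
    tr <- if (mode == "peaks") simulateTrack(L, mode, peakWidth = peakWidth, ...)
          else simulateTrack(L, mode, ...)
    if (numMigrationEdges(graph) == 2)
        tr <- combineTracks(tr, tr)
    simulateDataset(graph, track = tr, mu = mu, sigma2 = sigma2, N = N,
                    seed = seed)
}
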