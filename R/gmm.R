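#' Observed covariance of transformed frequencies
#'
#' Sample covariance of the arcsine-transformed observed frequencies across
#' loci, the starting guess for the drift covariance. Rank-deficient input
#' (too few loci) gets a small ridge with a warning.
#'
#' @param d matrix (L x M) of transformed frequencies.
#' @export
initCovariance <- function(d) {
    d <- as.matrix(d)
    W0 <- cov(d)
    ev <- eigen(W0, symmetric = TRUE, only.values = TRUE)$values
    if (nrow(d) < ncol(d) + 1 || min(ev) < 1e-10 * max(abs(ev), 1e-12)) {
        warning("observed covariance is (near) rank-deficient; adding ridge")
        W0 <- W0 + diag(max(1e-8, 1e-6 * mean(diag(W0))), ncol(d))
    }
    W0
}

## sigma2 heuristic: pairs of populations on opposite sides of the root share
## no drift, so their covariance is approximately the root-prior variance.
.sigma2Heuristic <- function(W0) {
    off <- W0[upper.tri(W0)]
    if (length(off) == 0L) return(1e-2)
    max(1e-4, min(off))
}

.projectPSD <- function(A) {
    A <- (A + t(A)) / 2
    e <- eigen(A, symmetric = TRUE)
    v <- pmax(e$values, 0)
    B <- e$vectors %*% (v * t(e$vectors))
    (B + t(B)) / 2
}

#' Gaussian-mixture refinement of the drift covariance
#'
#' Fits the mixture \eqn{\sum_r \pi_r N(d_l; \mu 1, W_r + \bar\Sigma +
#' \sigma^2 1 1')} across loci with analytic EM updates: responsibilities,
#' weights, component total covariances (responsibility-weighted scatter) and
#' the shared scalar mean \eqn{\mu} by generalized least squares. The shared
#' \eqn{\sigma^2} is held at its supplied value during EM (the unconstrained
#' \eqn{W_r} would absorb it); the returned \code{W} slots are the total
#' covariances minus \eqn{\bar\Sigma + \sigma^2 1 1'}, projected to the
#' nearest PSD matrix. The log-likelihood trace is non-decreasing.
#'
#' @param d matrix (L x M) of transformed frequencies.
#' @param Sigmabar occurrence-weighted mean sampling covariance (M x M).
#' @param R number of components (>= 1).
#' @param seed RNG seed for the responsibility initialization.
#' @param sigma2 shared root-prior variance held fixed during EM.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param retries restarts allowed on component collapse.
#' @return a \linkS4class{MixtureInit}.
#' @export
gmmEM <- function(d, Sigmabar, R, seed = 1L, sigma2 = 0,
                  tol = 1e-8, maxIter = 500L, retries = 5L) {
    d <- as.matrix(d)
    L <- nrow(d); M <- ncol(d)
    stopifnot(R >= 1)
    base <- Sigmabar + sigma2
    for (attempt in 0:retries) {
        set.seed(seed + attempt)
        resp <- matrix(rgamma(L * R, shape = 1), L, R)
        resp <- resp / rowSums(resp)
        mu <- mean(d)
        Cr <- lapply(seq_len(R), function(r) {
            g <- resp[, r]
            crossprod(sqrt(g) * (d - mu)) / sum(g)
        })
        piR <- colMeans(resp)
        trace <- numeric(0)
        ok <- TRUE
        for (it in seq_len(maxIter)) {
            ## E-step
            logd <- matrix(NA_real_, L, R)
            for (r in seq_len(R)) {
                le <- logEmission(d, mu, Cr[[r]])
                if (any(!is.finite(le))) { ok <- FALSE; break }
                logd[, r] <- log(piR[r]) + le
            }
            if (!ok) break
            m <- apply(logd, 1L, max)
            p <- exp(logd - m)
            s <- rowSums(p)
            ll <- sum(log(s) + m)
            resp <- p / s
            trace <- c(trace, ll)
            ## M-step (analytic)
            piR <- colMeans(resp)
            if (any(piR < 1e-8)) { ok <- FALSE; break }
            for (r in seq_len(R)) {
                g <- resp[, r]
                Cr[[r]] <- crossprod(sqrt(g) * (d - mu)) / sum(g)
            }
            num <- 0; den <- 0
            for (r in seq_len(R)) {
                ctx <- .cholContext(Cr[[r]])
                if (is.null(ctx)) { ok <- FALSE; break }
                Ci <- chol2inv(ctx$R)
                u <- colSums(Ci)
                num <- num + sum(resp[, r] * (d %*% u))
                den <- den + sum(resp[, r]) * sum(u)
            }
            if (!ok) break
            mu <- num / den
            if (it > 1 && abs(trace[it] - trace[it - 1]) <
                    tol * (abs(trace[it - 1]) + 1e-8)) break
        }
        if (ok && length(trace) > 0) {
            W <- lapply(Cr, function(Ct) .projectPSD(Ct - base))
            return(new("MixtureInit",
                R = as.integer(R), pi = piR, mu = mu, sigma2 = sigma2,
                W = W, assignment = as.integer(max.col(resp, ties.method = "first")),
                logLik = trace[length(trace)], trace = trace))
        }
    }
    stop("gmmEM: component collapse in every restart")
}

setMethod("show", "MixtureInit", function(object) {
    cat(sprintf("MixtureInit: R = %d, pi = %s, logLik = %.4f\n", object@R,
        paste(sprintf("%.3f", object@pi), collapse = ", "), object@logLik))
})
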