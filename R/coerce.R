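#' Coerce learned covariances onto the population graph
#'
#' Finds shared branch lengths \code{c} and per-component migration rates
#' \code{w_r} minimizing the weighted residual sum of squares
#' \eqn{\sum_r \pi_r \| W_r - W(c, w_r) \|_F^2} by Nelder-Mead from \code{C}
#' random starts (\code{c} log-uniform in \code{[1e-4, 1]}, rates uniform in
#' \code{[0, 1]}, seeded), followed by restarted polish runs from the best
#' solution. Branch lengths are unconstrained in sign; rates are optimized on
#' the logit scale.
#'
#' @param W list of component covariance matrices (M x M).
#' @param pi component weights (RSS weights).
#' @param graph a \linkS4class{PopulationGraph}.
#' @param C number of random restarts.
#' @param seed RNG seed.
#' @param maxEdges enumeration cap passed to the covariance machinery.
#' @return list with \code{c} (named branch lengths), \code{w} (R x I matrix
#'   of rates), \code{rss} and the number of restarts that improved.
#' @export
coerceToGraph <- function(W, pi, graph, C = 1000L, seed = 1L, maxEdges = 12L) {
    if (is.matrix(W)) W <- list(W)
    R <- length(W)
    stopifnot(length(pi) == R, abs(sum(pi) - 1) < 1e-6)
    struct <- .configStructure(graph, maxEdges = maxEdges)
    K <- struct$K; I <- struct$I
    npar <- K + R * I
    ## branch lengths on the log scale: coercion seeds the likelihood fit and
    ## must stay inside the positive-length interior (the sign-unconstrained
    ## diagnostic lives in the Baum-Welch M-step, not here); rates on logit
    obj <- function(par) {
        cc <- exp(par[seq_len(K)])
        rss <- 0
        for (r in seq_len(R)) {
            w <- if (I > 0)
                plogis(par[K + (r - 1L) * I + seq_len(I)]) else numeric()
            Wg <- .covFromInclusion(.branchInclusion(struct, w), cc)
            rss <- rss + pi[r] * sum((W[[r]] - Wg)^2)
        }
        rss
    }
    set.seed(seed)
    best <- NULL; improved <- 0L
    for (s in seq_len(C)) {
        t0c <- runif(K, log(1e-4), log(1))
        t0 <- if (I > 0) qlogis(runif(R * I)) else numeric()
        par0 <- c(t0c, t0)
        res <- if (npar == 1L)
            optim(par0, obj, method = "Brent", lower = log(1e-8), upper = log(5))
        else
            optim(par0, obj, method = "Nelder-Mead",
                  control = list(maxit = 200L * npar, reltol = 1e-10))
        if (is.null(best) || res$value < best$value) {
            if (!is.null(best)) improved <- improved + 1L
            best <- res
        }
    }
    if (is.null(best)) {
        warning("coerceToGraph: no restart improved over initialization")
        return(list(c = setNames(rep(0.01, K), graph@branchChild),
                    w = matrix(0.5, R, I),
                    rss = obj(c(rep(log(0.01), K), rep(0, R * I))),
                    improved = 0L))
    }
    ## polish: Nelder-Mead restarted from its own optimum converges tightly
    if (npar > 1L) {
        for (k in 1:3) {
            res <- optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000L * npar, reltol = 1e-15))
            if (res$value < best$value) best <- res else break
        }
    }
    cc <- setNames(exp(best$par[seq_len(K)]), graph@branchChild)
    w <- if (I > 0)
        matrix(plogis(best$par[-seq_len(K)]), R, I, byrow = TRUE)
    else matrix(numeric(), R, 0)
    list(c = cc, w = w, rss = best$value, improved = improved)
}

#' Choose the number of mixture components
#'
#' Repeats \code{\link{gmmEM}} + \code{\link{coerceToGraph}} for
#' \code{R = 1, 2, ...}, accepting a larger R only while every component
#' weight exceeds \code{piThreshold} and the weighted RSS of the coercion
#' keeps decreasing; returns the last accepted configuration.
#'
#' @param d transformed frequencies (L x M).
#' @param Sigmabar mean sampling covariance.
#' @param graph a \linkS4class{PopulationGraph}.
#' @param config list of options (see \code{\link{mixScanConfig}}); uses
#'   \code{piThreshold}, \code{C}, \code{seed}, \code{maxComponents},
#'   \code{sigma2Init}.
#' @return list with \code{mixture} (a \linkS4class{MixtureInit}),
#'   \code{coercion} (see \code{\link{coerceToGraph}}) and \code{R}.
#' @export
selectNumComponents <- function(d, Sigmabar, graph, config = mixScanConfig()) {
    sigma2 <- config$sigma2Init
    if (is.null(sigma2)) sigma2 <- .sigma2Heuristic(initCovariance(d))
    accepted <- NULL
    for (R in seq_len(config$maxComponents)) {
        mix <- gmmEM(d, Sigmabar, R, seed = config$seed, sigma2 = sigma2)
        if (R > 1L && any(mix@pi <= config$piThreshold)) break
        co <- coerceToGraph(mix@W, mix@pi, graph, C = config$C,
                            seed = config$seed)
        if (!is.null(accepted) && co$rss >= accepted$coercion$rss) break
        accepted <- list(mixture = mix, coercion = co, R = R)
    }
    accepted
}
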