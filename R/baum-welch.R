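#' Fitting configuration
#'
#' Defaults: \code{C = 1000} coercion restarts, \code{T = 5} attractor
#' candidates, component-weight threshold 0.2, migration grid of
#' \code{J = 21} equally spaced rates, at most \code{u = 10} sampling-size
#' clusters, Baum-Welch relative tolerance \code{1e-6} with at most 500
#' iterations, SQUAREM acceleration on.
#'
#' @param C coercion random restarts.
#' @param T number of attractor candidates.
#' @param piThreshold minimum mixture weight for accepting more components.
#' @param J migration grid size per edge.
#' @param u maximum number of sampling-size clusters.
#' @param tol relative log-likelihood tolerance of Baum-Welch.
#' @param maxIter maximum Baum-Welch EM steps.
#' @param seed RNG seed (all randomness in the fit derives from it).
#' @param squarem use SQUAREM extrapolation.
#' @param maxComponents cap on the mixture size explored.
#' @param sigma2Init optional initial root-prior variance (default: a
#'   heuristic from the smallest off-diagonal observed covariance).
#' @return a named list of options.
#' @export
mixScanConfig <- function(C = 1000L, T = 5L, piThreshold = 0.2, J = 21L,
                          u = 10L, tol = 1e-6, maxIter = 500L, seed = 1L,
                          squarem = TRUE, maxComponents = 6L,
                          sigma2Init = NULL) {
    stopifnot(C >= 1, T >= 1, piThreshold > 0, piThreshold <= 1, J >= 1,
              u >= 1, tol > 0, maxIter >= 1)
    list(C = as.integer(C), T = as.integer(T), piThreshold = piThreshold,
         J = as.integer(J), u = as.integer(u), tol = tol,
         maxIter = as.integer(maxIter), seed = as.integer(seed),
         squarem = isTRUE(squarem), maxComponents = as.integer(maxComponents),
         sigma2Init = sigma2Init)
}

## Precomputed per-dataset/graph/state-space context shared by all EM steps.
.buildEngine <- function(counts, graph, space, config) {
    d <- transformedFrequencies(counts)
    L <- nrow(d)
    clusters <- clusterSampleSizes(totalCounts(counts), config$u)
    Sigmas <- samplingCovariances(clusters)
    delta <- interLocusDistances(counts)
    segStart <- is.na(delta)
    scale <- mean(delta, na.rm = TRUE)
    if (!is.finite(scale) || scale <= 0) scale <- 1
    rdelta <- delta / scale
    uval <- sort(unique(rdelta[!segStart]))
    group <- rep(1L, L)
    group[!segStart] <- match(rdelta[!segStart], uval)
    if (length(uval) == 0L) uval <- 1
    struct <- .configStructure(graph)
    stateP <- lapply(seq_len(numStates(space)), function(s)
        .branchInclusion(struct, space@stateRates[s, ]))
    I <- numMigrationEdges(graph)
    edgeAgg <- lapply(seq_len(I), function(i) {
        J <- length(space@grid@rates[[i]])
        A <- matrix(0, numStates(space), J)
        A[cbind(seq_len(numStates(space)), space@stateIndex[, i])] <- 1
        A
    })
    list(flags = new.env(parent = emptyenv()),
         d = d, L = L, M = ncol(d), clusters = clusters, Sigmas = Sigmas,
         clusterIdx = clusters@assignment, U = length(Sigmas),
         segStart = segStart, group = group, deltas = uval,
         distanceScale = scale, struct = struct, stateP = stateP,
         space = space, edgeAgg = edgeAgg, I = I,
         branchNames = graph@branchChild)
}

## Per-edge transition kernels for every distance group, their joint
## (product-space) kernels and the stationary initial law.
.transitionKernels <- function(theta, engine) {
    I <- engine$I
    S <- numStates(engine$space)
    if (I == 0L) {
        return(list(P = list(matrix(1, 1, 1)), init = 1))
    }
    perEdge <- vector("list", I)
    stat <- vector("list", I)
    for (i in seq_len(I)) {
        J <- length(engine$space@grid@rates[[i]])
        if (J == 1L) {   # degenerate single-rate grid: no transitions to model
            perEdge[[i]] <- rep(list(matrix(1, 1, 1)), length(engine$deltas))
            stat[[i]] <- 1
            next
        }
        Lam <- if (theta$variant[i] == "ladder") rateMatrix(J, "ladder")
            else rateMatrix(J, "attractor", phi = theta$phi[i],
                            zeta = theta$zeta[i], a = theta$a[i])
        cache <- .rateEigen(Lam)
        perEdge[[i]] <- lapply(engine$deltas, function(dg)
            transitionMatrix(Lam, theta$kappa[i], dg, cache = cache))
        stat[[i]] <- stationaryDistribution(Lam,
            a = if (theta$variant[i] == "ladder") NULL else theta$a[i])
    }
    P <- lapply(seq_along(engine$deltas), function(g)
        jointTransitionMatrix(lapply(perEdge, `[[`, g)))
    init <- rep(1, S)
    for (i in seq_len(I))
        init <- init * stat[[i]][engine$space@stateIndex[, i]]
    list(P = P, init = init / sum(init), stat = stat)
}

.logEmissions <- function(theta, engine) {
    stateW <- lapply(engine$stateP, .covFromInclusion, theta$c)
    tab <- .emissionTable(stateW, engine$Sigmas, theta$sigma2)
    .emissionMatrix(engine$d, theta$mu, tab, engine$clusterIdx)
}

.chainLogLik <- function(theta, engine) {
    kern <- .transitionKernels(theta, engine)
    logE <- .logEmissions(theta, engine)
    .fbCpp(logE, kern$P, engine$group, kern$init, engine$segStart)$loglik
}

## One EM step: E via forward-backward, M via the per-block optimizers.
## Returns the updated parameters, the log-likelihood AT the input
## parameters, and the E-step posteriors.
.emStep <- function(theta, engine) {
    kern <- .transitionKernels(theta, engine)
    logE <- .logEmissions(theta, engine)
    fb <- .fbCpp(logE, kern$P, engine$group, kern$init, engine$segStart)
    stats <- .emissionStats(fb$gamma, engine$d, engine$clusterIdx, engine$U)
    new <- theta
    new$mu <- .mStepMu(new$c, new$sigma2, stats, engine$stateP, engine$Sigmas)
    new$sigma2 <- .mStepSigma2(new$c, new$mu, new$sigma2, stats,
                               engine$stateP, engine$Sigmas)
    new$c <- .mStepBranchLengths(new$c, new$mu, new$sigma2, stats,
                                 engine$stateP, engine$Sigmas)
    if (engine$I > 0L) {
        startRows <- which(engine$segStart)
        for (i in seq_len(engine$I)) {
            A <- engine$edgeAgg[[i]]
            if (ncol(A) == 1L) next   # single-rate grid: nothing to fit
            xiE <- lapply(fb$xi, function(X) crossprod(A, X %*% A))
            sm <- colSums(matrix(fb$gamma[startRows, , drop = FALSE] %*% A,
                                 ncol = ncol(A)))
            up <- .mStepTransition(xiE, engine$deltas, sm, ncol(A),
                                   variant = theta$variant[i],
                                   kappa = theta$kappa[i],
                                   phi = theta$phi[i], zeta = theta$zeta[i],
                                   a = theta$a[i], flags = engine$flags)
            new$kappa[i] <- up$kappa
            if (theta$variant[i] == "attractor") {
                new$phi[i] <- up$phi
                new$zeta[i] <- up$zeta
            }
        }
    }
    list(theta = new, loglik = fb$loglik, gamma = fb$gamma)
}

.packTheta <- function(theta) {
    v <- c(theta$c, theta$mu, log(theta$sigma2), log(theta$kappa))
    att <- theta$variant == "attractor"
    if (any(att))
        v <- c(v, qlogis(pmin(theta$phi[att], 1 - 1e-10)),
               qlogis(pmin(theta$zeta[att], 1 - 1e-10)))
    v
}

.unpackTheta <- function(v, proto) {
    K <- length(proto$c)
    theta <- proto
    theta$c[] <- v[seq_len(K)]
    theta$mu <- v[K + 1]
    theta$sigma2 <- exp(v[K + 2])
    I <- length(proto$kappa)
    theta$kappa <- exp(v[K + 2 + seq_len(I)])
    att <- proto$variant == "attractor"
    if (any(att)) {
        na <- sum(att)
        theta$phi[att] <- plogis(v[K + 2 + I + seq_len(na)])
        theta$zeta[att] <- plogis(v[K + 2 + I + na + seq_len(na)])
    }
    theta
}

#' Baum-Welch fit of the migration-rate HMM
#'
#' Iterates E (forward-backward with a precomputed emission table) and M
#' steps (analytic root mean, Newton updates for the root variance and branch
#' lengths, line-search / Nelder-Mead for transition parameters), optionally
#' accelerated by SQUAREM squared extrapolation; an extrapolated step that
#' lowers the likelihood is rejected in favour of the plain EM step. Stops on
#' a relative log-likelihood change below \code{config$tol} or after
#' \code{config$maxIter} EM steps. A likelihood decrease on a plain EM step
#' beyond tolerance aborts with a diagnostic.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param graph a \linkS4class{PopulationGraph} (its branch lengths are the
#'   starting values unless \code{init} overrides them).
#' @param space a \linkS4class{HiddenStateSpace} over the graph's migration
#'   edges.
#' @param variant \code{"ladder"} or \code{"attractor"}, recycled per edge.
#' @param a attractor grid index per edge (attractor variant).
#' @param init list with starting values \code{c}, \code{mu}, \code{sigma2},
#'   \code{kappa}, \code{phi}, \code{zeta} (missing entries get defaults).
#' @param config see \code{\link{mixScanConfig}}.
#' @param engine internal precomputed context (reused by the orchestrator).
#' @return list with the fitted \code{theta}, \code{logLik}, the accepted
#'   log-likelihood \code{trace}, \code{niter}, \code{converged}, and the
#'   final posteriors \code{gamma}.
#' @export
baumWelch <- function(counts, graph, space, variant = "ladder", a = NULL,
                      init = list(), config = mixScanConfig(),
                      engine = NULL) {
    if (is.null(engine)) engine <- .buildEngine(counts, graph, space, config)
    I <- engine$I
    theta <- list(
        c = if (!is.null(init$c)) setNames(as.numeric(init$c), engine$branchNames)
            else setNames(rep(0.01, length(engine$branchNames)), engine$branchNames),
        mu = if (!is.null(init$mu)) init$mu else mean(engine$d),
        sigma2 = if (!is.null(init$sigma2)) init$sigma2 else 0.1,
        kappa = rep_len(if (!is.null(init$kappa)) init$kappa else 1, I),
        phi = rep_len(if (!is.null(init$phi)) init$phi else 0.5, I),
        zeta = rep_len(if (!is.null(init$zeta)) init$zeta else 0.5, I),
        variant = rep_len(variant, I),
        a = rep_len(if (is.null(a)) NA_integer_ else as.integer(a), I))
    if (any(theta$variant == "attractor") && anyNA(theta$a))
        stop("attractor variant needs attractor indices")
    trace <- numeric(0)
    nEM <- 0L
    converged <- FALSE
    lastGamma <- NULL
    tolAbs <- function(ll) config$tol * (abs(ll) + 1)
    while (nEM < config$maxIter) {
        s1 <- .emStep(theta, engine); nEM <- nEM + 1L
        trace <- c(trace, s1$loglik)
        lastGamma <- s1$gamma
        if (nEM >= config$maxIter) { theta <- s1$theta; break }
        s2 <- .emStep(s1$theta, engine); nEM <- nEM + 1L
        if (s2$loglik < s1$loglik - 1e-6 * (abs(s1$loglik) + 1) - 1e-8)
            stop("baumWelch: likelihood decreased on a plain EM step (",
                 s1$loglik, " -> ", s2$loglik, "); M-step defect")
        trace <- c(trace, s2$loglik)
        lastGamma <- s2$gamma
        if (abs(s2$loglik - s1$loglik) < tolAbs(s1$loglik)) {
            theta <- s2$theta; converged <- TRUE; break
        }
        accepted <- FALSE
        if (config$squarem) {
            ## SQUAREM squared extrapolation through the last two EM steps;
            ## rejected (in favour of the plain EM result) if it lowers the
            ## likelihood.
            t0 <- .packTheta(theta)
            t1 <- .packTheta(s1$theta)
            t2 <- .packTheta(s2$theta)
            r <- t1 - t0
            v <- (t2 - t1) - r
            nv <- sqrt(sum(v^2))
            if (nv > 1e-12) {
                alpha <- min(-sqrt(sum(r^2)) / nv, -1)
                thSq <- .unpackTheta(t0 - 2 * alpha * r + alpha^2 * v, s2$theta)
                llSq <- tryCatch(suppressWarnings(.chainLogLik(thSq, engine)),
                                 error = function(e) -Inf)
                ll2 <- .chainLogLik(s2$theta, engine)
                if (is.finite(llSq) && llSq >= ll2) {
                    theta <- thSq
                    accepted <- TRUE
                }
            }
        }
        if (!accepted) theta <- s2$theta
    }
    list(theta = theta, logLik = if (length(trace)) trace[length(trace)] else NA,
         trace = trace, niter = nEM, converged = converged, gamma = lastGamma,
         engine = engine)
}
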