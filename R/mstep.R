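## E-step sufficient statistics. For every hidden state j and sample-size
## cluster u the Q-function only needs
##   G[j,u]  = sum_{l in u} gamma_l(j)
##   T1[j,u] = sum gamma_l(j) d_l          (M-vector)
##   T2[j,u] = sum gamma_l(j) d_l d_l'     (M x M),
## so every emission-side M-step costs O(S * u * M^3) per evaluation
## regardless of L.
.emissionStats <- function(gamma, d, clusterIdx, nClusters) {
    S <- ncol(gamma); M <- ncol(d)
    G <- matrix(0, S, nClusters)
    T1 <- array(0, dim = c(S, nClusters, M))
    T2 <- array(0, dim = c(S, nClusters, M, M))
    for (u in seq_len(nClusters)) {
        idx <- which(clusterIdx == u)
        if (length(idx) == 0L) next
        g <- gamma[idx, , drop = FALSE]
        du <- d[idx, , drop = FALSE]
        G[, u] <- colSums(g)
        T1[, u, ] <- t(g) %*% du
        for (j in seq_len(S)) {
            gj <- g[, j]
            if (sum(gj) == 0) next
            T2[j, u, , ] <- crossprod(sqrt(gj) * du)
        }
    }
    list(G = G, T1 = T1, T2 = T2, M = M, S = S, U = nClusters)
}

## Centered scatter A_{ju}(mu) = T2 - mu (1 T1' + T1 1') + mu^2 G 11'
.centeredScatter <- function(stats, j, u, mu) {
    M <- stats$M
    t1 <- stats$T1[j, u, ]
    A <- stats$T2[j, u, , ] - mu * (outer(rep(1, M), t1) + outer(t1, rep(1, M))) +
        mu^2 * stats$G[j, u] * matrix(1, M, M)
    (A + t(A)) / 2
}

## Emission part of the Q-function for given branch lengths / root prior.
## stateP: list of per-state inclusion matrices p (M x K); Sigmas: per-cluster
## sampling covariances. Returns -Inf if any needed S_{ju} is not PD.
.emissionQ <- function(cc, mu, sigma2, stats, stateP, Sigmas) {
    Q <- 0
    M <- stats$M
    for (j in seq_len(stats$S)) {
        Wj <- .covFromInclusion(stateP[[j]], cc)
        for (u in seq_len(stats$U)) {
            g <- stats$G[j, u]
            if (g == 0) next
            S <- marginalCovariance(Wj, Sigmas[[u]], sigma2)
            ctx <- .cholContext(S)
            if (is.null(ctx)) return(-Inf)
            Si <- chol2inv(ctx$R)
            A <- .centeredScatter(stats, j, u, mu)
            Q <- Q - 0.5 * (g * (M * log(2 * pi) + ctx$logdet) + sum(Si * A))
        }
    }
    Q
}

#' Analytic root-prior mean update
#'
#' Generalized-least-squares maximizer of the Q-function:
#' \eqn{\mu = [\sum_{j,u} 1' S_{ju}^{-1} T1_{ju}] /
#'            [\sum_{j,u} G_{ju} 1' S_{ju}^{-1} 1]}.
#' @keywords internal
.mStepMu <- function(cc, sigma2, stats, stateP, Sigmas) {
    num <- 0; den <- 0
    for (j in seq_len(stats$S)) {
        Wj <- .covFromInclusion(stateP[[j]], cc)
        for (u in seq_len(stats$U)) {
            g <- stats$G[j, u]
            if (g == 0) next
            S <- marginalCovariance(Wj, Sigmas[[u]], sigma2)
            ctx <- .cholContext(S)
            if (is.null(ctx)) next
            Si <- chol2inv(ctx$R)
            u1 <- colSums(Si)
            num <- num + sum(u1 * stats$T1[j, u, ])
            den <- den + g * sum(u1)
        }
    }
    if (den == 0) stop("mu update: no usable states")
    num / den
}

## dQ/dsigma2 and d2Q/dsigma2^2 (S depends on sigma2 through sigma2*11')
.sigma2Derivs <- function(cc, mu, sigma2, stats, stateP, Sigmas) {
    d1 <- 0; d2 <- 0
    for (j in seq_len(stats$S)) {
        Wj <- .covFromInclusion(stateP[[j]], cc)
        for (u in seq_len(stats$U)) {
            g <- stats$G[j, u]
            if (g == 0) next
            S <- marginalCovariance(Wj, Sigmas[[u]], sigma2)
            ctx <- .cholContext(S)
            if (is.null(ctx)) return(NULL)
            Si <- chol2inv(ctx$R)
            A <- .centeredScatter(stats, j, u, mu)
            u1 <- colSums(Si)                 # Si %*% 1
            uu <- sum(u1)                     # 1' Si 1
            v <- sum(u1 * (A %*% u1))         # 1' Si A Si 1
            d1 <- d1 - 0.5 * (g * uu - v)
            d2 <- d2 - 0.5 * (-g * uu^2 + 2 * uu * v)
        }
    }
    c(d1, d2)
}

#' Root-prior variance update by safeguarded Newton-Raphson
#'
#' Newton on \eqn{\sigma^2} with step halving toward a non-decreasing
#' Q-function and positivity enforced by bisecting toward the current value;
#' falls back to a bracketed golden-section search (on the log scale) if
#' Newton fails to improve.
#' @keywords internal
.mStepSigma2 <- function(cc, mu, sigma2, stats, stateP, Sigmas,
                         maxIter = 25L, tol = 1e-9) {
    qfun <- function(s2) .emissionQ(cc, mu, s2, stats, stateP, Sigmas)
    cur <- sigma2
    qcur <- qfun(cur)
    for (it in seq_len(maxIter)) {
        dv <- .sigma2Derivs(cc, mu, cur, stats, stateP, Sigmas)
        if (is.null(dv)) break
        if (abs(dv[1]) < tol * (abs(qcur) + 1)) break
        step <- if (dv[2] < 0) -dv[1] / dv[2] else sign(dv[1]) * 0.5 * cur
        new <- cur + step
        half <- 0L
        while ((new <= 1e-10 || (qnew <- qfun(new)) < qcur) && half < 30L) {
            step <- step / 2; new <- cur + step; half <- half + 1L
        }
        if (half >= 30L) break
        if (qnew <= qcur + tol * (abs(qcur) + 1)) { cur <- new; break }
        cur <- new; qcur <- qnew
    }
    ## safeguard: bracketed search must not do worse than the Newton result
    ## (suppressWarnings: -Inf is the intended penalty for non-PD proposals)
    opt <- suppressWarnings(optimize(function(t) qfun(exp(t)),
                                     interval = log(c(1e-8, 10)),
                                     maximum = TRUE, tol = 1e-10))
    if (opt$objective > qcur + 1e-12) exp(opt$maximum) else cur
}

## Analytic gradient and Hessian of the emission Q in the branch lengths.
## W is linear in c with dW_j/dc_k = p_jk p_jk', which gives, per state and
## cluster, with U = P'S^-1 P and V = P'S^-1 A S^-1 P:
##   dQ/dc_k      = -0.5 [ G U_kk - V_kk ]
##   d2Q/dc_k dc_l = -0.5 [ -G (U o U)_kl + 2 (U o V)_kl ]   (o: elementwise)
.branchGradHess <- function(cc, mu, sigma2, stats, stateP, Sigmas,
                            hessian = TRUE) {
    K <- ncol(stateP[[1]])
    gr <- numeric(K)
    H <- if (hessian) matrix(0, K, K) else NULL
    for (j in seq_len(stats$S)) {
        p <- stateP[[j]]
        Wj <- .covFromInclusion(p, cc)
        for (u in seq_len(stats$U)) {
            g <- stats$G[j, u]
            if (g == 0) next
            S <- marginalCovariance(Wj, Sigmas[[u]], sigma2)
            ctx <- .cholContext(S)
            if (is.null(ctx)) return(NULL)
            Si <- chol2inv(ctx$R)
            A <- .centeredScatter(stats, j, u, mu)
            Sp <- Si %*% p                    # M x K
            U <- crossprod(p, Sp)
            V <- crossprod(Sp, A %*% Sp)
            gr <- gr - 0.5 * (g * diag(U) - diag(V))
            if (hessian) H <- H - 0.5 * (-g * U * U + 2 * U * V)
        }
    }
    list(gradient = gr, hessian = H)
}

.branchGradient <- function(cc, mu, sigma2, stats, stateP, Sigmas) {
    gh <- .branchGradHess(cc, mu, sigma2, stats, stateP, Sigmas, hessian = FALSE)
    if (is.null(gh)) NULL else gh$gradient
}

#' Branch-length update by safeguarded Newton-Raphson
#'
#' Maximizes the Q-function over the branch lengths using the analytic
#' gradient and Hessian (W is linear in c, so both are exact matrix-calculus
#' expressions; a finite-difference cross-check is part of the test suite),
#' with step halving on any Q decrease and a gradient-ascent fallback when
#' the Hessian is not negative definite. Lengths are unconstrained in sign
#' (negative solutions are a diagnostic flagged by the caller); non-PD
#' proposals are rejected by the step-halving guard.
#' @keywords internal
.mStepBranchLengths <- function(cc, mu, sigma2, stats, stateP, Sigmas,
                                maxIter = 15L, tol = 1e-8) {
    qfun <- function(x) .emissionQ(x, mu, sigma2, stats, stateP, Sigmas)
    cur <- cc
    qcur <- qfun(cur)
    for (it in seq_len(maxIter)) {
        gh <- .branchGradHess(cur, mu, sigma2, stats, stateP, Sigmas)
        if (is.null(gh) || !all(is.finite(gh$gradient))) break
        gr <- gh$gradient
        if (max(abs(gr)) < tol * (abs(qcur) + 1)) break
        step <- NULL
        H <- gh$hessian
        if (all(is.finite(H))) {
            H <- (H + t(H)) / 2
            negdef <- tryCatch({ chol(-H); TRUE }, error = function(e) FALSE)
            if (negdef)
                step <- tryCatch(-solve(H, gr), error = function(e) NULL)
        }
        if (is.null(step)) step <- gr * (0.01 / max(abs(gr)))  # ascent fallback
        new <- cur + step
        half <- 0L
        while ((qnew <- qfun(new)) < qcur && half < 40L) {
            step <- step / 2; new <- cur + step; half <- half + 1L
        }
        if (half >= 40L) break
        if (qnew <= qcur + tol * (abs(qcur) + 1)) { cur <- new; qcur <- qnew; break }
        cur <- new; qcur <- qnew
    }
    cur
}

## Transition Q-term for one edge: sum over distance groups of
## sum(Xi * log P(delta_g)) plus the segment-start term under the stationary
## initial law (kept so the EM step is exactly monotone for attractor edges).
.transitionQ <- function(Lambda, kappa, deltas, xiList, startMarg, a = NULL,
                         cache = NULL) {
    if (is.null(cache)) cache <- .rateEigen(Lambda)
    Q <- 0
    for (g in seq_along(deltas)) {
        if (sum(xiList[[g]]) == 0) next
        P <- transitionMatrix(Lambda, kappa, deltas[g], cache = cache)
        Q <- Q + sum(xiList[[g]] * log(pmax(P, 1e-300)))
    }
    pstat <- stationaryDistribution(Lambda, a = a)
    Q + sum(startMarg * log(pmax(pstat, 1e-300)))
}

#' Transition-parameter update
#'
#' Ladder edges: bracketed line search for \eqn{\kappa} on the log scale
#' (bracket expanded up to a cap if the optimum sits on a boundary).
#' Attractor edges: Nelder-Mead over \eqn{(\log\kappa, logit\,\phi,
#' logit\,\zeta)}, keeping \eqn{\phi, \zeta} inside \eqn{(0, 1]}.
#'
#' @param xiList per-distance-group J x J pairwise transition expectations
#'   (already marginalized to this edge).
#' @param deltas rescaled distances, one per group.
#' @param startMarg summed posterior of this edge's grid states at
#'   chromosome-start loci (weights the stationary initial law).
#' @param J grid size; \code{variant}, \code{a} as in \code{\link{rateMatrix}}.
#' @param kappa,phi,zeta current values (used as the search start).
#' @return list with updated \code{kappa} (and \code{phi}, \code{zeta} for
#'   attractor edges) and the attained Q-term.
#' @keywords internal
.mStepTransition <- function(xiList, deltas, startMarg, J,
                             variant = c("ladder", "attractor"),
                             kappa = 1, phi = 0.5, zeta = 0.5, a = NULL,
                             flags = NULL) {
    variant <- match.arg(variant)
    if (variant == "ladder") {
        Lambda <- rateMatrix(J, "ladder")
        cache <- .rateEigen(Lambda)
        qk <- function(t) .transitionQ(Lambda, exp(t), deltas, xiList,
                                       startMarg, cache = cache)
        lo <- log(kappa) - 6; hi <- log(kappa) + 6
        for (expand in 1:4) {
            opt <- optimize(qk, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
            atEdge <- min(opt$maximum - lo, hi - opt$maximum) < 0.05
            if (!atEdge || (hi - lo) > 60) break
            lo <- lo - 6; hi <- hi + 6
        }
        if (atEdge && (is.null(flags) || !isTRUE(flags$kappaWarned))) {
            warning("kappa search hit the bracket boundary (weak or absent ",
                    "linkage signal)", call. = FALSE)
            if (!is.null(flags)) flags$kappaWarned <- TRUE
        }
        list(kappa = exp(opt$maximum), Q = opt$objective)
    } else {
        obj <- function(par) {
            Lam <- rateMatrix(J, "attractor", phi = plogis(par[2]),
                              zeta = plogis(par[3]), a = a)
            -.transitionQ(Lam, exp(par[1]), deltas, xiList, startMarg, a = a)
        }
        res <- suppressWarnings(
            optim(c(log(kappa), qlogis(min(phi, 1 - 1e-8)),
                    qlogis(min(zeta, 1 - 1e-8))), obj,
                  method = "Nelder-Mead",
                  control = list(maxit = 600L, reltol = 1e-12)))
        list(kappa = exp(res$par[1]), phi = plogis(res$par[2]),
             zeta = plogis(res$par[3]), Q = -res$value)
    }
}
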