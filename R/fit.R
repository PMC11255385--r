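#' Attractor search on top of a converged ladder fit
#'
#' Ranks the hidden states by their average posterior probability across loci,
#' takes the top \code{T} as candidate attractors and re-runs Baum-Welch with
#' the attractor transition kernel for each (re-optimizing all parameters,
#' initialized from the ladder fit). Returns whichever model — the ladder fit
#' or an attractor fit — attains the highest final likelihood.
#'
#' @param ladder result of \code{\link{baumWelch}} with the ladder variant.
#' @param counts,graph,space,config as in \code{\link{baumWelch}}.
#' @return list as from \code{\link{baumWelch}}, with an added
#'   \code{variantChosen} element (\code{"ladder"} or \code{"attractor"}) and
#'   \code{candidates} (the states tried).
#' @export
attractorSearch <- function(ladder, counts, graph, space,
                            config = mixScanConfig()) {
    meanPost <- colMeans(ladder$gamma)
    cand <- order(meanPost, decreasing = TRUE)[seq_len(min(config$T, length(meanPost)))]
    best <- ladder
    best$variantChosen <- "ladder"
    for (s in cand) {
        a <- space@stateIndex[s, ]
        fitA <- tryCatch(
            baumWelch(counts, graph, space, variant = "attractor", a = a,
                      init = list(c = ladder$theta$c, mu = ladder$theta$mu,
                                  sigma2 = ladder$theta$sigma2,
                                  kappa = ladder$theta$kappa),
                      config = config, engine = ladder$engine),
            error = function(e) NULL)
        if (!is.null(fitA) && is.finite(fitA$logLik) && fitA$logLik > best$logLik) {
            best <- fitA
            best$variantChosen <- "attractor"
        }
    }
    best$candidates <- cand
    best
}

#' Scan a genome for locus-specific mixture proportions
#'
#' The full empirical Bayes pipeline: observed covariance of the transformed
#' frequencies, Gaussian-mixture refinement with automatic component-count
#' selection, least-squares coercion of the learned covariances onto the
#' admixture graph (seeding branch lengths), SQUAREM-accelerated Baum-Welch
#' with the ladder transition kernel, an attractor search over the top states,
#' and a final forward-backward pass summarized per locus. Deterministic given
#' \code{config$seed}.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param graph a \linkS4class{PopulationGraph} (topology fixed; lengths are
#'   re-estimated).
#' @param config see \code{\link{mixScanConfig}}.
#' @param verbose print stage progress.
#' @return list with \code{fit} (a \linkS4class{MixScanFit}),
#'   \code{posterior} (a \linkS4class{PosteriorSummary}) and \code{init}
#'   (the mixture/coercion initialization).
#' @examples
#' \donttest{
#' g <- readPopulationGraph(text = c(
#'     "ROOT R", "BRANCH R P1 0.03", "BRANCH R P2 0.02",
#'     "LEAF P1 pop1", "LEAF P2 pop2"))
#' sim <- simulateDataset(g, track = simulateTrack(200, "constant", rate = 0),
#'     mu = -0.5, sigma2 = 0.3, N = 50, seed = 7)
#' res <- mixScan(sim$counts, g,
#'     config = mixScanConfig(C = 20, J = 2, maxIter = 20))
#' res$fit
#' }
#' @export
mixScan <- function(counts, graph, config = mixScanConfig(), verbose = FALSE) {
    say <- function(...) if (verbose) message(...)
    I <- numMigrationEdges(graph)
    d <- transformedFrequencies(counts)
    Sigmabar <- .meanSamplingCovariance(counts)
    say("selecting mixture components and coercing onto the graph")
    sel <- selectNumComponents(d, Sigmabar, graph, config)
    say(sprintf("  R = %d component(s), RSS = %.4g", sel$R, sel$coercion$rss))
    space <- HiddenStateSpace(MigrationGrid(nEdges = I, J = config$J))
    init <- list(c = sel$coercion$c, mu = sel$mixture@mu,
                 sigma2 = max(sel$mixture@sigma2, 1e-4))
    say("Baum-Welch (ladder kernel)")
    ladder <- baumWelch(counts, graph, space, variant = "ladder",
                        init = init, config = config)
    say(sprintf("  logLik = %.4f after %d EM step(s)", ladder$logLik,
                ladder$niter))
    if (I > 0L && config$J > 1L) {
        say("attractor search")
        best <- attractorSearch(ladder, counts, graph, space, config)
        say(sprintf("  chosen kernel: %s (logLik = %.4f)", best$variantChosen,
                    best$logLik))
    } else {
        best <- ladder
        best$variantChosen <- "ladder"
    }
    ## final E pass at the chosen parameters
    kern <- .transitionKernels(best$theta, best$engine)
    logE <- .logEmissions(best$theta, best$engine)
    fb <- .fbCpp(logE, kern$P, best$engine$group, kern$init,
                 best$engine$segStart)
    graphFit <- graph
    branchLengths(graphFit) <- best$theta$c
    tm <- new("TransitionModel",
        variant = best$theta$variant, kappa = best$theta$kappa,
        phi = ifelse(best$theta$variant == "attractor", best$theta$phi, NA_real_),
        zeta = ifelse(best$theta$variant == "attractor", best$theta$zeta, NA_real_),
        attractor = ifelse(best$theta$variant == "attractor",
                           as.integer(best$theta$a), NA_integer_))
    fit <- new("MixScanFit",
        graph = graphFit, mu = best$theta$mu, sigma2 = best$theta$sigma2,
        transition = tm, stateSpace = space,
        logLik = fb$loglik, trace = best$trace, niter = best$niter,
        converged = best$converged,
        negativeBranch = any(best$theta$c < -.negBranchTol),
        distanceScale = best$engine$distanceScale,
        config = config)
    attractor <- if (best$variantChosen == "attractor") best$theta$a
                 else rep(NA_integer_, I)
    post <- posteriorSummaries(fb$gamma, space, attractor = attractor,
                               stationary = kern$stat, logLik = fb$loglik)
    list(fit = fit, posterior = post, init = sel)
}

## Negative-branch diagnostic threshold (drift units): lengths below this are
## "meaningfully negative" rather than estimation noise grazing zero.
.negBranchTol <- 1e-3

.meanSamplingCovariance <- function(counts) {
    N <- totalCounts(counts)
    diag(colMeans(1 / N), ncol(N))
}

setMethod("show", "MixScanFit", function(object) {
    cat("MixScanFit\n")
    cat(sprintf("  logLik = %.4f (%d EM steps, %sconverged)\n", object@logLik,
        object@niter, if (object@converged) "" else "NOT "))
    cat(sprintf("  mu = %.4f, sigma2 = %.4f\n", object@mu, object@sigma2))
    v <- object@transition@variant
    if (length(v)) {
        for (i in seq_along(v)) {
            if (v[i] == "attractor")
                cat(sprintf("  edge %d: attractor kernel, a = %d, kappa = %.3g, phi = %.3f, zeta = %.3f\n",
                    i, object@transition@attractor[i], object@transition@kappa[i],
                    object@transition@phi[i], object@transition@zeta[i]))
            else
                cat(sprintf("  edge %d: ladder kernel, kappa = %.3g\n", i,
                    object@transition@kappa[i]))
        }
    }
    if (object@negativeBranch)
        cat("  NOTE: negative branch length(s) inferred; the graph may have\n",
            "  too many degrees of freedom for these data\n")
})
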