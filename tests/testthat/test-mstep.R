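# Shared scaffolding: a tiny single-state "HMM" so emission M-steps can be
# exercised directly on sufficient statistics.
singleStateStats <- function(d) {
    gamma <- matrix(1, nrow(d), 1)
    mixscan:::.emissionStats(gamma, d, rep(1L, nrow(d)), 1L)
}

test_that("the analytic mu update is the GLS maximizer", {
    set.seed(201)
    d <- matrix(rnorm(120 * 3, mean = 0.4), ncol = 3)
    stats <- singleStateStats(d)
    # identity covariance: the update is the grand mean
    stateP <- list(matrix(0, 3, 1))    # no drift contribution
    Sigmas <- list(diag(3))
    mu <- mixscan:::.mStepMu(cc = 0, sigma2 = 0, stats = stats,
                             stateP = stateP, Sigmas = Sigmas)
    expect_equal(mu, mean(d), tolerance = 1e-12)
    # general covariance: the maximizer beats nearby perturbations
    Sigmas <- list(diag(c(0.5, 1, 2)))
    mu2 <- mixscan:::.mStepMu(cc = 0.05, sigma2 = 0.2, stats = stats,
                              stateP = list(matrix(1, 3, 1)), Sigmas = Sigmas)
    qf <- function(m) mixscan:::.emissionQ(0.05, m, 0.2, stats,
                                           list(matrix(1, 3, 1)), Sigmas)
    expect_gte(qf(mu2), qf(mu2 + 1e-4))
    expect_gte(qf(mu2), qf(mu2 - 1e-4))
})

test_that("the root-variance update recovers a known sigma2", {
    g <- fourPopTipGraph()
    sim <- simulateDataset(g, track = simulateTrack(8000, "constant", rate = 0.3),
                           mu = -0.5, sigma2 = 0.3, N = 100, seed = 202)
    d <- transformedFrequencies(sim$counts)
    stats <- singleStateStats(d)
    struct <- mixscan:::.configStructure(g)
    stateP <- list(mixscan:::.branchInclusion(struct, 0.3))
    Sigmas <- list(diag(1 / 100, 4))
    s2 <- mixscan:::.mStepSigma2(branchLengths(g), -0.5, 0.1, stats,
                                 stateP, Sigmas)
    expect_lt(abs(s2 - 0.3), 0.05)
    # and the returned value maximizes Q along sigma2
    qf <- function(x) mixscan:::.emissionQ(branchLengths(g), -0.5, x, stats,
                                           stateP, Sigmas)
    expect_gte(qf(s2), qf(s2 * 1.05))
    expect_gte(qf(s2), qf(s2 * 0.95))
})

test_that("analytic and finite-difference branch gradients agree", {
    set.seed(203)
    g <- fourPopTipGraph()
    sim <- simulateToy(g, L = 150, seed = 203)
    d <- transformedFrequencies(sim$counts)
    space <- HiddenStateSpace(MigrationGrid(nEdges = 1, J = 4))
    struct <- mixscan:::.configStructure(g)
    stateP <- lapply(seq_len(4), function(s)
        mixscan:::.branchInclusion(struct, space@stateRates[s, ]))
    gamma <- matrix(rgamma(150 * 4, 1), 150, 4); gamma <- gamma / rowSums(gamma)
    stats <- mixscan:::.emissionStats(gamma, d, rep(1L, 150), 1L)
    Sigmas <- list(diag(1 / 100, 4))
    cc <- unname(branchLengths(g))
    gh <- mixscan:::.branchGradHess(cc, -0.5, 0.3, stats, stateP, Sigmas)
    gFD <- fdGradient(function(x)
        mixscan:::.emissionQ(x, -0.5, 0.3, stats, stateP, Sigmas), cc, h = 1e-7)
    expect_equal(gh$gradient, gFD, tolerance = 1e-6)
    # analytic Hessian vs finite differences of the analytic gradient
    K <- length(cc)
    HFD <- matrix(0, K, K)
    for (k in seq_len(K)) {
        h <- 1e-6
        cp <- cc; cp[k] <- cp[k] + h
        cm <- cc; cm[k] <- cm[k] - h
        HFD[, k] <- (mixscan:::.branchGradient(cp, -0.5, 0.3, stats, stateP, Sigmas) -
                     mixscan:::.branchGradient(cm, -0.5, 0.3, stats, stateP, Sigmas)) / (2 * h)
    }
    expect_equal(gh$hessian, (HFD + t(HFD)) / 2, tolerance = 1e-4)
})

test_that("branch updates ascend Q and match the scalar closed form", {
    # single population, single branch: S = c + Sigma + sigma2 is scalar and
    # the optimum matches the variance of the data exactly
    set.seed(204)
    d <- matrix(rnorm(4000, mean = 0.2, sd = sqrt(0.05 + 0.01 + 0.2)), ncol = 1)
    stats <- singleStateStats(d)
    stateP <- list(matrix(1, 1, 1))
    Sigmas <- list(diag(0.01, 1))
    cHat <- mixscan:::.mStepBranchLengths(0.02, 0.2, 0.2, stats, stateP, Sigmas)
    vHat <- mean((d - 0.2)^2)
    expect_equal(unname(cHat), vHat - 0.01 - 0.2, tolerance = 1e-6)

    # multivariate instance: the update never decreases Q
    g <- fourPopTipGraph()
    sim <- simulateToy(g, L = 200, seed = 204)
    d4 <- transformedFrequencies(sim$counts)
    stats4 <- singleStateStats(d4)
    struct <- mixscan:::.configStructure(g)
    stateP4 <- list(mixscan:::.branchInclusion(struct, 0.3))
    Sigmas4 <- list(diag(1 / 100, 4))
    c0 <- unname(branchLengths(g)) * 2
    c1 <- mixscan:::.mStepBranchLengths(c0, -0.5, 0.3, stats4, stateP4, Sigmas4)
    q0 <- mixscan:::.emissionQ(c0, -0.5, 0.3, stats4, stateP4, Sigmas4)
    q1 <- mixscan:::.emissionQ(c1, -0.5, 0.3, stats4, stateP4, Sigmas4)
    expect_gte(q1, q0)
})

test_that("the transition update recovers a known kappa from chain expectations", {
    set.seed(205)
    J <- 5; kappaTrue <- 2; delta <- 1
    tr <- simulateTrack(30000, "markov", grid = MigrationGrid(J = J),
                        kappa = kappaTrue, delta = delta, seed = 205)
    st <- match(trackRates(tr)[, 1], seq(0, 1, length.out = J))
    xi <- matrix(0, J, J)
    for (l in 2:length(st)) xi[st[l - 1], st[l]] <- xi[st[l - 1], st[l]] + 1
    startMarg <- tabulate(st[1], J)
    up <- mixscan:::.mStepTransition(list(xi), delta, startMarg, J,
                                     variant = "ladder", kappa = 1)
    expect_lt(abs(up$kappa - kappaTrue) / kappaTrue, 0.10)

    # optimizer contract: the returned Q beats random probes
    Lam <- rateMatrix(J, "ladder")
    for (k in exp(runif(10, -2, 2))) {
        expect_gte(up$Q + 1e-9,
                   mixscan:::.transitionQ(Lam, k, delta, list(xi), startMarg))
    }
})

test_that("attractor transition updates respect the (0,1] box", {
    set.seed(206)
    J <- 5
    Lam <- rateMatrix(J, "attractor", phi = 0.3, zeta = 0.6, a = 2)
    P <- transitionMatrix(Lam, 1.5, 1)
    pstat <- stationaryDistribution(Lam, 2)
    xi <- 5000 * (pstat * P)          # expected transition counts at stationarity
    up <- mixscan:::.mStepTransition(list(xi), 1, pstat * 10, J,
                                     variant = "attractor", kappa = 1,
                                     phi = 0.5, zeta = 0.5, a = 2)
    expect_true(up$phi > 0 && up$phi <= 1)
    expect_true(up$zeta > 0 && up$zeta <= 1)
    expect_lt(abs(up$kappa - 1.5) / 1.5, 0.2)
    # the attractor kernel at phi = zeta = 1 differs from the ladder kernel
    expect_false(isTRUE(all.equal(
        rateMatrix(J, "attractor", phi = 1, zeta = 1, a = 2),
        rateMatrix(J, "ladder"))))
})
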