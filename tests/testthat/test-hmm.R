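test_that("rate matrices follow the ladder and attractor patterns", {
    expect_equal(rateMatrix(3, "ladder"),
                 rbind(c(-1, 1, 0), c(1, -2, 1), c(0, 1, -1)))
    La <- rateMatrix(5, "attractor", phi = 0.5, zeta = 0.2, a = 3)
    expect_equal(La, rbind(
        c(-1.0, 1.0, 0.0, 0.0, 0.0),
        c(0.8, -2.0, 1.2, 0.0, 0.0),
        c(0.0, 0.5, -1.0, 0.5, 0.0),
        c(0.0, 0.0, 1.2, -2.0, 0.8),
        c(0.0, 0.0, 0.0, 1.0, -1.0)))
    # generator laws on random instances, including boundary attractors
    set.seed(2)
    for (rep in 1:10) {
        J <- sample(2:8, 1)
        L <- rateMatrix(J, "attractor", phi = runif(1, 0.05, 1),
                        zeta = runif(1, 0.05, 1), a = sample(J, 1))
        expect_equal(rowSums(L), rep(0, J))
        expect_true(all(L[row(L) != col(L)] >= 0))
    }
    expect_error(rateMatrix(5, "attractor", phi = 0.5, zeta = 0.2, a = 9),
                 "bad attractor index")
    expect_error(rateMatrix(5, "attractor", phi = 1.4, zeta = 0.2, a = 2),
                 "phi and zeta")
})

test_that("stationary laws: uniform for the ladder, unimodal at the attractor", {
    expect_equal(stationaryDistribution(rateMatrix(7, "ladder")), rep(1 / 7, 7))
    for (phi in seq(0.1, 1, by = 0.1)) {
        for (zeta in seq(0.1, 1, by = 0.1)) {
            for (a in c(1, 3, 5)) {
                p <- stationaryDistribution(
                    rateMatrix(5, "attractor", phi = phi, zeta = zeta, a = a), a)
                expect_equal(sum(p), 1)
                expect_identical(which.max(p), as.integer(a))
                expect_true(all(p[a] > p[-a]))
            }
        }
    }
})

test_that("transition matrices are stochastic and satisfy Chapman-Kolmogorov", {
    L2 <- rateMatrix(2, "ladder")
    expect_equal(transitionMatrix(L2, 1, 1e-12), diag(2), tolerance = 1e-9)
    expect_equal(transitionMatrix(L2, 1, 0.5)[1, 2], (1 - exp(-1)) / 2,
                 tolerance = 1e-12)
    set.seed(3)
    for (rep in 1:12) {
        J <- sample(2:9, 1)
        variant <- sample(c("ladder", "attractor"), 1)
        Lam <- if (variant == "ladder") rateMatrix(J, "ladder")
            else rateMatrix(J, "attractor", phi = runif(1, 0.1, 1),
                            zeta = runif(1, 0.1, 1), a = sample(J, 1))
        kappa <- exp(runif(1, -2, 2))
        d1 <- exp(runif(1, -2, 1)); d2 <- exp(runif(1, -2, 1))
        P1 <- transitionMatrix(Lam, kappa, d1)
        P2 <- transitionMatrix(Lam, kappa, d2)
        P12 <- transitionMatrix(Lam, kappa, d1 + d2)
        expect_equal(rowSums(P1), rep(1, J), tolerance = 1e-12)
        expect_true(all(P1 >= 0))
        expect_equal(P1 %*% P2, P12, tolerance = 1e-10)
    }
    # reducible generator (zeta = 1) goes through the expm fallback unharmed
    Lam1 <- rateMatrix(5, "attractor", phi = 0.5, zeta = 1, a = 3)
    P <- transitionMatrix(Lam1, 1, 0.7)
    expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-10)
    expect_equal(transitionMatrix(Lam1, 1, 0.3) %*% transitionMatrix(Lam1, 1, 0.4),
                 P, tolerance = 1e-10)
})

test_that("joint transitions factorize over edges", {
    PA <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
    J <- jointTransitionMatrix(list(PA, PA))
    # state order: edge 1 fastest; ((1,1) -> (1,2)) keeps edge 1 and moves edge 2
    expect_equal(J[1, 3], 0.9 * 0.1)
    expect_equal(jointTransitionMatrix(list(PA)), PA)
    set.seed(4)
    P1 <- transitionMatrix(rateMatrix(3, "ladder"), 1, 0.4)
    P2 <- transitionMatrix(rateMatrix(4, "ladder"), 2, 0.2)
    Pj <- jointTransitionMatrix(list(P1, P2))
    v <- runif(12)
    expect_equal(applyJointTransition(list(P1, P2), v),
                 as.vector(Pj %*% v), tolerance = 1e-12)
    expect_equal(applyJointTransition(list(P1, P2), v, transpose = TRUE),
                 as.vector(t(Pj) %*% v), tolerance = 1e-12)
    expect_equal(rowSums(Pj), rep(1, 12), tolerance = 1e-12)
    expect_error(applyJointTransition(list(P1, P2), runif(5)), "dimension")
})

test_that("the marginal chain of one edge under the product transition is its own chain", {
    P1 <- transitionMatrix(rateMatrix(3, "ladder"), 1, 0.4)
    P2 <- transitionMatrix(rateMatrix(2, "ladder"), 2, 0.7)
    Pj <- jointTransitionMatrix(list(P1, P2))
    space <- HiddenStateSpace(MigrationGrid(list(c(0, 0.5, 1), c(0, 1))))
    init2 <- c(0.3, 0.7)
    init <- rep(1 / 3, 3)[space@stateIndex[, 1]] * init2[space@stateIndex[, 2]]
    after <- as.vector(t(Pj) %*% init)
    marg2 <- vapply(1:2, function(j) sum(after[space@stateIndex[, 2] == j]),
                    numeric(1))
    expect_equal(marg2, as.vector(t(P2) %*% init2), tolerance = 1e-12)
})

test_that("forward-backward reproduces hand-enumerated and brute-force results", {
    # no data: posteriors stay at the initial (stationary) law
    logE <- matrix(0, 6, 3)
    P <- transitionMatrix(rateMatrix(3, "ladder"), 1, 0.5)
    fb <- forwardBackward(logE, P, init = rep(1 / 3, 3))
    expect_equal(fb$gamma, matrix(1 / 3, 6, 3), tolerance = 1e-12)

    # two-state worked instance (all four paths enumerated by hand)
    logE2 <- log(rbind(c(1, 0.5), c(1, 0.5)))
    P2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
    fb2 <- forwardBackward(logE2, P2, init = c(0.5, 0.5))
    expect_equal(exp(fb2$loglik), 0.6125, tolerance = 1e-12)
    expect_equal(fb2$gamma[1, 1], 0.475 / 0.6125, tolerance = 1e-12)

    # random instances vs exhaustive path enumeration, with chromosome breaks
    set.seed(6)
    for (rep in 1:20) {
        S <- sample(2:4, 1); L <- sample(2:5, 1)
        logE <- matrix(log(runif(L * S)), L, S)
        P <- transitionMatrix(rateMatrix(S, "ladder"), exp(runif(1, -1, 1)),
                              exp(runif(1, -1, 0)))
        init <- runif(S); init <- init / sum(init)
        segStart <- c(TRUE, runif(L - 1) < 0.2)
        fb <- forwardBackward(logE, P, init, segStart = segStart)
        oracle <- pathEnumOracle(logE, P, init, segStart = segStart)
        expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
        expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10)
    }
})

test_that("forward-backward likelihood shifts by the exact constant under emission rescaling", {
    set.seed(8)
    logE <- matrix(log(runif(12)), 4, 3)
    P <- transitionMatrix(rateMatrix(3, "ladder"), 1, 0.5)
    init <- rep(1 / 3, 3)
    shift <- rnorm(4)
    fb0 <- forwardBackward(logE, P, init)
    fb1 <- forwardBackward(logE + shift, P, init)
    expect_equal(fb1$loglik, fb0$loglik + sum(shift), tolerance = 1e-10)
    expect_equal(fb1$gamma, fb0$gamma, tolerance = 1e-12)
})

test_that("an all-impossible locus is reported as such", {
    logE <- matrix(0, 3, 2)
    logE[2, ] <- -Inf
    P <- matrix(0.5, 2, 2)
    expect_error(forwardBackward(logE, P, c(0.5, 0.5)), "impossible datum at locus 2")
})

test_that("posterior summaries collapse states to per-edge quantities", {
    space1 <- HiddenStateSpace(MigrationGrid(list(c(0, 0.5, 1))))
    gamma <- rbind(c(0.2, 0.5, 0.3), c(0, 0, 1))
    ps <- posteriorSummaries(gamma, space1, attractor = 1L)
    expect_equal(meanMigrationRate(ps)[, 1], c(0.55, 1.0))
    expect_equal(excessFDR(ps)[2, 1], 0)   # all mass above the attractor
    expect_equal(dearthFDR(ps)[2, 1], 1)
    expect_equal(ps@mapState, c(2L, 3L))
    # identity q_e + q_d - 1 = posterior mass at the attractor
    set.seed(9)
    g <- matrix(rgamma(5 * 3, 1), 5, 3); g <- g / rowSums(g)
    for (a in 1:3) {
        psa <- posteriorSummaries(g, space1, attractor = a)
        expect_equal(excessFDR(psa)[, 1] + dearthFDR(psa)[, 1] - 1, g[, a],
                     tolerance = 1e-12)
    }
    # two edges: marginalization over the product space
    space2 <- HiddenStateSpace(MigrationGrid(list(c(0, 1), c(0, 0.5, 1))))
    g2 <- matrix(rgamma(4 * 6, 1), 4, 6); g2 <- g2 / rowSums(g2)
    ps2 <- posteriorSummaries(g2, space2, attractor = c(1L, 2L))
    margE1 <- g2 %*% outer(space2@stateIndex[, 1], 1:2, "==")
    expect_equal(meanMigrationRate(ps2)[, 1], as.vector(margE1 %*% c(0, 1)))
    # surrogate attractor for ladder fits is flagged
    pss <- posteriorSummaries(gamma, space1, attractor = NA)
    expect_true(pss@attractorSurrogate[1])
})
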