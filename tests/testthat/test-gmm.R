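test_that("the observed covariance seeds the drift matrix", {
    set.seed(101)
    # two identical populations: perfect correlation
    x <- rnorm(500)
    d <- cbind(x, x)
    W0 <- suppressWarnings(initCovariance(d))
    expect_equal(W0[1, 2], W0[1, 1], tolerance = 1e-6)
    # constant data: ridge keeps it usable
    expect_warning(Wc <- initCovariance(matrix(1, 50, 2)), "ridge")
    expect_gt(min(eigen(Wc, symmetric = TRUE, only.values = TRUE)$values), 0)
    # large-sample consistency against a known covariance
    S <- rbind(c(0.05, 0.02), c(0.02, 0.04))
    R <- chol(S)
    d2 <- matrix(rnorm(2e4 * 2), ncol = 2) %*% R
    expect_lt(norm(initCovariance(d2) - S, "F") / norm(S, "F"), 0.05)
})

test_that("single-component EM matches the direct Gaussian MLE", {
    set.seed(102)
    d <- matrix(rnorm(300 * 3, sd = 0.3), ncol = 3) + rnorm(300)  # shared row effect
    Sigmabar <- diag(0.01, 3)
    mix <- gmmEM(d, Sigmabar, R = 1, seed = 1, sigma2 = 0, tol = 1e-14,
                 maxIter = 5000)
    # oracle: profile likelihood over the scalar mean, scatter as covariance
    profile <- function(mu) {
        C <- crossprod(d - mu) / nrow(d)
        sum(logEmission(d, mu, C))
    }
    opt <- optimize(profile, c(-2, 2), maximum = TRUE, tol = 1e-12)
    expect_equal(mix@logLik, opt$objective, tolerance = 1e-8)
    expect_equal(mix@pi, 1)
})

test_that("EM responsibilities normalize and the trace is non-decreasing", {
    set.seed(103)
    d <- rbind(matrix(rnorm(400 * 2, sd = 0.1), ncol = 2),
               matrix(rnorm(400 * 2, sd = 0.6), ncol = 2))
    mix <- gmmEM(d, diag(1e-4, 2), R = 2, seed = 3)
    expect_true(all(diff(mix@trace) > -1e-8 * (abs(mix@trace[-1]) + 1)))
    expect_equal(sum(mix@pi), 1, tolerance = 1e-12)
    expect_true(all(mix@assignment %in% 1:2))
})

test_that("well-separated covariance regimes are recovered", {
    set.seed(104)
    C1 <- diag(0.01, 2)
    C2 <- rbind(c(0.5, 0.3), c(0.3, 0.5))
    L1 <- 6000; L2 <- 4000
    d <- rbind(matrix(rnorm(L1 * 2), ncol = 2) %*% chol(C1),
               matrix(rnorm(L2 * 2), ncol = 2) %*% chol(C2))
    mix <- gmmEM(d, diag(1e-6, 2), R = 2, seed = 5)
    expect_equal(sort(mix@pi), c(0.4, 0.6), tolerance = 0.05)
})

test_that("coercion recovers generating branch lengths and rates from clean input", {
    g <- fourPopTipGraph()
    cTrue <- branchLengths(g)
    wTrue <- c(0.2, 0.6)
    W <- lapply(wTrue, function(w) driftCovariance(g, w = w))
    co <- coerceToGraph(W, pi = c(0.5, 0.5), g, C = 80, seed = 11)
    expect_lt(co$rss, 1e-8)
    expect_equal(unname(co$c), unname(cTrue), tolerance = 1e-3)
    expect_equal(sort(co$w[, 1]), wTrue, tolerance = 1e-3)

    # component relabeling: same branch lengths, permuted rates
    co2 <- coerceToGraph(W[2:1], pi = c(0.5, 0.5), g, C = 80, seed = 11)
    expect_equal(unname(co2$c), unname(co$c), tolerance = 1e-3)
    expect_equal(sort(co2$w[, 1]), sort(co$w[, 1]), tolerance = 1e-3)
})

test_that("tree-only coercion agrees with dense least squares", {
    g <- twoPopGraph()
    set.seed(12)
    Wobs <- driftCovariance(g) + matrix(rnorm(4, sd = 1e-3), 2)
    Wobs <- (Wobs + t(Wobs)) / 2
    co <- coerceToGraph(list(Wobs), pi = 1, g, C = 40, seed = 13)
    # dense LS oracle: W is linear in c through the sharing matrices
    full <- driftCovariance(g, full = TRUE)
    X <- vapply(full$J, as.vector, numeric(4))
    cLS <- qr.solve(X, as.vector(Wobs))
    expect_equal(unname(co$c), unname(cLS), tolerance = 1e-4)
    # residual orthogonality at the solution
    resid <- as.vector(Wobs) - X %*% co$c
    expect_lt(max(abs(crossprod(X, resid))), 1e-6)
})

test_that("component-count selection follows the weight and RSS rules", {
    g <- twoPopMigGraph()
    set.seed(14)
    # single migration regime: R = 1 is kept
    sim1 <- simulateDataset(g, track = simulateTrack(800, "constant", rate = 0.3),
                            mu = -0.5, sigma2 = 0.2, N = 100, seed = 15)
    d1 <- transformedFrequencies(sim1$counts)
    sel1 <- selectNumComponents(d1, diag(0.01, 2), g,
                                mixScanConfig(C = 40, seed = 3))
    expect_equal(sel1$R, 1L)
    # an impossible weight threshold forces R = 1 regardless
    selT <- selectNumComponents(d1, diag(0.01, 2), g,
                                mixScanConfig(C = 10, piThreshold = 1.0, seed = 3))
    expect_equal(selT$R, 1L)
    # Two strongly separated regimes at even proportions: R = 2 accepted.
    # A mixture is only visible at the covariance level when some entry is
    # nonlinear in the rates (two edges sharing a source give a cross-
    # recipient covariance proportional to w1*w2) and the graph has fewer
    # free parameters than covariance entries; a single-edge graph has all
    # covariances linear in w, so the pooled covariance refits exactly there.
    g5 <- readPopulationGraph(text = c("ROOT R",
        "BRANCH R A 0.1", "BRANCH A P1 0.2",
        "BRANCH A s 0.075", "BRANCH s P2 0.125",
        "BRANCH R B 0.1", "BRANCH B P3 0.15", "BRANCH B P4 0.2",
        "BRANCH R P5 0.25",
        "MIG m1 s P3", "MIG m2 s P5",
        "LEAF P1 pop1", "LEAF P2 pop2", "LEAF P3 pop3", "LEAF P4 pop4",
        "LEAF P5 pop5"))
    tr2 <- simulateTrack(6000, "constant", rate = 0)
    tr2@rates[3001:6000, 1] <- 0.9
    sim2 <- simulateDataset(g5, track = combineTracks(tr2, tr2), mu = -0.5,
                            sigma2 = 0.05, N = 200, seed = 16)
    d2 <- transformedFrequencies(sim2$counts)
    sel2 <- selectNumComponents(d2, diag(0.005, 5), g5,
                                mixScanConfig(C = 40, seed = 3))
    expect_equal(sel2$R, 2L)
    expect_equal(sort(round(sel2$coercion$w[, 1], 1)), c(0, 0.9),
                 tolerance = 0.1)
})
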