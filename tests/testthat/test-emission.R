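test_that("the arcsine transform maps counts to the stabilized scale", {
    expect_equal(transformCounts(50, 100)$d, 0)
    expect_equal(transformCounts(100, 100)$d, pi / 2)
    expect_equal(transformCounts(25, 100)$d, -pi / 6)
    expect_error(transformCounts(1, 0), "N must be")
    expect_error(transformCounts(5, 3), "0 <= n <= N")

    # strictly increasing in f; antisymmetric under allele relabeling
    f <- seq(0.01, 0.99, by = 0.01)
    d <- transformCounts(round(f * 1000), rep(1000, length(f)))$d
    expect_true(all(diff(d) > 0))
    expect_equal(transformCounts(30, 100)$d, -transformCounts(70, 100)$d)
})

test_that("AlleleCounts validates, sorts and filters loci", {
    ac <- AlleleCounts(n = cbind(a = c(5L, 2L, 0L), b = c(2L, 9L, 0L)),
                       N = cbind(a = c(10L, 10L, 10L), b = c(10L, 10L, 10L)),
                       chrom = c("2", "1", "1"), pos = c(50, 200, 100))
    # monomorphic locus dropped, remaining sorted by (chrom, pos)
    expect_equal(nrow(ac), 2L)
    rr <- SummarizedExperiment::rowRanges(ac)
    expect_equal(as.character(GenomicRanges::seqnames(rr)), c("1", "2"))
    expect_equal(GenomicRanges::start(rr), c(200, 50))

    # zero total in one population: locus dropped with a message
    expect_message(
        ac2 <- AlleleCounts(n = cbind(c(5L, 0L), c(2L, 1L)),
                            N = cbind(c(10L, 0L), c(10L, 10L)),
                            chrom = c("1", "1"), pos = c(1, 2)),
        "zero total")
    expect_equal(nrow(ac2), 1L)
    expect_error(AlleleCounts(n = cbind(5L), N = cbind(3L),
                              chrom = "1", pos = 1), "0 <= n <= N")
})

test_that("inter-locus distances restart at chromosome breaks", {
    ac <- AlleleCounts(n = cbind(c(5L, 4L, 3L, 6L)), N = cbind(rep(10L, 4)),
                       chrom = c("1", "1", "2", "2"), pos = c(100, 400, 50, 90),
                       dropMonomorphic = FALSE)
    expect_equal(interLocusDistances(ac), c(NA, 300, NA, 40))
})

test_that("sample-size clustering merges the rarest vectors by weighted average", {
    N <- rbind(matrix(c(100, 100), 5, 2, byrow = TRUE),
               matrix(c(90, 100), 3, 2, byrow = TRUE),
               matrix(c(80, 100), 2, 2, byrow = TRUE))
    cl <- clusterSampleSizes(N, u = 2)
    reps <- cl@representatives[order(cl@representatives[, 1]), ]
    expect_equal(unname(reps), rbind(c(86, 100), c(100, 100)))
    expect_equal(sum(cl@counts), nrow(N))          # locus weight conserved
    expect_equal(length(cl@assignment), nrow(N))
    # already at target: unchanged
    cl3 <- clusterSampleSizes(N, u = 3)
    expect_equal(nrow(cl3@representatives), 3L)
    expect_equal(sort(cl3@representatives[, 1]), c(80, 90, 100))
    # single shared vector: identity clustering
    cl1 <- clusterSampleSizes(matrix(50, 7, 2), u = 5)
    expect_equal(nrow(cl1@representatives), 1L)
    expect_equal(samplingCovariances(cl1)[[1]], diag(1 / 50, 2))
    # deterministic under the lexicographic tie-break
    expect_equal(clusterSampleSizes(N, 2)@representatives,
                 clusterSampleSizes(N, 2)@representatives)
})

test_that("marginal covariance adds sampling, drift and root-prior parts", {
    W <- rbind(c(0.03, 0.006), c(0.006, 0.01415))
    S <- marginalCovariance(W, diag(0.01, 2), 0.3)
    expect_equal(S, rbind(c(0.34, 0.306), c(0.306, 0.32415)))
    expect_equal(marginalCovariance(matrix(0, 2, 2), diag(1 / c(10, 20)), 0),
                 diag(1 / c(10, 20)))
    # removing the added parts recovers W exactly
    expect_equal(S - 0.3 - diag(0.01, 2), W)
})

test_that("log emissions match the dense-inverse evaluation and Gaussian laws", {
    expect_equal(logEmission(0.7, 0.7, matrix(4)),
                 -0.5 * log(2 * pi * 4))
    set.seed(5)
    for (rep in 1:5) {
        M <- sample(2:4, 1)
        A <- matrix(rnorm(M * M), M)
        S <- crossprod(A) + diag(M) * 0.1
        d <- rnorm(M); mu <- rnorm(1)
        expect_equal(logEmission(d, mu, S), denseGaussLogDens(d, mu, S),
                     tolerance = 1e-12)
        # Gaussian reflection symmetry about the mean vector
        expect_equal(logEmission(d, mu, S),
                     logEmission(2 * mu - d, mu, S))
    }
    # non-PD covariance: -Inf with a one-time warning, not an error
    .mixscanState$warnedNonPD <- FALSE
    expect_warning(le <- logEmission(c(0, 0), 0, diag(c(1, -1))), "non-positive")
    expect_identical(le, -Inf)
    expect_silent(logEmission(c(0, 0), 0, diag(c(1, -1))))
    expect_error(logEmission(c(NA, 1), 0, diag(2)), "invalid datum")
})

test_that("the precomputed emission table equals locus-by-locus evaluation", {
    set.seed(7)
    g <- fourPopTipGraph()
    sim <- simulateToy(g, L = 60, seed = 7)
    d <- transformedFrequencies(sim$counts)
    # heterogeneous sample sizes so several clusters exist
    N <- totalCounts(sim$counts)
    N[1:20, 1] <- 80L
    cl <- clusterSampleSizes(N, u = 3)
    Sigmas <- samplingCovariances(cl)
    space <- HiddenStateSpace(MigrationGrid(nEdges = 1, J = 5))
    struct <- mixscan:::.configStructure(g)
    stateW <- lapply(seq_len(numStates(space)), function(s)
        mixscan:::.covFromInclusion(
            mixscan:::.branchInclusion(struct, space@stateRates[s, ]),
            branchLengths(g)))
    tab <- mixscan:::.emissionTable(stateW, Sigmas, 0.3)
    logE <- mixscan:::.emissionMatrix(d, -0.5, tab, cl@assignment)
    for (l in c(1, 15, 37, 60)) {
        for (s in seq_len(numStates(space))) {
            S <- marginalCovariance(stateW[[s]], Sigmas[[cl@assignment[l]]], 0.3)
            expect_equal(logE[l, s], logEmission(d[l, ], -0.5, S),
                         tolerance = 1e-10)
        }
    }
})
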