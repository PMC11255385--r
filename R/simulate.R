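#' MigrationTrack: per-locus true migration rates
#'
#' @slot rates numeric matrix (L x I) of rates in \code{[0, 1]}.
#' @slot labels character matrix of block labels (\code{"background"},
#'   \code{"intermediate"}, \code{"peak"}, \code{"constant"} or
#'   \code{"markov"}).
#' @export
setClass("MigrationTrack",
    representation(rates = "matrix", labels = "matrix"))

setMethod("show", "MigrationTrack", function(object) {
    cat(sprintf("MigrationTrack: %d loci x %d edge(s); levels: %s\n",
        nrow(object@rates), ncol(object@rates),
        paste(sort(unique(round(as.vector(object@rates), 6))), collapse = ", ")))
})

#' @rdname simulateTrack
#' @param object a \linkS4class{MigrationTrack}.
#' @export
trackRates <- function(object) object@rates
#' @rdname simulateTrack
#' @export
trackLabels <- function(object) object@labels

#' Simulate a migration-rate track
#'
#' Generates the per-locus true migration rate for one edge under one of
#' three designs:
#' \describe{
#'   \item{constant}{every locus at \code{rate}.}
#'   \item{peaks}{the block design used in the genome-scan benchmarks: 70\% of
#'     loci at the background rate, 10\% at the peak rate and 20\% at an
#'     intermediate rate, arranged as evenly spaced peak regions of
#'     \code{peakWidth} intermediate + \code{peakWidth} peak +
#'     \code{peakWidth} intermediate loci. With the default \code{L = 10000}
#'     this yields 7000 background, 2000 intermediate and 1000 peak loci.}
#'   \item{markov}{a draw from the HMM prior itself: a chain over
#'     \code{grid} started at its stationary law with transition kernel
#'     \eqn{\exp(\delta\kappa\Lambda)}.}
#' }
#'
#' @param L number of loci.
#' @param mode \code{"constant"}, \code{"peaks"} or \code{"markov"}.
#' @param rate constant-mode rate.
#' @param background,peak,intermediate peaks-mode rate levels; the
#'   intermediate level defaults to the midpoint.
#' @param peakWidth number of peak loci per peak region (\code{m}); \code{L}
#'   must be a multiple of \code{10 * peakWidth} so the block arithmetic adds
#'   up.
#' @param grid,variant,kappa,delta,phi,zeta,a markov-mode chain parameters
#'   (see \code{\link{rateMatrix}}).
#' @param seed optional RNG seed (markov mode only uses randomness).
#' @return a \linkS4class{MigrationTrack} with one column.
#' @examples
#' tr <- simulateTrack(10000, "peaks")
#' table(trackLabels(tr))
#' @export
simulateTrack <- function(L, mode = c("constant", "peaks", "markov"),
                          rate = 0.1,
                          background = 0.1, peak = 0.6,
                          intermediate = (background + peak) / 2,
                          peakWidth = 50L,
                          grid = MigrationGrid(J = 21L), variant = "ladder",
                          kappa = 1, delta = 1, phi = NULL, zeta = NULL,
                          a = NULL, seed = NULL) {
    mode <- match.arg(mode)
    stopifnot(L > 0)
    if (!is.null(seed)) set.seed(seed)
    if (mode == "constant") {
        rates <- rep(rate, L)
        labels <- rep("constant", L)
    } else if (mode == "peaks") {
        nPeakLoci <- L / 10
        if (nPeakLoci != floor(nPeakLoci) || nPeakLoci %% peakWidth != 0)
            stop("design mismatch: L must be a multiple of 10 * peakWidth")
        nRegions <- nPeakLoci / peakWidth
        regionWidth <- 3L * peakWidth
        gapTotal <- L - nRegions * regionWidth
        gaps <- rep(gapTotal %/% (nRegions + 1L), nRegions + 1L)
        extra <- gapTotal - sum(gaps)
        if (extra > 0) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L
        rates <- numeric(0); labels <- character(0)
        for (r in seq_len(nRegions)) {
            rates <- c(rates, rep(background, gaps[r]),
                       rep(c(intermediate, peak, intermediate), each = peakWidth))
            labels <- c(labels, rep("background", gaps[r]),
                        rep(c("intermediate", "peak", "intermediate"),
                            each = peakWidth))
        }
        rates <- c(rates, rep(background, gaps[nRegions + 1L]))
        labels <- c(labels, rep("background", gaps[nRegions + 1L]))
        if (length(rates) != L) stop("design mismatch")
    } else {
        g <- if (is(grid, "MigrationGrid")) grid@rates[[1]] else grid
        J <- length(g)
        Lam <- rateMatrix(J, variant, phi = phi, zeta = zeta, a = a)
        P <- transitionMatrix(Lam, kappa, delta)
        pstat <- stationaryDistribution(Lam, a = if (is.null(a)) NULL else a)
        st <- integer(L)
        st[1] <- sample.int(J, 1L, prob = pstat)
        for (l in seq_len(L - 1L))
            st[l + 1L] <- sample.int(J, 1L, prob = P[st[l], ])
        rates <- g[st]
        labels <- rep("markov", L)
    }
    new("MigrationTrack", rates = cbind(rates), labels = cbind(labels))
}

#' Combine single-edge tracks
#'
#' @param ... \linkS4class{MigrationTrack} objects of equal length.
#' @export
combineTracks <- function(...) {
    tr <- list(...)
    new("MigrationTrack",
        rates = do.call(cbind, lapply(tr, trackRates)),
        labels = do.call(cbind, lapply(tr, trackLabels)))
}

#' Simulate allele counts under the drift-graph model
#'
#' The generative process the inference machinery assumes: per locus, a root
#' value \eqn{\mu_l \sim N(\mu, \sigma^2)} on the arcsine scale, latent
#' transformed population frequencies
#' \eqn{x_l \sim N(\mu_l 1, W(c, w_l))} with \eqn{w_l} the locus's migration
#' rates from the track, back-transform
#' \eqn{y_{lm} = (\sin(x_{lm}) + 1)/2} (always inside \code{[0, 1]}), and
#' binomially sampled counts \eqn{n_{lm} \sim Bin(N_{lm}, y_{lm})}.
#'
#' Monomorphic loci are retained so rows align with the simulation truth.
#'
#' @param graph a \linkS4class{PopulationGraph}.
#' @param c branch lengths (default: the graph's own).
#' @param track a \linkS4class{MigrationTrack} (columns = migration edges).
#' @param mu,sigma2 root prior; \code{sigma2 = 0} fixes the root at \code{mu}.
#' @param N total alleles per locus and population: scalar, per-population
#'   vector, or an L x M matrix.
#' @param positions,chrom locus coordinates; default 1 kb spacing on one
#'   chromosome, so inter-locus distances are uniform.
#' @param seed RNG seed (same seed, identical dataset).
#' @return list with \code{counts} (an \linkS4class{AlleleCounts}) and
#'   \code{truth} (track, root draws \code{muL}, latent \code{x}, \code{y},
#'   the parameters and seed used).
#' @export
simulateDataset <- function(graph, c = branchLengths(graph), track, mu, sigma2,
                            N = 100, positions = NULL, chrom = NULL,
                            seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    rates <- trackRates(track)
    L <- nrow(rates)
    M <- numPopulations(graph)
    I <- numMigrationEdges(graph)
    if (I == 0L) rates <- matrix(numeric(), L, 0)   # track irrelevant on a tree
    else stopifnot(ncol(rates) == I)
    stopifnot(sigma2 >= 0)
    if (is.null(positions)) positions <- seq_len(L) * 1000
    if (is.null(chrom)) chrom <- rep("chr1", L)
    if (length(N) == 1L) N <- matrix(N, L, M)
    else if (is.null(dim(N))) N <- matrix(N, L, M, byrow = TRUE)
    struct <- .configStructure(graph)
    muL <- mu + sqrt(sigma2) * rnorm(L)
    x <- matrix(0, L, M)
    key <- if (I == 0L) rep("", L) else apply(rates, 1L, paste, collapse = ",")
    for (kk in unique(key)) {
        idx <- which(key == kk)
        w <- rates[idx[1], ]
        W <- .covFromInclusion(.branchInclusion(struct, w), c)
        e <- eigen(W, symmetric = TRUE)
        if (min(e$values) < -1e-8 * max(abs(e$values), 1e-12))
            stop("invalid generative parameters: drift covariance not PSD")
        R <- sqrt(pmax(e$values, 0)) * t(e$vectors)   # R'R = W, PSD-safe
        z <- matrix(rnorm(length(idx) * M), length(idx), M)
        x[idx, ] <- muL[idx] + z %*% R
    }
    y <- (sin(x) + 1) / 2
    n <- matrix(rbinom(L * M, size = as.vector(N), prob = as.vector(y)), L, M)
    counts <- AlleleCounts(n, N, chrom = chrom, pos = positions,
                           populations = unname(graph@leafPop),
                           dropMonomorphic = FALSE)
    truth <- list(track = track, muL = muL, x = x, y = y,
                  c = c, mu = mu, sigma2 = sigma2, seed = seed)
    list(counts = counts, truth = truth)
}

#' Rank-based AUC for detecting elevated-migration loci
#'
#' Area under the ROC curve of a per-locus score against binary truth labels
#' (peak vs background), computed from midranks so ties are handled exactly.
#'
#' @param score numeric score per locus (higher = more evidence).
#' @param labels logical or 0/1 truth per locus.
#' @export
evaluateDetection <- function(score, labels) {
    stopifnot(all(is.finite(score)))
    labels <- as.logical(labels)
    n1 <- sum(labels); n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L)
        stop("AUC undefined: labels contain a single class")
    r <- rank(score)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
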