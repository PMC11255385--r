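#' Construct an AlleleCounts dataset
#'
#' @param n integer matrix (loci x populations) of derived allele counts.
#' @param N integer matrix of total observed alleles (same shape, all >= 1 at
#'   retained loci).
#' @param chrom chromosome label per locus.
#' @param pos physical (bp) or genetic (cM) position per locus.
#' @param populations population labels (default: column names of \code{n}).
#' @param dropMonomorphic drop loci with f = 0 or f = 1 in every population
#'   (no information under the model; boundary of the normal approximation).
#' @return an \linkS4class{AlleleCounts} object sorted by (chromosome,
#'   position). Loci with a zero total in any population are dropped with a
#'   message (the model assumes at least one observed sample per locus and
#'   population).
#' @examples
#' ac <- AlleleCounts(n = cbind(a = c(5L, 0L), b = c(2L, 9L)),
#'                    N = cbind(a = c(10L, 10L), b = c(10L, 10L)),
#'                    chrom = c("1", "1"), pos = c(100, 200))
#' transformedFrequencies(ac)
#' @export
AlleleCounts <- function(n, N, chrom, pos, populations = colnames(n),
                         dropMonomorphic = TRUE) {
    n <- as.matrix(n); N <- as.matrix(N)
    stopifnot(all(dim(n) == dim(N)), nrow(n) == length(chrom),
              nrow(n) == length(pos))
    if (any(n != round(n)) || any(N != round(N)))
        stop("allele counts must be whole numbers")
    storage.mode(n) <- "integer"
    storage.mode(N) <- "integer"
    if (is.null(populations))
        populations <- paste0("pop", seq_len(ncol(n)))
    if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N at every locus")
    keep <- rowSums(N == 0) == 0
    if (!all(keep)) {
        message(sum(!keep), " locus/loci dropped: zero total in some population")
    }
    if (dropMonomorphic) {
        mono <- rowSums(n == 0) == ncol(n) | rowSums(n == N) == ncol(n)
        if (any(mono & keep))
            message(sum(mono & keep), " monomorphic locus/loci dropped")
        keep <- keep & !mono
    }
    n <- n[keep, , drop = FALSE]; N <- N[keep, , drop = FALSE]
    chrom <- as.character(chrom)[keep]; pos <- pos[keep]
    o <- order(chrom, pos)
    n <- n[o, , drop = FALSE]; N <- N[o, , drop = FALSE]
    chrom <- chrom[o]; pos <- pos[o]
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
    colnames(n) <- colnames(N) <- populations
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(n = n, N = N), rowRanges = rr,
        colData = S4Vectors::DataFrame(population = populations,
                                       row.names = populations))
    new("AlleleCounts", se)
}

setValidity("AlleleCounts", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("n", "N") %in% a)) return("assays 'n' and 'N' required")
    n <- SummarizedExperiment::assay(object, "n")
    N <- SummarizedExperiment::assay(object, "N")
    if (any(n < 0) || any(n > N)) return("need 0 <= n <= N")
    if (nrow(object) > 1L) {
        chrom <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object)))
        pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
        if (is.unsorted(order(chrom, pos)))
            return("loci must be sorted by (chromosome, position)")
    }
    TRUE
})

#' @rdname AlleleCounts
#' @param object an \linkS4class{AlleleCounts}.
#' @export
derivedCounts <- function(object) SummarizedExperiment::assay(object, "n")
#' @rdname AlleleCounts
#' @export
totalCounts <- function(object) SummarizedExperiment::assay(object, "N")

#' Arcsine transform of observed allele frequencies
#'
#' \code{transformCounts} maps counts to observed frequencies
#' \eqn{f = n/N} and to the variance-stabilized scale
#' \eqn{d = \arcsin(2f - 1)} (radians, in \eqn{[-\pi/2, \pi/2]}), on which both
#' the drift and the sampling variance lose their \eqn{f(1-f)} factor.
#' \code{transformedFrequencies} applies it to an \linkS4class{AlleleCounts}.
#'
#' @param n,N derived and total counts (vectors or matrices, \code{0 <= n <= N},
#'   \code{N >= 1}).
#' @return list with elements \code{f} and \code{d} (same shape as the input).
#' @export
transformCounts <- function(n, N) {
    if (any(N < 1)) stop("N must be >= 1 for every retained locus and population")
    if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N")
    f <- n / N
    list(f = f, d = asin(2 * f - 1))
}

#' @rdname transformCounts
#' @param object an \linkS4class{AlleleCounts}.
#' @export
transformedFrequencies <- function(object) {
    transformCounts(derivedCounts(object), totalCounts(object))$d
}

#' Inter-locus distances within chromosomes
#'
#' Distances between consecutive retained loci; the first locus of each
#' chromosome has \code{NA} (the hidden chain restarts there).
#'
#' @param object an \linkS4class{AlleleCounts}.
#' @return numeric vector of length \code{nrow(object)}.
#' @export
interLocusDistances <- function(object) {
    rr <- SummarizedExperiment::rowRanges(object)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    delta <- c(NA_real_, diff(pos))
    delta[c(TRUE, chrom[-1] != chrom[-length(chrom)])] <- NA_real_
    if (any(delta <= 0, na.rm = TRUE))
        stop("positions must be strictly increasing within chromosomes")
    delta
}

#' Cluster per-locus sample-size vectors
#'
#' Reduces the number of distinct sampling covariance matrices
#' \eqn{\Sigma_l = diag(1/N_{l1}, ..., 1/N_{lM})} by iteratively merging the
#' two least-frequent total-allele vectors into their occurrence-weighted
#' average (occurrence counts summed) until at most \code{u} representatives
#' remain. Ties in rarity are broken by merging the lexicographically smallest
#' pair, making the clustering deterministic.
#'
#' @param N matrix (loci x populations) of totals, or an
#'   \linkS4class{AlleleCounts}.
#' @param u target number of representatives (>= 1).
#' @return a \linkS4class{SampleSizeClusters}.
#' @export
clusterSampleSizes <- function(N, u) {
    stopifnot(u >= 1)
    if (is(N, "AlleleCounts")) N <- totalCounts(N)
    N <- as.matrix(N)
    key <- apply(N, 1L, paste, collapse = ",")
    tab <- table(key)
    reps <- do.call(rbind, lapply(strsplit(names(tab), ","), as.numeric))
    cnt <- as.numeric(tab)
    group <- match(key, names(tab))   # locus -> representative row
    merged <- seq_len(nrow(reps))     # union-find style redirection
    active <- rep(TRUE, nrow(reps))
    lexOrder <- function(idx) idx[do.call(order, as.data.frame(reps[idx, , drop = FALSE]))]
    while (sum(active) > u) {
        ia <- which(active)
        o <- ia[order(cnt[ia])]
        ## the two rarest; among equal counts take lexicographically smallest
        cmin1 <- cnt[o[1]]
        cand1 <- lexOrder(ia[cnt[ia] == cmin1])
        i1 <- cand1[1]
        ia2 <- setdiff(ia, i1)
        cmin2 <- min(cnt[ia2])
        cand2 <- lexOrder(ia2[cnt[ia2] == cmin2])
        i2 <- cand2[1]
        w1 <- cnt[i1]; w2 <- cnt[i2]
        reps[i1, ] <- (w1 * reps[i1, ] + w2 * reps[i2, ]) / (w1 + w2)
        cnt[i1] <- w1 + w2
        active[i2] <- FALSE
        merged[merged == i2] <- i1
    }
    keep <- which(active)
    assignment <- match(merged[group], keep)
    new("SampleSizeClusters",
        representatives = reps[keep, , drop = FALSE],
        counts = cnt[keep], assignment = as.integer(assignment))
}

#' @rdname clusterSampleSizes
#' @param object a \linkS4class{SampleSizeClusters}.
#' @export
samplingCovariances <- function(object) {
    lapply(seq_len(nrow(object@representatives)), function(i)
        diag(1 / object@representatives[i, ], ncol(object@representatives)))
}

setMethod("show", "SampleSizeClusters", function(object) {
    cat(sprintf("SampleSizeClusters: %d representative(s) for %d loci\n",
        nrow(object@representatives), length(object@assignment)))
})

#' Marginal covariance of transformed frequencies
#'
#' \eqn{S = \Sigma + W + \sigma^2 1 1'}: sampling noise, drift along the graph
#' and the root-prior variance combine additively on the arcsine scale.
#'
#' @param W drift covariance (M x M).
#' @param Sigma diagonal sampling covariance (M x M).
#' @param sigma2 root-prior variance (>= 0).
#' @export
marginalCovariance <- function(W, Sigma, sigma2) {
    stopifnot(all(dim(W) == dim(Sigma)), sigma2 >= 0)
    S <- Sigma + W + sigma2
    (S + t(S)) / 2
}

## Cholesky context for one state x cluster combination; NULL if not PD
.cholContext <- function(S) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    list(R = R, logdet = 2 * sum(log(diag(R))))
}

#' Log emission density
#'
#' Log of the marginal Gaussian likelihood \eqn{N(d; \mu 1, S)} evaluated via
#' a Cholesky factorization. A non-positive-definite \code{S} yields
#' \code{-Inf} (with a one-time warning) rather than an error: invalid
#' branch-length proposals are thereby penalized smoothly during optimization.
#'
#' @param d transformed frequencies at one locus (length M) or a matrix
#'   (loci x M) for vectorized evaluation.
#' @param mu root-prior mean (scalar).
#' @param S marginal covariance (M x M).
#' @return log-density (scalar or vector).
#' @export
logEmission <- function(d, mu, S) {
    d <- rbind(d)
    if (anyNA(d)) stop("invalid datum: NaN/NA in d")
    M <- ncol(d)
    ctx <- .cholContext(S)
    if (is.null(ctx)) {
        .emitNonPDWarning()
        return(rep(-Inf, nrow(d)))
    }
    z <- backsolve(ctx$R, t(d) - mu, transpose = TRUE)
    q <- colSums(z^2)
    -0.5 * (M * log(2 * pi) + ctx$logdet + q)
}

.mixscanState <- new.env(parent = emptyenv())
.mixscanState$warnedNonPD <- FALSE

.emitNonPDWarning <- function() {
    if (!.mixscanState$warnedNonPD) {
        warning("non-positive-definite marginal covariance: emission set to -Inf",
                call. = FALSE)
        .mixscanState$warnedNonPD <- TRUE
    }
    invisible(NULL)
}

## Emission table: per hidden state and sample-size cluster, the Cholesky
## context of S_{j,u} = Sigma_u + W(c, w_j) + sigma2 * 11'. States with a
## non-PD S get a NULL context (log-emission -Inf).
.emissionTable <- function(stateW, Sigmas, sigma2) {
    lapply(stateW, function(W)
        lapply(Sigmas, function(Sg) .cholContext(marginalCovariance(W, Sg, sigma2))))
}

## Log-emission matrix (L x S) from a precomputed table.
## d: L x M, clusterIdx: length-L representative index
.emissionMatrix <- function(d, mu, table, clusterIdx) {
    L <- nrow(d); S <- length(table)
    M <- ncol(d)
    out <- matrix(-Inf, L, S)
    byCluster <- split(seq_len(L), clusterIdx)
    for (j in seq_len(S)) {
        for (uc in names(byCluster)) {
            ctx <- table[[j]][[as.integer(uc)]]
            if (is.null(ctx)) { .emitNonPDWarning(); next }
            idx <- byCluster[[uc]]
            z <- backsolve(ctx$R, t(d[idx, , drop = FALSE]) - mu, transpose = TRUE)
            out[idx, j] <- -0.5 * (M * log(2 * pi) + ctx$logdet + colSums(z^2))
        }
    }
    out
}
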