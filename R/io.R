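#' @importClassesFrom vcfR vcfR
NULL

#' Read a sample-to-population map
#'
#' Two whitespace-separated columns: sample identifier, population label.
#' @param file path.
#' @return named character vector (sample -> population).
#' @export
readPopulationMap <- function(file) {
    tab <- read.table(file, header = FALSE, stringsAsFactors = FALSE)
    setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Read allele counts from a VCF
#'
#' Counts ALT alleles per population from the GT field: \code{n} is the
#' number of ALT alleles among called genotypes, \code{N} the number of
#' called alleles. Non-biallelic records are skipped; loci failing the global
#' minor-allele-frequency threshold, or with no called allele in some
#' population, are dropped (all counts reported via messages). Positions and
#' chromosomes are retained for the inter-locus distances.
#'
#' @param file VCF path (plain or bgzipped).
#' @param popmap named character vector (sample -> population), e.g. from
#'   \code{\link{readPopulationMap}}.
#' @param maf global minor-allele-frequency threshold (default 0.05).
#' @param biallelicOnly skip non-biallelic records (default TRUE; only
#'   biallelic records are countable anyway).
#' @param minDistance optional thinning: minimum bp between consecutive
#'   retained SNPs (0 = keep all).
#' @param ignoreExtra allow VCF samples absent from the map (dropped).
#' @param dropMonomorphic see \code{\link{AlleleCounts}}.
#' @return an \linkS4class{AlleleCounts}.
#' @export
readVcfCounts <- function(file, popmap, maf = 0.05, biallelicOnly = TRUE,
                          minDistance = 0, ignoreExtra = FALSE,
                          dropMonomorphic = TRUE) {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gt)
    unmapped <- setdiff(samples, names(popmap))
    if (length(unmapped) > 0) {
        if (!ignoreExtra)
            stop("unmapped sample(s): ", paste(unmapped, collapse = ", "),
                 " (use ignoreExtra = TRUE to drop)")
        gt <- gt[, setdiff(samples, unmapped), drop = FALSE]
        samples <- colnames(gt)
    }
    pops <- unique(unname(popmap[samples]))
    biall <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "" &
             !is.na(fix[, "ALT"]) & nchar(fix[, "REF"]) >= 1
    if (biallelicOnly && any(!biall))
        message(sum(!biall), " non-biallelic record(s) skipped")
    gt <- gt[biall, , drop = FALSE]
    fix <- fix[biall, , drop = FALSE]
    L <- nrow(gt)
    M <- length(pops)
    n <- matrix(0L, L, M, dimnames = list(NULL, pops))
    N <- matrix(0L, L, M, dimnames = list(NULL, pops))
    for (m in seq_len(M)) {
        cols <- samples[popmap[samples] == pops[m]]
        sub <- gt[, cols, drop = FALSE]
        alt <- vapply(seq_len(L), function(l) {
            al <- unlist(strsplit(sub[l, ], "[/|]"))
            al <- al[al %in% c("0", "1")]
            c(sum(al == "1"), length(al))
        }, integer(2))
        n[, m] <- alt[1, ]
        N[, m] <- alt[2, ]
    }
    fGlobal <- rowSums(n) / pmax(rowSums(N), 1L)
    keep <- pmin(fGlobal, 1 - fGlobal) >= maf
    if (any(!keep)) message(sum(!keep), " locus/loci below the MAF threshold")
    zero <- rowSums(N == 0) > 0
    if (any(zero & keep))
        message(sum(zero & keep), " locus/loci with an uncalled population")
    keep <- keep & !zero
    chrom <- fix[keep, "CHROM"]
    pos <- as.numeric(fix[keep, "POS"])
    n <- n[keep, , drop = FALSE]; N <- N[keep, , drop = FALSE]
    if (minDistance > 0) {
        o <- order(chrom, pos)
        chrom <- chrom[o]; pos <- pos[o]
        n <- n[o, , drop = FALSE]; N <- N[o, , drop = FALSE]
        keep2 <- logical(length(pos))
        last <- -Inf; lastChr <- ""
        for (l in seq_along(pos)) {
            if (chrom[l] != lastChr || pos[l] - last >= minDistance) {
                keep2[l] <- TRUE; last <- pos[l]; lastChr <- chrom[l]
            }
        }
        message(sum(!keep2), " locus/loci removed by thinning")
        chrom <- chrom[keep2]; pos <- pos[keep2]
        n <- n[keep2, , drop = FALSE]; N <- N[keep2, , drop = FALSE]
    }
    AlleleCounts(n, N, chrom = chrom, pos = pos, populations = pops,
                 dropMonomorphic = dropMonomorphic)
}

#' Write allele counts as a VCF of pseudo-genotypes
#'
#' Distributes each population's \code{n} ALT alleles over
#' \code{ceiling(N/2)} diploid pseudo-samples (a trailing odd allele becomes
#' a haploid genotype; alleles beyond a locus's \code{N} are missing), so
#' \code{\link{readVcfCounts}} recovers \code{n} and \code{N} exactly.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param file output path (gzipped VCF written by \code{vcfR}).
#' @return invisibly, the named popmap vector for the written samples.
#' @export
writeVcfCounts <- function(counts, file) {
    n <- derivedCounts(counts); N <- totalCounts(counts)
    rr <- SummarizedExperiment::rowRanges(counts)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    pops <- colnames(n)
    L <- nrow(n)
    nSamp <- ceiling(apply(N, 2L, max) / 2)
    sampleNames <- unlist(lapply(seq_along(pops), function(m)
        paste0(pops[m], "_", seq_len(nSamp[m]))))
    popmap <- setNames(rep(pops, nSamp), sampleNames)
    gtCols <- matrix(".", L, length(sampleNames),
                     dimnames = list(NULL, sampleNames))
    for (m in seq_along(pops)) {
        for (l in seq_len(L)) {
            alleles <- c(rep("1", n[l, m]), rep("0", N[l, m] - n[l, m]))
            gts <- character(nSamp[m])
            for (s in seq_len(nSamp[m])) {
                a <- alleles[(2 * s - 1):(2 * s)]
                a <- a[!is.na(a)]
                gts[s] <- if (length(a) == 2) paste(a, collapse = "/")
                          else if (length(a) == 1) a else "./."
            }
            gtCols[l, paste0(pops[m], "_", seq_len(nSamp[m]))] <- gts
        }
    }
    meta <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    fix <- cbind(CHROM = chrom, POS = as.character(pos),
                 ID = paste0("snp", seq_len(L)), REF = "A", ALT = "T",
                 QUAL = ".", FILTER = "PASS", INFO = ".")
    gt <- cbind(FORMAT = "GT", gtCols)
    v <- new("vcfR", meta = meta, fix = fix, gt = gt)
    vcfR::write.vcf(v, file = file)
    invisible(popmap)
}

#' Read a plain counts table
#'
#' Tab-separated with header: \code{chrom}, \code{pos}, then per population a
#' pair of columns \code{n<POP>} and \code{N<POP>}.
#' @param file path.
#' @param dropMonomorphic see \code{\link{AlleleCounts}}.
#' @export
readCountsTable <- function(file, dropMonomorphic = TRUE) {
    tab <- read.table(file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    cn <- colnames(tab)
    nCols <- grep("^n", cn[-(1:2)], value = TRUE)
    pops <- sub("^n", "", nCols)
    if (!all(paste0("N", pops) %in% cn))
        stop("counts table: need matching n<POP>/N<POP> column pairs")
    AlleleCounts(as.matrix(tab[paste0("n", pops)]),
                 as.matrix(tab[paste0("N", pops)]),
                 chrom = tab$chrom, pos = tab$pos, populations = pops,
                 dropMonomorphic = dropMonomorphic)
}

#' @rdname readCountsTable
#' @param counts an \linkS4class{AlleleCounts}.
#' @export
writeCountsTable <- function(counts, file) {
    n <- derivedCounts(counts); N <- totalCounts(counts)
    rr <- SummarizedExperiment::rowRanges(counts)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr), check.names = FALSE)
    for (m in seq_len(ncol(n))) {
        out[[paste0("n", colnames(n)[m])]] <- n[, m]
        out[[paste0("N", colnames(n)[m])]] <- N[, m]
    }
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Convert physical positions to genetic-map positions
#'
#' Replaces the loci's bp coordinates with linearly interpolated genetic-map
#' positions so inter-locus distances are in cM. The map has columns
#' \code{chrom}, \code{pos} (bp) and \code{cM}; positions outside the map
#' range are extrapolated from the nearest map segment. Coordinates are
#' stored as micro-centimorgans (cM times 1e6, rounded) — distances are
#' rescaled by their genome-wide mean before use, so the unit constant
#' cancels; ties after rounding are bumped to keep positions strictly
#' increasing.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param map path to a whitespace-separated file with header columns
#'   \code{chrom}, \code{pos}, \code{cM}, or an equivalent data.frame.
#' @return an \linkS4class{AlleleCounts} with converted coordinates.
#' @export
applyGeneticMap <- function(counts, map) {
    if (is.character(map)) map <- read.table(map, header = TRUE)
    stopifnot(all(c("chrom", "pos", "cM") %in% colnames(map)))
    rr <- SummarizedExperiment::rowRanges(counts)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    newPos <- pos
    for (ch in unique(chrom)) {
        idx <- chrom == ch
        seg <- map[map$chrom == ch, ]
        if (nrow(seg) < 2)
            stop("genetic map needs at least two points for chromosome ", ch)
        cm <- approx(seg$pos, seg$cM, xout = pos[idx], rule = 2)$y
        ## linear extrapolation beyond the map ends
        below <- pos[idx] < min(seg$pos); above <- pos[idx] > max(seg$pos)
        o <- order(seg$pos)
        slopeLo <- diff(seg$cM[o][1:2]) / diff(seg$pos[o][1:2])
        nTop <- nrow(seg)
        slopeHi <- diff(seg$cM[o][(nTop - 1):nTop]) / diff(seg$pos[o][(nTop - 1):nTop])
        cm[below] <- seg$cM[o][1] + (pos[idx][below] - seg$pos[o][1]) * slopeLo
        cm[above] <- seg$cM[o][nTop] + (pos[idx][above] - seg$pos[o][nTop]) * slopeHi
        mcM <- round(cm * 1e6)
        mcM <- mcM + cumsum(c(0, as.integer(diff(mcM) <= 0)))  # keep strict order
        newPos[idx] <- mcM
    }
    AlleleCounts(derivedCounts(counts), totalCounts(counts), chrom = chrom,
                 pos = newPos, populations = colnames(derivedCounts(counts)),
                 dropMonomorphic = FALSE)
}

#' Write scan results
#'
#' Writes \code{<prefix>.loci.tsv} (one row per retained locus: chromosome,
#' position, per-edge posterior mean rate, excess/dearth FDR scores and MAP
#' state), \code{<prefix>.params.yaml} (the fitted graph, root prior,
#' transition parameters, grid, likelihood, seed and distance rescaling
#' constant — sufficient to recompute the likelihood) and
#' \code{<prefix>.log}.
#'
#' @param fit a \linkS4class{MixScanFit}.
#' @param posterior a \linkS4class{PosteriorSummary}.
#' @param counts the \linkS4class{AlleleCounts} the fit used.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
writeResults <- function(fit, posterior, counts, prefix) {
    rr <- SummarizedExperiment::rowRanges(counts)
    I <- ncol(posterior@meanRate)
    tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr))
    for (i in seq_len(I)) {
        tab[[paste0("meanRate", i)]] <- posterior@meanRate[, i]
        tab[[paste0("qe", i)]] <- posterior@qe[, i]
        tab[[paste0("qd", i)]] <- posterior@qd[, i]
    }
    tab$mapState <- posterior@mapState
    lociFile <- paste0(prefix, ".loci.tsv")
    write.table(tab, lociFile, sep = "\t", quote = FALSE, row.names = FALSE)
    paramFile <- paste0(prefix, ".params.yaml")
    writeFitParameters(fit, paramFile)
    logFile <- paste0(prefix, ".log")
    writeLines(c(sprintf("loci: %d", nrow(tab)),
                 sprintf("logLik: %.10f", fit@logLik),
                 sprintf("converged: %s", fit@converged),
                 sprintf("EM steps: %d", fit@niter)), logFile)
    invisible(c(lociFile, paramFile, logFile))
}

#' @rdname writeResults
#' @param file parameter file path.
#' @export
writeFitParameters <- function(fit, file) {
    tm <- fit@transition
    gtxt <- character()
    con <- textConnection("gtxt", "w", local = TRUE)
    writePopulationGraph(fit@graph, con)
    close(con)
    yaml::write_yaml(list(
        graph = gtxt,
        mu = fit@mu, sigma2 = fit@sigma2,
        variant = as.list(tm@variant), kappa = as.list(tm@kappa),
        phi = as.list(tm@phi), zeta = as.list(tm@zeta),
        attractor = as.list(tm@attractor),
        grid = lapply(fit@stateSpace@grid@rates, as.numeric),
        u = fit@config$u, seed = fit@config$seed,
        distanceScale = fit@distanceScale,
        logLik = fit@logLik), file,
        precision = 15L)
    invisible(file)
}

#' Reload fitted parameters
#'
#' @param file a \code{.params.yaml} written by \code{\link{writeFitParameters}}.
#' @return list with \code{graph}, \code{theta}, \code{space}, \code{u},
#'   \code{distanceScale} and the stored \code{logLik}.
#' @export
readFitParameters <- function(file) {
    y <- yaml::read_yaml(file)
    graph <- readPopulationGraph(text = unlist(y$graph))
    space <- HiddenStateSpace(MigrationGrid(lapply(y$grid, as.numeric)))
    theta <- list(c = branchLengths(graph), mu = y$mu, sigma2 = y$sigma2,
                  kappa = as.numeric(unlist(y$kappa)),
                  phi = as.numeric(unlist(y$phi)),
                  zeta = as.numeric(unlist(y$zeta)),
                  variant = as.character(unlist(y$variant)),
                  a = as.integer(unlist(y$attractor)))
    list(graph = graph, theta = theta, space = space, u = y$u,
         distanceScale = y$distanceScale, logLik = y$logLik, seed = y$seed)
}

#' Recompute posterior summaries from saved parameters
#'
#' Runs a forward-backward pass at the stored parameters and rebuilds the
#' per-locus summaries (posterior mean rates, FDR scores, MAP states).
#'
#' @param params result of \code{\link{readFitParameters}}.
#' @param counts the \linkS4class{AlleleCounts} the fit used.
#' @return a \linkS4class{PosteriorSummary}.
#' @export
recomputePosteriors <- function(params, counts) {
    theta <- params$theta
    theta$phi[is.na(theta$phi)] <- 0.5
    theta$zeta[is.na(theta$zeta)] <- 0.5
    engine <- .buildEngine(counts, params$graph, params$space,
                           mixScanConfig(u = params$u))
    kern <- .transitionKernels(theta, engine)
    logE <- .logEmissions(theta, engine)
    fb <- .fbCpp(logE, kern$P, engine$group, kern$init, engine$segStart)
    attractor <- ifelse(theta$variant == "attractor", theta$a, NA_integer_)
    posteriorSummaries(fb$gamma, params$space, attractor = attractor,
                       stationary = kern$stat, logLik = fb$loglik)
}

#' Recompute the chain log-likelihood from saved parameters
#'
#' @param params result of \code{\link{readFitParameters}} (or a
#'   \linkS4class{MixScanFit}).
#' @param counts the \linkS4class{AlleleCounts} the fit used.
#' @export
recomputeLogLik <- function(params, counts) {
    if (is(params, "MixScanFit")) {
        tm <- params@transition
        params <- list(graph = params@graph, space = params@stateSpace,
                       u = params@config$u,
                       theta = list(c = branchLengths(params@graph),
                                    mu = params@mu, sigma2 = params@sigma2,
                                    kappa = tm@kappa, phi = tm@phi,
                                    zeta = tm@zeta, variant = tm@variant,
                                    a = tm@attractor))
    }
    theta <- params$theta
    theta$phi[is.na(theta$phi)] <- 0.5
    theta$zeta[is.na(theta$zeta)] <- 0.5
    engine <- .buildEngine(counts, params$graph, params$space,
                           mixScanConfig(u = params$u))
    .chainLogLik(theta, engine)
}
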