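#' Forward-backward pass of the migration-rate HMM
#'
#' Scaled forward-backward over the hidden states, with the chain restarting
#' from \code{init} at every chromosome break (chromosomes are independent
#' segments). Transition matrices are shared between loci with equal
#' (rescaled) inter-locus distance; \code{group} maps each locus to its
#' distance group.
#'
#' @param logE matrix (L x S) of log emission densities; \code{-Inf} allowed,
#'   but a locus with \code{-Inf} in every state is an error.
#' @param P list of S x S stochastic matrices, one per distance group; or a
#'   single matrix used for all transitions.
#' @param init initial state distribution (length S).
#' @param segStart logical length L, TRUE where a chromosome starts; default:
#'   only the first locus.
#' @param group integer length L mapping each locus to an element of \code{P}
#'   (the transition into that locus); ignored at segment starts.
#' @return list with \code{loglik} (total log-likelihood, summed over
#'   segments), \code{gamma} (L x S posterior state probabilities) and
#'   \code{xi} (per distance group, the S x S matrix of summed pairwise
#'   transition expectations).
#' @export
forwardBackward <- function(logE, P, init, segStart = NULL, group = NULL) {
    logE <- as.matrix(logE)
    L <- nrow(logE)
    if (is.matrix(P)) P <- list(P)
    if (is.null(segStart)) segStart <- c(TRUE, rep(FALSE, L - 1L))
    if (is.null(group)) group <- rep(1L, L)
    stopifnot(length(init) == ncol(logE), abs(sum(init) - 1) < 1e-8)
    .fbCpp(logE, P, as.integer(group), as.numeric(init), segStart)
}
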