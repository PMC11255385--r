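#' Posterior summaries of the migration-rate scan
#'
#' Collapses the product-state posteriors to per-edge summaries: the posterior
#' mean migration rate \eqn{\bar w_{il} = \sum_j w_{i j_i} P(z_l = j | d)},
#' the false-discovery scores for excess and dearth of introgression relative
#' to the attractor state,
#' \eqn{q_e(l) = 1 - P(z_l > a_i | d)} and \eqn{q_d(l) = 1 - P(z_l < a_i | d)},
#' and the MAP state. For ladder fits (no fitted attractor) the attractor is
#' replaced by the surrogate highest-stationary-probability state, with ties
#' broken by the highest mean posterior across loci, and flagged as a
#' surrogate.
#'
#' @param gamma matrix (L x S) of normalized state posteriors.
#' @param space the \linkS4class{HiddenStateSpace}.
#' @param attractor integer per-edge attractor grid index; \code{NA} entries
#'   request the surrogate.
#' @param stationary optional list of per-edge stationary distributions (used
#'   for the surrogate; uniform if missing).
#' @param logLik total log-likelihood to store.
#' @return a \linkS4class{PosteriorSummary}.
#' @export
posteriorSummaries <- function(gamma, space, attractor = NA, stationary = NULL,
                               logLik = NA_real_) {
    gamma <- as.matrix(gamma)
    I <- ncol(space@stateIndex)
    L <- nrow(gamma)
    attractor <- rep_len(as.integer(attractor), I)
    surrogate <- is.na(attractor)
    meanRate <- qe <- qd <- matrix(NA_real_, L, I)
    for (i in seq_len(I)) {
        rates <- space@grid@rates[[i]]
        J <- length(rates)
        A <- matrix(0, numStates(space), J)
        A[cbind(seq_len(numStates(space)), space@stateIndex[, i])] <- 1
        marg <- gamma %*% A                        # L x J marginal posteriors
        if (is.na(attractor[i])) {
            pstat <- if (is.null(stationary)) rep(1 / J, J) else stationary[[i]]
            best <- which(pstat > max(pstat) - 1e-12)
            if (length(best) > 1L)                  # tie: highest mean posterior
                best <- best[which.max(colMeans(marg)[best])]
            attractor[i] <- best[1]
        }
        a <- attractor[i]
        meanRate[, i] <- as.vector(marg %*% rates)
        qe[, i] <- 1 - if (a < J) rowSums(marg[, (a + 1):J, drop = FALSE]) else 0
        qd[, i] <- 1 - if (a > 1) rowSums(marg[, 1:(a - 1), drop = FALSE]) else 0
    }
    qe <- pmin(pmax(qe, 0), 1); qd <- pmin(pmax(qd, 0), 1)
    new("PosteriorSummary",
        statePosteriors = gamma, meanRate = meanRate, qe = qe, qd = qd,
        mapState = as.integer(max.col(gamma, ties.method = "first")),
        attractor = attractor, attractorSurrogate = surrogate,
        logLik = logLik)
}

#' @rdname posteriorSummaries
#' @param object a \linkS4class{PosteriorSummary}.
#' @export
meanMigrationRate <- function(object) object@meanRate
#' @rdname posteriorSummaries
#' @export
excessFDR <- function(object) object@qe
#' @rdname posteriorSummaries
#' @export
dearthFDR <- function(object) object@qd

setMethod("show", "PosteriorSummary", function(object) {
    cat(sprintf("PosteriorSummary: %d loci, %d state(s), %d edge(s)\n",
        nrow(object@statePosteriors), ncol(object@statePosteriors),
        ncol(object@meanRate)))
    cat(sprintf("attractor state(s): %s%s; logLik = %.4f\n",
        paste(object@attractor, collapse = ", "),
        if (any(object@attractorSurrogate)) " (surrogate)" else "",
        object@logLik))
})
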