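#' Migration-rate grid and hidden state space
#'
#' \code{MigrationGrid} holds one strictly increasing vector of discretized
#' rates in \code{[0, 1]} per migration edge (default: \code{J} equally spaced
#' rates from 0 to 1). \code{HiddenStateSpace} enumerates the product space of
#' the per-edge grids; the linear state order has the first edge's grid index
#' varying fastest.
#'
#' @param rates list of per-edge rate vectors, or a single vector recycled to
#'   all edges.
#' @param nEdges number of migration edges (needed when \code{rates} is a
#'   single vector).
#' @param J grid size used when \code{rates} is missing.
#' @export
MigrationGrid <- function(rates = NULL, nEdges = 1L, J = 21L) {
    if (is.null(rates)) rates <- seq(0, 1, length.out = J)
    if (!is.list(rates)) rates <- rep(list(rates), nEdges)
    obj <- new("MigrationGrid", rates = rates)
    validObject(obj)
    obj
}

setValidity("MigrationGrid", function(object) {
    for (r in object@rates) {
        if (any(r < 0 | r > 1)) return("grid rates must be in [0, 1]")
        if (is.unsorted(r, strictly = TRUE)) return("grid rates must be strictly increasing")
    }
    TRUE
})

#' @rdname MigrationGrid
#' @param grid a \linkS4class{MigrationGrid}.
#' @export
HiddenStateSpace <- function(grid) {
    if (!is(grid, "MigrationGrid")) grid <- MigrationGrid(grid)
    Js <- vapply(grid@rates, length, integer(1))
    idx <- as.matrix(expand.grid(lapply(Js, seq_len)))
    dimnames(idx) <- NULL
    rates <- vapply(seq_along(Js), function(i) grid@rates[[i]][idx[, i]],
                    numeric(nrow(idx)))
    rates <- matrix(rates, nrow = nrow(idx))
    new("HiddenStateSpace", grid = grid, stateIndex = idx, stateRates = rates)
}

#' @rdname MigrationGrid
#' @param space a \linkS4class{HiddenStateSpace}.
#' @export
numStates <- function(space) nrow(space@stateIndex)

setMethod("show", "HiddenStateSpace", function(object) {
    Js <- vapply(object@grid@rates, length, integer(1))
    cat(sprintf("HiddenStateSpace: %d state(s) = %s\n", numStates(object),
        paste(Js, collapse = " x ")))
})

#' Infinitesimal rate matrix of the migration-rate chain
#'
#' Ladder variant: transitions to neighbouring grid states only, at unit rate
#' (boundary rows \code{(-1, 1)} / \code{(1, -1)}, interior \code{(1, -2, 1)}).
#' Attractor variant: interior rows move toward the attractor state \code{a}
#' at rate \eqn{1 + \zeta} and away at \eqn{1 - \zeta}; the attractor row is
#' \eqn{(\ldots, \phi, -2\phi, \phi, \ldots)} (or \eqn{(-\phi, \phi)} at a
#' boundary); boundary rows keep unit rates. Both are valid generator
#' matrices: non-negative off-diagonals, zero row sums.
#'
#' @param J number of grid states (>= 2).
#' @param variant \code{"ladder"} or \code{"attractor"}.
#' @param phi,zeta attractor parameters in \code{(0, 1]}; this range
#'   guarantees the stationary mass of the attractor state exceeds that of
#'   every other state.
#' @param a attractor grid index in \code{1..J}.
#' @return a J x J rate matrix.
#' @export
rateMatrix <- function(J, variant = c("ladder", "attractor"),
                       phi = NULL, zeta = NULL, a = NULL) {
    variant <- match.arg(variant)
    stopifnot(J >= 2)
    L <- matrix(0, J, J)
    if (variant == "ladder") {
        for (j in seq_len(J)) {
            if (j > 1) L[j, j - 1] <- 1
            if (j < J) L[j, j + 1] <- 1
        }
    } else {
        stopifnot(!is.null(phi), !is.null(zeta), !is.null(a))
        if (!(a %in% seq_len(J))) stop("bad attractor index")
        if (phi <= 0 || phi > 1 || zeta <= 0 || zeta > 1)
            stop("phi and zeta must lie in (0, 1]")
        for (j in seq_len(J)) {
            if (j == a) {
                if (j > 1) L[j, j - 1] <- phi
                if (j < J) L[j, j + 1] <- phi
            } else if (j == 1) {
                L[j, j + 1] <- 1
            } else if (j == J) {
                L[j, j - 1] <- 1
            } else if (j < a) {
                L[j, j + 1] <- 1 + zeta   # toward the attractor
                L[j, j - 1] <- 1 - zeta
            } else {
                L[j, j - 1] <- 1 + zeta
                L[j, j + 1] <- 1 - zeta
            }
        }
    }
    diag(L) <- -rowSums(L)
    L
}

#' Stationary distribution of a migration-rate chain
#'
#' Both variants are birth-death chains, so the stationary law follows from
#' detailed balance. It is built outward from the mode (the attractor state,
#' or any state for the ladder), which stays well defined when
#' \eqn{\zeta = 1} sets some away-rates to zero. The ladder chain is
#' symmetric, hence uniform.
#'
#' @param Lambda a tridiagonal rate matrix from \code{\link{rateMatrix}}.
#' @param a index to build outward from (default: most stable choice).
#' @export
stationaryDistribution <- function(Lambda, a = NULL) {
    J <- nrow(Lambda)
    if (is.null(a)) a <- which.min(abs(diag(Lambda)))[1]
    p <- numeric(J); p[a] <- 1
    if (a > 1) for (j in (a - 1):1) {
        up <- Lambda[j, j + 1]
        p[j] <- if (up > 0) p[j + 1] * Lambda[j + 1, j] / up else 0
    }
    if (a < J) for (j in (a + 1):J) {
        dn <- Lambda[j, j - 1]
        p[j] <- if (dn > 0) p[j - 1] * Lambda[j - 1, j] / dn else 0
    }
    p / sum(p)
}

## Cached eigendecomposition so repeated exponentials over varying distances
## cost O(J^2) each. Falls back to NULL when the eigenbasis is ill-conditioned
## (e.g. zeta = 1 makes the chain reducible).
.rateEigen <- function(Lambda) {
    e <- tryCatch(eigen(Lambda), error = function(err) NULL)
    if (is.null(e)) return(NULL)
    if (max(abs(Im(e$values))) > 1e-8) return(NULL)
    V <- Re(e$vectors)
    Vi <- tryCatch(solve(V), error = function(err) NULL)
    if (is.null(Vi)) return(NULL)
    if (max(abs(V %*% Vi - diag(nrow(Lambda)))) > 1e-9) return(NULL)
    list(values = Re(e$values), V = V, Vi = Vi)
}

#' Distance-scaled transition matrix
#'
#' \eqn{P = \exp(\delta \kappa \Lambda)}, computed from a cached
#' eigendecomposition of \eqn{\Lambda} (supply \code{cache} when evaluating
#' many distances for one edge) with a scaling-and-squaring fallback
#' (\code{Matrix::expm}) when the eigenbasis is ill-conditioned.
#'
#' @param Lambda rate matrix.
#' @param kappa positive scaling rate.
#' @param delta positive inter-locus distance (already rescaled).
#' @param cache optional result of the internal eigendecomposition; computed
#'   on the fly if missing.
#' @return a stochastic matrix.
#' @export
transitionMatrix <- function(Lambda, kappa, delta, cache = NULL) {
    stopifnot(kappa > 0, delta >= 0)
    if (is.null(cache)) cache <- .rateEigen(Lambda)
    P <- NULL
    if (!is.null(cache)) {
        P <- cache$V %*% (exp(delta * kappa * cache$values) * cache$Vi)
        if (min(P) < -1e-9 || max(abs(rowSums(P) - 1)) > 1e-9) P <- NULL
    }
    if (is.null(P)) {
        P <- as.matrix(Matrix::expm(delta * kappa * Lambda))
        if (max(abs(rowSums(P) - 1)) > 1e-8) stop("transition failure")
    }
    P[P < 0] <- 0
    P / rowSums(P)
}

#' Joint transition matrix over the product state space
#'
#' Migration edges evolve independently, so the joint transition probability
#' factorizes: \eqn{P(j, j') = \prod_i P_i(j_i, j_i')}. The materialized form
#' is the Kronecker product in the state-space order (first edge fastest).
#' \code{applyJointTransition} applies the factorized product to a vector
#' without materializing the joint matrix (\code{transpose = TRUE} applies
#' \eqn{P'v}, as used in the forward recursion).
#'
#' @param Plist list with one per-edge transition matrix.
#' @export
jointTransitionMatrix <- function(Plist) {
    Reduce(function(a, b) kronecker(b, a), Plist)
}

#' @rdname jointTransitionMatrix
#' @param v vector over the product state space.
#' @param transpose apply the transposed operator.
#' @export
applyJointTransition <- function(Plist, v, transpose = FALSE) {
    Js <- vapply(Plist, nrow, integer(1))
    if (length(v) != prod(Js)) stop("dimension mismatch")
    arr <- array(v, dim = Js)
    nI <- length(Js)
    for (i in seq_len(nI)) {
        Pi <- if (transpose) t(Plist[[i]]) else Plist[[i]]
        perm <- c(i, setdiff(seq_len(nI), i))
        a2 <- aperm(array(arr, dim = Js), perm)
        m <- matrix(a2, nrow = Js[i])
        m2 <- Pi %*% m      # contracts the i-th index of v with P_i's columns
        arr <- aperm(array(m2, dim = Js[perm]), order(perm))
    }
    as.vector(arr)
}
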