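#' Construct a PopulationGraph
#'
#' Builds and validates a rooted admixture graph from its edge lists. Branches
#' are oriented parent to child; migration edges carry no length and their
#' target node must have a tree parent, so that every binary configuration of
#' open/closed migration edges resolves to a single-parent forest.
#'
#' @param root root node name.
#' @param branches data.frame with columns \code{parent}, \code{child} and
#'   optionally \code{length} (NA allowed; initialized by fitting).
#' @param leaves named character vector mapping leaf nodes to population
#'   labels.
#' @param migrations optional data.frame with columns \code{id}, \code{source},
#'   \code{target}.
#' @return a validated \linkS4class{PopulationGraph}.
#' @examples
#' g <- PopulationGraph(
#'     root = "R",
#'     branches = data.frame(parent = c("R", "R"), child = c("P1", "P2"),
#'                           length = c(0.03, 0.02)),
#'     leaves = c(P1 = "pop1", P2 = "pop2"))
#' numBranches(g)
#' @export
PopulationGraph <- function(root, branches, leaves, migrations = NULL) {
    stopifnot(is.data.frame(branches), all(c("parent", "child") %in% names(branches)))
    if (is.null(branches$length)) branches$length <- NA_real_
    if (is.null(migrations)) {
        migrations <- data.frame(id = character(), source = character(),
                                 target = character())
    }
    nodes <- unique(c(root, branches$parent, branches$child))
    parent <- setNames(as.character(branches$parent), as.character(branches$child))
    ids <- as.character(migrations$id)
    if (length(ids) == 0L) ids <- character()
    g <- new("PopulationGraph",
        nodes = nodes, root = root, parent = parent,
        branchChild = as.character(branches$child),
        branchLength = setNames(as.numeric(branches$length),
                                as.character(branches$child)),
        migSource = setNames(as.character(migrations$source), ids),
        migTarget = setNames(as.character(migrations$target), ids),
        leafPop = leaves)
    validObject(g)
    g
}

setValidity("PopulationGraph", function(object) {
    msg <- character()
    if (length(object@root) != 1L)
        msg <- c(msg, "exactly one root required")
    nonroot <- setdiff(object@nodes, object@root)
    if (!all(nonroot %in% names(object@parent)))
        msg <- c(msg, "every non-root node must have exactly one tree parent")
    if (object@root %in% names(object@parent))
        msg <- c(msg, "root must not have a tree parent")
    if (anyDuplicated(names(object@parent)))
        msg <- c(msg, "a node has more than one tree parent")
    if (!all(object@parent %in% object@nodes))
        msg <- c(msg, "branch parent not a declared node")
    if (!setequal(object@branchChild, names(object@parent)) && length(msg) == 0L)
        msg <- c(msg, "branch list does not match parent map")
    ## tree part must be cycle-free and reach the root
    for (v in names(object@parent)) {
        seen <- character(); cur <- v
        while (cur != object@root) {
            if (cur %in% seen) return("cyclic graph (tree branches)")
            seen <- c(seen, cur)
            if (!cur %in% names(object@parent)) return("cyclic graph (node detached from root)")
            cur <- object@parent[[cur]]
        }
    }
    ## migration edges
    I <- length(object@migSource)
    if (I > 0L) {
        bad <- !(object@migSource %in% object@nodes) |
               !(object@migTarget %in% object@nodes) |
               !(object@migTarget %in% names(object@parent))
        if (any(bad)) msg <- c(msg, "dangling edge")
        if (anyDuplicated(object@migTarget))
            msg <- c(msg, "multiple migration edges share a target node")
    }
    ## leaves
    if (anyDuplicated(object@leafPop)) msg <- c(msg, "label clash")
    if (!all(names(object@leafPop) %in% object@nodes))
        msg <- c(msg, "leaf node not in graph")
    kids <- unique(object@parent)
    if (any(names(object@leafPop) %in% kids))
        msg <- c(msg, "leaf node has children")
    ## acyclicity under every configuration (cheap for the supported I)
    if (length(msg) == 0L && I > 0L && I <= 12L) {
        B <- .allConfigurations(I)
        for (r in seq_len(nrow(B))) {
            if (.configurationHasCycle(object, B[r, ])) {
                msg <- c(msg, "cyclic graph"); break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname PopulationGraph-accessors
#' @export
numPopulations <- function(graph) length(graph@leafPop)
#' @rdname PopulationGraph-accessors
#' @export
numBranches <- function(graph) length(graph@branchChild)
#' Graph accessors
#'
#' \code{numPopulations}, \code{numBranches} and \code{numMigrationEdges}
#' return M, K and I; \code{branchLengths} returns/sets the drift lengths
#' \eqn{c_k} (named by branch child node); \code{leafPopulations} the
#' leaf-to-population map.
#' @param graph,value a \linkS4class{PopulationGraph} / replacement lengths.
#' @name PopulationGraph-accessors
#' @export
numMigrationEdges <- function(graph) length(graph@migSource)
#' @rdname PopulationGraph-accessors
#' @export
branchLengths <- function(graph) graph@branchLength
#' @rdname PopulationGraph-accessors
#' @export
`branchLengths<-` <- function(graph, value) {
    stopifnot(length(value) == length(graph@branchLength))
    graph@branchLength[] <- as.numeric(value)
    graph
}
#' @rdname PopulationGraph-accessors
#' @export
leafPopulations <- function(graph) graph@leafPop

setMethod("show", "PopulationGraph", function(object) {
    cat(sprintf("PopulationGraph: %d populations, %d branches, %d migration edge(s)\n",
        numPopulations(object), numBranches(object), numMigrationEdges(object)))
    cat("root:", object@root, "\n")
    if (numMigrationEdges(object) > 0L) {
        cat("migration:", paste(sprintf("%s: %s -> %s", names(object@migSource),
            object@migSource, object@migTarget), collapse = ", "), "\n")
    }
    cl <- object@branchLength
    cat("branch lengths:",
        if (all(is.na(cl))) "unset" else
        paste(sprintf("%s=%.4g", names(cl), cl), collapse = ", "), "\n")
})

## all 2^I binary configurations, one per row, edge 1 in column 1
.allConfigurations <- function(I) {
    if (I == 0L) return(matrix(integer(), nrow = 1L, ncol = 0L))
    as.matrix(rev(expand.grid(rev(lapply(seq_len(I), function(i) 0:1)))))
}

## effective parent map for configuration b: open migration edges replace the
## tree parent of their target node
.effectiveParent <- function(graph, b) {
    par <- graph@parent
    via <- setNames(rep(NA_integer_, length(par)), names(par))
    open <- which(b == 1)
    for (i in open) {
        tgt <- graph@migTarget[[i]]
        par[[tgt]] <- graph@migSource[[i]]
        via[[tgt]] <- i
    }
    list(parent = par, migEdge = via)
}

.configurationHasCycle <- function(graph, b) {
    par <- .effectiveParent(graph, b)$parent
    nmax <- length(graph@nodes)
    for (v in names(par)) {
        cur <- v; steps <- 0L
        while (cur != graph@root) {
            if (!cur %in% names(par)) break   # detached: not a cycle
            cur <- par[[cur]]
            steps <- steps + 1L
            if (steps > nmax) return(TRUE)
        }
    }
    FALSE
}

#' Resolve a migration configuration to root paths
#'
#' For a binary configuration \code{b} over the migration edges, each target
#' node's effective parent is the migration source when the edge is open
#' (\code{b[i] == 1}) and the tree parent otherwise. In the resulting
#' single-parent forest every leaf has at most one path to the root; the
#' function returns, per leaf, the set of tree branches (identified by their
#' child nodes) on that path. Migration edges themselves carry no branch. An
#' empty set encodes a leaf disconnected from the root.
#'
#' @param graph a \linkS4class{PopulationGraph}.
#' @param b integer vector of 0/1 of length \code{numMigrationEdges(graph)}.
#' @return named list (by population label) of character vectors of branch
#'   child nodes.
#' @export
resolveConfiguration <- function(graph, b) {
    if (length(b) != numMigrationEdges(graph))
        stop("dimension error: |b| must equal the number of migration edges")
    ep <- .effectiveParent(graph, b)
    nmax <- length(graph@nodes) + 1L
    out <- vector("list", numPopulations(graph))
    names(out) <- unname(graph@leafPop)
    for (m in seq_along(graph@leafPop)) {
        leaf <- names(graph@leafPop)[m]
        path <- character(); cur <- leaf; steps <- 0L; ok <- TRUE
        while (cur != graph@root) {
            if (!cur %in% names(ep$parent)) { ok <- FALSE; break }
            if (is.na(ep$migEdge[[cur]])) path <- c(path, cur)
            cur <- ep$parent[[cur]]
            steps <- steps + 1L
            if (steps > nmax) { ok <- FALSE; break }
        }
        out[[m]] <- if (ok) path else character()
    }
    out
}

#' Probability of a migration configuration
#'
#' \eqn{w(b) = \prod_i w_i^{b_i} (1-w_i)^{1-b_i}}: each migration edge is open
#' independently with its rate.
#'
#' @param w per-edge rates in \code{[0, 1]}.
#' @param b binary vector of the same length.
#' @export
configurationProbability <- function(w, b) {
    if (length(w) != length(b)) stop("dimension error")
    stopifnot(all(w >= 0 & w <= 1), all(b %in% c(0, 1)))
    prod(ifelse(b == 1, w, 1 - w))
}

## Precompute, per graph, everything needed to evaluate W(c, w) fast:
## B (2^I x I configurations) and the indicator array I_mk(b) flattened to an
## (M*K) x 2^I matrix, so that p_mk(w) is a single matrix-vector product.
.configStructure <- function(graph, maxEdges = 12L) {
    I <- numMigrationEdges(graph)
    if (I > maxEdges)
        stop("too many migration edges (", I, "); enumeration capped at ",
             maxEdges, " (override with maxEdges)")
    M <- numPopulations(graph); K <- numBranches(graph)
    B <- .allConfigurations(I)
    nb <- nrow(B)
    Imat <- matrix(0, nrow = M * K, ncol = nb)
    for (r in seq_len(nb)) {
        paths <- resolveConfiguration(graph, B[r, ])
        ind <- matrix(0, M, K)
        for (m in seq_len(M))
            ind[m, match(paths[[m]], graph@branchChild)] <- 1
        Imat[, r] <- as.vector(ind)
    }
    list(B = B, Imat = Imat, M = M, K = K, I = I,
         populations = unname(graph@leafPop))
}

.configWeights <- function(B, w) {
    nb <- nrow(B)
    wb <- rep(1, nb)
    for (i in seq_along(w))
        wb <- wb * ifelse(B[, i] == 1, w[i], 1 - w[i])
    wb
}

## marginal branch-inclusion probabilities p_mk = sum_b w(b) I_mk(b), M x K
.branchInclusion <- function(struct, w) {
    wb <- .configWeights(struct$B, w)
    matrix(struct$Imat %*% wb, struct$M, struct$K)
}

#' Drift variance-covariance matrix of an admixture graph
#'
#' Computes the expected covariance \eqn{W} of arcsine-transformed allele
#' frequencies at the leaves: per-leaf marginal branch-inclusion probabilities
#' \eqn{p_{mk} = \sum_b w(b) I_{mk}(b)} over all \eqn{2^I} configurations,
#' per-branch sharing matrices \eqn{[J_k]_{mn} = p_{mk} p_{nk}} and
#' \eqn{W = \sum_k c_k J_k}. \eqn{W} depends only on the topology, branch
#' lengths and migration rates.
#'
#' Negative branch lengths are accepted (they arise as a diagnostic of
#' overparameterized graphs during fitting) but yield a possibly non-PSD
#' matrix; emission code guards positive definiteness downstream.
#'
#' @param graph a \linkS4class{PopulationGraph}.
#' @param c branch lengths in branch order (default: the graph's own).
#' @param w per-edge migration rates in \code{[0, 1]}.
#' @param full if TRUE also return the sharing matrices \code{J} and the
#'   inclusion probabilities \code{p}.
#' @param maxEdges enumeration cap on the number of migration edges.
#' @return the M x M matrix \code{W} (populations in leaf order), or a list
#'   \code{(W, J, p)} when \code{full = TRUE}.
#' @examples
#' g <- PopulationGraph("R",
#'     data.frame(parent = c("R", "R"), child = c("P1", "P2"),
#'                length = c(0.03, 0.02)),
#'     leaves = c(P1 = "pop1", P2 = "pop2"))
#' driftCovariance(g)
#' @export
driftCovariance <- function(graph, c = branchLengths(graph), w = numeric(),
                            full = FALSE, maxEdges = 12L) {
    struct <- .configStructure(graph, maxEdges = maxEdges)
    if (length(c) != struct$K) stop("dimension error: |c| != K")
    if (length(w) != struct$I) stop("dimension error: |w| != I")
    stopifnot(all(w >= 0 & w <= 1), !anyNA(c))
    p <- .branchInclusion(struct, w)
    W <- .covFromInclusion(p, c)
    dimnames(W) <- list(struct$populations, struct$populations)
    if (!full) return(W)
    J <- lapply(seq_len(struct$K), function(k) tcrossprod(p[, k]))
    list(W = W, J = J, p = p)
}

.covFromInclusion <- function(p, c) {
    W <- p %*% (c * t(p))
    (W + t(W)) / 2
}

#' Orient an opposed (bidirectional) pair of migration edges
#'
#' Bidirectional migration between two branches is modelled as two opposed
#' migration edges whose attachment nodes are ordered by an inserted
#' zero-length branch, so that no open/closed configuration creates a cycle:
#' the source of one edge is made to precede the target of the other. Pairs
#' sharing both endpoint nodes in opposite orientation are rewired; graphs
#' with no such pair are returned unchanged.
#'
#' @param graph a \linkS4class{PopulationGraph} (possibly not yet valid if an
#'   opposed pair shares its attachment nodes).
#' @return a valid \linkS4class{PopulationGraph}.
#' @export
expandBidirectional <- function(graph) {
    src <- graph@migSource; tgt <- graph@migTarget
    I <- length(src)
    if (I == 0L) return(graph)
    done <- logical(I)
    for (i in seq_len(I)) {
        if (done[i]) next
        opp <- which(!done & src == tgt[i] & tgt == src[i])
        opp <- setdiff(opp, i)
        if (length(opp) == 0L) next
        if (length(opp) > 1L)
            stop("cannot orient bidirectional pair: more than two opposed edges")
        j <- opp[1]
        ## tau_i: x -> y, tau_j: y -> x. Split x: insert child node below x via
        ## a zero-length branch, move x's subtree there, and point tau_j at it,
        ## so the source of tau_i precedes the target of tau_j.
        x <- src[i][[1]]
        newnode <- paste0(x, "..in")
        while (newnode %in% graph@nodes) newnode <- paste0(newnode, ".")
        kids <- names(graph@parent)[graph@parent == x]
        graph@parent[kids] <- newnode
        graph@parent[[newnode]] <- x
        graph@nodes <- c(graph@nodes, newnode)
        graph@branchChild <- c(graph@branchChild, newnode)
        graph@branchLength <- c(graph@branchLength, setNames(0, newnode))
        graph@migTarget[[j]] <- newnode
        if (x %in% names(graph@leafPop)) {
            ## leaf target: the population now hangs below the inserted node
            names(graph@leafPop)[names(graph@leafPop) == x] <- newnode
            graph@parent[[newnode]] <- x
        }
        done[c(i, j)] <- TRUE
    }
    tryCatch(validObject(graph),
             error = function(e) stop("cannot orient bidirectional pair: ",
                                      conditionMessage(e)))
    graph
}
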