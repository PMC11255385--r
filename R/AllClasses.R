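#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats cov dnorm optim optimize rbinom rnorm runif setNames
#' @importFrom stats plogis qlogis rgamma approx median
#' @importFrom utils read.table write.table head tail
NULL

#' PopulationGraph: a rooted admixture graph
#'
#' A rooted population graph with \code{K} oriented branches (each with a drift
#' length \eqn{c_k}, dimensionless drift units), \code{I} oriented migration
#' edges (no length) and \code{M} leaves mapped to population labels. Branches
#' are identified by their child node; the branch order fixes the order of the
#' branch-length vector used throughout.
#'
#' @slot nodes character vector of node identifiers.
#' @slot root the root node identifier.
#' @slot parent named character vector mapping each non-root node to its tree
#'   parent.
#' @slot branchChild child nodes defining branch order \code{k = 1..K}.
#' @slot branchLength numeric branch lengths \eqn{c_k}, named by child node.
#'   May contain \code{NA} for lengths to be initialized by fitting.
#' @slot migSource,migTarget character vectors (length \code{I}) of migration
#'   edge endpoints; names are the edge identifiers.
#' @slot leafPop named character vector mapping leaf nodes to population labels.
#'
#' @export
setClass("PopulationGraph",
    representation(
        nodes = "character",
        root = "character",
        parent = "character",
        branchChild = "character",
        branchLength = "numeric",
        migSource = "character",
        migTarget = "character",
        leafPop = "character"
    )
)

#' AlleleCounts: per-locus, per-population allele counts
#'
#' Extends \linkS4class{RangedSummarizedExperiment}: rows are loci (with
#' genomic positions in \code{rowRanges}), columns are populations, and the
#' two assays \code{"n"} (derived allele count) and \code{"N"} (total observed
#' alleles) hold the data. Loci must be sorted by (chromosome, position).
#'
#' @export
setClass("AlleleCounts", contains = "RangedSummarizedExperiment")

#' SampleSizeClusters: clustered per-locus sampling variance matrices
#'
#' Representatives of the per-locus total-allele vectors after iterative
#' merging of the rarest vectors, with the per-locus assignment. The
#' representative vectors define the diagonal sampling covariances
#' \eqn{\Sigma_u = diag(1/N_{u1}, ..., 1/N_{uM})}.
#'
#' @slot representatives numeric matrix (u x M) of (weighted-average) totals.
#' @slot counts integer occurrence count per representative.
#' @slot assignment integer vector mapping each locus to a representative row.
#' @export
setClass("SampleSizeClusters",
    representation(
        representatives = "matrix",
        counts = "numeric",
        assignment = "integer"
    )
)

#' MigrationGrid: discretized per-edge migration rates
#'
#' @slot rates list with one strictly increasing numeric vector of rates in
#'   \code{[0, 1]} per migration edge.
#' @export
setClass("MigrationGrid", representation(rates = "list"))

#' HiddenStateSpace: product space over per-edge migration grids
#'
#' States are multi-indices \eqn{j = (j_1, ..., j_I)} over the per-edge grids;
#' the linear state order has the first edge's index varying fastest.
#'
#' @slot grid a \linkS4class{MigrationGrid}.
#' @slot stateIndex integer matrix (S x I) of per-edge grid indices.
#' @slot stateRates numeric matrix (S x I) of per-edge rates.
#' @export
setClass("HiddenStateSpace",
    representation(
        grid = "MigrationGrid",
        stateIndex = "matrix",
        stateRates = "matrix"
    )
)

#' TransitionModel: per-edge continuous-time transition kernels
#'
#' Each migration edge carries a ladder-type rate matrix (moves between
#' neighbouring grid states only) or an attractor variant in which the chain
#' drifts toward a distinguished background state \code{a} at rate
#' \eqn{1+\zeta} and away at \eqn{1-\zeta}, leaving the attractor at rate
#' \eqn{\phi}. Transition probabilities over distance \eqn{\delta} are
#' \eqn{P = \exp(\delta \kappa \Lambda)}.
#'
#' @slot variant character, \code{"ladder"} or \code{"attractor"} per edge.
#' @slot kappa positive scaling rate per edge.
#' @slot phi,zeta attractor parameters in \code{(0, 1]} (NA for ladder edges).
#' @slot attractor integer grid index of the attractor state (NA for ladder).
#' @export
setClass("TransitionModel",
    representation(
        variant = "character",
        kappa = "numeric",
        phi = "numeric",
        zeta = "numeric",
        attractor = "integer"
    )
)

#' MixtureInit: Gaussian-mixture initialization of the drift covariance
#'
#' @slot R number of mixture components.
#' @slot pi component weights.
#' @slot mu,sigma2 shared root-prior parameters used during the fit.
#' @slot W list of per-component excess covariance matrices (sampling and
#'   root-prior parts removed, projected to the nearest PSD matrix).
#' @slot assignment integer MAP component per locus.
#' @slot logLik final mixture log-likelihood.
#' @slot trace per-iteration log-likelihoods (non-decreasing).
#' @export
setClass("MixtureInit",
    representation(
        R = "integer",
        pi = "numeric",
        mu = "numeric",
        sigma2 = "numeric",
        W = "list",
        assignment = "integer",
        logLik = "numeric",
        trace = "numeric"
    )
)

#' MixScanFit: fitted model parameters
#'
#' @slot graph the \linkS4class{PopulationGraph} with fitted branch lengths.
#' @slot mu,sigma2 fitted root prior (arcsine scale; \code{mu}'s sign depends
#'   on the chosen allele polarization).
#' @slot transition fitted \linkS4class{TransitionModel}.
#' @slot stateSpace the \linkS4class{HiddenStateSpace} used.
#' @slot logLik final log-likelihood; \code{trace} the accepted per-iteration
#'   log-likelihoods.
#' @slot niter,converged Baum-Welch iteration count and convergence flag.
#' @slot negativeBranch TRUE if any fitted branch length is below -1e-3 drift
#'   units, i.e. negative beyond estimation noise (a diagnostic for a graph
#'   with too many degrees of freedom).
#' @slot distanceScale the genome-wide mean inter-locus distance used to
#'   rescale distances before exponentiation (kappa absorbs the scale).
#' @slot config list of fitting options used.
#' @export
setClass("MixScanFit",
    representation(
        graph = "PopulationGraph",
        mu = "numeric",
        sigma2 = "numeric",
        transition = "TransitionModel",
        stateSpace = "HiddenStateSpace",
        logLik = "numeric",
        trace = "numeric",
        niter = "integer",
        converged = "logical",
        negativeBranch = "logical",
        distanceScale = "numeric",
        config = "list"
    )
)

#' PosteriorSummary: per-locus posterior state summaries
#'
#' @slot statePosteriors numeric matrix (L x S) of state posteriors.
#' @slot meanRate posterior mean migration rate per locus and edge (L x I).
#' @slot qe,qd false-discovery scores for excess / dearth of introgression
#'   relative to the attractor state (L x I).
#' @slot mapState maximum-a-posteriori state index per locus.
#' @slot attractor per-edge attractor grid index the q-values refer to.
#' @slot attractorSurrogate TRUE per edge when the fit used a ladder kernel
#'   and the attractor was inferred as the surrogate highest-stationary-mass
#'   state rather than fitted.
#' @slot logLik total log-likelihood of the chain at the fitted parameters.
#' @export
setClass("PosteriorSummary",
    representation(
        statePosteriors = "matrix",
        meanRate = "matrix",
        qe = "matrix",
        qd = "matrix",
        mapState = "integer",
        attractor = "integer",
        attractorSurrogate = "logical",
        logLik = "numeric"
    )
)
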