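#' Read an admixture graph from a plain-text file
#'
#' One record per line, \code{'#'} starts a comment. Records:
#' \preformatted{
#'   NODE <name>                       # optional pre-declaration
#'   ROOT <name>
#'   BRANCH <parent> <child> [length]  # length optional (fitted if absent)
#'   MIG <id> <source> <target>
#'   LEAF <node> <population>
#' }
#' Opposed pairs of migration edges (bidirectional migration) are oriented
#' automatically via \code{\link{expandBidirectional}} before validation.
#'
#' @param file path to the graph file, or a character vector of lines via
#'   \code{text}.
#' @param text optional character vector of lines (overrides \code{file}).
#' @return a validated \linkS4class{PopulationGraph}.
#' @export
readPopulationGraph <- function(file, text = NULL) {
    lines <- if (!is.null(text)) text else readLines(file)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    root <- NULL
    br <- list(); mig <- list(); leaves <- character()
    for (ln in lines) {
        tok <- strsplit(ln, "[[:space:]]+")[[1]]
        kw <- toupper(tok[1])
        if (kw == "NODE") {
            next  # declaration only; nodes are collected from edges
        } else if (kw == "ROOT") {
            if (!is.null(root)) stop("graph file: multiple ROOT records")
            root <- tok[2]
        } else if (kw == "BRANCH") {
            if (length(tok) < 3) stop("graph file: BRANCH needs parent and child")
            br[[length(br) + 1L]] <- data.frame(
                parent = tok[2], child = tok[3],
                length = if (length(tok) >= 4) as.numeric(tok[4]) else NA_real_)
        } else if (kw == "MIG") {
            if (length(tok) < 4) stop("graph file: MIG needs id, source, target")
            mig[[length(mig) + 1L]] <- data.frame(
                id = tok[2], source = tok[3], target = tok[4])
        } else if (kw == "LEAF") {
            if (length(tok) < 3) stop("graph file: LEAF needs node and population")
            leaves[tok[2]] <- tok[3]
        } else stop("graph file: unknown record '", tok[1], "'")
    }
    if (is.null(root)) stop("graph file: no ROOT record")
    if (length(br) == 0L) stop("graph file: no BRANCH records")
    branches <- do.call(rbind, br)
    migrations <- if (length(mig)) do.call(rbind, mig) else NULL
    ## build the migration-free tree first (validated), then attach migration
    ## edges and orient opposed pairs before the full validation
    g <- PopulationGraph(root, branches, leaves)
    if (!is.null(migrations)) {
        ids <- as.character(migrations$id)
        g@migSource <- setNames(as.character(migrations$source), ids)
        g@migTarget <- setNames(as.character(migrations$target), ids)
        g <- expandBidirectional(g)
    }
    validObject(g)
    g
}

#' Write a PopulationGraph to the plain-text graph format
#'
#' @param graph a \linkS4class{PopulationGraph}.
#' @param file output path or connection.
#' @export
writePopulationGraph <- function(graph, file) {
    lines <- c(paste("ROOT", graph@root),
        vapply(seq_along(graph@branchChild), function(k) {
            ch <- graph@branchChild[k]
            len <- graph@branchLength[[ch]]
            if (is.na(len)) paste("BRANCH", graph@parent[[ch]], ch)
            else sprintf("BRANCH %s %s %.12g", graph@parent[[ch]], ch, len)
        }, character(1)),
        if (numMigrationEdges(graph) > 0)
            sprintf("MIG %s %s %s", names(graph@migSource),
                    graph@migSource, graph@migTarget),
        sprintf("LEAF %s %s", names(graph@leafPop), graph@leafPop))
    writeLines(lines, file)
    invisible(file)
}
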