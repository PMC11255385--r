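# Shared fixture graphs, built in code.

twoPopGraph <- function() {
    PopulationGraph("R",
        data.frame(parent = c("R", "R"), child = c("P1", "P2"),
                   length = c(0.03, 0.02)),
        leaves = c(P1 = "pop1", P2 = "pop2"))
}

# two populations with one migration edge between internal nodes
twoPopMigGraph <- function(lens = c(s = 0.02, P1 = 0.01, t = 0.015, P2 = 0.005)) {
    readPopulationGraph(text = c(
        "ROOT R",
        sprintf("BRANCH R s %g", lens[["s"]]),
        sprintf("BRANCH s P1 %g", lens[["P1"]]),
        sprintf("BRANCH R t %g", lens[["t"]]),
        sprintf("BRANCH t P2 %g", lens[["P2"]]),
        "MIG m1 s t",
        "LEAF P1 pop1", "LEAF P2 pop2"))
}

# four populations, migration from a node ancestral to P2 into the P3 tip
fourPopTipGraph <- function() {
    readPopulationGraph(text = c(
        "ROOT R",
        "BRANCH R A 0.02", "BRANCH A P1 0.04",
        "BRANCH A s 0.015", "BRANCH s P2 0.025",
        "BRANCH R B 0.02", "BRANCH B P3 0.03", "BRANCH B P4 0.04",
        "MIG m1 s P3",
        "LEAF P1 pop1", "LEAF P2 pop2", "LEAF P3 pop3", "LEAF P4 pop4"))
}

# same but the edge ends ancestral to P3 (splitting its branch), the
# constant-migration nonidentifiable case; the split branches are kept well
# away from zero so sign flips indicate the ridge, not estimation noise
fourPopInternalGraph <- function() {
    readPopulationGraph(text = c(
        "ROOT R",
        "BRANCH R A 0.02", "BRANCH A P1 0.04",
        "BRANCH A s 0.02", "BRANCH s P2 0.025",
        "BRANCH R B 0.02", "BRANCH B t 0.02", "BRANCH t P3 0.025",
        "BRANCH B P4 0.04",
        "MIG m1 s t",
        "LEAF P1 pop1", "LEAF P2 pop2", "LEAF P3 pop3", "LEAF P4 pop4"))
}

randomSmallGraph <- function(M = 3, I = 1) {
    # caterpillar tree over M leaves with I migration edges between distinct
    # pendant branches (sources pre-split), random lengths
    stopifnot(M >= 2, I <= M %/% 2)
    lines <- c("ROOT R")
    prev <- "R"
    for (m in seq_len(M - 1)) {
        nd <- paste0("N", m)
        lines <- c(lines,
            sprintf("BRANCH %s %s %.4f", prev, nd, runif(1, 0.005, 0.05)),
            sprintf("BRANCH %s P%d %.4f", nd, m, runif(1, 0.005, 0.05)))
        prev <- nd
    }
    lines <- c(lines, sprintf("BRANCH %s P%d %.4f", prev, M, runif(1, 0.005, 0.05)))
    for (i in seq_len(I)) {
        src <- paste0("N", 2 * i - 1)
        tgt <- paste0("P", 2 * i)
        lines <- c(lines, sprintf("MIG m%d %s %s", i, src, tgt))
    }
    lines <- c(lines, sprintf("LEAF P%d pop%d", seq_len(M), seq_len(M)))
    readPopulationGraph(text = lines)
}
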