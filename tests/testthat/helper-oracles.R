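# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (double loops, exhaustive enumeration)
# so agreement is evidence, not tautology.

# TOM by direct double-loop evaluation of the formula.
bruteTom <- function(a) {
    n <- nrow(a)
    k <- rowSums(a) - diag(a)
    tom <- diag(n)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) next
            l <- 0
            for (u in seq_len(n)) {
                if (u != i && u != j) l <- l + a[i, u] * a[u, j]
            }
            tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
        }
    }
    dimnames(tom) <- dimnames(a)
    tom
}

# All maximal cliques of a small graph by scanning every vertex subset.
bruteMaximalCliques <- function(adjMat) {
    n <- nrow(adjMat)
    stopifnot(n <= 14)
    nodes <- rownames(adjMat)
    isClique <- function(idx) {
        if (length(idx) <= 1L) return(TRUE)
        all(adjMat[idx, idx][upper.tri(diag(length(idx)))] == 1)
    }
    cliques <- list()
    for (code in seq_len(2^n - 1L)) {
        idx <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
        if (!isClique(idx)) next
        extendable <- any(vapply(setdiff(seq_len(n), idx), function(v) {
            all(adjMat[v, idx] == 1)
        }, logical(1)))
        if (!extendable) cliques[[length(cliques) + 1L]] <- sort(nodes[idx])
    }
    key <- vapply(cliques, paste, character(1), collapse = "\r")
    cliques[order(lengths(cliques), key)]
}

bruteMcc <- function(adjMat, singletonScore = 1) {
    cl <- bruteMaximalCliques(adjMat)
    score <- stats::setNames(numeric(nrow(adjMat)), rownames(adjMat))
    for (cc in cl) {
        score[cc] <- score[cc] +
            if (length(cc) == 1L) singletonScore else factorial(length(cc) - 1L)
    }
    score
}

randomGraph <- function(n, pEdge, seed) {
    set.seed(seed)
    adjMat <- matrix(0L, n, n,
                     dimnames = list(paste0("v", seq_len(n)),
                                     paste0("v", seq_len(n))))
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            if (runif(1) < pEdge) adjMat[i, j] <- adjMat[j, i] <- 1L
        }
    }
    adjMat
}

graphFromAdj <- function(adjMat) {
    igraph::graph_from_adjacency_matrix(adjMat, mode = "undirected")
}

# Exact-rational hypergeometric upper-tail values, frozen from integer
# arithmetic (tail numerator summed exactly, divided exactly): k, K, n, N, p.
exactHyperCases <- rbind(
    c(5L, 5L, 5L, 10L, 0.003968253968253968),
    c(1L, 2L, 2L, 4L, 0.8333333333333334),
    c(0L, 3L, 4L, 20L, 1.0),
    c(3L, 10L, 5L, 100L, 0.0066379128971176095),
    c(7L, 20L, 30L, 60L, 0.9730513971085855),
    c(2L, 4L, 6L, 12L, 0.7272727272727273),
    c(10L, 15L, 20L, 40L, 0.09539628616380563),
    c(1L, 50L, 2L, 60L, 0.9745762711864406),
    c(25L, 30L, 30L, 60L, 1.7820777368954872e-07),
    c(4L, 8L, 8L, 16L, 0.6903651903651904))

# Locate the exact-arithmetic oracle interpreter (same image as the tests).
pythonBin <- function() {
    p <- Sys.which(c("python", "python3"))
    p <- p[nzchar(p)]
    if (length(p)) p[[1]] else ""
}

hypergeomOracleScript <- function() {
    system.file("tools", "hypergeom_oracle.py", package = "coexAge")
}

# ARI between two labelings (independent implementation kept out of the
# package; mclust's version cross-checks it in the acceptance suite).
ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

# default planted-cohort module set: 10 modules with mutually
# distinguishable age trends (distinct linear slopes standardize to the
# same trend, so only one linear module is planted; the breakpoint module
# uses a rise-and-fall trajectory whose trend is nearly uncorrelated with
# the linear one)
recoveryModules <- function(nGenes = 50, nHubs = 1,
                            eigengeneNoiseSd = 0.3, geneNoiseSd = 0.5) {
    c(lapply(1:8, function(i) {
        moduleSpec(paste0("none", i), nGenes, nHubs = nHubs,
                   eigengeneNoiseSd = eigengeneNoiseSd,
                   geneNoiseSd = geneNoiseSd)
    }),
    list(moduleSpec("lin", nGenes, ageEffect = ageEffectLinear(0.05),
                    nHubs = nHubs, eigengeneNoiseSd = eigengeneNoiseSd,
                    geneNoiseSd = geneNoiseSd),
         moduleSpec("tent", nGenes,
                    ageEffect = ageEffectBreakpoint(57, 0.1, -0.1),
                    nHubs = nHubs, eigengeneNoiseSd = eigengeneNoiseSd,
                    geneNoiseSd = geneNoiseSd)))
}
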