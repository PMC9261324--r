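#' Induced subgraph on a gene list
#'
#' Restricts a PPI graph to the requested genes (absent genes are ignored
#' with a warning); edges survive when both endpoints are retained.
#'
#' @param graph undirected simple \code{igraph} graph.
#' @param genes gene IDs to keep.
#' @return the induced \code{igraph} subgraph.
#' @export
inducedSubgraph <- function(graph, genes) {
    present <- intersect(genes, igraph::V(graph)$name)
    absent <- setdiff(genes, present)
    if (length(absent)) {
        warning(length(absent), " gene(s) absent from the graph, e.g. ",
                paste(head(absent, 3L), collapse = ", "))
    }
    if (!length(present)) stop("no requested gene is present in the graph")
    igraph::induced_subgraph(graph, present)
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of a simple undirected graph (Bron--Kerbosch with
#' pivoting, via igraph), each returned once as a sorted member vector;
#' isolated nodes yield singleton cliques. Output order is canonical:
#' by size, then lexicographically.
#'
#' @param graph undirected simple \code{igraph} graph.
#' @param maxNodes guard against exponential blow-up: refuse graphs with
#'   more than this many nodes (default 2000).
#' @return list of character vectors (clique members, sorted).
#' @export
maximalCliques <- function(graph, maxNodes = 2000L) {
    n <- igraph::vcount(graph)
    if (n > maxNodes) {
        stop("graph has ", n, " nodes; maximal-clique enumeration is ",
             "exponential in the worst case. Raise maxNodes to force it.")
    }
    cl <- igraph::max_cliques(graph, min = 1L)
    cl <- lapply(cl, function(v) sort(igraph::V(graph)$name[v]))
    key <- vapply(cl, paste, character(1), collapse = "\r")
    cl[order(lengths(cl), key)]
}

#' Maximal clique centrality (MCC) scores
#'
#' \deqn{MCC(v) = \sum_{C \in S(v)} (|C| - 1)!}{MCC(v) = sum over maximal
#' cliques C containing v of (|C|-1)!} where \eqn{S(v)} is the set of
#' maximal cliques containing \eqn{v}. Scores are integer-valued sums of
#' factorials; they are represented exactly for every clique size up to 18
#' (factorials below 2^53), and a warning is emitted beyond that. An
#' isolated node forms a singleton maximal clique and scores
#' \eqn{(1-1)! = 1} by default (\code{singletonScore = 0} switches the
#' convention off).
#'
#' @param graph undirected simple \code{igraph} graph.
#' @param singletonScore score of an isolated node: 1 (default) or 0.
#' @param maxNodes passed to \code{\link{maximalCliques}}.
#' @return data.frame (gene, mcc, log10Mcc, degree) sorted by mcc
#'   descending, then degree descending, then gene ID.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("A", "B", "C")
#' mccScores(g)   # every node (3-1)! = 2
#' @export
mccScores <- function(graph, singletonScore = 1, maxNodes = 2000L) {
    stopifnot(singletonScore %in% c(0, 1))
    cliques <- maximalCliques(graph, maxNodes = maxNodes)
    sizes <- lengths(cliques)
    if (any(sizes > 18L)) {
        warning("maximal clique of size > 18: factorial terms exceed 2^53 ",
                "and MCC scores are no longer exact integers")
    }
    nodes <- igraph::V(graph)$name
    score <- stats::setNames(numeric(length(nodes)), nodes)
    for (i in seq_along(cliques)) {
        contrib <- if (sizes[i] == 1L) singletonScore
                   else factorial(sizes[i] - 1L)
        score[cliques[[i]]] <- score[cliques[[i]]] + contrib
    }
    deg <- igraph::degree(graph)[nodes]
    out <- data.frame(gene = nodes, mcc = unname(score),
                      log10Mcc = ifelse(score > 0, log10(score), -Inf),
                      degree = unname(deg), stringsAsFactors = FALSE)
    out[order(-out$mcc, -out$degree, out$gene), , drop = FALSE]
}

#' Top hub genes by MCC
#'
#' Deterministic top-\code{k}: MCC descending, degree descending, then gene
#' ID ascending as tie-breaks.
#'
#' @param scores data.frame from \code{\link{mccScores}}.
#' @param k how many hubs (default 5).
#' @return character vector of hub gene IDs.
#' @export
topHubs <- function(scores, k = 5L) {
    stopifnot(k >= 1)
    if (k > nrow(scores)) {
        warning("k exceeds node count; returning all ", nrow(scores), " genes")
        k <- nrow(scores)
    }
    scores$gene[seq_len(k)]
}
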