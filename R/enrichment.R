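#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(\eqn{N, K, n}): the
#' chance of drawing at least \code{k} marked genes when \code{n} genes are
#' drawn without replacement from a universe of \code{N} containing
#' \code{K} marked ones. Computed stably through \code{stats::phyper}
#' (log-gamma based). \eqn{p(k = 0) = 1} always.
#'
#' @param k observed overlap, \code{0 <= k <= min(K, n)}.
#' @param K gene-set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return the upper-tail probability.
#' @examples
#' hypergeomUpperTail(5, 5, 5, 10)   # 1/252
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    stopifnot(length(k) == length(K) || length(K) == 1L)
    if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n))) {
        stop("require 0 <= k <= min(K, n) and K, n <= N")
    }
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests each gene set for enrichment in the query by the upper-tail
#' hypergeometric probability within the supplied universe, corrects across
#' all tested sets by Benjamini-Hochberg (one BH family per collection —
#' run GO-like and KEGG-like collections separately to mirror their
#' separate cutoffs), and flags sets with adjusted \code{p < fdr} and
#' overlap count strictly greater than \code{minCount}. Query genes outside
#' the universe are dropped with a warning; sets are intersected with the
#' universe; only sets with non-empty overlap are reported.
#'
#' @param query character vector of genes of interest.
#' @param sets named list of gene sets (e.g. from \code{\link{readGmt}}).
#' @param universe background gene vector (conventionally: all genes that
#'   survived preprocessing in the analyzed cohort).
#' @param fdr adjusted-p cutoff (default 0.05; use 0.01 for KEGG-like
#'   collections).
#' @param minCount overlap count that must be strictly exceeded
#'   (default 6).
#' @return data.frame (set, k, K, n, N, pvalue, padj, significant,
#'   overlapGenes) sorted by padj then set name.
#' @export
runOra <- function(query, sets, universe, fdr = 0.05, minCount = 6L) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    query <- unique(query)
    outside <- setdiff(query, universe)
    if (length(outside)) {
        warning(length(outside), " query gene(s) outside the universe dropped")
        query <- intersect(query, universe)
    }
    if (!length(query)) stop("empty query after universe filtering")
    N <- length(universe)
    n <- length(query)
    setsU <- lapply(sets, intersect, universe)
    tested <- setsU[lengths(setsU) > 0L]
    if (!length(tested)) stop("no gene set overlaps the universe")
    k <- vapply(tested, function(s) length(intersect(s, query)), integer(1))
    K <- lengths(tested)
    p <- hypergeomUpperTail(k, K, n, N)
    padj <- bhAdjust(p)
    out <- data.frame(set = names(tested), k = k, K = K, n = n, N = N,
                      pvalue = unname(p), padj = unname(padj),
                      significant = unname(padj < fdr & k > minCount),
                      overlapGenes = vapply(tested, function(s) {
                          paste(sort(intersect(s, query)), collapse = ";")
                      }, character(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[out$k >= 1L, , drop = FALSE]
    out[order(out$padj, out$set), , drop = FALSE]
}
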