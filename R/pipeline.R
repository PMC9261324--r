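#' Run the full co-expression network stage
#'
#' The standard network workflow on one cohort: optional outlier-sample
#' removal, soft-threshold selection against the scale-free target (unless
#' \code{beta} is forced), adjacency and topological overlap, average-linkage
#' clustering with a static quantile cut, eigengene computation, and merging
#' of modules whose eigengenes correlate above \code{1 - mergeCutHeight}.
#'
#' @param x expression container (genes x samples; log-like scale).
#' @param config a \code{\link{pipelineConfig}}.
#' @param beta force a soft-threshold power; \code{NULL} (default) selects
#'   it from \code{config@betaCandidates}.
#' @param removeOutliers cluster samples and drop flagged outliers first
#'   (off by default; outlier handling belongs to preprocessing, and on
#'   age-structured cohorts the automatic cut can flag an age group).
#' @param verbose log stage dimensions and thresholds.
#' @return list with \code{partition} (\code{ModulePartition}),
#'   \code{eigengenes} (\code{ModuleEigengenes}), \code{beta},
#'   \code{scaleFreeFit}, \code{keptSamples}, \code{flaggedSamples}.
#' @examples
#' sim <- simulateCohort(100, list(moduleSpec("m1", 40),
#'                                 moduleSpec("m2", 40)),
#'                       nSamples = 30, seed = 1)
#' net <- discoverModules(sim$expr, pipelineConfig(minModuleSize = 20L))
#' net$partition
#' @export
discoverModules <- function(x, config = pipelineConfig(), beta = NULL,
                            removeOutliers = FALSE, verbose = FALSE) {
    m <- .exprs(x)
    .msg(verbose, "network stage: ", nrow(m), " genes x ", ncol(m), " samples")
    flagged <- character(0)
    if (removeOutliers && ncol(m) >= 3L) {
        out <- detectOutlierSamples(m)
        flagged <- out$flagged
        if (length(flagged)) {
            .msg(verbose, "removing ", length(flagged), " outlier sample(s): ",
                 paste(flagged, collapse = ", "))
            m <- m[, out$kept, drop = FALSE]
        }
    }
    r <- pairwiseCorrelation(m)
    if (is.null(beta)) {
        pick <- pickSoftThreshold(r, candidates = config@betaCandidates,
                                  target = config@scaleFreeTarget,
                                  signMode = config@networkSign)
        beta <- pick$beta
        fit <- pick$fit
        .msg(verbose, "soft threshold beta = ", beta, " (R^2 = ",
             round(fit$rSquared, 3), ")")
    } else {
        fit <- scaleFreeFit(softAdjacency(r, beta, config@networkSign))
    }
    adj <- softAdjacency(r, beta, config@networkSign)
    tom <- tomSimilarity(adj)
    part <- cutModules(tom, minModuleSize = config@minModuleSize,
                       cutQuantile = config@cutQuantile)
    .msg(verbose, length(moduleSizes(part)), " modules before merging; ",
         sum(moduleLabels(part) == "unassigned"), " genes unassigned")
    if (length(moduleSizes(part)) == 0L) {
        return(list(partition = part, eigengenes = NULL, beta = beta,
                    scaleFreeFit = fit,
                    keptSamples = colnames(m), flaggedSamples = flagged))
    }
    merged <- mergeCloseModules(m, part, cutHeight = config@mergeCutHeight)
    .msg(verbose, length(moduleSizes(merged$partition)),
         " modules after merging at cutline ", config@mergeCutHeight)
    list(partition = merged$partition, eigengenes = merged$eigengenes,
         beta = beta, scaleFreeFit = fit,
         keptSamples = colnames(m), flaggedSamples = flagged)
}

#' Genes of modules correlated with age
#'
#' Selects the modules whose eigengene-age Pearson correlation passes the
#' significance (and optional |r|) thresholds and returns their member
#' genes — the cohort's age-related signature fed into cross-cohort
#' comparison.
#'
#' @param network result of \code{\link{discoverModules}}.
#' @param traits trait table with \code{sample} and \code{age}.
#' @param pCut p-value threshold (default 0.05).
#' @param rCut optional minimum |r| (default 0, i.e. p alone decides).
#' @return list with \code{modules} (labels) and \code{genes}.
#' @export
ageRelatedGenes <- function(network, traits, pCut = 0.05, rCut = 0) {
    if (is.null(network$eigengenes)) {
        return(list(modules = character(0), genes = character(0)))
    }
    mt <- moduleTraitCorrelation(network$eigengenes, traits, which = "age")
    sel <- mt$module[mt$p < pCut & abs(mt$r) >= rCut]
    genes <- names(moduleLabels(network$partition))[
        moduleLabels(network$partition) %in% sel]
    list(modules = sel, genes = genes, table = mt)
}
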