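#' @import methods
#' @importFrom stats var sd cor quantile hclust cutree as.dist dist pt pnorm
#'   phyper p.adjust rnorm runif lm coef fitted resid smooth.spline predict
#'   wilcox.test prcomp rbinom
#' @importFrom utils head read.table write.table
NULL

#' Pipeline configuration
#'
#' Holds the tunable thresholds of the whole workflow, with defaults that
#' mirror the analysis conventions of the study design this package
#' implements: a scale-free topology fit target of 0.8 for soft-threshold
#' selection, an eigengene merge cutline of 0.2, DEG selection at
#' \code{|logFC| >= 0.5} and BH-adjusted \code{p < 0.05}, GO-style
#' over-representation at adjusted \code{p < 0.05} with overlap count
#' strictly greater than 6, KEGG-style at adjusted \code{p < 0.01},
#' interaction-score filtering at 900 on the STRING 0--1000 scale, and
#' top-5 hub reporting.
#'
#' @slot betaCandidates integer vector of candidate soft-threshold powers,
#'   sorted ascending.
#' @slot scaleFreeTarget target \eqn{R^2} for the scale-free topology fit.
#' @slot minModuleSize smallest gene count a cluster needs to become a module.
#' @slot cutQuantile fraction of the dendrogram merge-height span at which
#'   the gene tree is cut.
#' @slot mergeCutHeight eigengene dissimilarity (1 - cor) below which modules
#'   are merged.
#' @slot degLfcThreshold absolute log2 fold-change threshold for DEG calls.
#' @slot degFdr BH-adjusted p threshold for DEG calls.
#' @slot enrichGoFdr adjusted-p cutoff for GO-like collections.
#' @slot enrichKeggFdr adjusted-p cutoff for KEGG-like collections.
#' @slot enrichMinCount overlap count that must be strictly exceeded.
#' @slot ppiMinScore minimum interaction score (file scale) kept when reading
#'   edge lists.
#' @slot topKHubs number of hub genes reported.
#' @slot networkSign "unsigned" or "signed" adjacency.
#' @slot seed integer seed driving every stochastic step.
#' @export
setClass("PipelineConfig", representation(
    betaCandidates = "integer",
    scaleFreeTarget = "numeric",
    minModuleSize = "integer",
    cutQuantile = "numeric",
    mergeCutHeight = "numeric",
    degLfcThreshold = "numeric",
    degFdr = "numeric",
    enrichGoFdr = "numeric",
    enrichKeggFdr = "numeric",
    enrichMinCount = "integer",
    ppiMinScore = "numeric",
    topKHubs = "integer",
    networkSign = "character",
    seed = "integer"
))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    b <- object@betaCandidates
    if (length(b) == 0L || any(b < 1L)) {
        msg <- c(msg, "betaCandidates must be a non-empty set of powers >= 1")
    }
    if (is.unsorted(b, strictly = TRUE)) {
        msg <- c(msg, "betaCandidates must be sorted strictly ascending")
    }
    inRange <- function(x, lo, hi, loOpen = FALSE, hiOpen = FALSE) {
        length(x) == 1L && is.finite(x) &&
            (if (loOpen) x > lo else x >= lo) &&
            (if (hiOpen) x < hi else x <= hi)
    }
    if (!inRange(object@scaleFreeTarget, 0, 1, loOpen = TRUE)) {
        msg <- c(msg, "scaleFreeTarget must lie in (0, 1]")
    }
    if (object@minModuleSize < 1L) {
        msg <- c(msg, "minModuleSize must be a positive integer")
    }
    if (!inRange(object@cutQuantile, 0, 1, loOpen = TRUE, hiOpen = TRUE)) {
        msg <- c(msg, "cutQuantile must lie in (0, 1)")
    }
    if (!inRange(object@mergeCutHeight, 0, 1)) {
        msg <- c(msg, "mergeCutHeight must lie in [0, 1]")
    }
    if (object@degLfcThreshold < 0) {
        msg <- c(msg, "degLfcThreshold must be non-negative")
    }
    for (fdrSlot in c("degFdr", "enrichGoFdr", "enrichKeggFdr")) {
        v <- slot(object, fdrSlot)
        if (!inRange(v, 0, 1, loOpen = TRUE, hiOpen = TRUE)) {
            msg <- c(msg, paste(fdrSlot, "must lie in (0, 1)"))
        }
    }
    if (object@enrichMinCount < 0L) {
        msg <- c(msg, "enrichMinCount must be non-negative")
    }
    if (object@topKHubs < 1L) {
        msg <- c(msg, "topKHubs must be a positive integer")
    }
    if (!object@networkSign %in% c("unsigned", "signed")) {
        msg <- c(msg, "networkSign must be 'unsigned' or 'signed'")
    }
    if (length(msg)) msg else TRUE
})

#' @param betaCandidates,scaleFreeTarget,minModuleSize,cutQuantile,mergeCutHeight
#'   see slots.
#' @param degLfcThreshold,degFdr,enrichGoFdr,enrichKeggFdr,enrichMinCount
#'   see slots.
#' @param ppiMinScore,topKHubs,networkSign,seed see slots.
#' @return A validated \code{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(seed = 7L)
#' cfg
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(betaCandidates = c(1:10, seq(12L, 20L, 2L)),
                           scaleFreeTarget = 0.8,
                           minModuleSize = 30L,
                           cutQuantile = 0.95,
                           mergeCutHeight = 0.2,
                           degLfcThreshold = 0.5,
                           degFdr = 0.05,
                           enrichGoFdr = 0.05,
                           enrichKeggFdr = 0.01,
                           enrichMinCount = 6L,
                           ppiMinScore = 900,
                           topKHubs = 5L,
                           networkSign = c("unsigned", "signed"),
                           seed = 1L) {
    networkSign <- match.arg(networkSign)
    new("PipelineConfig",
        betaCandidates = as.integer(sort(unique(betaCandidates))),
        scaleFreeTarget = scaleFreeTarget,
        minModuleSize = as.integer(minModuleSize),
        cutQuantile = cutQuantile,
        mergeCutHeight = mergeCutHeight,
        degLfcThreshold = degLfcThreshold,
        degFdr = degFdr,
        enrichGoFdr = enrichGoFdr,
        enrichKeggFdr = enrichKeggFdr,
        enrichMinCount = as.integer(enrichMinCount),
        ppiMinScore = ppiMinScore,
        topKHubs = as.integer(topKHubs),
        networkSign = networkSign,
        seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat("  beta candidates   :", paste(object@betaCandidates, collapse = " "), "\n")
    cat("  scale-free target :", object@scaleFreeTarget,
        "| sign:", object@networkSign, "\n")
    cat("  module cut        : min size", object@minModuleSize,
        "| cut quantile", object@cutQuantile,
        "| merge height", object@mergeCutHeight, "\n")
    cat("  DEG               : |logFC| >=", object@degLfcThreshold,
        "& BH p <", object@degFdr, "\n")
    cat("  enrichment        : GO p <", object@enrichGoFdr,
        "| KEGG p <", object@enrichKeggFdr,
        "| count >", object@enrichMinCount, "\n")
    cat("  PPI/hubs          : score >=", object@ppiMinScore,
        "| top", object@topKHubs, "\n")
    cat("  seed              :", object@seed, "\n")
})

#' Gene-to-module partition
#'
#' Result of cutting the gene dendrogram: a named label per gene, with the
#' reserved label \code{"unassigned"} for genes in clusters smaller than the
#' minimum module size. Non-reserved labels are deterministic: modules are
#' ordered by size (largest first) and named from a fixed color palette,
#' so repeated runs on the same input produce byte-identical output.
#'
#' @slot labels named character vector, gene -> module label.
#' @slot minModuleSize the size threshold used at the cut.
#' @export
setClass("ModulePartition", representation(
    labels = "character",
    minModuleSize = "integer"
))

setValidity("ModulePartition", function(object) {
    msg <- character()
    lab <- object@labels
    if (is.null(names(lab)) || anyDuplicated(names(lab))) {
        msg <- c(msg, "labels must be named by unique gene IDs")
    }
    sizes <- table(lab[lab != "unassigned"])
    if (length(sizes) && any(sizes < object@minModuleSize)) {
        msg <- c(msg, "every named module must have >= minModuleSize members")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ModulePartition", function(object) {
    sizes <- moduleSizes(object)
    cat("ModulePartition:", length(object@labels), "genes,",
        length(sizes), "modules (min size", paste0(object@minModuleSize, ")"),
        "\n")
    if (length(sizes)) {
        shown <- head(sizes, 8L)
        cat("  ", paste(names(shown), shown, sep = "=", collapse = " "),
            if (length(sizes) > 8L) "..." else "", "\n")
    }
    cat("  unassigned:", sum(object@labels == "unassigned"), "\n")
})

#' Module eigengenes
#'
#' Per-module eigengene sample profiles. Each eigengene is the first
#' principal component of the module's gene-standardized expression,
#' rescaled to unit sample variance and oriented so that its correlation
#' with the module's mean standardized profile is non-negative.
#'
#' @slot eigengenes modules x samples numeric matrix.
#' @slot varianceExplained named numeric in [0, 1], share of the module's
#'   standardized variance carried by the eigengene.
#' @export
setClass("ModuleEigengenes", representation(
    eigengenes = "matrix",
    varianceExplained = "numeric"
))

setValidity("ModuleEigengenes", function(object) {
    msg <- character()
    e <- object@eigengenes
    if (is.null(rownames(e))) msg <- c(msg, "eigengene rows must be named by module")
    ve <- object@varianceExplained
    if (length(ve) != nrow(e) || !identical(names(ve), rownames(e))) {
        msg <- c(msg, "varianceExplained must be named to match eigengene rows")
    }
    if (length(ve) && (any(ve < -1e-8) || any(ve > 1 + 1e-8))) {
        msg <- c(msg, "varianceExplained must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleEigengenes", function(object) {
    cat("ModuleEigengenes:", nrow(object@eigengenes), "modules x",
        ncol(object@eigengenes), "samples\n")
    ve <- sort(object@varianceExplained, decreasing = TRUE)
    shown <- head(round(ve, 3), 8L)
    cat("  variance explained:",
        paste(names(shown), shown, sep = "=", collapse = " "),
        if (length(ve) > 8L) "..." else "", "\n")
})

#' Ground truth of a simulated cohort
#'
#' What the generator planted: the gene -> module map (background genes are
#' labeled \code{"background"}), the noise-free eigengene profile per planted
#' module, the planted hub genes, and the sample trait table (age in years,
#' sex, ethnicity), in the same sample order as the expression matrix.
#'
#' @slot geneModules named character vector, gene -> planted module or
#'   "background".
#' @slot eigengenes planted modules x samples matrix of true eigengenes.
#' @slot hubGenes character vector of planted hub genes.
#' @slot traits data.frame with columns sample, age, sex, ethnicity.
#' @export
setClass("CohortTruth", representation(
    geneModules = "character",
    eigengenes = "matrix",
    hubGenes = "character",
    traits = "data.frame"
))

setValidity("CohortTruth", function(object) {
    msg <- character()
    gm <- object@geneModules
    if (is.null(names(gm)) || anyDuplicated(names(gm))) {
        msg <- c(msg, "geneModules must be named by unique gene IDs")
    }
    if (!all(object@hubGenes %in% names(gm))) {
        msg <- c(msg, "hub genes must appear in the gene -> module map")
    }
    tr <- object@traits
    need <- c("sample", "age", "sex", "ethnicity")
    if (!all(need %in% colnames(tr))) {
        msg <- c(msg, paste("traits must have columns:",
                            paste(need, collapse = ", ")))
    } else {
        if (anyDuplicated(tr$sample)) msg <- c(msg, "duplicate sample IDs in traits")
        if (any(tr$age < 0 | tr$age > 120)) msg <- c(msg, "ages must lie in [0, 120]")
        if (!all(tr$sex %in% c("F", "M"))) msg <- c(msg, "sex must be 'F' or 'M'")
        if (ncol(object@eigengenes) && ncol(object@eigengenes) != nrow(tr)) {
            msg <- c(msg, "eigengene columns must match trait rows")
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CohortTruth", function(object) {
    gm <- object@geneModules
    planted <- table(gm[gm != "background"])
    cat("CohortTruth:", length(gm), "genes (",
        sum(gm == "background"), "background ),",
        nrow(object@traits), "samples\n")
    if (length(planted)) {
        cat("  planted modules:",
            paste(names(planted), planted, sep = "=", collapse = " "), "\n")
    }
    cat("  planted hubs:", paste(object@hubGenes, collapse = " "), "\n")
    cat("  age range:", paste(round(range(object@traits$age), 1),
                              collapse = " - "), "years\n")
})
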