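#' Accessors for coexAge S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{moduleLabels} returns the gene -> module map, \code{moduleSizes} the
#' per-module gene counts (largest first, reserved "unassigned" excluded),
#' \code{moduleGenes} the member genes of one module, \code{eigengenes} the
#' modules x samples eigengene matrix, \code{varianceExplained} its per-module
#' variance share, and the \code{truth*} accessors expose simulator ground
#' truth.
#'
#' @param object a \code{ModulePartition}, \code{ModuleEigengenes} or
#'   \code{CohortTruth}.
#' @param module a module label.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases moduleLabels moduleSizes moduleGenes eigengenes varianceExplained
#'   truthModules truthHubs truthTraits
#' @examples
#' truth <- simulateCohort(nBackground = 20,
#'                         modules = list(moduleSpec("m1", 10)),
#'                         nSamples = 12, seed = 1)$truth
#' table(truthModules(truth))
NULL

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModulePartition", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))
#' @rdname accessors
#' @export
setMethod("moduleSizes", "ModulePartition", function(object) {
    lab <- object@labels[object@labels != "unassigned"]
    if (!length(lab)) return(integer())
    sz <- table(lab)
    sz <- sort(sz, decreasing = TRUE)
    stats::setNames(as.integer(sz), names(sz))
})

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(object, module) standardGeneric("moduleGenes"))
#' @rdname accessors
#' @export
setMethod("moduleGenes", "ModulePartition", function(object, module) {
    if (!module %in% object@labels) {
        stop("unknown module label: ", module)
    }
    names(object@labels)[object@labels == module]
})

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))
#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleEigengenes", function(object) object@eigengenes)
#' @rdname accessors
#' @export
setMethod("eigengenes", "CohortTruth", function(object) object@eigengenes)

#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setMethod("varianceExplained", "ModuleEigengenes",
          function(object) object@varianceExplained)

#' @rdname accessors
#' @export
setGeneric("truthModules", function(object) standardGeneric("truthModules"))
#' @rdname accessors
#' @export
setMethod("truthModules", "CohortTruth", function(object) object@geneModules)

#' @rdname accessors
#' @export
setGeneric("truthHubs", function(object) standardGeneric("truthHubs"))
#' @rdname accessors
#' @export
setMethod("truthHubs", "CohortTruth", function(object) object@hubGenes)

#' @rdname accessors
#' @export
setGeneric("truthTraits", function(object) standardGeneric("truthTraits"))
#' @rdname accessors
#' @export
setMethod("truthTraits", "CohortTruth", function(object) object@traits)
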