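#' Keep genes expressed above a threshold in enough samples
#'
#' Implements the linear-scale expressed-gene filter (e.g. "FPKM > 1 in all
#' samples"): a gene survives when its value exceeds \code{minValue} in at
#' least a fraction \code{minFraction} of samples. Row order of survivors is
#' preserved and values are untouched.
#'
#' @param x \code{SummarizedExperiment} or genes x samples matrix on a
#'   linear scale.
#' @param minValue expression threshold (strict \code{>}).
#' @param minFraction required fraction of samples in [0, 1]; the default 1
#'   reads "in all samples".
#' @param verbose log the surviving count.
#' @return the filtered container, same type as \code{x}.
#' @export
filterExpressed <- function(x, minValue = 1, minFraction = 1, verbose = FALSE) {
    if (minFraction < 0 || minFraction > 1) {
        stop("minFraction must lie in [0, 1]")
    }
    m <- .exprs(x)
    frac <- rowMeans(m > minValue)
    keep <- frac >= minFraction
    .msg(verbose, "filterExpressed: ", sum(keep), " of ", nrow(m),
         " genes kept (value > ", minValue, " in >= ",
         round(100 * minFraction), "% of samples)")
    .rewrap(x, m[keep, , drop = FALSE])
}

#' Log2-transform a linear-scale matrix
#'
#' \code{log2(value + pseudocount)}; the conventional pseudocount of 1 keeps
#' zeros at zero. Needed so log fold changes downstream are well defined.
#'
#' @param x linear-scale expression container.
#' @param pseudocount positive offset added before the log.
#' @return transformed container, scale tag \code{log2}.
#' @export
log2Transform <- function(x, pseudocount = 1) {
    stopifnot(pseudocount > 0)
    m <- .exprs(x)
    if (any(m < 0)) {
        stop("negative values cannot be log2-transformed; is the input ",
             "already on a log scale?")
    }
    .rewrap(x, log2(m + pseudocount), scale = "log2")
}

#' Quantile-normalize samples
#'
#' Forces every sample's value distribution onto the across-sample mean of
#' sorted values (ties receive the mean reference value of their rank
#' positions), the normalization used for microarray-style intensity
#' matrices. Delegates to \code{limma::normalizeQuantiles}. The operation is
#' idempotent.
#'
#' @param x expression container with >= 2 samples.
#' @return normalized container.
#' @export
quantileNormalize <- function(x) {
    m <- .exprs(x)
    if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    .rewrap(x, out, scale = "normalized_intensity")
}

#' Flag outlier samples by average-linkage clustering
#'
#' Samples are clustered by average linkage on the Euclidean distance of
#' gene-standardized expression; cutting the dendrogram at \code{cutHeight}
#' flags every sample outside the largest cluster. The automatic cut height
#' is \code{mean(merge heights) + 2.5 * sd(merge heights)}; with fewer than
#' two distinct merge heights no sample is flagged.
#'
#' @param x expression container with >= 3 samples.
#' @param cutHeight numeric cut height, or \code{"auto"}.
#' @return list with \code{kept} and \code{flagged} sample ID vectors and
#'   the \code{cutHeight} used (a partition of all samples).
#' @examples
#' sim <- simulateCohort(50, list(), nSamples = 10, seed = 1)
#' detectOutlierSamples(sim$expr)
#' @export
detectOutlierSamples <- function(x, cutHeight = "auto") {
    m <- .exprs(x)
    if (ncol(m) < 3L) stop("outlier detection needs >= 3 samples")
    keepRows <- apply(m, 1L, sd) > 0
    if (!any(keepRows)) {
        # constant matrix: all samples identical, nothing to flag
        return(list(kept = colnames(m), flagged = character(0), cutHeight = 0))
    }
    z <- .standardizeRows(m[keepRows, , drop = FALSE])
    h <- hclust(dist(t(z)), method = "average")
    if (identical(cutHeight, "auto")) {
        cutHeight <- mean(h$height) + 2.5 * sd(h$height)
        if (!is.finite(cutHeight)) cutHeight <- max(h$height)
    }
    cl <- cutree(h, h = cutHeight)
    sizes <- table(cl)
    main <- as.integer(names(sizes)[which.max(sizes)])
    kept <- colnames(m)[cl == main]
    flagged <- colnames(m)[cl != main]
    if (!length(kept)) stop("degenerate cut: every sample flagged")
    list(kept = kept, flagged = flagged, cutHeight = cutHeight)
}

#' Align a trait table to an expression matrix
#'
#' Subsets and reorders a trait table to the samples of an expression
#' container, erroring when any sample lacks a trait row. Sample subsetting
#' (e.g. after outlier removal) propagates to traits only through this
#' explicit step.
#'
#' @param x expression container.
#' @param traits data.frame with a \code{sample} column.
#' @return the reordered trait rows.
#' @export
alignTraits <- function(x, traits) {
    m <- .exprs(x)
    idx <- match(colnames(m), traits$sample)
    if (anyNA(idx)) {
        stop("samples missing from trait table: ",
             paste(head(colnames(m)[is.na(idx)], 5L), collapse = ", "))
    }
    out <- traits[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
}
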