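#' Gene-gene Pearson correlation matrix
#'
#' @param x expression container with >= 3 samples; zero-variance genes are
#'   an error (they cannot be correlated).
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
pairwiseCorrelation <- function(x) {
    m <- .exprs(x)
    if (ncol(m) < 3L) stop("correlation needs >= 3 samples")
    sdv <- apply(m, 1L, sd)
    if (any(sdv == 0)) {
        stop("zero-variance gene(s): ",
             paste(head(rownames(m)[sdv == 0], 10L), collapse = ", "))
    }
    r <- cor(t(m))
    diag(r) <- 1
    r
}

#' Soft-thresholded adjacency
#'
#' Raises correlations to the power \eqn{\beta}: unsigned
#' \eqn{a_{ij} = |r_{ij}|^\beta}, signed
#' \eqn{a_{ij} = ((1 + r_{ij})/2)^\beta}; the diagonal is set to 1.
#'
#' @param cor correlation matrix.
#' @param beta integer power >= 1.
#' @param signMode \code{"unsigned"} (default) or \code{"signed"}.
#' @return adjacency matrix in [0, 1] with attributes \code{beta} and
#'   \code{signMode}.
#' @export
softAdjacency <- function(cor, beta, signMode = c("unsigned", "signed")) {
    signMode <- match.arg(signMode)
    if (beta < 1) stop("beta must be >= 1")
    a <- if (signMode == "unsigned") abs(cor)^beta else ((1 + cor) / 2)^beta
    diag(a) <- 1
    attr(a, "beta") <- as.integer(beta)
    attr(a, "signMode") <- signMode
    a
}

#' Scale-free topology fit of a weighted network
#'
#' Computes each gene's connectivity \eqn{k_i = \sum_{j \ne i} a_{ij}}, bins
#' the genes into \code{nBins} equal-width connectivity bins, and regresses
#' \eqn{\log_{10}}(bin frequency) on \eqn{\log_{10}}(bin-mean k) over
#' non-empty bins. A high \eqn{R^2} with negative slope indicates scale-free
#' (power-law) topology. With only two occupied bins the two-point fit has
#' \eqn{R^2 = 1} by construction.
#'
#' @param adj adjacency matrix, or a numeric vector of connectivities.
#' @param nBins number of equal-width bins (default 10).
#' @return list with \code{rSquared} in [0, 1] and \code{slope}.
#' @export
scaleFreeFit <- function(adj, nBins = 10L) {
    k <- if (is.matrix(adj)) rowSums(adj) - diag(adj) else as.numeric(adj)
    if (length(unique(k)) < 2L) {
        warning("all connectivities equal; scale-free fit undefined")
        return(list(rSquared = 0, slope = 0))
    }
    breaks <- seq(min(k), max(k), length.out = nBins + 1L)
    bin <- cut(k, breaks, include.lowest = TRUE)
    counts <- tapply(k, bin, length)
    meanK <- tapply(k, bin, mean)
    ok <- !is.na(counts) & counts > 0 & meanK > 0
    if (sum(ok) < 2L) {
        warning("fewer than two occupied bins; scale-free fit undefined")
        return(list(rSquared = 0, slope = 0))
    }
    xlog <- log10(meanK[ok])
    ylog <- log10(counts[ok] / length(k))
    fit <- lm(ylog ~ xlog)
    tss <- sum((ylog - mean(ylog))^2)
    r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else 0
    list(rSquared = r2, slope = unname(coef(fit)[2L]))
}

#' Choose the soft-threshold power
#'
#' Returns the smallest candidate power whose scale-free fit exceeds
#' \code{target} with a negative slope; when none qualifies, falls back to
#' the power maximizing \eqn{R^2} (negative-slope candidates preferred) with
#' a warning. The fit table for every candidate is returned for inspection.
#'
#' @param cor correlation matrix.
#' @param candidates ascending candidate powers.
#' @param target required fit \eqn{R^2} (default 0.8).
#' @param signMode adjacency sign mode.
#' @param nBins connectivity bins for the fit.
#' @return list with \code{beta}, \code{fit} (the chosen candidate's fit)
#'   and \code{table} (data.frame over all candidates).
#' @export
pickSoftThreshold <- function(cor, candidates = c(1:10, seq(12L, 20L, 2L)),
                              target = 0.8,
                              signMode = c("unsigned", "signed"),
                              nBins = 10L) {
    signMode <- match.arg(signMode)
    if (!length(candidates)) stop("no candidate powers supplied")
    candidates <- as.integer(sort(candidates))
    rows <- lapply(candidates, function(b) {
        f <- scaleFreeFit(softAdjacency(cor, b, signMode), nBins = nBins)
        data.frame(beta = b, rSquared = f$rSquared, slope = f$slope)
    })
    tab <- do.call(rbind, rows)
    ok <- tab$rSquared > target & tab$slope < 0
    if (any(ok)) {
        i <- which(ok)[1L]
    } else {
        warning("no candidate reached scale-free fit R^2 > ", target,
                "; falling back to the best-fitting power")
        neg <- tab$slope < 0
        i <- if (any(neg)) which(neg)[which.max(tab$rSquared[neg])]
             else which.max(tab$rSquared)
    }
    list(beta = tab$beta[i],
         fit = list(rSquared = tab$rSquared[i], slope = tab$slope[i]),
         table = tab)
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' for \eqn{i \ne j}, where \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}
#' and \eqn{k_i = \sum_{u \ne i} a_{iu}}; \eqn{TOM_{ii} = 1}. Two genes have
#' high topological overlap when they are strongly connected to each other
#' and share the same network neighborhood; \code{1 - TOM} is the clustering
#' dissimilarity.
#'
#' @param adj adjacency matrix in [0, 1] with unit diagonal.
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tomSimilarity <- function(adj) {
    a <- unclass(adj)
    attributes(a)[c("beta", "signMode")] <- NULL
    stopifnot(nrow(a) == ncol(a))
    k <- rowSums(a) - diag(a)
    # l_ij = (A^2)_ij - a_ii a_ij - a_ij a_jj = (A^2)_ij - 2 a_ij (diag = 1)
    l <- a %*% a - 2 * a
    minK <- outer(k, k, pmin)
    denom <- minK + 1 - a
    tom <- (l + a) / denom
    tom[denom <= 0] <- 1   # isolated mutually-saturated pair
    diag(tom) <- 1
    tom <- pmin(pmax(tom, 0), 1)
    dimnames(tom) <- dimnames(adj)
    tom
}

#' Cut the gene dendrogram into modules
#'
#' Average-linkage hierarchical clustering on \code{1 - TOM}, cut statically
#' at the height \code{min + cutQuantile * (max - min)} of the merge-height
#' span; clusters of at least \code{minModuleSize} genes become modules,
#' ordered by size and named from a fixed color palette; smaller clusters
#' are pooled into the reserved \code{"unassigned"} label. (A static cut is
#' this package's deterministic, testable stand-in for dynamic tree
#' cutting; the fraction is exposed. It is taken on the merge-height span
#' rather than the height distribution because the latter is dominated by
#' the many low within-module merges, which makes its upper quantiles
#' unstable.)
#'
#' @param tom TOM matrix.
#' @param minModuleSize minimum module size (>= 2), default 30.
#' @param cutQuantile fraction of the merge-height span in (0, 1) at which
#'   the tree is cut, default 0.95.
#' @return a \code{\link{ModulePartition-class}}.
#' @export
cutModules <- function(tom, minModuleSize = 30L, cutQuantile = 0.95) {
    stopifnot(minModuleSize >= 2)
    n <- nrow(tom)
    genes <- rownames(tom)
    if (minModuleSize > n) {
        warning("minModuleSize exceeds gene count; everything unassigned")
        return(new("ModulePartition",
                   labels = stats::setNames(rep("unassigned", n), genes),
                   minModuleSize = as.integer(minModuleSize)))
    }
    h <- hclust(as.dist(1 - tom), method = "average")
    # average linkage is monotone; clamp floating-point fuzz on exact ties
    if (is.unsorted(h$height)) h$height <- cummax(h$height)
    cutH <- min(h$height) + cutQuantile * diff(range(h$height))
    cl <- cutree(h, h = cutH)
    sizes <- sort(table(cl), decreasing = TRUE)
    big <- names(sizes)[sizes >= minModuleSize]
    labels <- rep("unassigned", n)
    names(labels) <- genes
    cols <- .moduleNames(length(big))
    for (i in seq_along(big)) {
        labels[cl == as.integer(big[i])] <- cols[i]
    }
    new("ModulePartition", labels = labels,
        minModuleSize = as.integer(minModuleSize))
}

#' Module eigengenes (first principal component per module)
#'
#' For each module, gene rows are standardized and the eigengene is the
#' first right-singular direction of the standardized block, rescaled to
#' unit sample variance, with its sign fixed so that the correlation with
#' the module's mean standardized profile is non-negative. The variance
#' explained is the first squared singular value over the total. The
#' reserved \code{"unassigned"} label gets no eigengene.
#'
#' @param x expression container (>= 3 samples).
#' @param partition a \code{\link{ModulePartition-class}} (or named label
#'   vector) over the genes of \code{x}.
#' @return a \code{\link{ModuleEigengenes-class}}.
#' @export
moduleEigengenes <- function(x, partition) {
    m <- .exprs(x)
    if (ncol(m) < 3L) stop("eigengenes need >= 3 samples")
    labels <- if (is(partition, "ModulePartition")) moduleLabels(partition)
              else partition
    labels <- labels[intersect(names(labels), rownames(m))]
    mods <- setdiff(unique(labels), "unassigned")
    # deterministic order: size desc, then name
    sz <- table(labels[labels %in% mods])
    mods <- names(sort(sz, decreasing = TRUE))
    if (!length(mods)) stop("no modules to summarize")
    e <- matrix(0, length(mods), ncol(m),
                dimnames = list(mods, colnames(m)))
    ve <- stats::setNames(numeric(length(mods)), mods)
    for (mod in mods) {
        genes <- names(labels)[labels == mod]
        z <- .standardizeRows(m[genes, , drop = FALSE])
        if (length(genes) == 1L) {
            e[mod, ] <- as.numeric(z) / sd(as.numeric(z))
            ve[mod] <- 1
            next
        }
        sv <- svd(z, nu = 0, nv = 1)
        score <- sv$v[, 1L]
        score <- score / sd(score)
        meanProf <- colMeans(z)
        if (sd(meanProf) > 0 && cor(score, meanProf) < 0) score <- -score
        e[mod, ] <- score
        ve[mod] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    new("ModuleEigengenes", eigengenes = e, varianceExplained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively clusters module eigengenes by average linkage on the
#' dissimilarity \code{1 - cor(ME_a, ME_b)} and merges every group falling
#' below \code{cutHeight} (default 0.2, i.e. eigengene correlation >= 0.8),
#' recomputing eigengenes after each pass until no pair is closer than the
#' cutline. \code{"unassigned"} never merges. Raising the cutline can only
#' reduce the module count.
#'
#' @param x expression container.
#' @param partition a \code{\link{ModulePartition-class}}.
#' @param cutHeight eigengene dissimilarity cutline in [0, 1].
#' @return list with the merged \code{partition} and recomputed
#'   \code{eigengenes}.
#' @export
mergeCloseModules <- function(x, partition, cutHeight = 0.2) {
    stopifnot(cutHeight >= 0, cutHeight <= 1)
    labels <- moduleLabels(partition)
    me <- moduleEigengenes(x, labels)
    repeat {
        e <- eigengenes(me)
        if (nrow(e) < 2L) break
        d <- 1 - cor(t(e))
        h <- hclust(as.dist(d), method = "average")
        grp <- cutree(h, h = cutHeight)
        if (max(table(grp)) == 1L) break
        sizes <- table(labels[labels != "unassigned"])
        for (g in unique(grp)) {
            members <- rownames(e)[grp == g]
            if (length(members) < 2L) next
            # merged module keeps the largest constituent's name
            keep <- members[which.max(sizes[members])]
            labels[labels %in% members] <- keep
        }
        me <- moduleEigengenes(x, labels)
    }
    part <- new("ModulePartition", labels = labels,
                minModuleSize = partition@minModuleSize)
    list(partition = part, eigengenes = me)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each eigengene with each numerically-encoded
#' trait (age in years; sex F=0/M=1; two-level groups 0/1; ethnicity with
#' more than two levels as one-vs-rest indicators), with two-sided p from
#' the t transform \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} df.
#'
#' @param me a \code{\link{ModuleEigengenes-class}} (or modules x samples
#'   matrix).
#' @param traits trait data.frame with a \code{sample} column matching the
#'   eigengene sample order.
#' @param which trait columns to use; default all non-sample columns.
#' @return data.frame with columns module, trait, r, p.
#' @export
moduleTraitCorrelation <- function(me, traits,
                                   which = c("age", "sex", "ethnicity")) {
    e <- if (is(me, "ModuleEigengenes")) eigengenes(me) else me
    which <- intersect(which, colnames(traits))
    tm <- .encodeTraits(alignTraitsToSamples(traits, colnames(e)), which)
    n <- ncol(e)
    r <- cor(t(e), tm)
    p <- matrix(.corPvalue(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
    out <- expand.grid(module = rownames(r), trait = colnames(r),
                       stringsAsFactors = FALSE)
    out$r <- r[cbind(out$module, out$trait)]
    out$p <- p[cbind(out$module, out$trait)]
    out[order(out$trait, out$p), , drop = FALSE]
}

# match trait rows to a sample vector (internal; errors on missing samples)
alignTraitsToSamples <- function(traits, samples) {
    idx <- match(samples, traits$sample)
    if (anyNA(idx)) {
        stop("samples missing from trait table: ",
             paste(head(samples[is.na(idx)], 5L), collapse = ", "))
    }
    traits[idx, , drop = FALSE]
}

#' Gene significance and module membership
#'
#' GS is the absolute Pearson correlation of each gene with a trait vector;
#' MM is the (signed) correlation of each gene with each module eigengene.
#' Both carry two-sided p-values from the t transform. Constant genes are
#' excluded with a warning.
#'
#' @param x expression container.
#' @param me a \code{\link{ModuleEigengenes-class}}.
#' @param trait numeric trait vector in the sample order of \code{x}.
#' @return list with \code{gs} (data.frame gene, gs, p) and \code{mm} /
#'   \code{mmP} (genes x modules matrices).
#' @export
geneSignificanceMembership <- function(x, me, trait) {
    m <- .exprs(x)
    stopifnot(length(trait) == ncol(m))
    sdv <- apply(m, 1L, sd)
    if (any(sdv == 0)) {
        warning("excluding ", sum(sdv == 0), " constant gene(s) from GS/MM")
        m <- m[sdv > 0, , drop = FALSE]
    }
    if (sd(trait) == 0) stop("constant trait")
    n <- ncol(m)
    gsR <- as.numeric(cor(t(m), trait))
    gs <- data.frame(gene = rownames(m), gs = abs(gsR),
                     p = .corPvalue(gsR, n), stringsAsFactors = FALSE)
    e <- eigengenes(me)
    mm <- cor(t(m), t(e))
    mmP <- matrix(.corPvalue(mm, n), nrow(mm), ncol(mm),
                  dimnames = dimnames(mm))
    list(gs = gs, mm = mm, mmP = mmP)
}
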