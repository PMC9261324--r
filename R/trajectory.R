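#' Fit an age trajectory with breakpoint detection
#'
#' Fits continuous piecewise-linear least-squares models with 0, 1, or 2
#' breakpoints to an eigengene (or any per-sample summary) against age. The
#' breakpoint locations are grid-searched over the observed age range (step
#' \code{gridStep} years, strictly inside the range, at least \code{minGap}
#' years apart and from a kink nothing prevents), and the number of
#' breakpoints is chosen by BIC, counting each breakpoint as two extra
#' parameters (slope change + location). A cubic smoothing spline is
#' returned alongside for plotting; inference rests on the piecewise-linear
#' fit, since the scientific claim is about change periods in the adult
#' lifespan.
#'
#' @param values numeric per-sample values (e.g. a module eigengene).
#' @param ages matching ages in years (non-constant, >= 8 samples).
#' @param maxBreaks 0, 1 or 2.
#' @param gridStep breakpoint grid step in years (default 1).
#' @param minGap minimum separation between two breakpoints in years
#'   (default 10), preventing the two-break model from fitting one kink
#'   twice.
#' @return list of class \code{"trajectoryFit"}: \code{breakpoints} (ages),
#'   \code{nBreaks}, \code{segmentSlopes}, \code{fitted}, \code{bicByCount}
#'   (named numeric over candidate counts), \code{rss}, and \code{spline}
#'   (a \code{smooth.spline} fit, or NULL when too few distinct ages).
#' @examples
#' set.seed(1)
#' age <- runif(80, 21, 93)
#' y <- 0.02 * pmax(age - 70, 0) + rnorm(80, 0, 0.05)
#' fit <- fitTrajectory(y, age)
#' fit$breakpoints
#' @export
fitTrajectory <- function(values, ages, maxBreaks = 2L, gridStep = 1,
                          minGap = 10) {
    stopifnot(length(values) == length(ages), maxBreaks %in% 0:2,
              gridStep > 0, minGap >= 0)
    if (length(values) < 8L) stop("need >= 8 samples")
    if (sd(ages) == 0) stop("ages must not be constant")
    n <- length(values)
    maxParams <- 2L + 2L * maxBreaks
    if (n <= maxParams) stop("fewer samples than model parameters")

    basis <- function(breaks) {
        X <- cbind(1, ages)
        for (b in breaks) X <- cbind(X, pmax(ages - b, 0))
        X
    }
    rssOf <- function(breaks) {
        X <- basis(breaks)
        fit <- stats::lm.fit(X, values)
        sum(fit$residuals^2)
    }
    grid <- seq(min(ages), max(ages), by = gridStep)
    grid <- grid[grid > min(ages) & grid < max(ages)]
    # each segment must contain at least 2 observations for identifiability
    okBreak <- function(breaks) {
        cuts <- c(-Inf, breaks, Inf)
        all(vapply(seq_len(length(cuts) - 1L), function(i) {
            sum(ages > cuts[i] & ages <= cuts[i + 1L]) >= 2L
        }, logical(1)))
    }

    best <- list()
    best[["0"]] <- list(breaks = numeric(0), rss = rssOf(numeric(0)))
    if (maxBreaks >= 1L && length(grid)) {
        cand <- Filter(function(b) okBreak(b), as.list(grid))
        if (length(cand)) {
            rss1 <- vapply(cand, rssOf, numeric(1))
            i <- which.min(rss1)
            best[["1"]] <- list(breaks = cand[[i]], rss = rss1[i])
        }
    }
    if (maxBreaks >= 2L && length(grid) >= 2L) {
        pairs <- list()
        for (i in seq_along(grid)) {
            for (j in seq_along(grid)) {
                if (grid[j] - grid[i] >= minGap) {
                    pairs[[length(pairs) + 1L]] <- c(grid[i], grid[j])
                }
            }
        }
        pairs <- Filter(okBreak, pairs)
        if (length(pairs)) {
            rss2 <- vapply(pairs, rssOf, numeric(1))
            i <- which.min(rss2)
            best[["2"]] <- list(breaks = pairs[[i]], rss = rss2[i])
        }
    }

    # BIC with RSS floored so that exact fits compare by parameter count
    bicOf <- function(rss, nBreaks) {
        rss <- max(rss, n * 1e-20)
        n * log(rss / n) + (2 + 2 * nBreaks) * log(n)
    }
    counts <- names(best)
    bic <- vapply(counts, function(cn) {
        bicOf(best[[cn]]$rss, as.integer(cn))
    }, numeric(1))
    chosen <- counts[which.min(bic)]
    breaks <- best[[chosen]]$breaks

    X <- basis(breaks)
    fit <- stats::lm.fit(X, values)
    co <- fit$coefficients
    slopes <- cumsum(co[-1L])
    spline <- if (length(unique(ages)) >= 4L) {
        smooth.spline(ages, values)
    } else NULL
    structure(list(breakpoints = breaks, nBreaks = as.integer(chosen),
                   segmentSlopes = unname(slopes),
                   fitted = unname(fit$fitted.values),
                   bicByCount = bic, rss = best[[chosen]]$rss,
                   ages = ages, spline = spline),
              class = "trajectoryFit")
}

#' @param x a \code{trajectoryFit}.
#' @param ... ignored.
#' @rdname fitTrajectory
#' @export
print.trajectoryFit <- function(x, ...) {
    cat("Piecewise-linear age trajectory:", x$nBreaks, "breakpoint(s)")
    if (x$nBreaks > 0) {
        cat(" at", paste(round(x$breakpoints, 1), collapse = ", "), "years")
    }
    cat("\n  segment slopes:",
        paste(signif(x$segmentSlopes, 3), collapse = ", "),
        "\n  BIC by breakpoint count:",
        paste(names(x$bicByCount), round(x$bicByCount, 1),
              sep = "=", collapse = " "), "\n")
    invisible(x)
}

#' First principal component scores of samples
#'
#' Standardizes genes, takes the first principal direction of the samples,
#' and reports the per-sample scores and the fraction of total variance the
#' first component captures. The sign is fixed so that the correlation of
#' the scores with age (when supplied) is non-negative, otherwise with the
#' per-sample mean expression — making cohort contrasts deterministic.
#'
#' @param x expression container (>= 3 samples).
#' @param age optional ages for sign orientation.
#' @return list with \code{scores} (named per sample) and
#'   \code{varianceFraction}.
#' @export
pc1Scores <- function(x, age = NULL) {
    m <- .exprs(x)
    if (ncol(m) < 3L) stop("PCA needs >= 3 samples")
    sdv <- apply(m, 1L, sd)
    z <- .standardizeRows(m[sdv > 0, , drop = FALSE])
    sv <- svd(z, nu = 0, nv = 1)
    scores <- sv$v[, 1L] * sv$d[1L]
    ref <- if (!is.null(age)) age else colMeans(z)
    if (sd(ref) > 0 && cor(scores, ref) < 0) scores <- -scores
    names(scores) <- colnames(m)
    list(scores = scores, varianceFraction = sv$d[1L]^2 / sum(sv$d^2))
}

#' Wilcoxon-Mann-Whitney two-sided rank-sum test
#'
#' Exact enumeration when both samples have at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Used for cohort contrasts of PC1 scores.
#'
#' @param a,b numeric score vectors.
#' @return the two-sided p-value.
#' @export
rankSumTest <- function(a, b) {
    stopifnot(length(a) >= 1, length(b) >= 1)
    noTies <- !anyDuplicated(c(a, b))
    exact <- length(a) <= 8L && length(b) <= 8L && noTies
    if (!exact && sd(c(a, b)) == 0) return(1)  # all values identical
    res <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = TRUE))
    unname(res$p.value)
}

#' Cross-cohort shared aging signature
#'
#' Intersects the age-related module genes of two cohorts, intersects their
#' significant DEGs within those modules, and scores the module overlap by
#' the upper-tail hypergeometric probability in the shared gene universe.
#'
#' @param genesA,genesB age-related module gene sets of the two cohorts.
#' @param degsA,degsB significant DEG vectors of the two cohorts.
#' @param universeSize size of the harmonized gene universe.
#' @return list with \code{shared}, \code{sharedDifferential},
#'   \code{overlapP}, and \code{venn} (aOnly, shared, bOnly).
#' @export
sharedSignature <- function(genesA, genesB, degsA = character(0),
                            degsB = character(0), universeSize) {
    genesA <- unique(genesA); genesB <- unique(genesB)
    if (universeSize < max(length(genesA), length(genesB))) {
        stop("universe smaller than a gene set")
    }
    shared <- intersect(genesA, genesB)
    sharedDiff <- intersect(intersect(degsA, genesA),
                            intersect(degsB, genesB))
    p <- hypergeomUpperTail(length(shared), length(genesA),
                            length(genesB), universeSize)
    list(shared = sort(shared),
         sharedDifferential = sort(sharedDiff),
         overlapP = p,
         venn = c(aOnly = length(setdiff(genesA, genesB)),
                  shared = length(shared),
                  bOnly = length(setdiff(genesB, genesA))))
}

#' Relative expression by the 2^-ddCt method
#'
#' \eqn{\Delta\Delta C_T = (C_T^{target} - C_T^{ref}) -
#' (C_T^{target,cal} - C_T^{ref,cal})}; returns \eqn{2^{-\Delta\Delta C_T}},
#' the fold expression of the target gene relative to the reference gene
#' and calibrator sample.
#'
#' @param ctTarget,ctReference target/reference-gene Ct of the test sample.
#' @param ctTargetCalibrator,ctReferenceCalibrator same for the calibrator
#'   sample.
#' @return relative expression (fold).
#' @examples
#' deltaDeltaCt(25, 20, 24, 20)  # 0.5
#' @export
deltaDeltaCt <- function(ctTarget, ctReference, ctTargetCalibrator,
                         ctReferenceCalibrator) {
    stopifnot(is.finite(ctTarget), is.finite(ctReference),
              is.finite(ctTargetCalibrator), is.finite(ctReferenceCalibrator))
    ddct <- (ctTarget - ctReference) -
        (ctTargetCalibrator - ctReferenceCalibrator)
    2^(-ddct)
}
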