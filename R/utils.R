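# Internal helpers shared across the pipeline stages.

# Fixed module palette; modules beyond it get numeric suffixes. Ordering by
# size descending + this palette keeps outputs byte-stable across runs.
.MODULE_COLORS <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3")

.moduleNames <- function(n) {
    if (n <= length(.MODULE_COLORS)) return(.MODULE_COLORS[seq_len(n)])
    c(.MODULE_COLORS,
      paste0("module", seq.int(length(.MODULE_COLORS) + 1L, n)))
}

# Extract a genes x samples numeric matrix from a SummarizedExperiment or a
# plain matrix; every user-facing operation goes through this.
.exprs <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x)
    } else if (is.matrix(x)) {
        m <- x
    } else {
        stop("expected a SummarizedExperiment or a genes x samples matrix, got ",
             class(x)[1])
    }
    if (is.null(rownames(m)) || is.null(colnames(m))) {
        stop("expression matrix must carry gene rownames and sample colnames")
    }
    storage.mode(m) <- "double"
    m
}

.scaleTag <- function(x, default = "log2") {
    if (is(x, "SummarizedExperiment")) {
        tag <- S4Vectors::metadata(x)$scale
        if (!is.null(tag)) return(tag)
    }
    default
}

# Rebuild a container like `x` around a new matrix (row subset/transform).
.rewrap <- function(x, m, scale = NULL) {
    if (is(x, "SummarizedExperiment")) {
        out <- x[rownames(m), colnames(m)]
        SummarizedExperiment::assay(out) <- m
        if (!is.null(scale)) S4Vectors::metadata(out)$scale <- scale
        out
    } else {
        m
    }
}

# Standardize gene rows to mean 0, variance 1; errors on constant rows unless
# they are dropped by the caller first.
.standardizeRows <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, sd)
    if (any(sdv == 0)) {
        stop("zero-variance gene(s): ",
             paste(head(rownames(m)[sdv == 0], 5L), collapse = ", "))
    }
    (m - mu) / sdv
}

# Two-sided p for a Pearson correlation via the t transform; |r| = 1 maps to
# the smallest representable double rather than 0.
.corPvalue <- function(r, n) {
    r <- pmin(1, pmax(-1, r))
    p <- ifelse(abs(r) >= 1, .Machine$double.xmin, {
        tt <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.xmin))
        2 * pt(tt, df = n - 2, lower.tail = FALSE)
    })
    pmax(p, .Machine$double.xmin)
}

# Numeric trait encodings: age as-is, sex F=0/M=1, 2-level group 0/1,
# >2-level categorical expanded to one-vs-rest indicator columns.
.encodeTraits <- function(traits, which = setdiff(colnames(traits), "sample")) {
    stopifnot(is.data.frame(traits))
    cols <- list()
    for (tr in which) {
        v <- traits[[tr]]
        if (is.null(v)) stop("trait not found: ", tr)
        if (is.numeric(v)) {
            cols[[tr]] <- as.numeric(v)
        } else {
            v <- as.character(v)
            lev <- sort(unique(v))
            if (length(lev) == 1L) {
                stop("constant trait cannot be correlated: ", tr)
            } else if (identical(lev, c("F", "M"))) {
                cols[[tr]] <- as.numeric(v == "M")
            } else if (length(lev) == 2L) {
                cols[[tr]] <- as.numeric(v == lev[2L])
            } else {
                for (l in lev) {
                    cols[[paste(tr, l, sep = ".")]] <- as.numeric(v == l)
                }
            }
        }
    }
    out <- do.call(cbind, cols)
    rownames(out) <- traits$sample
    out
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

# Run an expression under a local RNG state seeded by `seed`, restoring the
# caller's RNG afterwards: generators are pure functions of (params, seed).
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}
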