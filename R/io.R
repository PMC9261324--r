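#' Read a gene x sample expression table
#'
#' Reads a delimited text file (TSV by default; comma auto-detected from the
#' header line) with one header row of sample IDs and a leading column of
#' gene IDs, into a \code{SummarizedExperiment} with a single \code{exprs}
#' assay. Orientation is normalized to genes x samples.
#'
#' @param path file path.
#' @param orientation \code{"genes_in_rows"} (default) or
#'   \code{"samples_in_rows"}.
#' @param scale scale tag recorded in the object metadata: one of
#'   \code{"raw_counts"}, \code{"fpkm"}, \code{"log2"},
#'   \code{"normalized_intensity"}.
#' @return \code{SummarizedExperiment}, assay \code{exprs}, metadata
#'   \code{scale}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' writeExpression(m, f)
#' se <- readExpression(f)
#' dim(se)
#' @export
readExpression <- function(path,
                           orientation = c("genes_in_rows", "samples_in_rows"),
                           scale = c("log2", "fpkm", "raw_counts",
                                     "normalized_intensity")) {
    orientation <- match.arg(orientation)
    scale <- match.arg(scale)
    sep <- .sniffSep(path)
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     row.names = NULL, colClasses = NA,
                     stringsAsFactors = FALSE, quote = "\"", comment.char = "")
    if (nrow(df) == 0L || ncol(df) < 2L) {
        stop("empty or malformed expression file: ", path)
    }
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) {
        stop("duplicate IDs in first column: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    valcols <- df[-1L]
    for (j in seq_along(valcols)) {
        v <- valcols[[j]]
        if (!is.numeric(v)) {
            suppressWarnings(vn <- as.numeric(v))
            bad <- which(is.na(vn) & !is.na(v))
            if (length(bad)) {
                stop("non-numeric value at row ", bad[1L] + 1L, ", column ",
                     colnames(valcols)[j], " of ", path)
            }
            valcols[[j]] <- vn
        }
    }
    m <- as.matrix(valcols)
    rownames(m) <- ids
    if (anyDuplicated(colnames(m))) {
        stop("duplicate IDs in header: ",
             paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
    }
    if (any(!is.finite(m))) {
        idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
        stop("non-finite value at gene ", rownames(m)[idx[1L]],
             ", sample ", colnames(m)[idx[2L]])
    }
    if (orientation == "samples_in_rows") m <- t(m)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = m))
    S4Vectors::metadata(se)$scale <- scale
    se
}

.sniffSep <- function(path) {
    hdr <- readLines(path, n = 1L)
    if (!length(hdr)) stop("empty file: ", path)
    if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else "\t"
}

#' Write an expression matrix as TSV
#'
#' Writes genes x samples values with a \code{gene} ID column, at full
#' double precision (15 significant digits), so write/read round trips are
#' value-exact.
#'
#' @param x \code{SummarizedExperiment} or genes x samples matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
    m <- .exprs(x)
    df <- data.frame(gene = rownames(m),
                     format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a sample trait table
#'
#' Trait tables are TSV with a \code{sample} column plus \code{age} (years),
#' \code{sex} (F/M) and any further categorical columns (ethnicity, group).
#'
#' @param path file path.
#' @return \code{readTraits}: a data.frame; \code{writeTraits}: \code{path}.
#' @export
readTraits <- function(path) {
    df <- read.table(path, header = TRUE, sep = .sniffSep(path),
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample" %in% colnames(df)) stop("trait table needs a 'sample' column")
    df$sample <- as.character(df$sample)
    if (anyDuplicated(df$sample)) stop("duplicate sample IDs in trait table")
    if ("age" %in% colnames(df) && any(df$age < 0 | df$age > 120)) {
        stop("ages must lie in [0, 120]")
    }
    df
}

#' @param traits data.frame as returned by \code{readTraits}.
#' @rdname readTraits
#' @export
writeTraits <- function(traits, path) {
    write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name, description, member, member, ...}. Duplicate members within a
#' line are dropped; empty sets are dropped with a warning.
#'
#' @param path GMT file.
#' @return named list of unique member character vectors.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tA\tB\tB", f)
#' readGmt(f)
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty GMT file: ", path)
    out <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L) {
            stop("GMT line ", i, " has fewer than 3 fields")
        }
        members <- unique(f[-(1:2)])
        members <- members[nzchar(members)]
        if (!length(members)) {
            warning("dropping empty gene set '", f[1L], "' (line ", i, ")")
            next
        }
        out[[f[1L]]] <- members
    }
    out
}

#' @param sets named list of member vectors.
#' @param descriptions optional character vector of set descriptions.
#' @rdname readGmt
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Reads a STRING-style delimited edge list with two node columns and an
#' optional numeric score column (STRING \code{combined_score} convention:
#' 0--1000; \code{minScore} is compared on the file's own scale). The result
#' is a simple undirected \code{igraph} graph: self-loops removed, duplicate
#' and reversed edges collapsed, edges below \code{minScore} excluded.
#'
#' @param path edge-list file; first two columns are node IDs.
#' @param scoreColumn name of the score column, or \code{NULL} for no
#'   filtering.
#' @param minScore minimum retained score (same scale as the file).
#' @return undirected simple \code{igraph} graph with a \code{score} edge
#'   attribute when a score column is present.
#' @export
readEdgeList <- function(path, scoreColumn = "combined_score", minScore = 0) {
    df <- read.table(path, header = TRUE, sep = .sniffSep(path),
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("edge list needs at least two node columns")
    if (minScore > 0 && (is.null(scoreColumn) || !scoreColumn %in% colnames(df))) {
        stop("score filtering requested but score column '",
             scoreColumn, "' not found")
    }
    a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
    score <- if (!is.null(scoreColumn) && scoreColumn %in% colnames(df)) {
        as.numeric(df[[scoreColumn]])
    } else NULL
    keep <- a != b
    if (!is.null(score)) keep <- keep & score >= minScore
    a2 <- a[keep]; b2 <- b[keep]
    s2 <- if (!is.null(score)) score[keep] else NULL
    lo <- pmin(a2, b2); hi <- pmax(a2, b2)
    key <- paste(lo, hi, sep = "\r")
    first <- !duplicated(key)
    g <- igraph::graph_from_data_frame(
        data.frame(from = lo[first], to = hi[first],
                   stringsAsFactors = FALSE),
        directed = FALSE, vertices = sort(unique(c(a2, b2))))
    if (!is.null(s2)) igraph::E(g)$score <- s2[first]
    g
}

#' @param graph an \code{igraph} graph.
#' @rdname readEdgeList
#' @export
writeEdgeList <- function(graph, path) {
    el <- igraph::as_data_frame(graph, what = "edges")
    colnames(el)[1:2] <- c("protein1", "protein2")
    if ("score" %in% colnames(el)) colnames(el)[colnames(el) == "score"] <-
        "combined_score"
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
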