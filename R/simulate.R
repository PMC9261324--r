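#' Specify a planted co-expression module
#'
#' A planted module is a factor-model block: a latent eigengene profile over
#' samples (driven by an age effect plus Gaussian noise) and member genes
#' that load on it with loadings drawn from \code{loadingRange} plus
#' independent gene-level noise. The factor model is chosen deliberately:
#' the pipeline's own module summary is the first principal component, so
#' the planted truth and the estimand are commensurable.
#'
#' @param name module name (used as the truth label).
#' @param nGenes number of member genes (>= 1).
#' @param ageEffect one of \code{ageEffectNone()},
#'   \code{ageEffectLinear(slope)} (eigengene units per year before
#'   standardization), or \code{ageEffectBreakpoint(changeAge, slopeBefore,
#'   slopeAfter)}.
#' @param loadingRange interval within (0, 1] from which gene loadings are
#'   drawn uniformly.
#' @param eigengeneNoiseSd sd of sample-level noise added to the
#'   standardized age trend (default 0.3).
#' @param geneNoiseSd sd of gene-level noise around \code{loading * eigengene}
#'   (default 0.5).
#' @param nHubs how many member genes (the first ones) are recorded as
#'   planted hubs for the interaction-network generator.
#' @param geneIds optional explicit member gene IDs (length \code{nGenes});
#'   needed when a module must be shared verbatim between two cohorts.
#' @return a \code{list} of class \code{"moduleSpec"}.
#' @examples
#' moduleSpec("green", 50, ageEffect = ageEffectLinear(0.05))
#' @export
moduleSpec <- function(name, nGenes,
                       ageEffect = ageEffectNone(),
                       loadingRange = c(0.5, 0.95),
                       eigengeneNoiseSd = 0.3,
                       geneNoiseSd = 0.5,
                       nHubs = 0L,
                       geneIds = NULL) {
    stopifnot(nGenes >= 1, length(loadingRange) == 2L,
              loadingRange[1] > 0, loadingRange[2] <= 1,
              loadingRange[1] <= loadingRange[2],
              eigengeneNoiseSd >= 0, geneNoiseSd >= 0,
              nHubs >= 0, nHubs <= nGenes)
    if (!is.null(geneIds)) {
        stopifnot(length(geneIds) == nGenes, !anyDuplicated(geneIds))
    }
    structure(list(name = name, nGenes = as.integer(nGenes),
                   ageEffect = ageEffect, loadingRange = loadingRange,
                   eigengeneNoiseSd = eigengeneNoiseSd,
                   geneNoiseSd = geneNoiseSd, nHubs = as.integer(nHubs),
                   geneIds = geneIds),
              class = "moduleSpec")
}

#' @rdname moduleSpec
#' @export
ageEffectNone <- function() {
    structure(list(type = "none"), class = "ageEffect")
}

#' @param slope eigengene change per year (pre-standardization scale).
#' @rdname moduleSpec
#' @export
ageEffectLinear <- function(slope) {
    structure(list(type = "linear", slope = slope), class = "ageEffect")
}

#' @param changeAge age (years) at which the slope changes.
#' @param slopeBefore,slopeAfter slopes on either side of the change age.
#' @rdname moduleSpec
#' @export
ageEffectBreakpoint <- function(changeAge, slopeBefore, slopeAfter) {
    structure(list(type = "breakpoint", changeAge = changeAge,
                   slopeBefore = slopeBefore, slopeAfter = slopeAfter),
              class = "ageEffect")
}

.ageTrend <- function(effect, ages) {
    switch(effect$type,
           none = rep(0, length(ages)),
           linear = effect$slope * ages,
           breakpoint = effect$slopeBefore * pmin(ages, effect$changeAge) +
               effect$slopeAfter * pmax(ages - effect$changeAge, 0),
           stop("unknown age effect type: ", effect$type))
}

#' Simulate one cohort with planted co-expression structure
#'
#' Samples get ages uniform over \code{ageRange} (or an explicit \code{ages}
#' vector) and balanced F/M sex labels. Each planted module's eigengene is
#' the standardized age trend plus \code{Normal(0, eigengeneNoiseSd)} sample
#' noise (an age-free module uses a standardized Gaussian profile, so it is
#' independent of age by construction); each member gene is
#' \code{loading * eigengene + Normal(0, geneNoiseSd)} with its loading drawn
#' from the module's loading range. Background genes are i.i.d.
#' \code{Normal(0, 1)}. Everything is a pure function of the parameters and
#' \code{seed}.
#'
#' @param nBackground number of unstructured background genes.
#' @param modules list of \code{\link{moduleSpec}} objects.
#' @param nSamples number of samples (>= 4).
#' @param ageRange two ages (years); default 21--93, the adult span the
#'   design emulates.
#' @param seed integer seed.
#' @param ages optional explicit ages (length \code{nSamples}).
#' @param ethnicity single label stored in the trait table.
#' @param samplePrefix prefix for generated sample IDs.
#' @return list with \code{expr} (a \code{SummarizedExperiment}, log-like
#'   continuous scale, traits in \code{colData}) and \code{truth}
#'   (\code{\link{CohortTruth-class}}).
#' @examples
#' sim <- simulateCohort(nBackground = 100,
#'                       modules = list(moduleSpec("green", 50,
#'                                      ageEffect = ageEffectLinear(0.05))),
#'                       nSamples = 30, seed = 1)
#' sim$expr
#' @export
simulateCohort <- function(nBackground, modules, nSamples,
                           ageRange = c(21, 93), seed = 1L, ages = NULL,
                           ethnicity = "cohortA", samplePrefix = "S") {
    stopifnot(nSamples >= 4)
    if (length(modules) == 0L && nBackground == 0L) {
        stop("nothing to simulate: no modules and no background genes")
    }
    .withSeed(seed, {
        if (is.null(ages)) {
            ages <- runif(nSamples, ageRange[1], ageRange[2])
        } else {
            stopifnot(length(ages) == nSamples)
        }
        sampleIds <- sprintf("%s%03d", samplePrefix, seq_len(nSamples))
        sex <- sample(rep(c("F", "M"), length.out = nSamples))
        group <- cut(ages, c(0, 40, 64, 120),
                     labels = c("young", "middle", "old"))
        traits <- data.frame(sample = sampleIds, age = ages, sex = sex,
                             ethnicity = ethnicity,
                             group = as.character(group),
                             stringsAsFactors = FALSE)

        geneRows <- list()
        geneModules <- character()
        hubs <- character()
        trueME <- matrix(0, nrow = 0, ncol = nSamples)
        for (ms in modules) {
            trend <- .ageTrend(ms$ageEffect, ages)
            base <- if (sd(trend) > 0) {
                as.numeric(scale(trend))
            } else {
                as.numeric(scale(rnorm(nSamples)))
            }
            e <- base + rnorm(nSamples, 0, ms$eigengeneNoiseSd)
            ids <- if (is.null(ms$geneIds)) {
                sprintf("%s_g%03d", ms$name, seq_len(ms$nGenes))
            } else ms$geneIds
            loadings <- runif(ms$nGenes, ms$loadingRange[1], ms$loadingRange[2])
            block <- outer(loadings, e) +
                matrix(rnorm(ms$nGenes * nSamples, 0, ms$geneNoiseSd),
                       ms$nGenes, nSamples)
            rownames(block) <- ids
            geneRows[[ms$name]] <- block
            geneModules[ids] <- ms$name
            if (ms$nHubs > 0L) hubs <- c(hubs, ids[seq_len(ms$nHubs)])
            trueME <- rbind(trueME, e)
            rownames(trueME)[nrow(trueME)] <- ms$name
        }
        if (nBackground > 0L) {
            bgIds <- sprintf("bg_g%04d", seq_len(nBackground))
            bg <- matrix(rnorm(nBackground * nSamples), nBackground, nSamples)
            rownames(bg) <- bgIds
            geneRows[["..background"]] <- bg
            geneModules[bgIds] <- "background"
        }
        m <- do.call(rbind, geneRows)
        if (anyDuplicated(rownames(m))) {
            stop("duplicate gene IDs across modules/background: ",
                 paste(head(unique(rownames(m)[duplicated(rownames(m))]), 5L),
                       collapse = ", "))
        }
        colnames(m) <- sampleIds
        colnames(trueME) <- sampleIds

        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(exprs = m),
            colData = S4Vectors::DataFrame(traits, row.names = sampleIds))
        S4Vectors::metadata(se)$scale <- "log2"
        truth <- new("CohortTruth", geneModules = geneModules,
                     eigengenes = trueME, hubGenes = hubs, traits = traits)
        list(expr = se, truth = truth)
    })
}

#' Simulate two cohorts sharing a subset of modules
#'
#' Shared modules keep identical gene membership in both cohorts (with
#' independent noise realizations); cohort-specific modules exist only in
#' their own cohort and their genes appear as unstructured background in the
#' other, emulating a cross-population design where part of the
#' age-associated signature is ancestry-shared and part is
#' ancestry-specific.
#'
#' @param shared,onlyA,onlyB lists of \code{\link{moduleSpec}}; shared specs
#'   are given explicit gene IDs automatically if they lack them.
#' @param nSamplesA,nSamplesB cohort sizes.
#' @param nBackground unstructured background genes per cohort (on top of
#'   the other cohort's specific genes).
#' @param ageRange age span in years.
#' @param seed integer seed; the two cohorts use \code{seed} and
#'   \code{seed + 1}.
#' @return list of two \code{list(expr, truth)} pairs, named \code{A} and
#'   \code{B}.
#' @export
simulateTwoCohorts <- function(shared, onlyA = list(), onlyB = list(),
                               nSamplesA = 60L, nSamplesB = 60L,
                               nBackground = 300L, ageRange = c(21, 93),
                               seed = 1L) {
    fillIds <- function(ms, tag) {
        if (is.null(ms$geneIds)) {
            ms$geneIds <- sprintf("%s_%s_g%03d", tag, ms$name,
                                  seq_len(ms$nGenes))
        }
        ms
    }
    shared <- lapply(shared, fillIds, tag = "sh")
    onlyA <- lapply(onlyA, fillIds, tag = "a")
    onlyB <- lapply(onlyB, fillIds, tag = "b")
    idsOf <- function(specs) unlist(lapply(specs, `[[`, "geneIds"))
    if (length(intersect(idsOf(onlyA), idsOf(onlyB)))) {
        stop("gene ID collision between cohort-specific modules")
    }
    if (length(intersect(idsOf(shared), c(idsOf(onlyA), idsOf(onlyB))))) {
        stop("gene ID collision between shared and cohort-specific modules")
    }
    asBackground <- function(specs) {
        ids <- idsOf(specs)
        if (!length(ids)) return(NULL)
        ids
    }
    simOne <- function(own, foreign, n, s, eth, prefix) {
        sim <- simulateCohort(nBackground = nBackground, modules = own,
                              nSamples = n, ageRange = ageRange, seed = s,
                              ethnicity = eth, samplePrefix = prefix)
        fids <- asBackground(foreign)
        if (!is.null(fids)) {
            # the other cohort's specific genes exist here as plain noise
            extra <- .withSeed(s + 104729L, {
                matrix(rnorm(length(fids) * n), length(fids), n,
                       dimnames = list(fids, colnames(sim$expr)))
            })
            m <- rbind(.exprs(sim$expr), extra)
            se <- SummarizedExperiment::SummarizedExperiment(
                assays = list(exprs = m),
                colData = SummarizedExperiment::colData(sim$expr))
            S4Vectors::metadata(se)$scale <- "log2"
            gm <- truthModules(sim$truth)
            gm[fids] <- "background"
            sim$truth@geneModules <- gm
            validObject(sim$truth)
            sim$expr <- se
        }
        sim
    }
    list(A = simOne(c(shared, onlyA), onlyB, nSamplesA, seed,
                    "Asian", "A"),
         B = simOne(c(shared, onlyB), onlyA, nSamplesB, seed + 1L,
                    "Caucasian", "B"))
}

#' Simulate a protein-protein interaction network around planted hubs
#'
#' For each planted hub gene in \code{truth}, \code{cliquesPerHub} cliques
#' of \code{hubCliqueSize} nodes are wired over the hub plus sampled
#' same-module genes (the cliques of one hub intersect only in the hub);
#' every remaining node pair is connected independently with probability
#' \code{backgroundEdgeProb}. The result is a simple undirected graph on
#' the requested genes, emulating a STRING-style neighborhood where hub
#' genes sit in dense maximal cliques. The default of two cliques per hub
#' makes the hub identifiable: a node in a single clique is
#' score-equivalent to its clique-mates under maximal clique centrality,
#' whereas a node joining several cliques — the signature of a protein
#' shared by several complexes — uniquely dominates them.
#'
#' @param truth a \code{\link{CohortTruth-class}}.
#' @param genes nodes of the graph; default all genes in the truth map.
#' @param hubCliqueSize clique size planted around each hub (>= 3).
#' @param cliquesPerHub number of cliques planted through each hub (>= 1).
#' @param backgroundEdgeProb background edge probability in [0, 0.2].
#' @param seed integer seed.
#' @return undirected simple \code{igraph} graph.
#' @export
simulatePPI <- function(truth, genes = names(truthModules(truth)),
                        hubCliqueSize = 6L, cliquesPerHub = 2L,
                        backgroundEdgeProb = 0.02, seed = 1L) {
    stopifnot(hubCliqueSize >= 3, cliquesPerHub >= 1,
              backgroundEdgeProb >= 0, backgroundEdgeProb <= 0.2)
    gm <- truthModules(truth)
    hubs <- truthHubs(truth)
    missingHubs <- setdiff(hubs, names(gm))
    if (length(missingHubs)) {
        stop("hub gene(s) not in truth map: ",
             paste(missingHubs, collapse = ", "))
    }
    hubs <- intersect(hubs, genes)
    genes <- unique(genes)
    .withSeed(seed, {
        edges <- character(0)
        cliqueEdges <- list()
        # mate pools are disjoint across all cliques of all hubs of a
        # module, so a clique-mate belongs to exactly one planted clique
        # and cannot tie a multi-clique hub
        for (mod in unique(gm[hubs])) {
            modHubs <- hubs[gm[hubs] == mod]
            pool <- sample(setdiff(intersect(names(gm)[gm == mod], genes),
                                   modHubs))
            used <- 0L
            for (h in modHubs) {
                for (cl in seq_len(cliquesPerHub)) {
                    take <- min(hubCliqueSize - 1L, length(pool) - used)
                    if (take < 1L) break
                    members <- c(h, pool[used + seq_len(take)])
                    used <- used + take
                    cliqueEdges[[paste(h, cl)]] <-
                        t(utils::combn(members, 2L))
                }
            }
        }
        n <- length(genes)
        bgEdges <- NULL
        if (backgroundEdgeProb > 0 && n >= 2L) {
            pairs <- t(utils::combn(genes, 2L))
            pick <- runif(nrow(pairs)) < backgroundEdgeProb
            bgEdges <- pairs[pick, , drop = FALSE]
        }
        allEdges <- do.call(rbind, c(cliqueEdges, list(bgEdges)))
        if (is.null(allEdges) || nrow(allEdges) == 0L) {
            return(igraph::make_empty_graph(n = n, directed = FALSE) |>
                       igraph::set_vertex_attr("name", value = genes))
        }
        lo <- pmin(allEdges[, 1L], allEdges[, 2L])
        hi <- pmax(allEdges[, 1L], allEdges[, 2L])
        key <- paste(lo, hi, sep = "\r")
        first <- !duplicated(key)
        igraph::graph_from_data_frame(
            data.frame(from = lo[first], to = hi[first],
                       stringsAsFactors = FALSE),
            directed = FALSE, vertices = genes)
    })
}

#' Exponentiate a log-like matrix to an FPKM-like scale
#'
#' \code{2^x} applied elementwise, retagged as \code{fpkm}, so the
#' linear-scale expressed-gene filter path can be exercised on synthetic
#' data.
#'
#' @param x \code{SummarizedExperiment} or matrix on a log-like scale.
#' @return same container type on the exponentiated scale.
#' @export
toFpkmLike <- function(x) {
    m <- 2^.exprs(x)
    .rewrap(x, m, scale = "fpkm")
}
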