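test_that("pairwise correlation matches a direct covariance/SD computation", {
    set.seed(1)
    m <- matrix(rnorm(200), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
    m[2, ] <- m[1, ]           # duplicate
    m[3, ] <- -m[1, ]          # negation
    r <- pairwiseCorrelation(m)
    expect_equal(r[1, 2], 1)
    expect_equal(r[1, 3], -1)
    # brute-force oracle
    brute <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
        xi <- m[i, ] - mean(m[i, ]); xj <- m[j, ] - mean(m[j, ])
        brute[i, j] <- sum(xi * xj) /
            sqrt(sum(xi^2)) / sqrt(sum(xj^2))
    }
    expect_lt(max(abs(unname(r) - brute)), 1e-12)
    m[4, ] <- 5
    expect_error(pairwiseCorrelation(m), "zero-variance")
})

test_that("soft adjacency follows the unsigned/signed definitions", {
    r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 1, -0.5, 1, 1), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    au <- softAdjacency(r, 2)
    expect_equal(au["a", "b"], 0.25)
    expect_equal(au["a", "c"], 0.25)
    expect_equal(au["b", "c"], 1)
    as <- softAdjacency(r, 2, "signed")
    expect_equal(as["a", "c"], 0.0625)
    expect_true(all(diag(au) == 1))
    expect_error(softAdjacency(r, 0), "beta")
})

test_that("scale-free fit is exact on an exact power law", {
    # counts proportional to 1/k: freq = (400/75)/k exactly
    k <- rep(c(10, 20, 40, 80), times = c(40, 20, 10, 5))
    fit <- scaleFreeFit(k, nBins = 10)
    expect_equal(fit$rSquared, 1, tolerance = 1e-12)
    expect_equal(fit$slope, -1, tolerance = 1e-12)
    # two occupied bins: R^2 = 1 by construction
    fit2 <- scaleFreeFit(rep(c(1, 10), c(30, 3)), nBins = 2)
    expect_equal(fit2$rSquared, 1, tolerance = 1e-12)
    expect_warning(fitc <- scaleFreeFit(rep(2, 10)), "equal")
    expect_identical(fitc$rSquared, 0)
})

test_that("soft-threshold selection honors target, fallback and single candidate", {
    set.seed(4)
    sim <- simulateCohort(100, recoveryModules(30), nSamples = 40, seed = 4)
    r <- pairwiseCorrelation(sim$expr)
    one <- suppressWarnings(pickSoftThreshold(r, candidates = 6))
    expect_identical(one$beta, 6L)
    pick <- suppressWarnings(pickSoftThreshold(r, target = 0.3))
    i <- match(pick$beta, pick$table$beta)
    ok <- pick$table$rSquared > 0.3 & pick$table$slope < 0
    if (any(ok)) expect_identical(i, which(ok)[1])
    # hub-free dense adjacency: no candidate fits, fallback warns
    set.seed(5)
    mm <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
    expect_warning(pickSoftThreshold(pairwiseCorrelation(mm),
                                     candidates = c(1L, 2L), target = 0.99),
                   "falling back")
})

test_that("low-noise modular data passes the scale-free target at moderate powers", {
    # heterogeneous module sizes produce the right-skewed connectivity a
    # soft threshold is meant to expose; equal-sized blocks would not
    sizes <- c(200, 130, 90, 60, 45, 35, 30, 25, 20, 15)
    for (s in 1:5) {
        mods <- lapply(seq_along(sizes), function(i) {
            moduleSpec(paste0("m", i), sizes[i],
                       eigengeneNoiseSd = 0.1, geneNoiseSd = 0.2)
        })
        sim <- simulateCohort(350, mods, nSamples = 60, seed = s)
        pick <- pickSoftThreshold(pairwiseCorrelation(sim$expr))
        expect_lte(pick$beta, 12L)
        expect_gt(pick$fit$rSquared, 0.8)
        expect_lt(pick$fit$slope, 0)
    }
})

test_that("TOM matches hand evaluations and the double-loop oracle", {
    a4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    expect_equal(unname(tomSimilarity(a4)),
                 matrix(1, 4, 4))                      # (2+1)/(3+1-1) = 1
    a0 <- diag(3); dimnames(a0) <- list(letters[1:3], letters[1:3])
    expect_equal(unname(tomSimilarity(a0)), diag(3))   # all-zero off-diagonal
    path <- diag(3)
    path[1, 2] <- path[2, 1] <- 0.5
    path[2, 3] <- path[3, 2] <- 0.5
    dimnames(path) <- list(letters[1:3], letters[1:3])
    expect_equal(tomSimilarity(path)["a", "c"], 1 / 6)

    for (s in 1:3) {
        set.seed(s)
        a <- matrix(runif(30 * 30), 30, 30)
        a <- (a + t(a)) / 2; diag(a) <- 1
        dimnames(a) <- list(paste0("g", 1:30), paste0("g", 1:30))
        tom <- tomSimilarity(a)
        expect_lt(max(abs(tom - bruteTom(a))), 1e-12)
        expect_true(all(tom >= 0 & tom <= 1))
        expect_equal(tom, t(tom))
    }
})

test_that("tree cut recovers planted TOM blocks exactly", {
    set.seed(6)
    n <- 80
    tom <- matrix(0.05 + runif(n * n, -0.02, 0.02), n, n)
    tom <- (tom + t(tom)) / 2
    tom[1:40, 1:40] <- 0.9 + runif(1600, -0.02, 0.02)
    tom[41:80, 41:80] <- 0.9 + runif(1600, -0.02, 0.02)
    tom <- (tom + t(tom)) / 2; diag(tom) <- 1
    dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
    part <- cutModules(tom, minModuleSize = 30)
    expect_length(moduleSizes(part), 2)
    truthLab <- rep(c("A", "B"), each = 40)
    expect_equal(ariOf(truthLab, moduleLabels(part)), 1)
})

test_that("near-uniform null TOM yields at most one module", {
    for (s in 1:5) {
        set.seed(s)
        tom <- matrix(runif(50 * 50, 0, 0.05), 50, 50)
        tom <- (tom + t(tom)) / 2; diag(tom) <- 1
        dimnames(tom) <- list(paste0("g", 1:50), paste0("g", 1:50))
        part <- cutModules(tom, minModuleSize = 30)
        expect_lte(length(moduleSizes(part)), 1)
    }
    expect_warning(part <- cutModules(tom, minModuleSize = 51), "unassigned")
    expect_true(all(moduleLabels(part) == "unassigned"))
})

test_that("module eigengene matches the eigendecomposition oracle", {
    set.seed(7)
    m <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:15)))
    part <- setNames(rep("mod", 20), rownames(m))
    me <- moduleEigengenes(m, part)
    e <- eigengenes(me)["mod", ]
    z <- t(scale(t(m)))
    eig <- eigen(crossprod(z))          # sample-space covariance (up to const)
    oracle <- eig$vectors[, 1]
    oracle <- oracle / sd(oracle)
    if (cor(oracle, e) < 0) oracle <- -oracle
    expect_equal(unname(e), oracle, tolerance = 1e-8)
    expect_equal(unname(varianceExplained(me)["mod"]),
                 eig$values[1] / sum(eig$values), tolerance = 1e-10)
    expect_equal(var(e), 1, tolerance = 1e-12)
})

test_that("degenerate modules: identical genes and mirrored pairs", {
    prof <- rnorm(10)
    m <- rbind(a = prof, b = prof, c = prof)
    colnames(m) <- paste0("s", 1:10)
    me <- moduleEigengenes(m, setNames(rep("mod", 3), rownames(m)))
    expect_equal(unname(varianceExplained(me)), 1)
    expect_gt(cor(eigengenes(me)["mod", ], prof), 0.999)

    m2 <- rbind(x = prof, y = -prof)
    colnames(m2) <- paste0("s", 1:10)
    me2 <- moduleEigengenes(m2, setNames(rep("mod", 2), rownames(m2)))
    expect_equal(unname(varianceExplained(me2)), 1)
    # single-gene module: eigengene is the standardized profile
    me3 <- moduleEigengenes(rbind(m, z = rnorm(10)),
                            setNames(c(rep("mod", 3), "solo"),
                                     c("a", "b", "c", "z")))
    expect_equal(unname(varianceExplained(me3)["solo"]), 1)
})

test_that("eigengene is optimal among random unit gene combinations", {
    set.seed(8)
    m <- matrix(rnorm(15 * 12), 15, 12,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:12)))
    me <- moduleEigengenes(m, setNames(rep("mod", 15), rownames(m)))
    z <- t(scale(t(m)))
    total <- sum(z^2)
    best <- varianceExplained(me)["mod"]
    for (i in 1:1000) {
        w <- rnorm(15); w <- w / sqrt(sum(w^2))
        proj <- drop(w %*% z)
        expect_lte(sum(proj^2) / total, best + 1e-10)
    }
})

test_that("eigengene-based merging joins duplicates and respects the cutline", {
    set.seed(9)
    e1 <- rnorm(30); e2 <- rnorm(30)
    mk <- function(e, n, name) {
        out <- outer(runif(n, 0.7, 0.95), e) + matrix(rnorm(n * 30, 0, 0.05),
                                                      n, 30)
        rownames(out) <- paste0(name, "_", seq_len(n))
        out
    }
    m <- rbind(mk(e1, 20, "p"), mk(e1, 20, "q"), mk(e2, 20, "r"))
    colnames(m) <- paste0("s", 1:30)
    part <- new("ModulePartition",
                labels = setNames(rep(c("p", "q", "r"), each = 20),
                                  rownames(m)),
                minModuleSize = 10L)
    merged <- mergeCloseModules(m, part, cutHeight = 0.2)
    lab <- moduleLabels(merged$partition)
    expect_length(unique(lab[1:40]), 1)          # p and q joined
    expect_length(moduleSizes(merged$partition), 2)
    # uncorrelated modules untouched at the same cutline
    expect_false(lab[41] == lab[1])
})

test_that("chained eigengene similarity collapses to one module and terminates", {
    set.seed(10)
    n <- 60
    eA <- rnorm(n)
    eB <- 0.92 * eA + sqrt(1 - 0.92^2) * rnorm(n)
    eC <- 0.92 * eB + sqrt(1 - 0.92^2) * rnorm(n)
    mk <- function(e, name) {
        out <- outer(rep(1, 15), e) + matrix(rnorm(15 * n, 0, 0.02), 15, n)
        rownames(out) <- paste0(name, "_", 1:15)
        out
    }
    m <- rbind(mk(eA, "A"), mk(eB, "B"), mk(eC, "C"))
    colnames(m) <- paste0("s", 1:n)
    part <- new("ModulePartition",
                labels = setNames(rep(c("A", "B", "C"), each = 15),
                                  rownames(m)),
                minModuleSize = 5L)
    merged <- mergeCloseModules(m, part, cutHeight = 0.2)
    expect_length(moduleSizes(merged$partition), 1)
})

test_that("raising the merge cutline never increases module count", {
    sim <- simulateCohort(100, recoveryModules(30), nSamples = 40, seed = 11)
    m <- SummarizedExperiment::assay(sim$expr)
    tom <- tomSimilarity(softAdjacency(pairwiseCorrelation(m), 6))
    part <- cutModules(tom, minModuleSize = 20)
    counts <- vapply(c(0, 0.1, 0.2, 0.4, 0.8), function(h) {
        length(moduleSizes(mergeCloseModules(m, part, h)$partition))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("module-trait correlation matches the t transform and a permutation oracle", {
    sim <- simulateCohort(0, list(moduleSpec("m", 5)), nSamples = 20, seed = 12)
    tr <- truthTraits(sim$truth)
    # eigengene equal to age: r = 1, p at the representable minimum
    e <- rbind(m = tr$age); colnames(e) <- tr$sample
    res <- moduleTraitCorrelation(e, tr, which = "age")
    expect_equal(res$r, 1)
    expect_identical(res$p, .Machine$double.xmin)
    # orthogonal to centered age: r = 0, p = 1
    v <- rnorm(20)
    v <- resid(lm(v ~ tr$age))
    e2 <- rbind(m = v); colnames(e2) <- tr$sample
    res2 <- moduleTraitCorrelation(e2, tr, which = "age")
    expect_equal(res2$r, 0, tolerance = 1e-12)
    expect_equal(res2$p, 1, tolerance = 1e-12)

    # permutation oracle at n = 20, r ~ 0.7
    set.seed(13)
    age <- tr$age
    y <- 0.7 * scale(age)[, 1] + sqrt(1 - 0.49) * rnorm(20)
    e3 <- rbind(m = y); colnames(e3) <- tr$sample
    pT <- moduleTraitCorrelation(e3, tr, which = "age")$p
    rObs <- abs(cor(y, age))
    B <- 1e5
    perms <- replicate(B, abs(cor(y, sample(age))))
    pPerm <- (1 + sum(perms >= rObs)) / (B + 1)
    expect_lt(abs(pT - pPerm), 3 * sqrt(pPerm * (1 - pPerm) / B) + 2e-4)
})

test_that("constant traits are rejected for correlation", {
    sim <- simulateCohort(0, list(moduleSpec("m", 5)), nSamples = 10, seed = 1)
    me <- moduleEigengenes(sim$expr, truthModules(sim$truth))
    tr <- truthTraits(sim$truth)
    expect_error(moduleTraitCorrelation(me, tr, which = "ethnicity"),
                 "constant")
})

test_that("GS and MM hit 1 on self-matches and rank own modules highest", {
    sim <- simulateCohort(50, list(moduleSpec("m1", 20), moduleSpec("m2", 20)),
                          nSamples = 30, seed = 14)
    m <- SummarizedExperiment::assay(sim$expr)
    me <- moduleEigengenes(m, truthModules(sim$truth))
    age <- truthTraits(sim$truth)$age
    m2 <- rbind(m, ageGene = age,
                me1Gene = eigengenes(me)["m1", ])
    res <- geneSignificanceMembership(m2, me, age)
    expect_equal(res$gs$gs[res$gs$gene == "ageGene"], 1)
    expect_equal(res$mm["me1Gene", "m1"], 1)

    for (s in 1:5) {
        simS <- simulateCohort(20, list(moduleSpec("m1", 15),
                                        moduleSpec("m2", 15)),
                               nSamples = 25, seed = 100 + s)
        mS <- SummarizedExperiment::assay(simS$expr)
        meS <- moduleEigengenes(mS, truthModules(simS$truth))
        resS <- geneSignificanceMembership(
            mS, meS, truthTraits(simS$truth)$age)
        gm <- truthModules(simS$truth)
        for (mod in c("m1", "m2")) {
            own <- mean(resS$mm[names(gm)[gm == mod], mod])
            other <- mean(resS$mm[names(gm)[gm == mod],
                                  setdiff(c("m1", "m2"), mod)])
            expect_gt(own, other)
        }
    }
})
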