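mkGroups <- function(n1, n2) rep(c("young", "old"), c(n1, n2))

test_that("log fold change is the difference of group means on log2 scale", {
    m <- matrix(rnorm(8 * 6), 6, 8,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
    gr <- mkGroups(4, 4)
    lfc <- logFoldChange(m, gr)
    hand <- rowMeans(m[, 5:8]) - rowMeans(m[, 1:4])
    expect_equal(lfc, hand, tolerance = 1e-14)
    m2 <- m; m2[, 5:8] <- m2[, 1:4] + 1
    expect_equal(unname(logFoldChange(m2, gr)), rep(1, 6))
    m3 <- m; m3[, 5:8] <- m3[, 1:4]
    expect_equal(unname(logFoldChange(m3, gr)), rep(0, 6))
    expect_error(logFoldChange(m, rep("old", 8)), "young")
})

test_that("welch test separates a near-degenerate contrast", {
    m <- rbind(g1 = c(0, 0, 0, 1, 1, 1) + c(0, 1e-9, -1e-9, 0, 1e-9, -1e-9))
    colnames(m) <- paste0("s", 1:6)
    res <- degTest(m, mkGroups(3, 3), method = "welch")
    expect_lt(res$p[1], 1e-6)
})

test_that("both test methods control the type-I rate under the global null", {
    for (method in c("welch", "moderated")) {
        set.seed(21)
        m <- matrix(rnorm(5000 * 20), 5000, 20,
                    dimnames = list(paste0("g", 1:5000), paste0("s", 1:20)))
        res <- degTest(m, mkGroups(10, 10), method = method)
        rate <- mean(res$p < 0.05)
        expect_gt(rate, 0.04)
        expect_lt(rate, 0.06)
    }
})

test_that("forcing infinite prior df reduces the moderated t to a z statistic", {
    set.seed(22)
    m <- matrix(rnorm(200 * 12), 200, 12,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
    gr <- mkGroups(6, 6)
    res <- degTest(m, gr, method = "moderated", priorDf = Inf)
    mu1 <- rowMeans(m[, 1:6]); mu2 <- rowMeans(m[, 7:12])
    z <- (mu2 - mu1) / sqrt(res$s02 * (1 / 6 + 1 / 6))
    expect_equal(unname(res$statistic), unname(z), tolerance = 1e-12)
    expect_equal(unname(res$p),
                 unname(2 * pnorm(abs(z), lower.tail = FALSE)),
                 tolerance = 1e-12)
})

test_that("moderated p-values track limma and welch on well-behaved data", {
    set.seed(23)
    m <- matrix(rnorm(500 * 40, sd = rep(runif(500, 0.5, 2), 40)), 500, 40,
                dimnames = list(paste0("g", 1:500), paste0("s", 1:40)))
    m[1:50, 21:40] <- m[1:50, 21:40] + 1
    gr <- mkGroups(20, 20)
    pm <- degTest(m, gr, method = "moderated")$p
    pw <- degTest(m, gr, method = "welch")$p
    expect_gt(cor(rank(pm), rank(pw)), 0.95)
    # independent oracle: limma's empirical-Bayes pipeline
    design <- cbind(1, as.numeric(gr == "old"))
    fit <- limma::eBayes(limma::lmFit(m, design))
    pl <- fit$p.value[, 2]
    expect_gt(cor(rank(pm), rank(pl)), 0.99)
    expect_lt(max(abs(log10(pm) - log10(pl))), 0.2)
})

test_that("degenerate genes get the conventional p-values", {
    m <- rbind(flat = rep(1, 8), shift = rep(c(1, 2), each = 4))
    colnames(m) <- paste0("s", 1:8)
    gr <- mkGroups(4, 4)
    for (method in c("welch", "moderated")) {
        res <- degTest(m, gr, method = method)
        expect_equal(unname(res$p["flat"]), 1)
        expect_lt(res$p["shift"], 1e-300)
    }
})

test_that("BH adjustment reproduces hand-computed step-up results", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_error(bhAdjust(c(0.1, 0)), "0, 1")
    expect_error(bhAdjust(numeric(0)), "empty")
    # permutation invariance and monotonicity
    set.seed(24)
    p <- runif(100)
    idx <- sample(100)
    expect_equal(bhAdjust(p)[idx], bhAdjust(p[idx]))
    adj <- bhAdjust(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("DEG selection applies both thresholds and counts directions", {
    lfc <- c(a = 0.6, b = 0.6, c = -1.2, d = 0.4)
    p <- c(a = 1e-4, b = 0.9, c = 1e-5, d = 1e-6)
    tab <- selectDegs(lfc, p, lfcThreshold = 0.5, fdr = 0.05)
    expect_identical(tab$significant, c(TRUE, FALSE, TRUE, FALSE))
    expect_identical(tab$direction[tab$gene == "c"], "down")
    s <- attr(tab, "summary")
    expect_identical(unname(s["nUp"]), 1L)
    expect_identical(unname(s["nDown"]), 1L)
    # adjusted p >= raw p elementwise
    expect_true(all(tab$padj >= tab$pvalue))
})

test_that("planted strong effects are recovered with controlled FDR", {
    for (s in 1:5) {
        set.seed(30 + s)
        m <- matrix(rnorm(2000 * 60), 2000, 60,
                    dimnames = list(paste0("g", 1:2000), paste0("s", 1:60)))
        m[1:300, 31:60] <- m[1:300, 31:60] + 1.5
        gr <- mkGroups(30, 30)
        res <- degTest(m, gr, method = "moderated")
        tab <- selectDegs(logFoldChange(m, gr), res$p,
                          lfcThreshold = 0.5, fdr = 0.05)
        called <- tab$gene[tab$significant]
        sens <- length(intersect(called, paste0("g", 1:300))) / 300
        fdp <- if (length(called)) {
            length(setdiff(called, paste0("g", 1:300))) / length(called)
        } else 0
        expect_gte(sens, 0.9)
        expect_lte(fdp, 0.1)
    }
})

test_that("module intersection returns the overlap and Venn regions", {
    part <- new("ModulePartition",
                labels = setNames(c("blue", "blue", "blue", "grey2",
                                    "unassigned"),
                                  c("B", "C", "D", "E", "F")),
                minModuleSize = 1L)
    deg <- data.frame(gene = c("A", "B", "C"),
                      significant = c(TRUE, TRUE, TRUE))
    out <- intersectWithModule(deg, part, "blue")
    expect_setequal(out$overlap, c("B", "C"))
    expect_identical(unname(out$venn), c(1L, 2L, 1L))
    expect_error(intersectWithModule(deg, part, "nosuch"), "unknown")
    # brute-force random cross-check
    set.seed(25)
    for (i in 1:10) {
        degs <- sample(LETTERS, 10)
        mod <- sample(LETTERS, 12)
        brute <- character(0)
        for (g in degs) for (h in mod) if (g == h) brute <- c(brute, g)
        lab <- setNames(rep("m", length(mod)), mod)
        partR <- new("ModulePartition", labels = lab, minModuleSize = 1L)
        degR <- data.frame(gene = degs, significant = TRUE)
        expect_setequal(intersectWithModule(degR, partR, "m")$overlap, brute)
    }
})
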