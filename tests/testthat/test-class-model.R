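test_that("the model classes are exactly the weak orderings of three means", {
    cls <- enumerateModelClasses()
    expect_equal(nrow(cls), 13)
    expect_equal(length(unique(cls$label)), 13)
    ## brute force: canonical dense-rank strings of all 27 rank maps
    brute <- bruteForceWeakOrderings()
    ours <- apply(cls[, c("rank_F", "rank_Y", "rank_A")], 1,
                  paste, collapse = "")
    expect_setequal(ours, brute)
    ## 6 all-distinct, 6 single-equality, 1 all-equal
    n_lv <- apply(cls[, c("rank_F", "rank_Y", "rank_A")], 1,
                  function(r) length(unique(r)))
    expect_equal(sum(n_lv == 3), 6)
    expect_equal(sum(n_lv == 2), 6)
    expect_equal(sum(n_lv == 1), 1)
    ## canonical numbering anchors
    expect_equal(cls$label[1], "F<Y=A")
    expect_equal(cls$label[7], "F<Y<A")
    expect_equal(cls$label[13], "F=Y=A")
})

test_that("single-gene fits recover planted structures", {
    g <- factor(rep(c("fetal", "young", "adult"), each = 12),
                levels = c("fetal", "young", "adult"))
    ## identically zero: all-equal, p = 1
    f0 <- fitGene(rep(0, 36), g, alpha = 0.0019)
    expect_equal(f0@partition, "FYA")
    expect_equal(f0@pattern, "F=Y=A")
    expect_equal(f0@p_value, 1)
    expect_true("exact_fit" %in% f0@flags)
    ## fetal depressed: F|YA with F below
    set.seed(7)
    v1 <- rnorm(36, rep(c(-2, 0, 0), each = 12), 0.1)
    f1 <- fitGene(v1, g, alpha = 0.0019)
    expect_equal(f1@partition, "F|YA")
    expect_equal(f1@pattern, "F<Y=A")
    expect_equal(classifyDirection(f1), "F<Y=A")
    ## three separated means: full order
    v2 <- rnorm(36, rep(c(0, 1, 2), each = 12), 0.1)
    f2 <- fitGene(v2, g, alpha = 0.0019)
    expect_equal(f2@partition, "F|Y|A")
    expect_equal(f2@pattern, "F<Y<A")
    ## and its reverse
    f3 <- fitGene(-v2, g, alpha = 0.0019)
    expect_equal(f3@pattern, "F>Y>A")
    ## exact fit with distinct means: p = 0
    f4 <- fitGene(rep(c(0, 1, 1), each = 12), g, alpha = 0.0019)
    expect_equal(f4@p_value, 0)
    expect_equal(f4@pattern, "F<Y=A")
})

test_that("degenerate designs are flagged or rejected", {
    g2 <- factor(rep(c("fetal", "young"), each = 6),
                 levels = c("fetal", "young", "adult"))
    f <- fitGene(rnorm(12, rep(c(0, 3), each = 6), 0.1), g2,
                 alpha = 0.01)
    expect_true("missing_category" %in% f@flags)
    expect_equal(f@partition, "F|Y")
    expect_equal(f@pattern, "F<Y")
    expect_error(fitGene(c(1, 2), factor(c("fetal", "fetal"),
                                         levels = c("fetal", "young",
                                                    "adult"))),
                 ">= 2")
})

test_that("vectorized and scalar fitters agree", {
    cfg <- synthConfig(n_features = 150, n_fetal = 9, n_young = 7,
                       n_adult = 5, seed = 14)
    d <- generateLogRatioMatrix(cfg)
    x <- logRatios(d$matrix)
    catg <- sampleCategories(d$matrix)
    ## plant some missing values to exercise the NA paths
    set.seed(14)
    x[sample(length(x), 150)] <- NA
    fits <- classifyGenes(x, catg, alpha = 0.01)
    for (i in sample(nrow(x), 60)) {
        f <- fitGene(x[i, ], catg, alpha = 0.01)
        expect_equal(fits$p_value[i], f@p_value, tolerance = 1e-10)
        expect_equal(fits$pattern[i], f@pattern)
        expect_equal(fits$partition[i], f@partition)
    }
})

test_that("selection matches the exhaustive five-partition oracle", {
    set.seed(42)
    agree <- logical(800)
    for (i in seq_along(agree)) {
        ns <- sample(2:10, 3, replace = TRUE)
        g <- factor(rep(c("fetal", "young", "adult"), ns),
                    levels = c("fetal", "young", "adult"))
        v <- rnorm(sum(ns)) +
            rep(rnorm(3, 0, sample(c(0, 0.5, 1), 1)), ns)
        agree[i] <- fitGene(v, g, alpha = 0.05)@partition ==
            oraclePartition(v, g, 0.05)
    }
    expect_gte(mean(agree), 0.99)
})

test_that("the selected partition is invariant to positive scaling", {
    set.seed(3)
    g <- factor(rep(c("fetal", "young", "adult"), c(8, 6, 4)),
                levels = c("fetal", "young", "adult"))
    for (i in 1:25) {
        v <- rnorm(18) + rep(rnorm(3, 0, 0.8), c(8, 6, 4))
        f1 <- fitGene(v, g, alpha = 0.05)
        f2 <- fitGene(v * 7.3, g, alpha = 0.05)
        expect_equal(f1@partition, f2@partition)
        expect_equal(f1@pattern, f2@pattern)
        expect_equal(f1@p_value, f2@p_value, tolerance = 1e-9)
    }
})

test_that("planted mean patterns are recovered at high effect size", {
    ## effect/noise = 6, n = 12 per group, all twelve directional classes
    cfg <- synthConfig(n_features = 1000, n_fetal = 12, n_young = 12,
                       n_adult = 12, seed = 5)
    d <- generateLogRatioMatrix(cfg)
    fits <- classifyGenes(d$matrix, alpha = 0.001901)
    planted <- d$truth$pattern != "F=Y=A"
    expect_gt(sum(planted), 50)
    expect_gte(mean(fits$pattern[planted] == d$truth$pattern[planted]),
               0.95)
})

test_that("covariate scans detect planted trends and respect the null", {
    set.seed(6)
    n_genes <- 200
    weeks <- sample(14:24, 36, replace = TRUE)
    catg <- rep("fetal", 36)
    x <- matrix(rnorm(n_genes * 36, sd = 0.1), n_genes, 36)
    x[1, ] <- x[1, ] + 0.5 * weeks      # planted slope 0.5/week
    x[2, ] <- 3                          # constant expression
    rownames(x) <- paste0("g", seq_len(n_genes))
    res <- covariateScan(x, catg, subset = "fetal", covariate = weeks,
                         target_fdr = 0.01, n_sims = 150, seed = 2)
    expect_true("g1" %in% res$discoveries)
    expect_equal(unname(res$slope[2]), 0)
    expect_equal(unname(res$p[2]), 1)
    ## null-only matrix: essentially no discoveries at 1% calibrated FDR
    x0 <- matrix(rnorm(n_genes * 36, sd = 0.1), n_genes, 36)
    rownames(x0) <- paste0("g", seq_len(n_genes))
    res0 <- covariateScan(x0, catg, subset = "fetal", covariate = weeks,
                          target_fdr = 0.01, n_sims = 150, seed = 3)
    expect_lte(length(res0$discoveries), 2)
    expect_error(covariateScan(x[, 1:2], catg[1:2], subset = "fetal",
                               covariate = weeks[1:2]), ">= 3")
})

test_that("residual diagnostics summarise distributional shape", {
    cfg <- synthConfig(n_features = 300, n_fetal = 10, n_young = 10,
                       n_adult = 10, seed = 9)
    d <- generateLogRatioMatrix(cfg)
    rep1 <- residualDiagnostics(d$matrix)
    expect_lt(abs(rep1$qq_slope - 1), 0.1)
    expect_lt(abs(rep1$excess_kurtosis), 0.5)
    ## heavy-tailed noise shows positive excess kurtosis
    set.seed(10)
    xh <- matrix(rt(300 * 30, df = 3), 300, 30)
    rep2 <- residualDiagnostics(xh, rep(c("fetal", "young", "adult"),
                                        each = 10))
    expect_gt(rep2$excess_kurtosis, 0)
    ## empty input: empty report, no error
    rep0 <- residualDiagnostics(matrix(numeric(0), 0, 30),
                                rep(c("fetal", "young", "adult"),
                                    each = 10))
    expect_equal(rep0$n_genes, 0L)
    expect_equal(nrow(rep0$qq), 0)
})
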