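## hand-built Ct table: 4 guide assays, 1 passenger, 3 references
.ctFixture <- function() {
    data.frame(
        assay_id = c("miR-a", "miR-b", "miR-low", "miR-cens", "miR-star",
                     "RNU44", "RNU48", "U6"),
        strand = c("guide", "guide", "guide", "guide", "passenger",
                   "reference", "reference", "reference"),
        `14wk` = c(22, 25, 30, 24, 21, 20, 22, 24),
        `17wk` = c(21, 25, 35, 40, 21, 20, 22, 24),
        `98d`  = c(20, 25, 31, 24, 21, 20, 22, 24),
        check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("reference normalization is the mean-Ct (geometric-mean) rule", {
    ct <- .ctFixture()
    norm <- normalizeCt(ct)
    expect_equal(unname(norm$normalizer), c(22, 22, 22))
    expect_equal(norm$dct[norm$dct$assay_id == "miR-a", "14wk"], 0)
    ## shift invariance: +3 cycles on a whole column changes no delta-Ct
    ct2 <- ct
    ct2[["17wk"]] <- pmin(ct2[["17wk"]] + 3, 40)
    ct2[ct2$assay_id == "miR-cens", "17wk"] <- 40   # stays censored
    norm2 <- normalizeCt(ct2)
    keep <- norm$dct$assay_id != "miR-cens"
    expect_equal(norm2$dct[keep, "17wk"], norm$dct[keep, "17wk"])
    ## censored reference is a column error
    ct3 <- ct
    ct3[ct3$assay_id == "U6", "98d"] <- 40
    expect_error(normalizeCt(ct3), "98d")
    expect_error(normalizeCt(ct[ct$assay_id != "U6", ]), "U6")
})

test_that("the robust-expression and guide-strand filters apply", {
    ct <- .ctFixture()
    kept <- robustExpressionFilter(ct)
    expect_true(all(c("miR-a", "miR-b", "miR-cens") %in% kept))
    expect_false("miR-low" %in% kept)    # Ct > 29 at every timepoint
    expect_false("miR-star" %in% kept)   # passenger strand
    ## boundary: 28 at a single timepoint rescues an assay
    ct2 <- ct
    ct2[ct2$assay_id == "miR-low", "14wk"] <- 28
    expect_true("miR-low" %in% robustExpressionFilter(ct2))
})

test_that("fold changes follow 2^-ddCt with exact reference behaviour", {
    ct <- .ctFixture()
    norm <- normalizeCt(ct)
    fc <- foldChanges(norm, "14wk", assays = robustExpressionFilter(ct))
    ## the reference timepoint is exactly 1 (log2 exactly 0)
    expect_true(all(fc$fold[, "14wk"] == 1))
    expect_true(all(fc$log2fc[, "14wk"] == 0))
    ## ddCt of -1 is a fold change of 2
    expect_equal(fc$fold["miR-a", "17wk"], 2)
    expect_equal(fc$fold["miR-a", "98d"], 4)
    expect_equal(fc$fold["miR-b", "17wk"], 1)
    ## censored raw Ct propagates as a flag, not silently as a value
    expect_true(fc$censored["miR-cens", "17wk"])
    expect_false(fc$censored["miR-a", "17wk"])
    expect_error(foldChanges(norm, "33wk"), "not among")
})

test_that("noiseless planted fold changes round-trip exactly", {
    mix <- mixOf("F<Y=A" = 1)
    cfg <- synthConfig(n_features = 25, n_fetal = 2, n_young = 2,
                       n_adult = 2, class_mix = mix, effect_size = 2,
                       ct_noise_sd = 0, frac_low_expressed = 0,
                       frac_passenger = 0, seed = 26)
    tq <- generateTaqmanDataset(cfg)
    fc <- foldChanges(normalizeCt(tq$ct), "14wk",
                      assays = robustExpressionFilter(tq$ct))
    ## planted effect 2 log2 units between fetal and young epochs: fold 4
    uncens <- rownames(fc$fold)[rowSums(fc$censored) == 0]
    expect_gt(length(uncens), 10)
    expect_equal(unname(fc$fold[uncens, "98d"]),
                 rep(4, length(uncens)))
    expect_equal(unname(fc$fold[uncens, "17wk"]),
                 rep(1, length(uncens)))
})

test_that("the SD screen flags single-timepoint spikes", {
    set.seed(27)
    n <- 40
    tps <- c("14wk", "16wk", "17wk", "18wk", "98d")
    dctv <- matrix(rnorm(n * 5, 0, 0.05), n, 5,
                   dimnames = list(paste0("m", 1:n), tps))
    dct <- data.frame(assay_id = rownames(dctv), strand = "guide",
                      dctv, check.names = FALSE)
    cens <- matrix(FALSE, n, 5, dimnames = dimnames(dctv))
    norm <- list(dct = dct, censored = cens)
    fc <- foldChanges(norm, "14wk")
    fc$log2fc["m7", "17wk"] <- 8     # the week-17 spike
    screen <- sdOutlierScreen(fc, k = 2)
    expect_true("m7" %in% screen$assays_any)
    expect_true(any(screen$flagged$assay_id == "m7" &
                    screen$flagged$timepoint == "17wk"))
    ## k = Inf flags nothing
    expect_equal(nrow(sdOutlierScreen(fc, k = Inf)$flagged), 0)
    ## a zero-variance pool is a screen error
    fc0 <- fc
    fc0$log2fc[] <- 0
    expect_error(sdOutlierScreen(fc0), "zero variance")
})

test_that("a planted spike survives the full generator round trip", {
    cfg <- synthConfig(n_features = 60, n_fetal = 4, n_young = 4,
                       n_adult = 2, class_mix = mixOf("F=Y=A" = 1),
                       ct_noise_sd = 0.05, frac_low_expressed = 0,
                       frac_passenger = 0, seed = 28)
    probe <- generateTaqmanDataset(cfg)
    target <- probe$truth$assay_id[1]
    tq <- generateTaqmanDataset(cfg, spike = list(assay = target,
                                                  timepoint = "17wk",
                                                  log2 = 6))
    fc <- foldChanges(normalizeCt(tq$ct), "14wk",
                      assays = robustExpressionFilter(tq$ct))
    screen <- sdOutlierScreen(fc)
    expect_true(target %in% screen$assays_any)
    hit <- screen$flagged[screen$flagged$assay_id == target, ]
    expect_true("17wk" %in% hit$timepoint)
})

test_that("fold-change bins match brute-force counting and are monotone", {
    set.seed(29)
    n <- 80
    tps <- c("14wk", "17wk", "98d", "1.5yr", "adult")
    epochs <- stats::setNames(c("fetal", "fetal", "young", "young",
                                "adult"), tps)
    l2 <- matrix(rnorm(n * 5, 0, 3), n, 5,
                 dimnames = list(paste0("m", 1:n), tps))
    l2[, "14wk"] <- 0
    fc <- list(log2fc = l2, censored = matrix(FALSE, n, 5,
                                              dimnames = dimnames(l2)),
               reference_timepoint = "14wk")
    bins <- c(2, 5, 10, 100)
    tab <- tabulateFoldBins(fc, epochs, bins = bins)
    ## brute force per pair and bin
    em <- vapply(c("fetal", "young", "adult"), function(e)
        rowMeans(l2[, epochs == e, drop = FALSE]), numeric(n))
    for (pr in list(c("fetal", "adult"), c("young", "adult"),
                    c("fetal", "young"))) {
        ratio <- 2^(em[, pr[1]] - em[, pr[2]])
        for (b in seq_along(bins)) {
            row_i <- tab$comparison == paste(pr[1], "vs", pr[2])
            expect_equal(tab[row_i & tab$direction == "increase",
                             paste0("gt_", bins[b])],
                         sum(ratio > bins[b]))
            expect_equal(tab[row_i & tab$direction == "decrease",
                             paste0("gt_", bins[b])],
                         sum(1 / ratio > bins[b]))
        }
    }
    ## counts shrink (weakly) along 2 -> 5 -> 10 -> 100
    counts <- as.matrix(tab[, paste0("gt_", bins)])
    expect_true(all(counts[, -1] <= counts[, -ncol(counts)]))
    ## a single fold-6 pair lands in >2 and >5 but not >10
    one <- list(log2fc = matrix(c(0, log2(6), 0, 0, 0, rep(0, 5),
                                  rep(0, 5)), nrow = 3, byrow = TRUE,
                                dimnames = list(paste0("x", 1:3), tps)),
                censored = matrix(FALSE, 3, 5),
                reference_timepoint = "14wk")
    one$log2fc[1, ] <- c(log2(6), log2(6), 0, 0, 0)
    t1 <- tabulateFoldBins(one, epochs)
    fa_inc <- t1[t1$comparison == "fetal vs adult" &
                 t1$direction == "increase", ]
    expect_equal(unname(unlist(fa_inc[, paste0("gt_", bins)])),
                 c(1, 1, 0, 0))
})

test_that("Q-Q data pair the fold changes with Blom normal scores", {
    tps <- c("14wk", "17wk", "98d")
    l2 <- matrix(c(rep(0, 5), 1:5, 6:10), 5, 3,
                 dimnames = list(paste0("m", 1:5), tps))
    fc <- list(log2fc = l2, censored = matrix(FALSE, 5, 3),
               reference_timepoint = "14wk")
    qq <- qqData(fc)
    expect_equal(nrow(qq), 10)
    expect_equal(qq$empirical, sort(as.vector(l2[, -1])))
    expect_equal(qq$theoretical,
                 stats::qnorm(((1:10) - 0.375) / 10.25))
    ## Gaussian input: Q-Q slope near 1
    set.seed(30)
    lg <- matrix(rnorm(2000), 500, 4,
                 dimnames = list(paste0("g", 1:500),
                                 c("14wk", "a", "b", "c")))
    fcg <- list(log2fc = lg, censored = matrix(FALSE, 500, 4),
                reference_timepoint = "14wk")
    qg <- qqData(fcg)
    expect_lt(abs(stats::coef(stats::lm(qg$empirical ~
                                        qg$theoretical))[2] - 1), 0.1)
})
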