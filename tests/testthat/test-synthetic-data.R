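test_that("sample table follows the configured design", {
    cfg <- synthConfig(n_features = 10, n_fetal = 36, n_young = 9,
                       n_adult = 2, seed = 1)
    tab <- generateSampleTable(cfg)
    expect_equal(nrow(tab), 47)
    expect_equal(as.vector(table(tab$age_category)[c("fetal", "young",
                                                     "adult")]),
                 c(36, 9, 2))
    fet <- tab[tab$age_category == "fetal", ]
    expect_true(all(fet$gestational_weeks >= 14 &
                    fet$gestational_weeks <= 24))
    expect_true(all(is.na(fet$postnatal_days)))
    expect_true(all(is.na(tab$gestational_weeks[tab$age_category !=
                                                "fetal"])))
    ## pools: shared by samples of the same developmental age, fetal pools
    ## first, one adult pool last
    expect_true(all(tapply(tab$pool[tab$age_category == "fetal"],
                           fet$gestational_weeks,
                           function(p) length(unique(p))) == 1))
    expect_equal(length(unique(tab$pool[tab$age_category == "adult"])), 1)
    expect_equal(max(tab$pool[tab$age_category == "fetal"]) <
                     min(tab$pool[tab$age_category == "young"]), TRUE)
})

test_that("generators are byte-identical under a fixed seed", {
    cfg <- synthConfig(n_features = 40, n_fetal = 3, n_young = 3,
                       n_adult = 3, seed = 99)
    expect_identical(generateSampleTable(cfg), generateSampleTable(cfg))
    expect_identical(generateArrayDataset(cfg), generateArrayDataset(cfg))
    expect_identical(generateTaqmanDataset(cfg),
                     generateTaqmanDataset(cfg))
    expect_identical(generateLogRatioMatrix(cfg)$matrix,
                     generateLogRatioMatrix(cfg)$matrix)
})

test_that("invalid configurations are rejected", {
    expect_error(synthConfig(n_fetal = 0), "counts")
    expect_error(synthConfig(noise_sd = 0), "noise_sd")
    bad <- mixOf("F=Y=A" = 0.5, "F<Y=A" = 0.4)   # sums to 0.9
    expect_error(synthConfig(class_mix = bad), "sum to 1")
    expect_error(synthConfig(class_mix = c(nonsense = 1)), "label")
})

test_that("novel fraction and planted truth match the configuration", {
    cfg <- synthConfig(n_features = 400, frac_novel = 0.35, n_fetal = 4,
                       n_young = 4, n_adult = 4, seed = 3)
    d <- generateLogRatioMatrix(cfg)
    expect_lte(abs(mean(d$truth$annotation_source == "novel") - 0.35),
               1 / 400 + 1e-12)
    ## pattern-implied equalities hold exactly in the true means
    cls <- enumerateModelClasses()
    i <- match(d$truth$pattern, cls$label)
    mu <- as.matrix(d$truth[, c("mean_F", "mean_Y", "mean_A")])
    rk <- as.matrix(cls[i, c("rank_F", "rank_Y", "rank_A")])
    expect_true(all(vapply(seq_len(nrow(mu)), function(r)
        identical(unname(rank(mu[r, ], ties.method = "min")),
                  unname(rank(rk[r, ], ties.method = "min"))),
        logical(1))))
    ## adjacent unequal means are separated by effect_size exactly
    spread <- apply(mu, 1, function(m) diff(range(m)))
    expect_true(all(spread[d$truth$pattern == "F<Y<A"] ==
                        2 * cfg@effect_size))
    expect_true(all(spread[d$truth$pattern == "F<Y=A"] ==
                        cfg@effect_size))
})

test_that("empirical group means converge to the truth as noise vanishes", {
    mix <- mixOf("F<Y=A" = 0.5, "F=Y=A" = 0.5)
    cfg <- synthConfig(n_features = 60, n_fetal = 30, n_young = 30,
                       n_adult = 30, class_mix = mix, noise_sd = 1e-4,
                       seed = 8)
    d <- generateLogRatioMatrix(cfg)
    x <- logRatios(d$matrix)
    catg <- sampleCategories(d$matrix)
    for (lev in levels(catg)) {
        emp <- rowMeans(x[, catg == lev, drop = FALSE])
        tru <- d$truth[[paste0("mean_", c(fetal = "F", young = "Y",
                                          adult = "A")[lev])]]
        expect_lt(max(abs(emp - tru)), 1e-3)
    }
})

test_that("bright features saturate in the 100% scan but not at 10%", {
    cfg <- synthConfig(n_features = 300, n_fetal = 2, n_young = 2,
                       n_adult = 2, seed = 21)
    arr <- generateArrayDataset(cfg)
    hi <- arr$scans[[1]]$high
    lo <- arr$scans[[1]]$low
    ## a 10%-intensity of 7000 at gain 10 exceeds the 16-bit ceiling
    bright <- lo$median_fg - lo$median_bg > 7000
    expect_gt(sum(bright), 0)
    expect_true(all(hi$median_fg[bright] <= 65535))
    expect_true(all(hi$frac_saturated[bright] >= 0.2))
    expect_true(all(lo$median_fg <= 65535))
    ## saturation hits the bright novel features predominantly
    expect_gt(mean(hi$annotation_source[bright] == "novel"), 0.9)
})

test_that("all-null class mix plants only the all-equal pattern", {
    cfg <- synthConfig(n_features = 50, n_fetal = 3, n_young = 3,
                       n_adult = 3, class_mix = mixOf("F=Y=A" = 1),
                       seed = 2)
    d <- generateLogRatioMatrix(cfg)
    expect_true(all(d$truth$pattern == "F=Y=A"))
    expect_true(all(d$truth[, c("mean_F", "mean_Y", "mean_A")] == 0))
})

test_that("TaqMan generator encodes abundance on the Ct scale exactly", {
    ## noiseless: a 2-fold abundance increase lowers Ct by exactly 1 cycle
    mix <- mixOf("F<Y=A" = 1)
    cfg <- synthConfig(n_features = 30, n_fetal = 2, n_young = 2,
                       n_adult = 2, class_mix = mix, effect_size = 1,
                       ct_noise_sd = 0, frac_low_expressed = 0, seed = 4)
    tq <- generateTaqmanDataset(cfg)
    ct <- tq$ct
    expect_true(all(c("RNU44", "RNU48", "U6") %in% ct$assay_id))
    targets <- ct[!ct$assay_id %in% c("RNU44", "RNU48", "U6"), ]
    ## fetal pools sit 1 cycle above young pools (2-fold lower abundance)
    expect_equal(targets[["14wk"]] - targets[["98d"]],
                 rep(1, nrow(targets)))
    expect_true(all(as.matrix(ct[, -(1:2)]) <= 40))
    ## constant truth: the ddCt pipeline returns fold change 1 everywhere
    cfg0 <- synthConfig(n_features = 30, n_fetal = 2, n_young = 2,
                        n_adult = 2, class_mix = mixOf("F=Y=A" = 1),
                        ct_noise_sd = 0, frac_low_expressed = 0, seed = 4)
    tq0 <- generateTaqmanDataset(cfg0)
    fc0 <- foldChanges(normalizeCt(tq0$ct), "14wk")
    expect_equal(max(abs(fc0$fold - 1)), 0)
})

test_that("TaqMan generator rejects missing reference setup", {
    cfg <- synthConfig(n_features = 10, seed = 1)
    expect_error(generateTaqmanDataset(cfg, timepoints = "14wk"),
                 "2 timepoints")
})
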