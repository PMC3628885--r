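## shared fixtures and independent oracles, built in code at test time

## class-mix helper: named fractions over the 13 labels
mixOf <- function(...) {
    parts <- c(...)
    mix <- stats::setNames(rep(0, 13), enumerateModelClasses()$label)
    mix[names(parts)] <- parts
    mix
}

## hand-built scan table rows (one channel)
fakeScanChannel <- function(ids, channel, fg, bg = 100, power = 10,
                            px = 0.9, r2 = 0.9, fs = 0, flag = 0,
                            source = "known") {
    data.frame(feature_id = ids, annotation_source = source,
               channel = channel, scan_power = power,
               median_fg = fg, median_bg = bg, bg_sd = 10,
               frac_pixels_gt_bg2sd = px, r_squared = r2,
               frac_saturated = fs, flag = flag, stringsAsFactors = FALSE)
}

fakeScanTable <- function(ids, fg3, fg5, bg = 100, power = 10, ...) {
    rbind(fakeScanChannel(ids, "Cy3", fg3, bg, power, ...),
          fakeScanChannel(ids, "Cy5", fg5, bg, power, ...))
}

## independent exhaustive oracle for the backward model selection: fit all
## five partitions from scratch, accept a partition when the partial F of
## the full three-mean model against it is not significant at alpha, and
## choose the most parsimonious acceptable one (all-equal first, then the
## best two-group partition, then the full model)
oraclePartition <- function(v, g, alpha) {
    g <- factor(as.character(g), levels = c("fetal", "young", "adult"))
    ms <- tapply(v, g, mean)
    n <- length(v)
    rssf <- sum((v - ms[g])^2)
    rss1 <- sum((v - mean(v))^2)
    pOmni <- stats::pf(((rss1 - rssf) / 2) / (rssf / (n - 3)), 2, n - 3,
                       lower.tail = FALSE)
    if (pOmni > alpha) return("FYA")
    merges <- list("FY|A" = c("fetal", "young"),
                   "FA|Y" = c("fetal", "adult"),
                   "F|YA" = c("young", "adult"))
    pm <- vapply(merges, function(pair) {
        gg <- as.character(g)
        gg[gg %in% pair] <- "M"
        mm <- tapply(v, gg, mean)
        rssr <- sum((v - mm[gg])^2)
        stats::pf((rssr - rssf) / (rssf / (n - 3)), 1, n - 3,
                  lower.tail = FALSE)
    }, numeric(1))
    acc <- pm[pm > alpha]
    if (length(acc)) names(acc)[which.max(acc)] else "F|Y|A"
}

## brute-force enumeration of the weak orderings of three labelled items:
## all 27 rank assignments, canonicalized to dense ranks
bruteForceWeakOrderings <- function() {
    ranks <- expand.grid(F = 1:3, Y = 1:3, A = 1:3)
    canon <- apply(ranks, 1, function(r) {
        paste(match(r, sort(unique(r))), collapse = "")
    })
    unique(canon)
}
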