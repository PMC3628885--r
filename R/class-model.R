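## Per-gene ANOVA with backward model selection over the three age-category
## means, and refinement into direction-aware mean-pattern classes.

## Canonical table of the 13 weak orderings of three labelled means.
## Ranks are per category (F, Y, A); 1 = lowest mean.
.MODEL_CLASS_TABLE <- data.frame(
    class = 1:13,
    label = c("F<Y=A", "F>Y=A", "F=Y<A", "F=Y>A", "F=A<Y", "F=A>Y",
              "F<Y<A", "F>Y>A", "F<A<Y", "F>A>Y", "Y<F<A", "A<F<Y",
              "F=Y=A"),
    rank_F = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 3L, 1L, 3L, 2L, 2L, 1L),
    rank_Y = c(2L, 1L, 1L, 2L, 2L, 1L, 2L, 2L, 3L, 1L, 1L, 3L, 1L),
    rank_A = c(2L, 1L, 2L, 1L, 1L, 2L, 3L, 1L, 2L, 2L, 3L, 1L, 1L),
    partition = c("F|YA", "F|YA", "FY|A", "FY|A", "FA|Y", "FA|Y",
                  "F|Y|A", "F|Y|A", "F|Y|A", "F|Y|A", "F|Y|A", "F|Y|A",
                  "FYA"),
    stringsAsFactors = FALSE
)

modelClassLabels <- function() .MODEL_CLASS_TABLE$label

#' Enumerate the direction-aware mean-pattern model classes
#'
#' Every weak ordering of the three age-category means (fetal F, young Y,
#' adult A) defines one model class: six total orders, six orders with
#' exactly one equality, and the all-equal class, 13 in total. The numbering
#' follows the convention used for developmental expression classes:
#' classes 1--6 are the single-equality patterns (fetal apart, adult apart,
#' young apart, each in both directions), class 7 is F<Y<A, classes 8--12
#' the remaining total orders, and the all-equal class comes last.
#'
#' @return A data.frame with one row per class: \code{class} (integer id),
#'   \code{label} (canonical pattern string such as \code{"F<Y=A"}),
#'   \code{rank_F}, \code{rank_Y}, \code{rank_A} (dense ranks of the
#'   category means, 1 = lowest) and \code{partition} (the equality
#'   structure, e.g. \code{"F|YA"}).
#'
#' @examples
#' enumerateModelClasses()
#' @export
enumerateModelClasses <- function() .MODEL_CLASS_TABLE

## ---- vectorized fitting engine ------------------------------------------

.asCategories <- function(categories) {
    categories <- as.character(categories)
    bad <- !categories %in% AGE_CATEGORIES
    if (any(bad))
        stop("unknown age categories: ", paste(unique(categories[bad]),
                                               collapse = ", "))
    factor(categories, levels = AGE_CATEGORIES)
}

## Per-gene, per-category observation counts, sums and sums of squares,
## tolerating missing values.
.groupStats <- function(x, categories) {
    categories <- .asCategories(categories)
    G <- vapply(AGE_CATEGORIES, function(l) as.numeric(categories == l),
                numeric(length(categories)))
    obs <- !is.na(x)
    xz <- x
    xz[!obs] <- 0
    storage.mode(obs) <- "numeric"
    list(N = obs %*% G, S = xz %*% G, S2 = (xz * xz) %*% G)
}

## Omnibus one-way ANOVA p-value (full three-mean model against all-equal)
## from group stats; returns NA where fewer than 2 categories are observed
## or no residual degrees of freedom remain.
.omnibusFromStats <- function(st) {
    N <- st$N; S <- st$S; S2 <- st$S2
    n_obs <- rowSums(N)
    k <- rowSums(N > 0)
    Nsafe <- ifelse(N > 0, N, 1)
    rss_full <- rowSums(pmax(S2 - S * S / Nsafe, 0))
    grand <- rowSums(S) / n_obs
    rss1 <- pmax(rowSums(S2) - n_obs * grand * grand, 0)
    between <- pmax(rss1 - rss_full, 0)
    df1 <- k - 1
    df2 <- n_obs - k
    p <- rep(NA_real_, nrow(N))
    ok <- df1 >= 1 & df2 >= 1
    p[ok] <- stats::pf((between[ok] / df1[ok]) / (rss_full[ok] / df2[ok]),
                       df1[ok], df2[ok], lower.tail = FALSE)
    ## exact fits: zero residual variance
    eps <- 1e-12 * pmax(rowSums(S2), 1)
    exact <- ok & rss_full <= eps
    p[exact] <- ifelse(between[exact] > eps[exact], 0, 1)
    list(p = p, rss_full = rss_full, rss1 = rss1, n_obs = n_obs, k = k,
         eps = eps)
}

#' Omnibus ANOVA p-values for every gene
#'
#' Fast vectorized one-way ANOVA of each row of the log-ratio matrix on the
#' age-category labels: the p-value of the full three-mean model against
#' the all-equal model. This is the gene-level significance measure fed to
#' the simulation-based FDR calibration; it is uniform on (0, 1) under the
#' all-equal null.
#'
#' @param x numeric matrix (genes x samples), or a
#'   \linkS4class{LogRatioMatrix}.
#' @param categories per-sample age-category labels (ignored when \code{x}
#'   is a LogRatioMatrix).
#' @return numeric vector of p-values, one per row of \code{x}.
#' @export
omnibusPValues <- function(x, categories = NULL) {
    if (is(x, "LogRatioMatrix")) {
        categories <- sampleCategories(x)
        x <- logRatios(x)
    }
    .omnibusFromStats(.groupStats(x, categories))$p
}

## Full vectorized structure selection. Returns a list of per-gene vectors.
## Only rows with all three categories observed and >= 1 residual df go
## through the vectorized path; others are delegated to the scalar fitter.
.selectStructure <- function(x, categories, alpha) {
    st <- .groupStats(x, categories)
    om <- .omnibusFromStats(st)
    g <- nrow(x)
    N <- st$N; S <- st$S
    Nsafe <- ifelse(N > 0, N, 1)
    M <- S / Nsafe
    M[N == 0] <- NA_real_
    n_obs <- om$n_obs
    rss_full <- om$rss_full
    rss1 <- om$rss1
    eps <- om$eps

    vec <- om$k == 3 & (n_obs - 3) >= 1
    imin <- max.col(-M, ties.method = "first")
    imax <- max.col(M, ties.method = "last")
    imid <- 6L - imin - imax
    idx <- seq_len(g)
    pick <- function(i) M[cbind(idx, i)]
    pickN <- function(i) N[cbind(idx, i)]
    harm <- function(i, j) pickN(i) * pickN(j) / (pickN(i) + pickN(j))
    d_lm <- harm(imin, imid) * (pick(imin) - pick(imid))^2
    d_mh <- harm(imid, imax) * (pick(imid) - pick(imax))^2
    dfres <- n_obs - 3
    mse <- rss_full / pmax(dfres, 1)
    partialP <- function(d) {
        p <- stats::pf(d / mse, 1, dfres, lower.tail = FALSE)
        ## exact fit: zero residual variance
        zero <- rss_full <= eps
        p[zero] <- ifelse(d[zero] > eps[zero], 0, 1)
        p
    }
    p_lm <- partialP(d_lm)
    p_mh <- partialP(d_mh)
    merge_lo <- p_lm >= p_mh          # merge the two lowest means
    b1 <- pmax(p_lm, p_mh)
    d_sel <- ifelse(merge_lo, d_lm, d_mh)
    rss2 <- rss_full + d_sel
    b2 <- stats::pf((rss1 - rss2) / (rss2 / (n_obs - 2)), 1, n_obs - 2,
                    lower.tail = FALSE)
    zero2 <- rss2 <= eps
    b2[zero2] <- ifelse(rss1[zero2] - rss2[zero2] > eps[zero2], 0, 1)

    p_omni <- om$p
    significant <- vec & !is.na(p_omni) & p_omni <= alpha
    three <- significant & b1 <= alpha
    two <- significant & !three

    partition <- rep("FYA", g)
    pattern <- rep("F=Y=A", g)
    partition[three] <- "F|Y|A"
    ## total orders keyed on (imin, imid, imax) over columns F=1, Y=2, A=3
    orderKey <- imin * 100L + imid * 10L + imax
    orderLab <- c(`123` = "F<Y<A", `321` = "F>Y>A", `132` = "F<A<Y",
                  `231` = "F>A>Y", `213` = "Y<F<A", `312` = "A<F<Y")
    pattern[three] <- orderLab[as.character(orderKey[three])]

    if (any(two)) {
        a <- ifelse(merge_lo, imin, imid)   # merged pair
        b <- ifelse(merge_lo, imid, imax)
        pairKey <- pmin(a, b) * 10L + pmax(a, b)   # 23=YA, 13=FA, 12=FY
        partLab <- c(`23` = "F|YA", `13` = "FA|Y", `12` = "FY|A")
        partition[two] <- partLab[as.character(pairKey[two])]
        ## direction: merging the two lowest means leaves the singleton on top
        up <- merge_lo      # TRUE: singleton group has the highest mean
        twoLabUp <- c(`23` = "F>Y=A", `13` = "F=A<Y", `12` = "F=Y<A")
        twoLabDn <- c(`23` = "F<Y=A", `13` = "F=A>Y", `12` = "F=Y>A")
        lab <- ifelse(up[two], twoLabUp[as.character(pairKey[two])],
                      twoLabDn[as.character(pairKey[two])])
        ## exact mean ties collapse conservatively to the equality pattern
        msing <- ifelse(merge_lo, pick(imax), pick(imin))
        mpool <- (S[cbind(idx, a)] + S[cbind(idx, b)]) /
            (N[cbind(idx, a)] + N[cbind(idx, b)])
        tied <- msing[two] == mpool[two]
        lab[tied] <- "F=Y=A"
        partition[two][tied] <- "FYA"
        pattern[two] <- lab
    }

    list(p_value = p_omni, p_merge = b1, p_collapse = b2,
         partition = partition, pattern = pattern,
         means = M, n = N, rss_full = rss_full, n_obs = n_obs,
         vectorized = vec)
}

#' Classify every gene into a mean-pattern model class
#'
#' For each gene, a one-way ANOVA of the log-ratios on the three age
#' categories is followed by backward model selection: the omnibus p-value
#' (full three-mean model against all-equal) decides significance at
#' \code{alpha}; for significant genes the two merges of adjacent category
#' means (adjacent in the estimated-mean order) are tested by partial
#' F-tests against the full model and the merge with the largest p-value is
#' applied when that p-value exceeds \code{alpha}. A significant gene
#' therefore retains either the full three-mean structure or a two-group
#' structure; non-significant genes collapse to the all-equal class. The
#' retained structure plus the ordering of its group means gives the
#' direction-aware pattern label of [enumerateModelClasses()].
#'
#' Unbalanced group sizes are handled by the standard unweighted-cell-mean
#' F statistics; missing values are dropped per gene. Genes with an entire
#' category missing are fitted on the present categories and flagged.
#'
#' @param x numeric matrix (genes x samples) or a
#'   \linkS4class{LogRatioMatrix}.
#' @param categories per-sample age-category labels (ignored for a
#'   LogRatioMatrix).
#' @param alpha working significance level, typically the FDR-calibrated
#'   threshold (see [calibrateThreshold()]).
#' @return data.frame with one row per gene: \code{gene},
#'   \code{partition}, \code{pattern}, \code{p_value} (omnibus),
#'   \code{p_merge} (largest adjacent-merge partial-F p),
#'   \code{p_collapse} (collapse test of the merged model),
#'   \code{mean_F}, \code{mean_Y}, \code{mean_A}, \code{n_F}, \code{n_Y},
#'   \code{n_A} and \code{flag}.
#'
#' @examples
#' cfg <- synthConfig(n_features = 50, n_fetal = 8, n_young = 8, n_adult = 8,
#'                    seed = 1)
#' d <- generateLogRatioMatrix(cfg)
#' head(classifyGenes(d$matrix, alpha = 0.01))
#' @export
classifyGenes <- function(x, categories = NULL, alpha = 0.05) {
    stopifnot(alpha > 0, alpha < 1)
    if (is(x, "LogRatioMatrix")) {
        categories <- sampleCategories(x)
        x <- logRatios(x)
    }
    x <- as.matrix(x)
    if (is.null(rownames(x)))
        rownames(x) <- paste0("gene_", seq_len(nrow(x)))
    sel <- .selectStructure(x, categories, alpha)
    out <- data.frame(
        gene = rownames(x),
        partition = sel$partition,
        pattern = sel$pattern,
        p_value = sel$p_value,
        p_merge = sel$p_merge,
        p_collapse = sel$p_collapse,
        mean_F = sel$means[, 1], mean_Y = sel$means[, 2],
        mean_A = sel$means[, 3],
        n_F = sel$n[, 1], n_Y = sel$n[, 2], n_A = sel$n[, 3],
        flag = "", stringsAsFactors = FALSE, row.names = NULL
    )
    ## delegate degenerate rows (missing categories etc.) to the scalar path
    slow <- which(!sel$vectorized)
    for (i in slow) {
        fit <- tryCatch(fitGene(x[i, ], categories, alpha = alpha),
                        error = function(e) NULL)
        if (is.null(fit)) {
            out$partition[i] <- NA_character_
            out$pattern[i] <- NA_character_
            out$p_value[i] <- NA_real_
            out$flag[i] <- "unfittable"
        } else {
            out$partition[i] <- fit@partition
            out$pattern[i] <- fit@pattern
            out$p_value[i] <- fit@p_value
            out$p_merge[i] <- fit@p_merge
            out$p_collapse[i] <- fit@p_collapse
            out$flag[i] <- paste(fit@flags, collapse = ";")
        }
    }
    out
}

## ---- scalar fitter (independent route, built on lm/anova) ----------------

#' Single-gene fit
#'
#' Scalar counterpart of [classifyGenes()] built on \code{\link[stats]{lm}}
#' and partial F-tests via \code{\link[stats]{anova}}. Used for degenerate
#' genes (missing categories) and as an independently coded cross-check of
#' the vectorized engine.
#'
#' @param values per-sample log-ratios (numeric, may contain NA).
#' @param categories per-sample age-category labels.
#' @param alpha working significance level.
#' @return A \linkS4class{GeneFit} object.
#' @export
fitGene <- function(values, categories, alpha = 0.05) {
    stopifnot(alpha > 0, alpha < 1)
    categories <- .asCategories(categories)
    if (length(values) != length(categories))
        stop("values and categories must have equal length")
    keep <- !is.na(values)
    v <- values[keep]
    gcat <- droplevels(categories[keep])
    flags <- character()
    if (nlevels(gcat) < length(AGE_CATEGORIES))
        flags <- c(flags, "missing_category")
    if (length(v) < 2 || nlevels(gcat) < 2)
        stop("need >= 2 non-missing values in >= 2 categories")
    n <- length(v)
    k <- nlevels(gcat)
    means <- tapply(v, gcat, mean)
    ns <- tapply(v, gcat, length)
    full <- stats::lm(v ~ 0 + gcat)
    nullm <- stats::lm(v ~ 1)
    rss_full <- sum(stats::residuals(full)^2)
    rss1 <- sum(stats::residuals(nullm)^2)
    eps <- 1e-12 * max(sum(v^2), 1)
    if (n - k < 1) {
        flags <- c(flags, "no_residual_df")
        p_omni <- NA_real_
    } else if (rss_full <= eps) {
        flags <- c(flags, "exact_fit")
        p_omni <- if (rss1 - rss_full > eps) 0 else 1
    } else {
        p_omni <- stats::anova(nullm, full)[["Pr(>F)"]][2]
    }

    ## greedy path: merge adjacent (in estimated-mean order) groups, partial
    ## F against the full model
    ord <- order(means)
    mergedFactor <- function(pair) {
        lv <- levels(gcat)
        map <- stats::setNames(lv, lv)
        map[lv[pair]] <- paste(lv[pair], collapse = "+")
        factor(unname(map[as.character(gcat)]))
    }
    partialP <- function(reduced) {
        rssr <- sum(stats::residuals(reduced)^2)
        if (rss_full <= eps) return(if (rssr - rss_full > eps) 0 else 1)
        a <- stats::anova(reduced, full)
        a[["Pr(>F)"]][2]
    }
    b1 <- NA_real_; b2 <- NA_real_
    mergedPair <- NULL
    if (k == 3) {
        cand <- list(ord[1:2], ord[2:3])
        pc <- vapply(cand, function(p) partialP(stats::lm(v ~ 0 + mergedFactor(p))),
                     numeric(1))
        b1 <- max(pc)
        mergedPair <- cand[[which.max(pc)]]
        red2 <- stats::lm(v ~ 0 + mergedFactor(mergedPair))
        rss2 <- sum(stats::residuals(red2)^2)
        if (rss2 <= eps) {
            b2 <- if (rss1 - rss2 > eps) 0 else 1
        } else {
            b2 <- stats::anova(nullm, red2)[["Pr(>F)"]][2]
        }
    } else if (k == 2) {
        b1 <- p_omni
        b2 <- p_omni
    }

    ## decide the retained structure (protected: a significant gene never
    ## collapses to all-equal)
    lv <- levels(gcat)
    if (is.na(p_omni) || p_omni > alpha) {
        partition <- if (k == 3) "FYA" else .restrictedPartition(lv, NULL)
        groups <- list(lv)
    } else if (k == 2) {
        partition <- .restrictedPartition(lv, "split")
        groups <- as.list(lv)
    } else if (!is.na(b1) && b1 > alpha) {
        groups <- list(lv[mergedPair], lv[-mergedPair])
        partition <- .partitionLabel(groups)
    } else {
        groups <- as.list(lv)
        partition <- "F|Y|A"
    }
    pattern <- .directionLabel(groups, means, all_cats = levels(categories))
    fullMeans <- stats::setNames(rep(NA_real_, 3), AGE_CATEGORIES)
    fullMeans[names(means)] <- means
    fullN <- stats::setNames(rep(0L, 3), AGE_CATEGORIES)
    fullN[names(ns)] <- as.integer(ns)
    new("GeneFit", gene = "gene", partition = partition, pattern = pattern,
        p_value = as.numeric(p_omni), p_merge = as.numeric(b1),
        p_collapse = as.numeric(b2),
        means = fullMeans, n = fullN,
        residual_var = if (n - k >= 1) rss_full / (n - k) else NA_real_,
        flags = flags)
}

.partitionLabel <- function(groups) {
    init <- c(fetal = "F", young = "Y", adult = "A")
    parts <- vapply(groups, function(g)
        paste(init[AGE_CATEGORIES[AGE_CATEGORIES %in% g]], collapse = ""),
        character(1))
    ## order blocks by first category appearing in F, Y, A order
    first <- vapply(groups, function(g) min(match(g, AGE_CATEGORIES)), 1)
    paste(parts[order(first)], collapse = "|")
}

.restrictedPartition <- function(lv, split) {
    init <- c(fetal = "F", young = "Y", adult = "A")
    if (is.null(split)) paste(init[lv], collapse = "")
    else paste(init[lv], collapse = "|")
}

## Canonical direction-aware label from group structure + estimated means.
## Exact ties between group means are merged (conservative).
.directionLabel <- function(groups, means, all_cats = AGE_CATEGORIES) {
    gm <- vapply(groups, function(g) mean(means[g]), numeric(1))
    ## merge exactly tied groups
    o <- order(gm)
    merged <- list(groups[[o[1]]])
    vals <- gm[o[1]]
    for (i in o[-1]) {
        if (gm[i] == vals[length(vals)]) {
            merged[[length(merged)]] <- c(merged[[length(merged)]], groups[[i]])
        } else {
            merged <- c(merged, list(groups[[i]]))
            vals <- c(vals, gm[i])
        }
    }
    ranks <- stats::setNames(rep(NA_integer_, length(all_cats)), all_cats)
    for (i in seq_along(merged)) ranks[merged[[i]]] <- i
    present <- !is.na(ranks)
    if (all(present) && setequal(all_cats, AGE_CATEGORIES)) {
        tab <- .MODEL_CLASS_TABLE
        hit <- which(tab$rank_F == ranks["fetal"] &
                     tab$rank_Y == ranks["young"] &
                     tab$rank_A == ranks["adult"])
        return(tab$label[hit])
    }
    ## restricted label over present categories only
    init <- c(fetal = "F", young = "Y", adult = "A")
    cats <- all_cats[present]
    o <- cats[order(ranks[cats])]
    lab <- init[o[1]]
    for (i in seq_along(o)[-1]) {
        lab <- paste0(lab, if (ranks[o[i]] == ranks[o[i - 1]]) "=" else "<",
                      init[o[i]])
    }
    unname(lab)
}

#' Direction-aware pattern of a fitted gene
#'
#' Orders the estimated means of the retained groups of a
#' \linkS4class{GeneFit} and returns the canonical pattern label; exactly
#' tied group means are merged conservatively (the equality is reported).
#'
#' @param fit a \linkS4class{GeneFit}.
#' @return a pattern label, one of \code{enumerateModelClasses()$label} for
#'   fits with all three categories present.
#' @export
classifyDirection <- function(fit) {
    stopifnot(is(fit, "GeneFit"))
    groups <- strsplit(fit@partition, "|", fixed = TRUE)[[1]]
    back <- c(F = "fetal", Y = "young", A = "adult")
    groups <- lapply(strsplit(groups, ""), function(g) unname(back[g]))
    present <- names(fit@means)[fit@n > 0]
    .directionLabel(groups, fit@means, all_cats =
        if (length(present) == 3) AGE_CATEGORIES else present)
}

## ---- covariate scan ------------------------------------------------------

#' Scan for expression trends on a continuous covariate within one category
#'
#' Per-gene simple linear regression of expression on a covariate (e.g.
#' gestational weeks within the fetal samples, or postnatal days within the
#' young samples), with slope-test p-values. Optionally calibrates a
#' discovery threshold by permuting the covariate across samples and
#' re-running the scan (the same SAM-like machinery as the category
#' analysis).
#'
#' @param x numeric matrix (genes x samples) or \linkS4class{LogRatioMatrix}.
#' @param categories per-sample age-category labels (ignored for a
#'   LogRatioMatrix).
#' @param subset the age category to scan within.
#' @param covariate numeric covariate per sample of \code{x} (NA outside the
#'   subset is fine), or the name of a colData column for a LogRatioMatrix.
#' @param target_fdr if non-NULL, calibrate a p-value threshold at this
#'   nominal FDR by covariate permutation.
#' @param n_sims number of permutation null datasets for calibration.
#' @param seed seed for the permutations.
#' @return list with \code{p} (per-gene p-values), \code{slope},
#'   \code{n} (samples used), and when calibrated, \code{calibration}
#'   (a \linkS4class{CalibrationResult}) and \code{discoveries}
#'   (gene identifiers at or below the threshold).
#' @export
covariateScan <- function(x, categories = NULL, subset = "fetal",
                          covariate, target_fdr = NULL, n_sims = 300L,
                          seed = 1L) {
    if (is(x, "LogRatioMatrix")) {
        categories <- sampleCategories(x)
        if (is.character(covariate) && length(covariate) == 1L)
            covariate <- SummarizedExperiment::colData(x)[[covariate]]
        x <- logRatios(x)
    }
    categories <- .asCategories(categories)
    stopifnot(subset %in% AGE_CATEGORIES,
              length(covariate) == ncol(x))
    cols <- which(categories == subset & !is.na(covariate))
    if (length(cols) < 3)
        stop("covariate scan needs >= 3 samples with the covariate")
    xs <- x[, cols, drop = FALSE]
    z <- covariate[cols]
    res <- .slopeTest(xs, z)
    out <- list(p = res$p, slope = res$slope, n = res$n)
    if (!is.null(target_fdr)) {
        set.seed(seed)
        nulls <- matrix(NA_real_, nrow = n_sims, ncol = nrow(xs))
        for (s in seq_len(n_sims))
            nulls[s, ] <- .slopeTest(xs, sample(z))$p
        calib <- calibrateThreshold(res$p, nulls, target_fdr = target_fdr,
                                    seed = seed)
        out$calibration <- calib
        ids <- rownames(xs)
        if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(xs)))
        out$discoveries <- ids[!is.na(res$p) &
                               res$p <= calib@threshold &
                               calib@n_discoveries > 0L]
        if (calib@n_discoveries == 0L) out$discoveries <- character()
    }
    out
}

## vectorized per-row slope test tolerating missing values
.slopeTest <- function(x, z) {
    obs <- !is.na(x)
    xz <- x; xz[!obs] <- 0
    storage.mode(obs) <- "numeric"
    n <- rowSums(obs)
    Sx <- drop(obs %*% z)
    Sxx <- drop(obs %*% (z * z))
    Sy <- rowSums(xz)
    Syy <- rowSums(xz * xz)
    Sxy <- drop(xz %*% z)
    vx <- Sxx - Sx * Sx / n
    slope <- ifelse(vx > 0, (Sxy - Sx * Sy / n) / vx, 0)
    sse <- pmax(Syy - Sy * Sy / n - slope * slope * vx, 0)
    df <- n - 2
    tt <- ifelse(vx > 0 & df > 0 & sse > 0,
                 slope * slope * vx / (sse / df), 0)
    p <- ifelse(vx > 0 & df > 0,
                stats::pf(tt, 1, pmax(df, 1), lower.tail = FALSE), NA_real_)
    ## exact fit with non-zero slope
    exact <- vx > 0 & df > 0 & sse == 0 & slope != 0
    p[exact] <- 0
    zerov <- vx > 0 & df > 0 & sse == 0 & slope == 0
    p[zerov] <- 1
    list(p = p, slope = slope, n = n)
}

## ---- residual diagnostics ------------------------------------------------

#' Distributional diagnostics of the per-gene ANOVA residuals
#'
#' Pools standardized residuals from the full three-mean fit of every gene
#' and summarises their agreement with the Gaussian working assumption:
#' normal Q-Q pairs, the Q-Q slope, excess kurtosis, and per-category
#' variance ratios. Reporting only; nothing is gated on the outcome.
#'
#' @param x numeric matrix (genes x samples) or \linkS4class{LogRatioMatrix}.
#' @param categories per-sample age-category labels.
#' @param max_points maximum number of Q-Q pairs returned (evenly thinned).
#' @return list with \code{qq} (data.frame theoretical/empirical),
#'   \code{qq_slope}, \code{excess_kurtosis}, \code{variance_ratio} (named
#'   per category: mean within-category residual variance over the pooled
#'   variance) and \code{n_genes}. All empty for an empty input.
#' @export
residualDiagnostics <- function(x, categories = NULL, max_points = 2000L) {
    if (is(x, "LogRatioMatrix")) {
        categories <- sampleCategories(x)
        x <- logRatios(x)
    }
    x <- as.matrix(x)
    if (nrow(x) == 0L) {
        return(list(qq = data.frame(theoretical = numeric(),
                                    empirical = numeric()),
                    qq_slope = NA_real_, excess_kurtosis = NA_real_,
                    variance_ratio = stats::setNames(numeric(0), character(0)),
                    n_genes = 0L))
    }
    categories <- .asCategories(categories)
    st <- .groupStats(x, categories)
    om <- .omnibusFromStats(st)
    Nsafe <- ifelse(st$N > 0, st$N, 1)
    M <- st$S / Nsafe
    fitted <- M[, as.integer(categories), drop = FALSE]
    resid <- x - fitted
    sdg <- sqrt(om$rss_full / pmax(om$n_obs - om$k, 1))
    std <- resid / ifelse(sdg > 0, sdg, 1)
    vals <- std[!is.na(std) & sdg > 0]
    if (length(vals) == 0L) {
        return(list(qq = data.frame(theoretical = numeric(),
                                    empirical = numeric()),
                    qq_slope = NA_real_, excess_kurtosis = NA_real_,
                    variance_ratio = stats::setNames(numeric(0), character(0)),
                    n_genes = nrow(x)))
    }
    vals <- sort(vals)
    n <- length(vals)
    theo <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
    if (n > max_points) {
        keep <- unique(round(seq(1, n, length.out = max_points)))
        qq <- data.frame(theoretical = theo[keep], empirical = vals[keep])
    } else {
        qq <- data.frame(theoretical = theo, empirical = vals)
    }
    slope <- stats::coef(stats::lm(vals ~ theo))[2]
    m2 <- mean((vals - mean(vals))^2)
    kurt <- mean((vals - mean(vals))^4) / m2^2 - 3
    vr <- vapply(AGE_CATEGORIES, function(l) {
        r <- std[, categories == l, drop = FALSE]
        stats::var(as.vector(r), na.rm = TRUE)
    }, numeric(1))
    vr <- vr / stats::var(as.vector(std), na.rm = TRUE)
    list(qq = qq, qq_slope = unname(slope), excess_kurtosis = kurt,
         variance_ratio = vr, n_genes = nrow(x))
}
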