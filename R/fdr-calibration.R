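## Simulation-based FDR estimation in the style of SAM: null p-value pools
## by whole-column label permutation, and threshold selection controlling
## the estimated FDR at a target rate.

#' Simulate null p-value pools by age-label permutation
#'
#' Each simulation permutes the age-category labels across samples (a
#' whole-column permutation, preserving the gene-gene correlation
#' structure) and recomputes every gene's omnibus ANOVA p-value. A
#' parametric Gaussian option (resampling residuals around a common mean)
#' is available behind \code{method}.
#'
#' @param x numeric matrix (genes x samples) or a
#'   \linkS4class{LogRatioMatrix}.
#' @param categories per-sample age-category labels (ignored for a
#'   LogRatioMatrix).
#' @param n_sims number of null datasets (the study-scale default is 2500;
#'   smaller values are adequate for desk-scale work).
#' @param seed integer seed.
#' @param method "permute" (label permutation, default) or "parametric"
#'   (Gaussian resampling from the pooled per-gene residual distribution).
#' @return numeric matrix, \code{n_sims} rows x genes columns, of null
#'   p-values.
#' @export
simulateNullPvalues <- function(x, categories = NULL, n_sims = 2500L,
                                seed = 1L,
                                method = c("permute", "parametric")) {
    method <- match.arg(method)
    if (is(x, "LogRatioMatrix")) {
        categories <- sampleCategories(x)
        x <- logRatios(x)
    }
    x <- as.matrix(x)
    categories <- .asCategories(categories)
    stopifnot(n_sims >= 1, nlevels(droplevels(categories)) >= 2)
    n <- ncol(x)
    ## warn when the design admits fewer distinct permutations than
    ## requested simulations (tiny designs): sampling is with replacement
    n_distinct <- exp(lfactorial(n) -
                      sum(lfactorial(table(categories))))
    if (is.finite(n_distinct) && n_distinct < n_sims)
        warning("only ", round(n_distinct),
                " distinct label permutations exist; ",
                "sampling with replacement")
    set.seed(seed)
    out <- matrix(NA_real_, n_sims, nrow(x))
    colnames(out) <- rownames(x)
    for (s in seq_len(n_sims)) {
        if (method == "permute") {
            out[s, ] <- omnibusPValues(x, categories[sample.int(n)])
        } else {
            mu <- rowMeans(x, na.rm = TRUE)
            sdg <- apply(x, 1, stats::sd, na.rm = TRUE)
            xs <- mu + matrix(stats::rnorm(length(x)), nrow(x), n) * sdg
            xs[is.na(x)] <- NA
            out[s, ] <- omnibusPValues(xs, categories)
        }
    }
    out
}

#' Choose a p-value threshold controlling the estimated FDR
#'
#' For candidate thresholds t (the sorted observed p-values), the FDR is
#' estimated as the median (or mean) across simulations of the null
#' discovery count at t, divided by the observed discovery count at t,
#' then made monotone non-decreasing in t by a running maximum. The chosen
#' threshold is the largest t whose adjusted estimate stays at or below
#' \code{target_fdr}; if no candidate qualifies, the smallest observed
#' p-value is returned with zero discoveries.
#'
#' @param observed_p per-gene observed p-values.
#' @param null_pools matrix of null p-values (simulations x genes), e.g.
#'   from [simulateNullPvalues()], or a list of numeric vectors.
#' @param target_fdr nominal FDR rate in (0, 1); the study-default working
#'   rate is 0.01. Values >= 1 are accepted for the degenerate
#'   everything-discovered bound.
#' @param summary "median" (default, robust) or "mean" across simulations.
#' @param seed seed recorded in the result (bookkeeping only).
#' @return a \linkS4class{CalibrationResult}.
#' @export
calibrateThreshold <- function(observed_p, null_pools, target_fdr = 0.01,
                               summary = c("median", "mean"),
                               seed = NA_integer_) {
    summary <- match.arg(summary)
    observed_p <- observed_p[!is.na(observed_p)]
    if (length(observed_p) == 0L)
        stop("no observed p-values to calibrate on")
    if (is.list(null_pools))
        null_pools <- do.call(rbind, null_pools)
    stopifnot(is.matrix(null_pools), nrow(null_pools) >= 1,
              target_fdr > 0)
    n_sims <- nrow(null_pools)
    cand <- sort(unique(observed_p))
    obs_sorted <- sort(observed_p)
    n_obs_le <- findInterval(cand, obs_sorted)
    ## per-simulation null discovery counts at every candidate threshold
    counts <- matrix(0, n_sims, length(cand))
    for (s in seq_len(n_sims)) {
        ns <- sort(null_pools[s, !is.na(null_pools[s, ])])
        counts[s, ] <- findInterval(cand, ns)
    }
    num <- if (summary == "median") apply(counts, 2, stats::median)
           else colMeans(counts)
    fdr_hat <- pmin(1, num / pmax(1, n_obs_le))   # an FDR is a proportion
    fdr_adj <- cummax(fdr_hat)          # monotone in t
    ok <- fdr_adj <= target_fdr
    if (any(ok)) {
        i <- max(which(ok))
        thr <- cand[i]
        est <- fdr_adj[i]
        disc <- n_obs_le[i]
    } else {
        thr <- cand[1]
        est <- fdr_adj[1]
        disc <- 0L
    }
    new("CalibrationResult", threshold = thr, target_fdr = target_fdr,
        n_simulations = as.integer(n_sims), estimated_fdr = est,
        n_discoveries = as.integer(disc), seed = as.integer(seed))
}

#' One-call SAM-like calibration of the category analysis
#'
#' Computes the per-gene omnibus p-values, simulates label-permutation
#' nulls, and picks the p-value threshold controlling the estimated FDR at
#' \code{target_fdr}.
#'
#' @inheritParams simulateNullPvalues
#' @inheritParams calibrateThreshold
#' @return list with \code{p} (observed p-values), \code{calibration}
#'   (a \linkS4class{CalibrationResult}) and \code{discoveries} (gene
#'   identifiers significant at the chosen threshold).
#' @export
calibrateCategoryAnalysis <- function(x, categories = NULL,
                                      target_fdr = 0.01, n_sims = 2500L,
                                      seed = 1L,
                                      method = c("permute", "parametric"),
                                      summary = c("median", "mean")) {
    if (is(x, "LogRatioMatrix")) {
        categories <- sampleCategories(x)
        x <- logRatios(x)
    }
    x <- as.matrix(x)
    if (is.null(rownames(x)))
        rownames(x) <- paste0("gene_", seq_len(nrow(x)))
    p <- omnibusPValues(x, categories)
    nulls <- simulateNullPvalues(x, categories, n_sims = n_sims,
                                 seed = seed, method = method)
    calib <- calibrateThreshold(p, nulls, target_fdr = target_fdr,
                                summary = summary, seed = seed)
    disc <- if (calib@n_discoveries > 0L)
        rownames(x)[!is.na(p) & p <= calib@threshold] else character()
    list(p = p, calibration = calib, discoveries = disc)
}

#' Benjamini-Hochberg cross-check
#'
#' Analytic FDR control via \code{\link[stats]{p.adjust}}, offered as a
#' cross-check utility for the simulation-based calibration (not the
#' primary path).
#'
#' @param observed_p per-gene p-values.
#' @param target_fdr nominal rate.
#' @return logical vector: discovery at \code{target_fdr} by BH.
#' @export
bhDiscoveries <- function(observed_p, target_fdr = 0.01)
    stats::p.adjust(observed_p, method = "BH") <= target_fdr
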