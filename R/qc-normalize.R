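## Standard feature-level quality filters, per-array LOWESS normalization of log-ratios,
## and assembly of the cross-array gene x sample matrix.

#' Feature-filter thresholds
#'
#' The four feature-level quality filters: (1) at least 70\% of pixels more
#' than 2 SD above background in the red or the green channel, (2) feature
#' uniformity regression R-squared strictly greater than 0.5, (3) not
#' saturated (>= 20\% of pixels) in both channels, (4) no inspection flag.
#'
#' @param min_frac_pixels_above_bg minimum pixel fraction (either channel).
#' @param min_r_squared R-squared bound (strict inequality).
#' @param max_frac_saturated_both saturation fraction that, reached in both
#'   channels, excludes the feature.
#' @param exclude_flagged drop features with a non-zero flag.
#' @return a named list of thresholds.
#' @export
filterThresholds <- function(min_frac_pixels_above_bg = 0.70,
                             min_r_squared = 0.5,
                             max_frac_saturated_both = 0.20,
                             exclude_flagged = TRUE) {
    stopifnot(min_frac_pixels_above_bg >= 0, min_frac_pixels_above_bg <= 1,
              max_frac_saturated_both >= 0, max_frac_saturated_both <= 1)
    list(min_frac_pixels_above_bg = min_frac_pixels_above_bg,
         min_r_squared = min_r_squared,
         max_frac_saturated_both = max_frac_saturated_both,
         exclude_flagged = exclude_flagged)
}

## long (2 channels) -> wide per-feature view of a merged scan table
.wideScan <- function(merged) {
    ch <- split(merged, merged$channel)
    if (length(ch) != 2L)
        stop("expected exactly two channels, got: ",
             paste(names(ch), collapse = ", "))
    a <- ch[[1]]; b <- ch[[2]]
    m <- match(a$feature_id, b$feature_id)
    if (anyNA(m)) stop("channels do not share feature ids")
    b <- b[m, ]
    list(ids = a$feature_id, source = a$annotation_source, ch1 = a, ch2 = b)
}

#' Apply the four feature-level quality filters
#'
#' @param merged merged scan table of one array (both channels).
#' @param thresholds a list from [filterThresholds()].
#' @return data.frame with \code{feature_id}, \code{keep} and
#'   \code{reason} (semicolon-joined codes among "pixels", "r_squared",
#'   "saturation", "flag"; empty when kept).
#' @export
applyFeatureFilters <- function(merged, thresholds = filterThresholds()) {
    .checkScanTable(merged, "merged table")
    w <- .wideScan(merged)
    px_ok <- w$ch1$frac_pixels_gt_bg2sd >= thresholds$min_frac_pixels_above_bg |
        w$ch2$frac_pixels_gt_bg2sd >= thresholds$min_frac_pixels_above_bg
    r2 <- (w$ch1$r_squared + w$ch2$r_squared) / 2
    r2_ok <- r2 > thresholds$min_r_squared
    sat_bad <- w$ch1$frac_saturated >= thresholds$max_frac_saturated_both &
        w$ch2$frac_saturated >= thresholds$max_frac_saturated_both
    flag_bad <- thresholds$exclude_flagged &
        (w$ch1$flag != 0 | w$ch2$flag != 0)
    reason <- character(length(w$ids))
    add <- function(reason, bad, code)
        ifelse(bad, ifelse(nzchar(reason), paste(reason, code, sep = ";"),
                           code), reason)
    reason <- add(reason, !px_ok, "pixels")
    reason <- add(reason, !r2_ok, "r_squared")
    reason <- add(reason, sat_bad, "saturation")
    reason <- add(reason, flag_bad, "flag")
    data.frame(feature_id = w$ids, keep = !nzchar(reason),
               reason = reason, stringsAsFactors = FALSE)
}

#' LOWESS-normalize the log-ratios of one array
#'
#' M-values (log2 sample/reference) are recentred by subtracting a LOWESS
#' fit of M on A (mean log2 intensity), removing intensity-dependent dye
#' bias. Tricube weights with 3 robustness iterations via
#' \code{\link[stats]{lowess}}.
#'
#' @param M per-feature log2 ratios.
#' @param A per-feature mean log2 intensities.
#' @param span LOWESS smoother span (fraction of points).
#' @param min_features minimum number of usable features.
#' @return normalized M-values (NA where M or A is NA).
#' @export
lowessNormalize <- function(M, A, span = 0.4, min_features = 30L) {
    stopifnot(length(M) == length(A))
    ok <- !is.na(M) & !is.na(A)
    if (sum(ok) < min_features)
        stop("too few features for LOWESS normalization (",
             sum(ok), " < ", min_features, ")")
    fit <- stats::lowess(A[ok], M[ok], f = span, iter = 3)
    trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2,
                           ties = mean)$y
    M - trend
}

#' Log-ratios and mean intensities of one merged array
#'
#' Background-subtracted intensities (floored at 1) give
#' M = log2(Cy3/Cy5) and A = mean of the channel log2 intensities.
#'
#' @param merged merged scan table (both channels).
#' @param sample_channel channel carrying the sample (the other is the
#'   reference pool).
#' @return data.frame with \code{feature_id}, \code{annotation_source},
#'   \code{M}, \code{A}.
#' @export
computeLogRatios <- function(merged, sample_channel = "Cy3") {
    .checkScanTable(merged, "merged table")
    w <- .wideScan(merged)
    s <- if (w$ch1$channel[1] == sample_channel) w$ch1 else w$ch2
    r <- if (w$ch1$channel[1] == sample_channel) w$ch2 else w$ch1
    ls <- log2(.bgsub(s)); lr <- log2(.bgsub(r))
    data.frame(feature_id = w$ids, annotation_source = w$source,
               M = ls - lr, A = (ls + lr) / 2, stringsAsFactors = FALSE)
}

#' Filter, normalize and assemble arrays into a LogRatioMatrix
#'
#' Runs the feature filters and LOWESS normalization on every array, then
#' retains genes passing the filters on at least \code{presence_min} of the
#' arrays; entries where a retained gene failed on an individual array stay
#' missing and are tolerated by the per-gene fits downstream.
#'
#' @param merged_tables named list (by sample id) of merged scan tables.
#' @param sample_table per-sample metadata with \code{sample_id} and
#'   \code{age_category}.
#' @param thresholds filter thresholds ([filterThresholds()]).
#' @param span LOWESS span.
#' @param presence_min minimum fraction of arrays a gene must pass on.
#' @param row_annotation optional extra per-feature annotation
#'   (data.frame keyed by \code{feature_id}, e.g. the large-ncRNA flag).
#' @return list with \code{matrix} (a \linkS4class{LogRatioMatrix}) and
#'   \code{qc_report} (per-filter exclusion counts per array and totals).
#' @export
assembleMatrix <- function(merged_tables, sample_table,
                           thresholds = filterThresholds(), span = 0.4,
                           presence_min = 0.70, row_annotation = NULL) {
    if (length(merged_tables) < 2L)
        stop("need at least 2 arrays to assemble a matrix")
    ids0 <- merged_tables[[1]]$feature_id[
        merged_tables[[1]]$channel == merged_tables[[1]]$channel[1]]
    n_arrays <- length(merged_tables)
    sample_ids <- names(merged_tables)
    if (is.null(sample_ids))
        stop("merged_tables must be named by sample id")
    keep_mat <- matrix(FALSE, length(ids0), n_arrays,
                       dimnames = list(ids0, sample_ids))
    m_mat <- matrix(NA_real_, length(ids0), n_arrays,
                    dimnames = list(ids0, sample_ids))
    excl <- list()
    src <- NULL
    for (j in seq_len(n_arrays)) {
        tab <- merged_tables[[j]]
        mask <- applyFeatureFilters(tab, thresholds)
        mr <- computeLogRatios(tab)
        stopifnot(identical(mask$feature_id, mr$feature_id))
        if (is.null(src))
            src <- stats::setNames(mr$annotation_source, mr$feature_id)
        Mn <- rep(NA_real_, nrow(mr))
        Mn[mask$keep] <- lowessNormalize(mr$M[mask$keep], mr$A[mask$keep],
                                         span = span)
        i <- match(mr$feature_id, ids0)
        keep_mat[i, j] <- mask$keep
        m_mat[i, j] <- ifelse(mask$keep, Mn, NA_real_)
        codes <- unlist(strsplit(mask$reason[!mask$keep], ";",
                                 fixed = TRUE))
        excl[[sample_ids[j]]] <- table(factor(codes,
            levels = c("pixels", "r_squared", "saturation", "flag")))
    }
    presence <- rowMeans(keep_mat)
    retained <- presence >= presence_min
    if (!any(retained)) stop("no gene passes the presence rule")
    m <- m_mat[retained, , drop = FALSE]
    ra <- data.frame(annotation_source = unname(src[rownames(m)]),
                     large_ncrna = FALSE, stringsAsFactors = FALSE)
    if (!is.null(row_annotation)) {
        i <- match(rownames(m), row_annotation$feature_id)
        for (col in setdiff(colnames(row_annotation), "feature_id"))
            ra[[col]] <- row_annotation[[col]][i]
    }
    st <- sample_table[match(colnames(m), sample_table$sample_id), ,
                       drop = FALSE]
    if (anyNA(st$sample_id))
        stop("sample_table lacks entries for some arrays")
    lrm <- LogRatioMatrix(m, st, row_annotation = ra)
    report <- list(
        n_features = length(ids0), n_arrays = n_arrays,
        n_retained = sum(retained),
        presence_min = presence_min,
        exclusions_per_array = excl,
        exclusions_total = Reduce(`+`, excl)
    )
    list(matrix = lrm, qc_report = report)
}
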