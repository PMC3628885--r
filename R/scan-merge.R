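## Merge the 10%- and 100%-laser-power scans of one array into a single
## extended-dynamic-range intensity per feature and channel.

.SCAN_COLUMNS <- c("feature_id", "annotation_source", "channel",
                   "scan_power", "median_fg", "median_bg", "bg_sd",
                   "frac_pixels_gt_bg2sd", "r_squared", "frac_saturated",
                   "flag")

.checkScanTable <- function(tab, what = "scan table") {
    missing <- setdiff(.SCAN_COLUMNS, colnames(tab))
    if (length(missing))
        stop(what, " lacks required columns: ",
             paste(missing, collapse = ", "))
    invisible(tab)
}

## background-subtracted intensity, floored at 1 for downstream logs
.bgsub <- function(tab) pmax(tab$median_fg - tab$median_bg, 1)

## least-absolute-deviations line by iteratively reweighted least squares;
## a 2-parameter robust fit, adequate for scan calibration
.ladFit <- function(x, y, iter = 30L, tol = 1e-8) {
    w <- rep(1, length(x))
    beta <- stats::coef(stats::lm(y ~ x))
    for (i in seq_len(iter)) {
        fit <- stats::lm(y ~ x, weights = w)
        new <- stats::coef(fit)
        if (max(abs(new - beta)) < tol * (1 + max(abs(beta)))) {
            beta <- new
            break
        }
        beta <- new
        r <- abs(stats::residuals(fit))
        w <- 1 / pmax(r, 1e-6 * stats::median(r[r > 0], na.rm = TRUE),
                      1e-12)
    }
    c(intercept = unname(beta[1]), slope = unname(beta[2]))
}

#' Fit the calibration between the two laser-power scans of one channel
#'
#' Robust (least absolute deviations) linear regression of the
#' background-subtracted 100\%-scan intensity on the 10\%-scan intensity,
#' over the support set of features that are unsaturated (saturated-pixel
#' fraction below \code{sat_cut}) in both scans and above background in
#' both.
#'
#' @param low,high scan tables of the same array at 10\% and 100\% power.
#' @param channel channel to calibrate ("Cy3" or "Cy5").
#' @param sat_cut saturation fraction above which a feature is considered
#'   saturated (default 0.20, the same constant as the saturation filter).
#' @return a \linkS4class{ScanCalibration}.
#' @export
fitScanCalibration <- function(low, high, channel = "Cy3",
                               sat_cut = 0.20) {
    .checkScanTable(low, "low scan")
    .checkScanTable(high, "high scan")
    lo <- low[low$channel == channel, ]
    hi <- high[high$channel == channel, ]
    if (!identical(lo$feature_id, hi$feature_id)) {
        m <- match(lo$feature_id, hi$feature_id)
        if (anyNA(m)) stop("scan tables do not share feature ids")
        hi <- hi[m, ]
    }
    support <- lo$frac_saturated < sat_cut & hi$frac_saturated < sat_cut &
        lo$median_fg > lo$median_bg & hi$median_fg > hi$median_bg
    if (sum(support) < 10L)
        stop("calibration support set has fewer than 10 features")
    beta <- .ladFit(.bgsub(lo)[support], .bgsub(hi)[support])
    if (beta["slope"] <= 0)
        stop("non-positive calibration slope; are the scans swapped?")
    new("ScanCalibration", slope = unname(beta["slope"]),
        intercept = unname(beta["intercept"]),
        n_support = as.integer(sum(support)), channel = channel)
}

#' Merge the two scans of one array into an extended-range table
#'
#' Features unsaturated in the 100\% scan keep their 100\%-scan values;
#' features saturated there (saturated-pixel fraction at or above
#' \code{sat_cut}) are replaced by the calibrated 10\%-scan intensity
#' (slope x background-subtracted low + intercept, re-expressed above the
#' high-scan background). QC fields come from the scan actually used, and
#' a \code{source_scan} column records the provenance of every feature.
#'
#' @param low,high scan tables of one array.
#' @param calib list of \linkS4class{ScanCalibration} objects, one per
#'   channel present (or a single object when only one channel is merged).
#' @param sat_cut saturation fraction triggering substitution.
#' @return merged scan table in the same dialect, \code{scan_power} set to
#'   "merged", plus \code{source_scan} ("high" or "low_calibrated").
#' @export
mergeScans <- function(low, high, calib, sat_cut = 0.20) {
    .checkScanTable(low, "low scan")
    .checkScanTable(high, "high scan")
    if (is(calib, "ScanCalibration")) calib <- list(calib)
    names(calib) <- vapply(calib, function(cc) cc@channel, character(1))
    out <- NULL
    for (channel in unique(high$channel)) {
        lo <- low[low$channel == channel, ]
        hi <- high[high$channel == channel, ]
        if (nrow(lo) != nrow(hi))
            stop("low/high scans disagree on features for channel ",
                 channel)
        m <- match(hi$feature_id, lo$feature_id)
        if (anyNA(m)) stop("feature ids of the two scans do not match")
        lo <- lo[m, ]
        if (!channel %in% names(calib))
            stop("no calibration supplied for channel ", channel)
        cc <- calib[[channel]]
        sat <- hi$frac_saturated >= sat_cut
        merged <- hi
        merged$scan_power <- "merged"
        merged$source_scan <- ifelse(sat, "low_calibrated", "high")
        sub <- cc@slope * .bgsub(lo)[sat] + cc@intercept
        merged$median_fg[sat] <- hi$median_bg[sat] + pmax(sub, 1)
        ## QC from the scan actually used
        for (col in c("frac_pixels_gt_bg2sd", "r_squared",
                      "frac_saturated", "flag"))
            merged[[col]][sat] <- lo[[col]][sat]
        out <- rbind(out, merged)
    }
    rownames(out) <- NULL
    out
}
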