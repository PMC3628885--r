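#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

AGE_CATEGORIES <- c("fetal", "young", "adult")

#' Configuration for the synthetic-data generators
#'
#' A validated container for every knob of the synthetic array-scan and
#' TaqMan generators. The defaults emulate the study design the package
#' targets: 36 fetal, 9 young and 2 adult arrays hybridised against a common
#' reference pool, roughly a third of the features being vendor-predicted
#' ("novel") sequences, 90\% of features flat across age categories and the
#' remaining 10\% spread over the twelve directional mean-pattern classes.
#'
#' @slot n_features number of array features (genes/assays).
#' @slot frac_novel fraction of features annotated as novel (vs known).
#' @slot n_fetal,n_young,n_adult samples per age category.
#' @slot class_mix named numeric over the 13 mean-pattern labels, summing
#'   to 1; the fraction of features planted with each pattern.
#' @slot effect_size log2 separation between adjacent unequal category means.
#' @slot noise_sd per-sample Gaussian noise SD on the log2 ratio scale.
#' @slot sat_threshold scanner intensity ceiling (16-bit: 65535).
#' @slot gain linear intensity gain between the 10\% and 100\% power scans.
#' @slot dye_bias amplitude (log2) of the smooth intensity-dependent dye
#'   bias added to raw log-ratios (removed downstream by LOWESS).
#' @slot qc_fail_pixels,qc_fail_r2,qc_fail_flag fractions of features drawn
#'   to fail, respectively, the pixels-above-background filter, the feature
#'   uniformity R-squared filter, and the visual-inspection flag filter.
#' @slot frac_low_expressed fraction of TaqMan assays generated near the
#'   detection limit (raw Ct > 29 everywhere).
#' @slot frac_passenger fraction of TaqMan assays annotated as
#'   passenger-strand sequences.
#' @slot ct_noise_sd Gaussian noise SD on the Ct scale (cycles).
#' @slot seed integer seed driving all randomness.
#'
#' @seealso [synthConfig()] for the user-facing constructor.
#' @export
setClass("SynthConfig", representation(
    n_features = "integer",
    frac_novel = "numeric",
    n_fetal = "integer",
    n_young = "integer",
    n_adult = "integer",
    class_mix = "numeric",
    effect_size = "numeric",
    noise_sd = "numeric",
    sat_threshold = "numeric",
    gain = "numeric",
    dye_bias = "numeric",
    qc_fail_pixels = "numeric",
    qc_fail_r2 = "numeric",
    qc_fail_flag = "numeric",
    frac_low_expressed = "numeric",
    frac_passenger = "numeric",
    ct_noise_sd = "numeric",
    seed = "integer"
))

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (object@n_features < 1L) msg <- c(msg, "n_features must be >= 1")
    if (object@n_fetal < 1L || object@n_young < 1L || object@n_adult < 1L)
        msg <- c(msg, "all per-category sample counts must be >= 1")
    if (object@frac_novel < 0 || object@frac_novel > 1)
        msg <- c(msg, "frac_novel must lie in [0, 1]")
    if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be > 0")
    mix <- object@class_mix
    labs <- modelClassLabels()
    if (!setequal(names(mix), labs))
        msg <- c(msg, "class_mix must be named by the 13 mean-pattern labels")
    if (any(mix < 0)) msg <- c(msg, "class_mix fractions must be >= 0")
    if (abs(sum(mix) - 1) > 1e-9)
        msg <- c(msg, "class_mix fractions must sum to 1 (tolerance 1e-9)")
    for (f in c("qc_fail_pixels", "qc_fail_r2", "qc_fail_flag",
                "frac_low_expressed", "frac_passenger")) {
        v <- slot(object, f)
        if (v < 0 || v > 1) msg <- c(msg, paste(f, "must lie in [0, 1]"))
    }
    if (object@sat_threshold <= 0) msg <- c(msg, "sat_threshold must be > 0")
    if (object@gain <= 1) msg <- c(msg, "gain must exceed 1")
    if (length(msg)) msg else TRUE
})

#' Calibration relating the two laser-power scans of one channel
#'
#' Robust linear relation (least absolute deviations) mapping
#' background-subtracted low-scan intensities onto the high-scan intensity
#' scale, fitted over features unsaturated and above background in both
#' scans.
#'
#' @slot slope unitless gain (> 0).
#' @slot intercept intensity units.
#' @slot n_support number of features in the support set (>= 10).
#' @slot channel channel identifier ("Cy3" or "Cy5").
#' @export
setClass("ScanCalibration", representation(
    slope = "numeric", intercept = "numeric",
    n_support = "integer", channel = "character"
))

setValidity("ScanCalibration", function(object) {
    msg <- character()
    if (object@slope <= 0) msg <- c(msg, "slope must be > 0")
    if (object@n_support < 10L) msg <- c(msg, "n_support must be >= 10")
    if (length(msg)) msg else TRUE
})

#' Normalized log-ratio matrix with sample and feature annotation
#'
#' The central expression container: a \linkS4class{SummarizedExperiment}
#' whose single assay \code{"logratio"} holds filtered, LOWESS-normalized
#' log2(sample / reference pool) values, genes in rows and arrays in
#' columns. Row annotation records the annotation source (known vs novel)
#' and the large-ncRNA flag; column annotation is the sample table with the
#' age category.
#'
#' @seealso [LogRatioMatrix()] (constructor), [logRatios()],
#'   [sampleCategories()], [annotationSource()].
#' @export
setClass("LogRatioMatrix", contains = "SummarizedExperiment")

setValidity("LogRatioMatrix", function(object) {
    msg <- character()
    if (!"logratio" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'logratio' is required")
    else if (any(is.infinite(SummarizedExperiment::assay(object, "logratio"))))
        msg <- c(msg, "log-ratio matrix must not contain infinities")
    cd <- SummarizedExperiment::colData(object)
    if (!"age_category" %in% colnames(cd))
        msg <- c(msg, "colData must contain 'age_category'")
    else if (!all(cd$age_category %in% AGE_CATEGORIES))
        msg <- c(msg, "age_category must be one of fetal/young/adult")
    if (!"annotation_source" %in%
            colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must contain 'annotation_source'")
    if (length(msg)) msg else TRUE
})

#' Result of simulation-based FDR calibration
#'
#' @slot threshold chosen p-value threshold in (0, 1].
#' @slot target_fdr nominal FDR rate the threshold was tuned to.
#' @slot n_simulations number of label-permutation null datasets.
#' @slot estimated_fdr estimated FDR at the chosen threshold (after the
#'   monotone running-maximum adjustment).
#' @slot n_discoveries number of observed p-values at or below the
#'   threshold.
#' @slot seed seed used for the null simulations (NA if nulls supplied).
#' @export
setClass("CalibrationResult", representation(
    threshold = "numeric", target_fdr = "numeric",
    n_simulations = "integer", estimated_fdr = "numeric",
    n_discoveries = "integer", seed = "integer"
))

setValidity("CalibrationResult", function(object) {
    msg <- character()
    if (object@threshold <= 0 || object@threshold > 1)
        msg <- c(msg, "threshold must lie in (0, 1]")
    if (object@n_discoveries > 0L &&
        object@estimated_fdr > object@target_fdr + 1e-12)
        msg <- c(msg, "estimated FDR exceeds the target at a non-empty threshold")
    if (length(msg)) msg else TRUE
})
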