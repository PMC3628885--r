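#' Single-gene fit result
#'
#' The retained mean structure of one gene: equality partition over the
#' three age categories, direction-aware pattern label, omnibus p-value,
#' the partial-F p-values encountered on the backward-selection path,
#' estimated category means and group sizes.
#'
#' @slot gene gene identifier.
#' @slot partition one of \code{"FYA"} (all equal), \code{"F|YA"},
#'   \code{"FY|A"}, \code{"FA|Y"}, \code{"F|Y|A"} (or a restricted label
#'   when a category is entirely missing).
#' @slot pattern canonical direction-aware label (see
#'   [enumerateModelClasses()]).
#' @slot p_value omnibus ANOVA p-value (full model against all-equal).
#' @slot p_merge largest partial-F p among the adjacent-mean merges.
#' @slot p_collapse partial-F p of collapsing the merged two-group model.
#' @slot means estimated category means (log2), named fetal/young/adult.
#' @slot n per-category observation counts.
#' @slot residual_var residual variance of the full fit.
#' @slot flags character vector of quality flags (e.g.
#'   \code{"missing_category"}, \code{"exact_fit"}).
#' @export
setClass("GeneFit", representation(
    gene = "character", partition = "character", pattern = "character",
    p_value = "numeric", p_merge = "numeric", p_collapse = "numeric",
    means = "numeric", n = "integer", residual_var = "numeric",
    flags = "character"
))

setMethod("show", "GeneFit", function(object) {
    cat("GeneFit:", object@gene, "\n")
    cat("  pattern:", object@pattern, " (partition ", object@partition,
        ")\n", sep = "")
    cat("  omnibus p:", format(object@p_value, digits = 4), "\n")
    cat("  means (F/Y/A):",
        paste(format(object@means, digits = 3), collapse = " / "), "\n")
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Construct a LogRatioMatrix
#'
#' @param logratio numeric matrix of normalized log2(sample/reference)
#'   values, genes in rows, samples in columns.
#' @param sample_table data.frame of per-sample metadata, one row per
#'   column of \code{logratio}; must contain \code{age_category}.
#' @param row_annotation optional data.frame of per-gene annotation
#'   (\code{annotation_source}, \code{large_ncrna}); defaults to all
#'   "known".
#' @return a \linkS4class{LogRatioMatrix}.
#'
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' st <- data.frame(sample_id = colnames(m),
#'                  age_category = c("fetal", "fetal", "young", "young",
#'                                   "adult"))
#' LogRatioMatrix(m, st)
#' @export
LogRatioMatrix <- function(logratio, sample_table,
                           row_annotation = NULL) {
    logratio <- as.matrix(logratio)
    if (is.null(rownames(logratio)))
        rownames(logratio) <- paste0("gene_", seq_len(nrow(logratio)))
    if (is.null(row_annotation)) {
        row_annotation <- S4Vectors::DataFrame(
            annotation_source = rep("known", nrow(logratio)),
            large_ncrna = rep(FALSE, nrow(logratio))
        )
    } else {
        row_annotation <- S4Vectors::DataFrame(row_annotation)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(logratio = logratio),
        rowData = row_annotation,
        colData = S4Vectors::DataFrame(sample_table)
    )
    new("LogRatioMatrix", se)
}

#' @describeIn LogRatioMatrix the normalized log-ratio matrix.
#' @param x a \linkS4class{LogRatioMatrix}.
#' @export
logRatios <- function(x) SummarizedExperiment::assay(x, "logratio")

#' @describeIn LogRatioMatrix per-sample age categories as a factor with
#'   levels fetal, young, adult.
#' @export
sampleCategories <- function(x)
    factor(SummarizedExperiment::colData(x)$age_category,
           levels = AGE_CATEGORIES)

#' @describeIn LogRatioMatrix per-gene annotation source ("known" or
#'   "novel").
#' @export
annotationSource <- function(x)
    SummarizedExperiment::rowData(x)$annotation_source

#' @describeIn LogRatioMatrix per-gene large-ncRNA flag (logical; FALSE if
#'   absent).
#' @export
isLargeNcRNA <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if ("large_ncrna" %in% colnames(rd)) rd$large_ncrna
    else rep(FALSE, nrow(x))
}

setMethod("show", "LogRatioMatrix", function(object) {
    cat("LogRatioMatrix:", nrow(object), "genes x", ncol(object),
        "samples\n")
    tab <- table(sampleCategories(object))
    cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
    src <- table(annotationSource(object))
    cat("  features:", paste(names(src), src, sep = "=", collapse = ", "),
        "\n")
    na <- sum(is.na(logRatios(object)))
    cat("  missing entries:", na, sprintf("(%.1f%%)",
        100 * na / length(logRatios(object))), "\n")
})

setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig:", object@n_features, "features;",
        object@n_fetal, "fetal /", object@n_young, "young /",
        object@n_adult, "adult samples\n")
    cat("  effect", object@effect_size, "log2; noise sd", object@noise_sd,
        "; novel fraction", object@frac_novel, "\n")
    nn <- object@class_mix[setdiff(names(object@class_mix), "F=Y=A")]
    cat(sprintf("  non-null fraction %.3f over %d directional classes; seed %d\n",
                sum(nn), sum(nn > 0), object@seed))
})

setMethod("show", "ScanCalibration", function(object) {
    cat(sprintf("ScanCalibration [%s]: slope %.4g, intercept %.4g (n = %d)\n",
                object@channel, object@slope, object@intercept,
                object@n_support))
})

setMethod("show", "CalibrationResult", function(object) {
    cat(sprintf("CalibrationResult: p <= %.6g controls FDR at %.3g\n",
                object@threshold, object@target_fdr))
    cat(sprintf("  estimated FDR %.4g; %d discoveries; %d null simulations\n",
                object@estimated_fdr, object@n_discoveries,
                object@n_simulations))
})
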