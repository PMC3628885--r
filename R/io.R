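## Readers and writers for the package's TSV dialects. Every output file
## is re-readable by the corresponding reader (round-trip suite).

.writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a scan table
#'
#' Tab-separated scan table in the package dialect (see
#' [generateArrayDataset()] for the columns). In strict mode (default)
#' every QC fraction must lie in [0, 1] and intensities must be
#' non-negative; offending rows raise an error naming the line. Unknown
#' columns are preserved.
#'
#' @param path file path.
#' @param strict validate ranges (TRUE) or pass values through (FALSE).
#' @return data.frame in the scan-table dialect.
#' @export
readScanTable <- function(path, strict = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (nrow(tab) == 0L) stop("no features in scan table: ", path)
    .checkScanTable(tab, paste("scan table", path))
    if (strict) {
        for (col in c("frac_pixels_gt_bg2sd", "r_squared",
                      "frac_saturated")) {
            bad <- which(tab[[col]] < 0 | tab[[col]] > 1)
            if (length(bad))
                stop("invalid ", col, " at line ", bad[1] + 1L, " of ",
                     path, " (value ", tab[[col]][bad[1]], ")")
        }
        bad <- which(tab$median_fg < 0 | tab$median_bg < 0)
        if (length(bad))
            stop("negative intensity at line ", bad[1] + 1L, " of ", path)
    }
    tab
}

#' @rdname readScanTable
#' @param tab scan table to write.
#' @export
writeScanTable <- function(tab, path) {
    .checkScanTable(tab)
    .writeTsv(tab, path)
}

#' Read / write a sample table
#' @param path file path.
#' @return data.frame with sample metadata.
#' @export
readSampleTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "age_category")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("sample table lacks columns: ", paste(miss, collapse = ", "))
    bad <- !tab$age_category %in% AGE_CATEGORIES
    if (any(bad))
        stop("unknown age_category at line ", which(bad)[1] + 1L)
    tab
}

#' @rdname readSampleTable
#' @param tab sample table to write.
#' @export
writeSampleTable <- function(tab, path) .writeTsv(tab, path)

#' Read / write a Ct table
#'
#' TSV dialect: \code{assay_id}, \code{strand}, then one raw-Ct column per
#' timepoint pool (censored reactions as 40).
#'
#' @param path file path.
#' @return Ct table data.frame.
#' @export
readCtTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    .checkCtTable(tab)
    tab
}

#' @rdname readCtTable
#' @param tab Ct table to write.
#' @export
writeCtTable <- function(tab, path) {
    .checkCtTable(tab)
    .writeTsv(tab, path)
}

#' Read / write a log-ratio matrix
#'
#' Matrix TSV (first column \code{gene}, then one column per sample id)
#' plus the sample table; together they rebuild a
#' \linkS4class{LogRatioMatrix}.
#'
#' @param matrix_path path of the matrix TSV.
#' @param samples_path path of the sample-table TSV.
#' @param annotation_path optional path of a per-gene annotation TSV
#'   (\code{gene}, \code{annotation_source}, \code{large_ncrna}).
#' @return a \linkS4class{LogRatioMatrix}.
#' @export
readLogRatioMatrix <- function(matrix_path, samples_path,
                               annotation_path = NULL) {
    tab <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (colnames(tab)[1] != "gene")
        stop("matrix file must start with a 'gene' column")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$gene
    st <- readSampleTable(samples_path)
    m <- m[, st$sample_id, drop = FALSE]
    ra <- NULL
    if (!is.null(annotation_path)) {
        an <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
        i <- match(rownames(m), an$gene)
        ra <- data.frame(annotation_source = an$annotation_source[i],
                         large_ncrna =
                             if ("large_ncrna" %in% colnames(an))
                                 an$large_ncrna[i] else FALSE)
    }
    LogRatioMatrix(m, st, row_annotation = ra)
}

#' @rdname readLogRatioMatrix
#' @param x a \linkS4class{LogRatioMatrix} to write.
#' @export
writeLogRatioMatrix <- function(x, matrix_path, samples_path = NULL,
                                annotation_path = NULL) {
    m <- logRatios(x)
    tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
    .writeTsv(tab, matrix_path)
    if (!is.null(samples_path))
        writeSampleTable(as.data.frame(
            SummarizedExperiment::colData(x)), samples_path)
    if (!is.null(annotation_path))
        .writeTsv(data.frame(gene = rownames(m),
                             annotation_source = annotationSource(x),
                             large_ncrna = isLargeNcRNA(x)),
                  annotation_path)
    invisible(matrix_path)
}
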