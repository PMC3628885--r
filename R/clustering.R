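## Correlation-metric hierarchical clustering of significant genes.

#' Correlation distance between gene expression profiles
#'
#' d(i, j) = 1 - r(row_i, row_j) with Pearson (default) or Spearman
#' correlation computed over the samples where both rows are non-missing.
#' Distances lie in [0, 2]; pairs sharing fewer than 3 non-missing samples
#' are set to the maximum distance 2 with a warning.
#'
#' @param x numeric matrix (genes x samples) or a
#'   \linkS4class{LogRatioMatrix}.
#' @param method correlation flavour, "pearson" or "spearman".
#' @return a \code{\link[stats]{dist}} object over the rows.
#' @export
correlationDistance <- function(x, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (is(x, "LogRatioMatrix")) x <- logRatios(x)
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("need at least 2 rows")
    vars <- apply(x, 1, stats::var, na.rm = TRUE)
    if (any(is.na(vars) | vars == 0))
        stop("rows with zero variance cannot be clustered on correlation: ",
             paste(utils::head(rownames(x)[is.na(vars) | vars == 0], 5),
                   collapse = ", "))
    r <- suppressWarnings(
        stats::cor(t(x), use = "pairwise.complete.obs", method = method))
    obs <- !is.na(x)
    shared <- obs %*% t(obs)
    thin <- shared < 3
    diag(thin) <- FALSE
    if (any(thin)) {
        warning(sum(thin) / 2, " gene pairs share fewer than 3 samples; ",
                "their distance is set to the maximum (2)")
        r[thin] <- -1
    }
    r[is.na(r)] <- -1
    d <- 1 - r
    diag(d) <- 0
    stats::as.dist(d)
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Average (default) or complete linkage via \code{\link[stats]{hclust}}.
#' The merge order is deterministic: equal-height candidates are joined in
#' order of their original indices (the hclust convention), so a fixed
#' input always yields the same tree and leaf order.
#'
#' @param d a \code{\link[stats]{dist}} object or symmetric matrix.
#' @param linkage "average" or "complete".
#' @return list with \code{hclust} (the merge tree), \code{leaf_order}
#'   (row indices in dendrogram order), \code{labels}.
#' @export
hierarchicalCluster <- function(d, linkage = c("average", "complete")) {
    linkage <- match.arg(linkage)
    if (is.matrix(d)) {
        if (!isSymmetric(unname(d)))
            stop("distance matrix must be symmetric")
        d <- stats::as.dist(d)
    }
    if (!inherits(d, "dist")) stop("d must be a dist or symmetric matrix")
    hc <- stats::hclust(d, method = linkage)
    list(hclust = hc, leaf_order = hc$order,
         labels = if (is.null(hc$labels))
             as.character(seq_len(attr(d, "Size"))) else hc$labels)
}

#' Export a dendrogram as Newick text
#'
#' @param cl result of [hierarchicalCluster()] (or an hclust object).
#' @param file optional path; when given the Newick string is written
#'   there.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogramNewick <- function(cl, file = NULL) {
    hc <- if (inherits(cl, "hclust")) cl else cl$hclust
    phy <- ape::as.phylo(hc)
    txt <- ape::write.tree(phy)
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

#' Order samples by their expression signature
#'
#' Convenience for heatmap-style displays: hierarchical clustering of the
#' sample columns on correlation distance, returning the column order.
#'
#' @param x matrix or \linkS4class{LogRatioMatrix}.
#' @param linkage linkage method.
#' @return integer vector of column indices.
#' @export
orderSamples <- function(x, linkage = "average") {
    if (is(x, "LogRatioMatrix")) x <- logRatios(x)
    hierarchicalCluster(correlationDistance(t(x)),
                        linkage = linkage)$leaf_order
}
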