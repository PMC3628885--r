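## Pooled-sample qPCR relative-expression analysis: 2^-ddCt with
## geometric-mean reference normalization, the robust-expression Ct filter,
## fold changes against a reference timepoint, the 2-SD outlier screen,
## fold-change bin tabulation and Q-Q data.

.CT_CENSOR <- 40
.REFERENCE_ASSAYS <- c("RNU44", "RNU48", "U6")

.ctColumns <- function(ct) setdiff(colnames(ct), c("assay_id", "strand"))

.checkCtTable <- function(ct) {
    if (!all(c("assay_id", "strand") %in% colnames(ct)))
        stop("Ct table needs 'assay_id' and 'strand' columns")
    tp <- .ctColumns(ct)
    if (length(tp) < 2) stop("Ct table needs at least 2 timepoint columns")
    vals <- as.matrix(ct[, tp])
    if (any(!is.na(vals) & (vals <= 0 | vals > .CT_CENSOR)))
        stop("raw Ct values must lie in (0, 40]")
    tp
}

#' Reference-normalize a Ct table (delta-Ct)
#'
#' Subtracts, per timepoint pool, the arithmetic mean of the reference
#' assays' Ct values from every target assay's Ct. On the linear 2^-Ct
#' scale this equals normalization to the geometric mean of the reference
#' RNAs. Reference rows must be present and uncensored in every column.
#'
#' @param ct Ct table: columns \code{assay_id}, \code{strand}, then one
#'   raw-Ct column per timepoint pool; censored/undetermined reactions
#'   encoded as Ct 40.
#' @param refs reference assay identifiers (default RNU44, RNU48, U6).
#' @return list with \code{dct} (delta-Ct table of the target assays; same
#'   layout, reference rows removed), \code{normalizer} (per-timepoint
#'   mean reference Ct) and \code{censored} (logical matrix flagging
#'   censored raw target Cts).
#' @export
normalizeCt <- function(ct, refs = .REFERENCE_ASSAYS) {
    tp <- .checkCtTable(ct)
    miss <- setdiff(refs, ct$assay_id)
    if (length(miss))
        stop("reference assays missing from the Ct table: ",
             paste(miss, collapse = ", "))
    refrows <- ct[match(refs, ct$assay_id), tp, drop = FALSE]
    refmat <- as.matrix(refrows)
    if (any(is.na(refmat) | refmat >= .CT_CENSOR))
        stop("censored or missing reference Ct in column(s): ",
             paste(tp[apply(is.na(refmat) | refmat >= .CT_CENSOR, 2, any)],
                   collapse = ", "))
    normalizer <- colMeans(refmat)
    targets <- ct[!ct$assay_id %in% refs, , drop = FALSE]
    raw <- as.matrix(targets[, tp, drop = FALSE])
    censored <- raw >= .CT_CENSOR
    dct <- sweep(raw, 2, normalizer, `-`)
    out <- targets
    out[, tp] <- dct
    rownames(out) <- NULL
    rownames(censored) <- targets$assay_id
    list(dct = out, normalizer = normalizer, censored = censored)
}

#' Robust-expression and guide-strand filter
#'
#' Drops assays whose raw Ct exceeds \code{ct_max} at every timepoint (no
#' robust expression anywhere) and passenger-strand assays (only mature,
#' guide-strand miRNAs are analysed). Reference rows are not returned.
#'
#' @param ct raw Ct table.
#' @param ct_max raw-Ct ceiling (default 29 cycles); strict: a Ct equal to
#'   \code{ct_max} at some timepoint retains the assay.
#' @param refs reference assay ids, always excluded from the result.
#' @return character vector of retained assay ids.
#' @export
robustExpressionFilter <- function(ct, ct_max = 29,
                                   refs = .REFERENCE_ASSAYS) {
    tp <- .checkCtTable(ct)
    targets <- ct[!ct$assay_id %in% refs, , drop = FALSE]
    raw <- as.matrix(targets[, tp, drop = FALSE])
    expressed <- apply(raw <= ct_max, 1, any, na.rm = TRUE)
    guide <- targets$strand != "passenger"
    targets$assay_id[expressed & guide]
}

#' Fold changes relative to a reference timepoint (2^-ddCt)
#'
#' ddCt(g, t) = dCt(g, t) - dCt(g, reference timepoint); fold change =
#' 2^-ddCt. Both linear and log2 scales are returned; entries involving a
#' censored raw Ct are flagged so they can be treated as bounds rather
#' than point values.
#'
#' @param norm result of [normalizeCt()] (delta-Ct table plus censoring).
#' @param reference_timepoint column name used as the fold-change
#'   reference.
#' @param assays optional assay ids to keep (e.g. from
#'   [robustExpressionFilter()]).
#' @return list with \code{fold} (linear), \code{log2fc}, \code{censored}
#'   (logical: the entry or its reference Ct was censored) — all matrices
#'   assays x timepoints — and \code{reference_timepoint}.
#' @export
foldChanges <- function(norm, reference_timepoint, assays = NULL) {
    dct <- norm$dct
    tp <- .ctColumns(dct)
    if (!reference_timepoint %in% tp)
        stop("reference timepoint '", reference_timepoint,
             "' not among the Ct columns")
    if (!is.null(assays)) {
        keep <- dct$assay_id %in% assays
        dct <- dct[keep, , drop = FALSE]
    }
    m <- as.matrix(dct[, tp, drop = FALSE])
    rownames(m) <- dct$assay_id
    ddct <- sweep(m, 1, m[, reference_timepoint], `-`)
    cens <- norm$censored[rownames(m), tp, drop = FALSE]
    cens <- cens | cens[, reference_timepoint]
    list(fold = 2^(-ddct), log2fc = -ddct, censored = cens,
         reference_timepoint = reference_timepoint)
}

#' Flag fold changes beyond k standard deviations
#'
#' Pools the log2 fold changes of all assays at all non-reference
#' timepoints, and flags entries farther than \code{k} SD from the pooled
#' mean. The linear-scale option pools 2^-ddCt values instead.
#'
#' @param fc result of [foldChanges()].
#' @param k SD multiplier (default 2).
#' @param scale "log2" (default, symmetric in up/down) or "linear".
#' @return list with \code{flagged} (data.frame assay/timepoint/log2fc for
#'   each flagged entry), \code{assays_any} (assays flagged at any
#'   timepoint), \code{pool_mean}, \code{pool_sd}, \code{n_pooled}.
#' @export
sdOutlierScreen <- function(fc, k = 2, scale = c("log2", "linear")) {
    scale <- match.arg(scale)
    vals <- if (scale == "log2") fc$log2fc else fc$fold
    keep_cols <- setdiff(colnames(vals), fc$reference_timepoint)
    pool <- vals[, keep_cols, drop = FALSE]
    pv <- pool[!is.na(pool)]
    if (length(pv) < 10)
        stop("need at least 10 fold-change values for the SD screen")
    mu <- mean(pv)
    sdv <- stats::sd(pv)
    if (sdv == 0) stop("zero variance in the fold-change pool")
    hits <- which(abs(pool - mu) > k * sdv, arr.ind = TRUE)
    flagged <- data.frame(
        assay_id = rownames(pool)[hits[, 1]],
        timepoint = keep_cols[hits[, 2]],
        log2fc = fc$log2fc[, keep_cols, drop = FALSE][hits],
        censored = fc$censored[, keep_cols, drop = FALSE][hits],
        stringsAsFactors = FALSE)
    flagged <- flagged[order(flagged$assay_id, flagged$timepoint), ,
                       drop = FALSE]
    rownames(flagged) <- NULL
    list(flagged = flagged, assays_any = unique(flagged$assay_id),
         pool_mean = mu, pool_sd = sdv, n_pooled = length(pv))
}

#' Tabulate fold-change bins between developmental epochs
#'
#' For each pair of epochs (fetal vs adult, young vs adult, fetal vs
#' young), the per-assay epoch value is the mean log2 relative quantity
#' across that epoch's pools; the count of assays whose fold increase
#' (or decrease, as the reciprocal) exceeds each bin is tabulated.
#'
#' @param fc result of [foldChanges()] (the log2 relative quantities are
#'   taken from \code{fc$log2fc}).
#' @param epochs named character vector mapping every timepoint column to
#'   an age category (fetal/young/adult).
#' @param bins fold-difference bins (default 2, 5, 10, 100; strict
#'   inequality).
#' @return data.frame with columns \code{comparison}, \code{direction}
#'   ("increase"/"decrease"), one count column per bin.
#' @export
tabulateFoldBins <- function(fc, epochs, bins = c(2, 5, 10, 100)) {
    vals <- fc$log2fc
    stopifnot(all(colnames(vals) %in% names(epochs)))
    epochs <- epochs[colnames(vals)]
    if (!all(AGE_CATEGORIES %in% epochs))
        stop("every epoch (fetal, young, adult) needs at least one pool")
    epochMean <- vapply(AGE_CATEGORIES, function(e)
        rowMeans(vals[, epochs == e, drop = FALSE], na.rm = TRUE),
        numeric(nrow(vals)))
    pairs <- list(c("fetal", "adult"), c("young", "adult"),
                  c("fetal", "young"))
    out <- NULL
    for (pr in pairs) {
        dl2 <- epochMean[, pr[1]] - epochMean[, pr[2]]
        dl2 <- dl2[!is.na(dl2)]
        for (dir in c("increase", "decrease")) {
            eff <- if (dir == "increase") dl2 else -dl2
            counts <- vapply(bins, function(b) sum(2^eff > b), numeric(1))
            row <- data.frame(
                comparison = paste(pr[1], "vs", pr[2]),
                direction = dir, t(counts))
            colnames(row)[-(1:2)] <- paste0("gt_", bins)
            out <- rbind(out, row)
        }
    }
    rownames(out) <- NULL
    out
}

#' Q-Q data of the pooled log2 fold changes
#'
#' Sorted log2 fold changes paired with standard-normal quantiles at Blom
#' plotting positions, for assessing the shape of the fold-change
#' distribution.
#'
#' @param fc result of [foldChanges()].
#' @param include_reference keep the reference-timepoint column (all
#'   zeros) in the pool; default FALSE.
#' @return data.frame with \code{theoretical} and \code{empirical}
#'   quantile columns.
#' @export
qqData <- function(fc, include_reference = FALSE) {
    vals <- fc$log2fc
    if (!include_reference)
        vals <- vals[, setdiff(colnames(vals), fc$reference_timepoint),
                     drop = FALSE]
    v <- sort(vals[!is.na(vals)])
    n <- length(v)
    if (n < 10) stop("need at least 10 fold-change values")
    data.frame(theoretical = stats::qnorm((seq_len(n) - 0.375) /
                                          (n + 0.25)),
               empirical = v)
}
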