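## Synthetic-data generators: array-scan tables, sample metadata and TaqMan
## Ct tables with known ground truth, so every downstream stage is testable
## without external downloads.

#' Build a synthetic-data configuration
#'
#' The defaults describe the emulated study design: an unbalanced
#' 36/9/2 fetal/young/adult sample set hybridised against a common
#' reference pool, about a third of array features being vendor-predicted
#' novel sequences (which run bright, approaching saturation in the
#' full-power scan), 90\% of features flat across the age categories and
#' 10\% spread evenly over the twelve directional mean-pattern classes with
#' an adjacent-mean separation of six noise standard deviations.
#'
#' @param n_features number of features.
#' @param frac_novel fraction annotated "novel".
#' @param n_fetal,n_young,n_adult samples per age category (all >= 1).
#' @param class_mix named fractions over the 13 pattern labels (sum 1). If
#'   NULL, \code{1 - frac_nonnull} goes to "F=Y=A" and the rest is split
#'   evenly over the 12 directional classes.
#' @param frac_nonnull convenience used only when \code{class_mix} is NULL.
#' @param effect_size log2 separation between adjacent unequal means.
#' @param noise_sd per-sample Gaussian noise SD (log2).
#' @param sat_threshold scanner ceiling (16-bit default 65535).
#' @param gain intensity gain of the 100\% scan over the 10\% scan.
#' @param dye_bias amplitude of the smooth intensity-dependent dye bias.
#' @param qc_fail_pixels,qc_fail_r2,qc_fail_flag per-filter failure
#'   fractions.
#' @param frac_low_expressed,frac_passenger,ct_noise_sd TaqMan generator
#'   knobs: fraction of assays near the detection limit, fraction of
#'   passenger-strand assays, Ct noise SD (cycles).
#' @param seed integer seed.
#' @return a validated \linkS4class{SynthConfig}.
#'
#' @examples
#' synthConfig(n_features = 200, seed = 7)
#' @export
synthConfig <- function(n_features = 1000L, frac_novel = 0.35,
                        n_fetal = 36L, n_young = 9L, n_adult = 2L,
                        class_mix = NULL, frac_nonnull = 0.10,
                        effect_size = 1.5, noise_sd = 0.25,
                        sat_threshold = 65535, gain = 10,
                        dye_bias = 0.3,
                        qc_fail_pixels = 0.05, qc_fail_r2 = 0.03,
                        qc_fail_flag = 0.02,
                        frac_low_expressed = 0.15, frac_passenger = 0.15,
                        ct_noise_sd = 0.15, seed = 1L) {
    labs <- modelClassLabels()
    if (is.null(class_mix)) {
        class_mix <- stats::setNames(rep(frac_nonnull / 12, 13), labs)
        class_mix["F=Y=A"] <- 1 - frac_nonnull
    }
    if (is.null(names(class_mix)))
        stop("class_mix must be a named vector over the pattern labels")
    full <- stats::setNames(rep(0, 13), labs)
    unknown <- setdiff(names(class_mix), labs)
    if (length(unknown))
        stop("unknown pattern labels in class_mix: ",
             paste(unknown, collapse = ", "))
    full[names(class_mix)] <- class_mix
    new("SynthConfig", n_features = as.integer(n_features),
        frac_novel = frac_novel, n_fetal = as.integer(n_fetal),
        n_young = as.integer(n_young), n_adult = as.integer(n_adult),
        class_mix = full, effect_size = effect_size, noise_sd = noise_sd,
        sat_threshold = sat_threshold, gain = gain, dye_bias = dye_bias,
        qc_fail_pixels = qc_fail_pixels, qc_fail_r2 = qc_fail_r2,
        qc_fail_flag = qc_fail_flag,
        frac_low_expressed = frac_low_expressed,
        frac_passenger = frac_passenger, ct_noise_sd = ct_noise_sd,
        seed = as.integer(seed))
}

#' Generate a synthetic sample table
#'
#' One row per sample: identifier, age category, gestational weeks (fetal
#' only, integer weeks 14--24), postnatal days (young only), and a pool id
#' shared by samples of the same developmental age (the pooling scheme used
#' for the TaqMan arrays).
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return data.frame with columns \code{sample_id}, \code{age_category},
#'   \code{gestational_weeks}, \code{postnatal_days}, \code{pool}.
#' @export
generateSampleTable <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    set.seed(config@seed)
    nf <- config@n_fetal; ny <- config@n_young; na_ <- config@n_adult
    weeks <- sort(sample(14:24, nf, replace = TRUE))
    days <- sort(sample(5:300, ny, replace = TRUE))
    n <- nf + ny + na_
    tab <- data.frame(
        sample_id = sprintf("sample_%03d", seq_len(n)),
        age_category = rep(AGE_CATEGORIES, c(nf, ny, na_)),
        gestational_weeks = c(weeks, rep(NA_integer_, ny + na_)),
        postnatal_days = c(rep(NA_integer_, nf), days,
                           rep(NA_integer_, na_)),
        stringsAsFactors = FALSE
    )
    ## pool by unique developmental age: fetal weeks ascending, then young
    ## postnatal year buckets, then one adult pool
    fp <- match(weeks, sort(unique(weeks)))
    ybucket <- findInterval(days, c(0, 365, 3 * 365))
    yp <- max(fp) + match(ybucket, sort(unique(ybucket)))
    tab$pool <- c(fp, yp, rep(max(yp) + 1L, na_))
    tab
}

## pattern -> centred true category means (log2), adjacent unequal means
## separated by effect_size
.patternMeans <- function(labels, effect_size) {
    tab <- .MODEL_CLASS_TABLE
    i <- match(labels, tab$label)
    ranks <- cbind(tab$rank_F[i], tab$rank_Y[i], tab$rank_A[i])
    mu <- (ranks - rowMeans(ranks)) * effect_size
    colnames(mu) <- AGE_CATEGORIES
    mu
}

## feature identifiers, annotation and planted patterns
.featureTruth <- function(config) {
    n <- config@n_features
    n_novel <- round(config@frac_novel * n)
    src <- rep(c("known", "novel"), c(n - n_novel, n_novel))
    src <- sample(src)
    ids <- character(n)
    ids[src == "known"] <- sprintf("hsa-miR-sim-%04d",
                                   seq_len(sum(src == "known")))
    ids[src == "novel"] <- sprintf("IVGN-novel-sim_%04d",
                                   seq_len(sum(src == "novel")))
    pattern <- sample(modelClassLabels(), n, replace = TRUE,
                      prob = config@class_mix)
    mu <- .patternMeans(pattern, config@effect_size)
    large <- src == "novel" & stats::runif(n) < 0.10
    data.frame(feature_id = ids, annotation_source = src,
               pattern = pattern, mean_F = mu[, 1], mean_Y = mu[, 2],
               mean_A = mu[, 3], large_ncrna = large,
               stringsAsFactors = FALSE)
}

#' Generate a log-ratio matrix directly (fast path)
#'
#' Skips the array-scan emulation and produces the normalized log-ratio
#' matrix a perfect upstream pipeline would deliver: per-gene Gaussian
#' noise around the planted age-category means. This is the workhorse for
#' calibration studies and power checks.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return list with \code{matrix} (a \linkS4class{LogRatioMatrix}),
#'   \code{samples} (the sample table) and \code{truth} (per-feature
#'   pattern, true means and annotation).
#' @export
generateLogRatioMatrix <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    samples <- generateSampleTable(config)
    truth <- .featureTruth(config)
    cat <- factor(samples$age_category, levels = AGE_CATEGORIES)
    mu <- as.matrix(truth[, c("mean_F", "mean_Y", "mean_A")])
    m <- mu[, as.integer(cat), drop = FALSE] +
        matrix(stats::rnorm(nrow(truth) * nrow(samples),
                            sd = config@noise_sd),
               nrow(truth), nrow(samples))
    dimnames(m) <- list(truth$feature_id, samples$sample_id)
    lrm <- LogRatioMatrix(m, samples,
        row_annotation = data.frame(
            annotation_source = truth$annotation_source,
            large_ncrna = truth$large_ncrna))
    list(matrix = lrm, samples = samples, truth = truth)
}

## QC columns for one scan of one array. Per-feature fail indicators are
## shared between channels (a dim or smeared feature is dim in both).
.qcColumns <- function(n, config, frac_sat) {
    fail_px <- stats::runif(n) < config@qc_fail_pixels
    fail_r2 <- stats::runif(n) < config@qc_fail_r2
    flag <- as.integer(stats::runif(n) < config@qc_fail_flag)
    px <- ifelse(fail_px, stats::runif(n, 0, 0.69),
                 stats::runif(n, 0.75, 1))
    r2 <- ifelse(fail_r2, stats::runif(n, 0.05, 0.5),
                 stats::runif(n, 0.55, 0.99))
    list(px = px, r2 = r2, flag = flag, frac_sat = frac_sat)
}

.scanTable <- function(truth, signal_cy3, signal_cy5, bg, bg_sd, qc,
                       frac_sat_cy3, frac_sat_cy5, power) {
    n <- nrow(truth)
    mk <- function(channel, signal, fs) data.frame(
        feature_id = truth$feature_id,
        annotation_source = truth$annotation_source,
        channel = channel, scan_power = power,
        median_fg = round(bg + signal, 1), median_bg = round(bg, 1),
        bg_sd = round(bg_sd, 2),
        frac_pixels_gt_bg2sd = round(qc$px, 4),
        r_squared = round(qc$r2, 4),
        frac_saturated = round(fs, 4),
        flag = qc$flag, stringsAsFactors = FALSE)
    out <- rbind(mk("Cy3", signal_cy3, frac_sat_cy3),
                 mk("Cy5", signal_cy5, frac_sat_cy5))
    rownames(out) <- NULL
    out
}

#' Generate a full synthetic dual-scan array dataset
#'
#' Emulates the acquisition design: per array (one per sample), a
#' 10\%-laser-power scan and a 100\%-power rescan of the same features in
#' both channels (Cy3 = sample, Cy5 = common reference pool). The
#' 100\%-scan intensities are a linear gain times the 10\%-scan intensities
#' with multiplicative noise, clipped at the scanner ceiling; features
#' clipped in the 100\% scan carry a high saturated-pixel fraction. Novel
#' features are drawn bright so that many approach saturation at full
#' power. True log-ratios follow each feature's planted mean pattern plus
#' Gaussian noise, with a smooth intensity-dependent dye bias that LOWESS
#' normalization removes downstream.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return list with \code{scans} (per array, a list with \code{low} and
#'   \code{high} scan tables), \code{samples}, \code{truth},
#'   \code{logratio_true} (genes x samples matrix of noiseless planted
#'   log-ratios per sample's category) and \code{true_intensities} (per
#'   array, the noise-free channel intensities on the 10\%-power scale).
#' @export
generateArrayDataset <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    samples <- generateSampleTable(config)
    set.seed(config@seed + 1L)
    truth <- .featureTruth(config)
    n <- nrow(truth)
    cat <- factor(samples$age_category, levels = AGE_CATEGORIES)
    mu <- as.matrix(truth[, c("mean_F", "mean_Y", "mean_A")])
    ## reference-pool intensity per feature at 10% power (fixed across
    ## arrays); novel features are bright and saturate at 100% power
    log2ref <- ifelse(truth$annotation_source == "novel",
                      stats::runif(n, 11.2, 12.7),
                      stats::runif(n, 8, 11.5))
    ref10 <- 2^log2ref
    arange <- range(log2ref)
    bias <- config@dye_bias *
        (log2ref - mean(arange)) / (diff(arange) / 2)
    scans <- vector("list", nrow(samples))
    true_intensities <- vector("list", nrow(samples))
    names(scans) <- names(true_intensities) <- samples$sample_id
    logratio_true <- mu[, as.integer(cat), drop = FALSE]
    dimnames(logratio_true) <- list(truth$feature_id, samples$sample_id)
    read_sd <- 30      # additive read noise per scan, intensity units:
                       # constant in absolute terms, so the 100% scan has
                       # gain-fold better relative precision until it clips
    for (j in seq_len(nrow(samples))) {
        lr <- logratio_true[, j] +
            stats::rnorm(n, sd = config@noise_sd) + bias
        cy3 <- ref10 * 2^lr          # true 10%-scale intensities
        cy5 <- ref10
        bg <- pmax(stats::rnorm(n, 100, 10), 50)
        bg_sd <- stats::runif(n, 8, 15)
        cy3_10 <- pmax(cy3 + stats::rnorm(n, 0, read_sd), 0)
        cy5_10 <- pmax(cy5 + stats::rnorm(n, 0, read_sd), 0)
        mnoise <- exp(stats::rnorm(n, 0, 0.03))
        raw3 <- config@gain * cy3 * mnoise + stats::rnorm(n, 0, read_sd)
        raw5 <- config@gain * cy5 * mnoise + stats::rnorm(n, 0, read_sd)
        sat <- config@sat_threshold
        clip3 <- (raw3 + bg) >= sat
        clip5 <- (raw5 + bg) >= sat
        cy3_100 <- pmax(pmin(raw3, sat - bg), 0)
        cy5_100 <- pmax(pmin(raw5, sat - bg), 0)
        qc <- .qcColumns(n, config, NULL)
        fs_low <- stats::runif(n, 0, 0.02)
        fsat <- function(clip) ifelse(clip, stats::runif(n, 0.3, 1),
                                      stats::runif(n, 0, 0.02))
        low <- .scanTable(truth, cy3_10, cy5_10, bg, bg_sd, qc,
                          fs_low, fs_low, 10)
        high <- .scanTable(truth, cy3_100, cy5_100, bg, bg_sd, qc,
                           fsat(clip3), fsat(clip5), 100)
        scans[[j]] <- list(low = low, high = high)
        true_intensities[[j]] <- data.frame(
            feature_id = truth$feature_id, cy3 = cy3, cy5 = cy5,
            stringsAsFactors = FALSE)
    }
    list(scans = scans, samples = samples, truth = truth,
         logratio_true = logratio_true,
         true_intensities = true_intensities)
}

#' Generate a synthetic pooled TaqMan Ct dataset
#'
#' One Ct column per timepoint pool, rows are miRNA assays plus the three
#' reference small RNAs (RNU44, RNU48, U6), which are near-constant across
#' pools. Target Ct = per-assay baseline minus the true log2 relative
#' abundance at the pool's epoch, plus Gaussian cycle noise; values beyond
#' 40 cycles are censored at 40 (undetermined). A configurable fraction of
#' assays sits near the detection limit (raw Ct > 29 in every pool) and a
#' fraction is annotated as passenger-strand sequences.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param timepoints ordered pool labels (prenatal weeks then postnatal
#'   ages); at least 2.
#' @param epochs age category per timepoint (same length); defaults to the
#'   study layout (weeks are fetal, day/year pools young, last pool adult)
#'   when \code{timepoints} is left at its default.
#' @param spike optional list \code{list(assay=, timepoint=, log2=)}
#'   planting a single-timepoint expression spike (for screen power
#'   checks).
#' @return list with \code{ct} (data.frame: \code{assay_id}, \code{strand},
#'   one column per pool) and \code{truth} (per-assay baseline Ct and true
#'   log2 relative abundance per timepoint).
#' @export
generateTaqmanDataset <- function(config,
        timepoints = c("14wk", "16wk", "17wk", "18wk", "19wk", "20wk",
                       "98d", "1.5yr", "4.5yr", "adult"),
        epochs = NULL, spike = NULL) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    if (length(timepoints) < 2)
        stop("need at least 2 timepoints")
    if (is.null(epochs)) {
        epochs <- ifelse(grepl("wk$", timepoints), "fetal",
                         ifelse(timepoints == "adult", "adult", "young"))
    }
    stopifnot(length(epochs) == length(timepoints),
              all(epochs %in% AGE_CATEGORIES))
    set.seed(config@seed + 2L)
    n <- config@n_features
    truth <- .featureTruth(config)
    ids <- sub("^hsa-miR-sim", "hsa-miR-tq", truth$feature_id)
    strand <- ifelse(stats::runif(n) < config@frac_passenger,
                     "passenger", "guide")
    low <- stats::runif(n) < config@frac_low_expressed
    base <- ifelse(low, stats::runif(n, 31, 36), stats::runif(n, 18, 28))
    mu <- as.matrix(truth[, c("mean_F", "mean_Y", "mean_A")])
    colnames(mu) <- AGE_CATEGORIES
    rel <- mu[, epochs, drop = FALSE]     # true log2 relative abundance
    colnames(rel) <- timepoints
    if (!is.null(spike)) {
        i <- match(spike$assay, ids)
        j <- match(spike$timepoint, timepoints)
        if (is.na(i) || is.na(j)) stop("spike assay/timepoint not found")
        rel[i, j] <- rel[i, j] + spike$log2
    }
    noise <- if (config@ct_noise_sd > 0)
        matrix(stats::rnorm(n * length(timepoints), sd = config@ct_noise_sd),
               n, length(timepoints)) else 0
    ct <- base - rel + noise
    ct <- pmin(ct, 40)                     # censored / undetermined
    ct <- round(ct, 3)
    refs <- data.frame(assay_id = c("RNU44", "RNU48", "U6"),
                       strand = "reference", stringsAsFactors = FALSE)
    refbase <- c(19, 20, 16)
    refct <- matrix(rep(refbase, length(timepoints)), 3,
                    length(timepoints)) +
        if (config@ct_noise_sd > 0)
            matrix(stats::rnorm(3 * length(timepoints),
                                sd = config@ct_noise_sd / 2),
                   3, length(timepoints)) else 0
    refct <- round(refct, 3)
    cttab <- data.frame(assay_id = c(ids, refs$assay_id),
                        strand = c(strand, refs$strand),
                        stringsAsFactors = FALSE)
    vals <- rbind(ct, refct)
    colnames(vals) <- timepoints
    cttab <- cbind(cttab, as.data.frame(vals))
    rownames(cttab) <- NULL
    truth_out <- data.frame(assay_id = ids, strand = strand,
                            base_ct = base, pattern = truth$pattern,
                            annotation_source = truth$annotation_source,
                            stringsAsFactors = FALSE)
    truth_out <- cbind(truth_out,
                       as.data.frame(`colnames<-`(rel,
                           paste0("log2rel_", timepoints))))
    list(ct = cttab, truth = truth_out, epochs =
             stats::setNames(epochs, timepoints))
}
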