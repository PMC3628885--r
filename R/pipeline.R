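## End-to-end pipeline driver: simulate -> merge -> normalize -> classify
## -> calibrate -> enrich -> cluster -> taqman, with a machine-readable run
## manifest.

## deterministic per-stage child seeds from the single run seed, kept
## within 32-bit integer range
.childSeed <- function(seed, stage)
    as.integer((as.numeric(seed) * 1009L + stage * 9973L) %% 2147483647)

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic dual-scan array dataset and a pooled TaqMan
#' dataset, merges the scans, filters and LOWESS-normalizes them into a
#' log-ratio matrix, calibrates the significance threshold at
#' \code{target_fdr} by label-permutation simulation, classifies every
#' gene into a mean-pattern class, tests novel-feature enrichment in a
#' target class, clusters the significant genes, and runs the 2^-ddCt
#' TaqMan screen. All stage outputs are written as TSV/JSON/Newick files
#' under \code{out_dir}, along with \code{manifest.json} recording seeds,
#' parameters and per-stage counts.
#'
#' @param config a \linkS4class{SynthConfig} (its seed drives every
#'   stage through deterministic child seeds).
#' @param out_dir output directory (created if needed).
#' @param target_fdr nominal FDR for the calibration stage.
#' @param n_sims null simulations for calibration.
#' @param n_perm permutations for the enrichment stage.
#' @param enrich_class pattern label tested for novel-feature enrichment.
#' @param reference_timepoint TaqMan fold-change reference pool.
#' @param verbose print one INFO line per stage.
#' @return the manifest, invisibly (a list).
#' @export
runPipeline <- function(config = synthConfig(), out_dir,
                        target_fdr = 0.01, n_sims = 200L, n_perm = 199L,
                        enrich_class = "F<Y=A",
                        reference_timepoint = "14wk", verbose = TRUE) {
    stopifnot(is(config, "SynthConfig"))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    info <- function(...) if (verbose) message("INFO ", ...)
    manifest <- list(package = "chronoclass",
                     version = as.character(
                         utils::packageVersion("chronoclass")),
                     seed = config@seed,
                     parameters = list(target_fdr = target_fdr,
                                       n_sims = n_sims, n_perm = n_perm,
                                       enrich_class = enrich_class),
                     started = format(Sys.time(), usetz = TRUE),
                     stages = list())
    stage <- function(name, counts) {
        manifest$stages[[name]] <<- counts
        info(name, ": ", paste(names(counts), unlist(counts),
                               sep = "=", collapse = ", "))
    }
    fail <- function(name, e) {
        manifest$stages[[name]] <<- list(error = conditionMessage(e))
        .writeManifest(manifest, out_dir)
        stop("pipeline stage '", name, "' failed: ",
             conditionMessage(e), call. = FALSE)
    }

    ## 1 simulate ---------------------------------------------------------
    arr <- tryCatch(generateArrayDataset(config),
                    error = function(e) fail("simulate", e))
    tq <- generateTaqmanDataset(config)
    writeSampleTable(arr$samples, file.path(out_dir, "samples.tsv"))
    .writeTsv(arr$truth, file.path(out_dir, "truth_features.tsv"))
    writeCtTable(tq$ct, file.path(out_dir, "taqman_ct.tsv"))
    scan_dir <- file.path(out_dir, "scans")
    dir.create(scan_dir, showWarnings = FALSE)
    for (sid in names(arr$scans)) {
        writeScanTable(arr$scans[[sid]]$low,
                       file.path(scan_dir, paste0(sid, "_low.tsv")))
        writeScanTable(arr$scans[[sid]]$high,
                       file.path(scan_dir, paste0(sid, "_high.tsv")))
    }
    stage("simulate", list(n_features = config@n_features,
                           n_arrays = nrow(arr$samples),
                           n_taqman_assays = nrow(tq$ct)))

    ## 2 merge ------------------------------------------------------------
    merged <- tryCatch(lapply(arr$scans, function(sc) {
        calib <- lapply(c("Cy3", "Cy5"), function(channel)
            fitScanCalibration(sc$low, sc$high, channel = channel))
        mergeScans(sc$low, sc$high, calib)
    }), error = function(e) fail("merge", e))
    n_sub <- sum(vapply(merged, function(m)
        sum(m$source_scan == "low_calibrated"), numeric(1)))
    stage("merge", list(n_arrays = length(merged),
                        n_substituted_feature_channels = n_sub))

    ## 3 normalize --------------------------------------------------------
    asm <- tryCatch(assembleMatrix(merged, arr$samples,
        row_annotation = data.frame(feature_id = arr$truth$feature_id,
                                    large_ncrna = arr$truth$large_ncrna)),
        error = function(e) fail("normalize", e))
    lrm <- asm$matrix
    writeLogRatioMatrix(lrm, file.path(out_dir, "matrix.tsv"),
                        annotation_path =
                            file.path(out_dir, "annotation.tsv"))
    jsonlite::write_json(asm$qc_report,
                         file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stage("normalize",
          list(n_retained = nrow(lrm),
               exclusions = as.list(asm$qc_report$exclusions_total)))

    ## 4 calibrate --------------------------------------------------------
    cal <- tryCatch(calibrateCategoryAnalysis(lrm,
        target_fdr = target_fdr, n_sims = n_sims,
        seed = .childSeed(config@seed, 4L)),
        error = function(e) fail("calibrate", e))
    calib <- cal$calibration
    jsonlite::write_json(list(threshold = calib@threshold,
                              target_fdr = calib@target_fdr,
                              estimated_fdr = calib@estimated_fdr,
                              n_discoveries = calib@n_discoveries,
                              n_simulations = calib@n_simulations),
                         file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage("calibrate", list(threshold = calib@threshold,
                            n_discoveries = calib@n_discoveries))

    ## 5 classify ---------------------------------------------------------
    fits <- tryCatch(classifyGenes(lrm, alpha = calib@threshold),
                     error = function(e) fail("classify", e))
    .writeTsv(fits, file.path(out_dir, "fits.tsv"))
    occ <- table(factor(fits$pattern, levels = modelClassLabels()))
    stage("classify", list(n_significant =
                               sum(fits$partition != "FYA", na.rm = TRUE),
                           class_occupancy = as.list(occ)))

    ## 6 enrich -----------------------------------------------------------
    enr <- tryCatch(annotationEnrichment(lrm,
        target_class = enrich_class, alpha = calib@threshold,
        n_perm = n_perm, seed = .childSeed(config@seed, 6L)),
        error = function(e) fail("enrich", e))
    jsonlite::write_json(enr[c("p_value", "observed",
                               "observed_class_size", "target_class",
                               "n_perm")],
                         file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage("enrich", list(class = enrich_class, p_value = enr$p_value))

    ## 7 cluster ----------------------------------------------------------
    sig <- fits$gene[fits$partition != "FYA" & !is.na(fits$partition)]
    cl_counts <- list(n_clustered = 0L)
    if (length(sig) >= 2) {
        sub <- logRatios(lrm)[sig, , drop = FALSE]
        keep <- apply(sub, 1, function(v) stats::var(v, na.rm = TRUE) > 0)
        sub <- sub[keep, , drop = FALSE]
        cl <- tryCatch(hierarchicalCluster(correlationDistance(sub)),
                       error = function(e) fail("cluster", e))
        dendrogramNewick(cl, file.path(out_dir, "dendrogram.newick"))
        .writeTsv(data.frame(order = seq_along(cl$leaf_order),
                             gene = cl$labels[cl$leaf_order]),
                  file.path(out_dir, "leaf_order.tsv"))
        cl_counts$n_clustered <- nrow(sub)
    }
    stage("cluster", cl_counts)

    ## 8 taqman -----------------------------------------------------------
    tqres <- tryCatch({
        norm <- normalizeCt(tq$ct)
        kept <- robustExpressionFilter(tq$ct)
        fc <- foldChanges(norm, reference_timepoint, assays = kept)
        screen <- sdOutlierScreen(fc)
        bins <- tabulateFoldBins(fc, tq$epochs)
        list(fc = fc, screen = screen, bins = bins)
    }, error = function(e) fail("taqman", e))
    fc_tab <- data.frame(assay_id = rownames(tqres$fc$log2fc),
                         tqres$fc$log2fc, check.names = FALSE)
    .writeTsv(fc_tab, file.path(out_dir, "taqman_log2fc.tsv"))
    .writeTsv(tqres$screen$flagged,
              file.path(out_dir, "taqman_sd_flags.tsv"))
    .writeTsv(tqres$bins, file.path(out_dir, "taqman_fold_bins.tsv"))
    .writeTsv(qqData(tqres$fc), file.path(out_dir, "taqman_qq.tsv"))
    stage("taqman", list(n_retained = nrow(tqres$fc$log2fc),
                         n_sd_flagged =
                             length(tqres$screen$assays_any)))

    manifest$finished <- format(Sys.time(), usetz = TRUE)
    .writeManifest(manifest, out_dir)
    invisible(manifest)
}

.writeManifest <- function(manifest, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
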