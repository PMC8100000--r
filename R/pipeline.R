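# End-to-end driver: synthetic cohort -> preprocessing -> seed selection ->
# connectivity maps -> group maps/ROIs -> ROI statistics; in parallel, the
# volumetric table -> composites -> ICV correction -> group statistics.

#' Run the end-to-end synthetic pipeline
#'
#' Generates a two-group BOLD phantom cohort with group-specific planted
#' hippocampus-PCC coupling, applies the full preprocessing chain, selects
#' left and right hippocampal seeds, builds normalized connectivity z maps,
#' thresholds and clusters the four group maps, forms the union ROI mask,
#' extracts per-subject ROI mean z and compares groups with FDR
#' adjustment. Alongside, simulates a volumetric cohort and runs the
#' composite/ICV-corrected group statistics and asymmetry indices.
#' Deterministic given `config@seed`.
#'
#' The seed search runs on confound-regressed, detrended (but unsmoothed,
#' unfiltered) series; connectivity maps use the fully preprocessed data.
#'
#' @param config a [PipelineConfig-class].
#' @param phantomTemplate a [PhantomSpec-class] supplying grid/acquisition
#'   parameters (its `rTarget` and `seed` are overridden per subject).
#' @param cohort a [CohortSpec-class] for the volumetric arm.
#' @param nPerGroup named subject counts for the connectivity arm.
#' @param rTargets named per-group planted coupling (the paper reports no
#'   connectivity effect sizes; group differences are user-set).
#' @param motionOutlierFrac fraction of subjects planted as motion outliers
#'   before exclusion.
#' @param outDir optional directory; when given, tables (TSV), group masks
#'   and ROI labels (NIfTI), seed ROIs and the provenance log (JSON) are
#'   written there.
#' @return list: `seedRois`, `zMaps` (per subject per hemisphere),
#'   `seedRecovered`, `groupMasks`, `roiMask`, `roiZ` (long table),
#'   `connStats`, `motion`, `volumes`, `volumesCorrected`, `volumeStats`,
#'   `aiTable`, `aiStats`, `log`.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        phantomTemplate = phantomSpec(),
                        cohort = cohortSpec(),
                        nPerGroup = c(DS = 6L, HC = 6L),
                        rTargets = c(DS = 0.35, HC = 0.7),
                        motionOutlierFrac = 0,
                        outDir = NULL) {
    validObject(config)
    withr::local_seed(config@seed)
    groups <- rep(names(nPerGroup), nPerGroup)
    nTotal <- length(groups)
    subjSeeds <- sample.int(.Machine$integer.max - 1L, nTotal + 2L)

    ## motion screening
    motion <- simulateMotion(nTotal, outlierFrac = motionOutlierFrac,
                             seed = subjSeeds[nTotal + 1L])
    motion$group <- groups
    excl <- excludeByMotion(motion, config@kSd)
    keptIdx <- match(excl$kept$subject, motion$subject)

    anatomy <- makePhantomAnatomy(phantomTemplate)
    conj <- conjunctionMask(anatomy$dmnNetwork, anatomy$pccGm)
    nt <- phantomTemplate@nVolumes - config@kDrop

    seedRois <- list(); zMaps <- list(); recovered <- list()
    subjTab <- list()
    for (i in keptIdx) {
        spec <- phantomTemplate
        spec@rTarget <- unname(rTargets[[groups[i]]])
        spec@seed <- subjSeeds[i]
        sim <- simulateBold(anatomy, spec)
        dropped <- dropInitialVolumes(sim$bold, config@kDrop)
        keep <- (config@kDrop + 1):phantomTemplate@nVolumes
        ph <- physioTrace(sim$physio@cardiac[keep],
                          sim$physio@respiratory[keep])
        reg <- buildPhysioRegressors(ph, config@physioOrder)
        clean <- regressConfounds(dropped, reg)
        search <- temporalDetrend(clean, config@detrendOrder)
        full <- lowpassFilter(
            temporalDetrend(spatialSmooth(clean, config@fwhmMm),
                            config@detrendOrder), config@cutoffHz)
        sid <- motion$subject[i]
        for (h in c("L", "R")) {
            hip <- if (h == "L") anatomy$hipHeadL else anatomy$hipHeadR
            planted <- if (h == "L") sim$truth$plantedL else sim$truth$plantedR
            cc <- crossCorrelateRegions(search, hip, conj)
            sel <- selectSeedVoxel(cc, config@aggregate)
            voxel <- attr(sel, "voxel")
            roi <- suppressWarnings(makeInplaneROI(voxel, hip, h))
            seed <- seedTimeseries(full, roi)
            rmap <- voxelwiseConnectivity(full, seed, anatomy$brain)
            zmap <- normalizeMap(suppressWarnings(rToT(rmap, nt)))
            key <- paste0(sid, "_", h)
            seedRois[[key]] <- roi
            zMaps[[key]] <- zmap
            recovered[[key]] <- identical(voxel, planted)
            subjTab[[key]] <- data.frame(subject = sid, group = groups[i],
                                         hemisphere = h)
        }
    }
    subjTab <- do.call(rbind, subjTab)

    ## group maps -> union ROI mask -> ROI mean z
    groupMasks <- list()
    for (g in names(nPerGroup)) for (h in c("L", "R")) {
        sel <- subjTab$group == g & subjTab$hemisphere == h
        maps <- zMaps[rownames(subjTab)[sel]]
        thr <- thresholdMap(maps, config@pThresh)
        groupMasks[[paste0(g, "_", h)]] <-
            clusterFilter(thr, config@minCluster, config@connectivity)
    }
    roiMask <- unionConjunction(groupMasks, config@connectivity)
    roiZ <- do.call(rbind, lapply(rownames(subjTab), function(k) {
        cbind(subjTab[k, , drop = FALSE],
              suppressWarnings(roiMeanZ(zMaps[[k]], roiMask)),
              row.names = NULL)
    }))

    ## connectivity group statistics, FDR per hemisphere family
    connStats <- do.call(rbind, lapply(c("L", "R"), function(h) {
        sub <- roiZ[roiZ$hemisphere == h, ]
        res <- do.call(rbind, lapply(unique(sub$label), function(l) {
            s <- sub[sub$label == l, ]
            r <- unpairedT(s$meanZ[s$group == names(nPerGroup)[1]],
                           s$meanZ[s$group == names(nPerGroup)[2]])
            data.frame(hemisphere = h, label = l, t = r$statistic,
                       df = r$df, p = r$p)
        }))
        fdr <- bhFdr(res$p, config@q)
        res$pAdjusted <- fdr$adjusted
        res$rejected <- fdr$rejected
        res
    }))

    ## volumetric arm
    cohort@seed <- subjSeeds[nTotal + 2L]
    volumes <- deriveComposites(simulateCohortVolumes(cohort))
    corrected <- icvCorrectTable(volumes)
    measureCols <- c("erc_l", "sub_l", "ca1_l", "cat_l", "dg_l", "tail_l",
                     "hip_l", "erc_r", "sub_r", "ca1_r", "cat_r", "dg_r",
                     "tail_r", "hip_r")
    volumeStats <- groupCompareTable(corrected, measureCols, config@q)
    base <- c("erc", "sub", "ca1", "cat", "dg", "tail", "hip")
    aiTable <- data.frame(id = volumes$id, group = volumes$group)
    for (b in base)
        aiTable[[b]] <- asymmetryIndex(volumes[[paste0(b, "_l")]],
                                       volumes[[paste0(b, "_r")]])
    aiStats <- groupCompareTable(aiTable, base, config@q)

    log <- list(config = stats::setNames(
                    lapply(configSlots, function(s) slot(config, s)),
                    configSlots),
                nPerGroup = as.list(nPerGroup),
                rTargets = as.list(rTargets),
                nExcludedByMotion = nrow(excl$excluded),
                seedRecoveryRate = mean(unlist(recovered)))

    out <- list(seedRois = seedRois, zMaps = zMaps,
                seedRecovered = unlist(recovered),
                groupMasks = groupMasks, roiMask = roiMask, roiZ = roiZ,
                connStats = connStats, motion = motion,
                volumes = volumes, volumesCorrected = corrected,
                volumeStats = volumeStats, aiTable = aiTable,
                aiStats = aiStats, log = log)
    if (!is.null(outDir))
        writePipelineOutputs(out, outDir, phantomTemplate@voxelSize)
    out
}

writePipelineOutputs <- function(bundle, outDir, voxelSize) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTsv(bundle$roiZ, file.path(outDir, "roi_mean_z.tsv"))
    writeTsv(bundle$connStats, file.path(outDir, "connectivity_stats.tsv"))
    writeTsv(bundle$motion, file.path(outDir, "motion.tsv"))
    writeTsv(bundle$volumes, file.path(outDir, "volumes.tsv"))
    writeTsv(bundle$volumesCorrected,
             file.path(outDir, "volumes_pct_icv.tsv"))
    writeTsv(bundle$volumeStats, file.path(outDir, "volume_stats.tsv"))
    writeTsv(bundle$aiStats, file.path(outDir, "ai_stats.tsv"))
    for (nm in names(bundle$groupMasks))
        writeMask(bundle$groupMasks[[nm]],
                  file.path(outDir, sprintf("groupmask_%s.nii.gz", nm)),
                  voxelSize)
    writeMask(bundle$roiMask@labels, file.path(outDir, "roi_labels.nii.gz"),
              voxelSize)
    rois <- lapply(bundle$seedRois, function(r)
        list(center = r@center, hemisphere = r@hemisphere,
             members = apply(r@members, 1, paste, collapse = ",")))
    jsonlite::write_json(rois, file.path(outDir, "seed_rois.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(bundle$log, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outDir)
}
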