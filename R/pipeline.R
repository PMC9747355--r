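## Pipeline orchestration: a JSON config drives cluster -> annotate ->
## survival -> drugrec -> combo, writing a persistent analysis bundle with
## a manifest that records every stage's parameters and input hashes so
## unchanged stages are skipped on re-run.

.stageOrder <- c("cluster", "annotate", "survival", "drugrec", "combo")

.configDefaults <- list(
    cluster = list(minGenesPerCell = 200, minCellsPerGene = 3,
                   maxMitoFrac = 0.30, mitoPrefix = "MT-",
                   targetSum = 10000, nPcs = 20, kNeighbors = 15,
                   resolution = 1.0, autoResolution = FALSE,
                   grid = seq(0.4, 1.4, by = 0.2), nReps = 5, frac = 0.8),
    annotate = list(lfcMin = 2, pMax = 0.01, adjPMax = 0.01,
                    ratioThreshold = 2),
    survival = list(topN = 20),
    drugrec = list(responseScale = "gdsc", latentDim = 10, lambda = 0.01,
                   learningRate = 0.01, maxEpochs = 100000,
                   mode = "cluster_wise", minAbsCorr = 0.2),
    combo = list(killThreshold = 0.90, consistencyThreshold = 0.75)
)

.validateConfig <- function(config) {
    errs <- character()
    req <- function(stage, field, type = "file") {
        v <- config[[stage]][[field]]
        path <- paste0(stage, ".", field)
        if (is.null(v)) errs <<- c(errs, paste0(path, ": required"))
        else if (type == "file" && !file.exists(v))
            errs <<- c(errs, paste0(path, ": file not found (", v, ")"))
    }
    if (is.null(config$cluster)) errs <- c(errs, "cluster: stage required")
    else req("cluster", "input")
    if (!is.null(config$annotate)) {
        req("annotate", "gmt"); req("annotate", "reference")
        if (!is.null(config$annotate$tumorOrigin))
            req("annotate", "tumorOrigin")
    }
    if (!is.null(config$survival)) {
        req("survival", "bulkExpression"); req("survival", "clinical")
    }
    if (!is.null(config$drugrec)) {
        req("drugrec", "panelExpression"); req("drugrec", "panelResponse")
        sc <- config$drugrec$responseScale
        if (!is.null(sc) && !sc %in% c("gdsc", "prism"))
            errs <- c(errs, "drugrec.responseScale: must be 'gdsc' or 'prism'")
    }
    if (!is.null(config$combo)) {
        req("combo", "screenMeta"); req("combo", "screenGEP")
    }
    for (stage in intersect(names(config), .stageOrder))
        for (fld in names(.configDefaults[[stage]])) {
            v <- config[[stage]][[fld]]
            dflt <- .configDefaults[[stage]][[fld]]
            if (!is.null(v) && is.numeric(dflt) && !is.numeric(v))
                errs <- c(errs, paste0(stage, ".", fld, ": must be numeric"))
        }
    if (length(errs))
        stop("invalid config:\n  ", paste(errs, collapse = "\n  "),
             call. = FALSE)
    invisible(TRUE)
}

.fillDefaults <- function(config) {
    for (stage in intersect(names(config), .stageOrder))
        for (fld in names(.configDefaults[[stage]]))
            if (is.null(config[[stage]][[fld]]))
                config[[stage]][[fld]] <- .configDefaults[[stage]][[fld]]
    if (is.null(config$seed)) config$seed <- 0
    config
}

.fileHashes <- function(paths) {
    paths <- unlist(paths)
    paths <- paths[vapply(paths, function(p)
        is.character(p) && file.exists(p), logical(1))]
    as.list(tools::md5sum(paths))
}

.stageFingerprint <- function(stage, config) {
    params <- config[[stage]]
    files <- Filter(function(v) is.character(v) && length(v) == 1 &&
                    file.exists(v), params)
    list(params = params, seed = config$seed, inputs = .fileHashes(files))
}

.log <- function(verbose, stage, msg) {
    if (verbose)
        message(format(Sys.time(), "[%H:%M:%S] "), stage, ": ", msg)
}

#' Run the full workflow from a configuration
#'
#' Executes the configured stages in order (cluster, annotate, survival,
#' drugrec, combo), writing each stage's tables under \code{outdir} and a
#' \code{manifest.json} recording parameters and input-file hashes. On
#' re-run, a stage whose fingerprint is unchanged and whose outputs exist
#' is skipped; stages needed only as inputs of later stages are recomputed
#' in memory. The configuration is validated up front and all schema
#' violations are reported together with their field paths.
#'
#' @param config a list, or path to a JSON file, with a block per stage;
#'   see the package vignette for the schema and the defaults table.
#' @param outdir bundle directory (created if missing).
#' @param verbose log per-stage progress with timestamps.
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config, outdir, verbose = TRUE) {
    if (is.character(config)) config <- jsonlite::read_json(config,
        simplifyVector = TRUE)
    .validateConfig(config)
    config <- .fillDefaults(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manPath <- file.path(outdir, "manifest.json")
    oldMan <- if (file.exists(manPath))
        jsonlite::read_json(manPath, simplifyVector = TRUE) else list()
    manifest <- list(package = "scRepurpose",
                     version = as.character(utils::packageVersion("scRepurpose")),
                     stages = list())

    fresh <- function(stage, outputs) {
        fp <- .stageFingerprint(stage, config)
        old <- oldMan$stages[[stage]]
        unchanged <- !is.null(old) &&
            identical(jsonlite::toJSON(old$fingerprint, auto_unbox = TRUE),
                      jsonlite::toJSON(fp, auto_unbox = TRUE)) &&
            all(file.exists(file.path(outdir, outputs)))
        list(fingerprint = fp, skip = unchanged)
    }
    record <- function(stage, fp, outputs) {
        manifest$stages[[stage]] <<- list(fingerprint = fp$fingerprint,
                                          outputs = outputs)
    }

    sce <- NULL
    degs <- NULL
    loadSCE <- function() {
        if (!is.null(sce)) return(sce)
        p <- config$cluster
        .log(verbose, "cluster", paste("reading", p$input))
        raw <- if (dir.exists(p$input)) readCounts10x(p$input)
               else readCountsTSV(p$input)
        sce <<- runClustering(raw,
            minGenesPerCell = p$minGenesPerCell,
            minCellsPerGene = p$minCellsPerGene,
            maxMitoFrac = p$maxMitoFrac, mitoPrefix = p$mitoPrefix,
            targetSum = p$targetSum, nPcs = p$nPcs,
            kNeighbors = p$kNeighbors, resolution = p$resolution,
            autoResolution = isTRUE(p$autoResolution), grid = p$grid,
            nReps = p$nReps, frac = p$frac, seed = config$seed)
        sce
    }
    loadDEGs <- function() {
        if (is.null(degs)) degs <<- rankDEGs(loadSCE())
        degs
    }

    ## cluster
    outs <- c("clustering.tsv",
              if (isTRUE(config$cluster$autoResolution))
                  "resolution_scores.tsv")
    st <- fresh("cluster", outs)
    if (st$skip) .log(verbose, "cluster", "unchanged, skipped")
    else {
        loadSCE()
        writeClusteringTSV(sce, file.path(outdir, "clustering.tsv"))
        if (isTRUE(config$cluster$autoResolution))
            .writeTSV(S4Vectors::metadata(sce)$resolution_scores,
                      file.path(outdir, "resolution_scores.tsv"))
        .log(verbose, "cluster",
             paste(S4Vectors::metadata(sce)$clustering$nClusters,
                   "clusters at resolution",
                   S4Vectors::metadata(sce)$clustering$resolution))
    }
    record("cluster", st, outs)

    ## annotate
    if (!is.null(config$annotate)) {
        p <- config$annotate
        outs <- c("degs.tsv", "cluster_gep.tsv", "cell_types.tsv",
                  "enrichment.tsv",
                  if (!is.null(p$tumorOrigin)) "tumor_clusters.tsv")
        st <- fresh("annotate", outs)
        if (st$skip) .log(verbose, "annotate", "unchanged, skipped")
        else {
            d <- loadDEGs()
            .writeTSV(d, file.path(outdir, "degs.tsv"))
            gep <- clusterGEP(loadSCE())
            .writeTSV(as.data.frame(gep), file.path(outdir,
                      "cluster_gep.tsv"), rowNames = TRUE)
            ref <- as.matrix(utils::read.delim(p$reference, row.names = 1,
                                               check.names = FALSE))
            .writeTSV(annotateCellTypes(gep, ref),
                      file.path(outdir, "cell_types.tsv"))
            enr <- enrichClusters(d, readGMT(p$gmt), lfcMin = p$lfcMin,
                                  pMax = p$pMax, adjPMax = p$adjPMax)
            .writeTSV(enr, file.path(outdir, "enrichment.tsv"))
            if (!is.null(p$tumorOrigin)) {
                org <- utils::read.delim(p$tumorOrigin)
                origin <- stats::setNames(org$origin, org$cell_id)
                tc <- selectTumorClusters(loadSCE(), origin,
                                          p$ratioThreshold)
                .writeTSV(data.frame(tumor_cluster = tc),
                          file.path(outdir, "tumor_clusters.tsv"))
            }
            .log(verbose, "annotate", "done")
        }
        record("annotate", st, outs)
    }

    ## survival
    if (!is.null(config$survival)) {
        p <- config$survival
        outs <- c("survival.tsv", "km_curves.tsv")
        st <- fresh("survival", outs)
        if (st$skip) .log(verbose, "survival", "unchanged, skipped")
        else {
            cohort <- readCohort(p$bulkExpression, p$clinical)
            sigs <- signatureGenes(loadDEGs(), colnames(cohort$expression),
                                   n = p$topN)
            act <- activityScores(cohort, sigs)
            .writeTSV(clusterSurvival(cohort, act),
                      file.path(outdir, "survival.tsv"))
            curves <- do.call(rbind, lapply(colnames(act), function(cl) {
                km <- tryCatch(kmLogrank(cohort$time, cohort$event,
                                         stratifyPatients(act[, cl])),
                               error = function(e) NULL)
                if (is.null(km)) return(NULL)
                cbind(cluster = cl, km$curves)
            }))
            .writeTSV(curves, file.path(outdir, "km_curves.tsv"))
            .log(verbose, "survival", "done")
        }
        record("survival", st, outs)
    }

    ## drugrec
    if (!is.null(config$drugrec)) {
        p <- config$drugrec
        outs <- c("drug_sensitivity.tsv", "retained_drugs.tsv")
        st <- fresh("drugrec", outs)
        if (st$skip) .log(verbose, "drugrec", "unchanged, skipped")
        else {
            panel <- readDrugPanel(p$panelExpression, p$panelResponse,
                                   p$responseScale)
            fg <- if (p$responseScale == "prism")
                selectFeatureGenes(panel$expression, panel$response,
                                   p$minAbsCorr) else NULL
            model <- trainDrugModel(panel, f = p$latentDim,
                                    lambda = p$lambda,
                                    learningRate = p$learningRate,
                                    maxEpochs = p$maxEpochs,
                                    seed = config$seed, featureGenes = fg)
            pred <- predictCells(model, loadSCE(), mode = p$mode)
            .writeTSV(as.data.frame(pred$sensitivity),
                      file.path(outdir, "drug_sensitivity.tsv"),
                      rowNames = TRUE)
            kept <- filterDrugs(model, panel)
            .writeTSV(data.frame(drug = as.character(kept),
                                 coefficient =
                                     attr(kept, "coefficients")[kept]),
                      file.path(outdir, "retained_drugs.tsv"))
            .log(verbose, "drugrec", "done")
        }
        record("drugrec", st, outs)
    }

    ## combo
    if (!is.null(config$combo)) {
        p <- config$combo
        outs <- c("proportions.tsv", "kill_table.tsv", "plans.json")
        st <- fresh("combo", outs)
        if (st$skip) .log(verbose, "combo", "unchanged, skipped")
        else {
            screen <- readScreen(p$screenMeta, p$screenGEP)
            sig <- signatureMatrix(clusterGEP(loadSCE()),
                                   rownames(screenGEP(screen)))
            props <- deconvolve(screen, sig)
            .writeTSV(as.data.frame(props),
                      file.path(outdir, "proportions.tsv"), rowNames = TRUE)
            kt <- callKilled(props, screen, p$killThreshold,
                             p$consistencyThreshold)
            .writeTSV(as.data.frame(kt), file.path(outdir, "kill_table.tsv"))
            plans <- greedyCombination(kt)
            jsonlite::write_json(lapply(plans, function(pl) list(
                steps = lapply(seq_len(nrow(pl$steps)), function(i) list(
                    experiment_id = pl$steps$experiment_id[i],
                    compound = pl$steps$compound[i],
                    concentration = pl$steps$concentration[i],
                    newly_killed = pl$steps$newly_killed[[i]],
                    efficacy = pl$steps$efficacy[i])),
                killed = pl$killed,
                total_efficacy = pl$totalEfficacy)),
                file.path(outdir, "plans.json"), auto_unbox = TRUE,
                digits = NA)
            .log(verbose, "combo", paste(length(plans), "plan(s)"))
        }
        record("combo", st, outs)
    }

    jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(manifest)
}
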