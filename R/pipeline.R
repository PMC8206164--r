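## Pipeline orchestration: a config-driven end-to-end run
## (filter -> standardize -> PCA -> k-means + cluster DE -> smoothness
## filter -> SOM -> optional concordance) writing every intermediate table
## plus a machine-readable manifest, and a fixture generator for the
## synthetic datasets.

#' Default pipeline configuration
#'
#' All analysis parameters with their standard values: intensity filter 3,
#' SD filter 0.3, PVE > 0.6, C < 0.35, F > 2, k = 6 temporal clusters,
#' 3 x 3 SOM grid.
#'
#' @return Nested named list of parameters.
#' @export
defaultPipelineConfig <- function() {
    list(
        input = list(expression = NULL, metadata = NULL,
                     comparator = NULL, comparatorMetadata = NULL),
        simulate = NULL,
        thresholds = list(intensity = 3, sd = 0.3,
                          pve = 0.6, c = 0.35, f = 2),
        kmeans = list(k = 6, nRestarts = 25, features = "consensus"),
        som = list(rows = 3, cols = 3, orderEpochs = 15, fineEpochs = 15),
        contrasts = NULL,
        seeds = list(simulate = 1, kmeans = 1, som = 1),
        mergeNodes = FALSE,
        mergeCorThreshold = 0.95)
}

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(override[[nm]]) && is.list(base[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; missing keys take their defaults from
#' \code{\link{defaultPipelineConfig}}.
#'
#' @param path config file path.
#' @return Full configuration list.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                            simplifyVector = TRUE)
           else yaml::read_yaml(path)
    .mergeConfig(defaultPipelineConfig(), cfg)
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: gene filtering, row standardization, sample PCA,
#' consensus-profile k-means with per-cluster High/Low differential
#' expression, the PVE/cohesion/interaction-F smoothness filter, 3 x 3 SOM
#' subsetting of the filtered genes, and (when a comparator is supplied)
#' transition concordance. Every stage's table is written to
#' \code{outDir}, along with \code{manifest.json} recording parameters,
#' seeds and per-stage gene counts.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}); either \code{input} paths or a
#'   \code{simulate} block must be provided.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, outDir) {
    config <- .mergeConfig(defaultPipelineConfig(), config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    ## ---- input stage
    comparator <- NULL
    if (!is.null(config$simulate)) {
        sim <- config$simulate
        specs <- lapply(sim$archetypes, function(s)
            archetypeSpec(s$name, s$nGenes,
                          amplitude = if (is.null(s$amplitude)) 2 else s$amplitude,
                          noiseSd = if (is.null(s$noiseSd)) 0.3 else s$noiseSd))
        tc <- simulateTimecourse(specs, seed = config$seeds$simulate)
        if (isTRUE(sim$comparator)) {
            comparator <- simulateStageSeries(
                tc,
                sharedSignFraction =
                    if (is.null(sim$sharedSignFraction)) 1
                    else sim$sharedSignFraction,
                noiseSd = if (is.null(sim$comparatorNoiseSd)) 0.3
                          else sim$comparatorNoiseSd,
                seed = config$seeds$simulate + 1L)
        }
    } else {
        if (is.null(config$input$expression) || is.null(config$input$metadata))
            stop("config error [input]: expression and metadata paths (or a ",
                 "simulate block) are required")
        for (p in c(config$input$expression, config$input$metadata))
            if (!file.exists(p))
                stop("config error [input]: file not found: ", p)
        tc <- readFollicleTimecourse(config$input$expression,
                                     config$input$metadata)
        if (!is.null(config$input$comparator)) {
            cm <- readExpressionTSV(config$input$comparator)
            cmeta <- readSampleMetaTSV(config$input$comparatorMetadata)
            cmeta <- cmeta[colnames(cm), , drop = FALSE]
            comparator <- StageSeries(cm, stage = cmeta$stage,
                                      replicate = cmeta$replicate)
        }
    }
    manifest <- list(parameters = config[c("thresholds", "kmeans", "som")],
                     seeds = config$seeds,
                     counts = list(input = nrow(tc)))

    ## ---- preprocess
    filt <- tryCatch(filterGenes(tc, config$thresholds$intensity,
                                 config$thresholds$sd),
                     error = function(e) stop("stage preprocess: ",
                                              conditionMessage(e)))
    tcf <- filt$matrix
    manifest$counts$filtered <- filt$report$nRetained
    jsonlite::write_json(filt$report[c("nInput", "nPassedIntensity",
                                       "nPassedSd", "nRetained")],
                         file.path(outDir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeExpressionTSV(tcf, file.path(outDir, "filtered_expression.tsv"))

    std <- standardizeRows(tcf)

    ## ---- trajectory: PCA + k-means + contrasts + DE
    pca <- pcaSamples(std, nComponents = min(5L, ncol(tcf) - 1L))
    .writeTSV(data.frame(sample_id = rownames(pca$scores),
                         pca$scores, check.names = FALSE),
              file.path(outDir, "pca_scores.tsv"))
    .writeTSV(data.frame(component = seq_along(pca$varianceFraction),
                         varianceFraction = pca$varianceFraction),
              file.path(outDir, "pca_variance.tsv"))

    traj <- consensusProfiles(std)
    km <- kmeansProfiles(traj, k = config$kmeans$k,
                         seed = config$seeds$kmeans,
                         nRestarts = config$kmeans$nRestarts,
                         features = config$kmeans$features)
    .writeTSV(data.frame(gene_id = names(assignments(km)),
                         cluster = assignments(km)),
              file.path(outDir, "cluster_assignments.tsv"))
    .writeTSV(data.frame(cluster = seq_len(km@k), km@centroids,
                         check.names = FALSE),
              file.path(outDir, "cluster_centroids.tsv"))

    contrasts <- if (is.null(config$contrasts))
        defaultContrasts(config$kmeans$k) else config$contrasts
    groups <- defineContrasts(tcf, contrasts)
    deTables <- list()
    for (cl in names(groups)) {
        g <- groups[[cl]]
        if (isTRUE(g$skip)) next
        members <- names(assignments(km))[assignments(km) == as.integer(cl)]
        if (length(members) < 10L) next
        de <- runDE(tcf[members, , drop = FALSE],
                    groupA = g$low, groupB = g$high)
        ord <- rankByLogFC(de)
        tab <- data.frame(gene_id = ord, as.data.frame(de[ord, ]),
                          check.names = FALSE)
        .writeTSV(tab, file.path(outDir, sprintf("de_cluster_%s.tsv", cl)))
        deTables[[cl]] <- de
    }
    manifest$counts$clusters <- as.list(table(assignments(km)))

    ## ---- smoothness filter
    scores <- smoothnessScores(tcf, thresholds = filterThresholds(
        pve = config$thresholds$pve, c = config$thresholds$c,
        f = config$thresholds$f))
    .writeTSV(data.frame(gene_id = rownames(scores),
                         as.data.frame(scores), check.names = FALSE),
              file.path(outDir, "smoothness_scores.tsv"))
    retained <- applySmoothnessFilter(scores)$retained
    manifest$counts$smoothnessRetained <- length(retained)

    ## ---- SOM on the filtered, standardized 14-sample vectors
    som <- NULL
    if (length(retained) >= config$som$rows * config$som$cols) {
        somData <- .getMatrix(std)[retained, , drop = FALSE]
        som <- trainSOM(somData, gridRows = config$som$rows,
                        gridCols = config$som$cols,
                        seed = config$seeds$som,
                        orderEpochs = config$som$orderEpochs,
                        fineEpochs = config$som$fineEpochs)
        coords <- som@gridCoords[assignments(som), , drop = FALSE]
        .writeTSV(data.frame(gene_id = names(assignments(som)),
                             node = assignments(som),
                             node_row = coords[, 1], node_col = coords[, 2]),
                  file.path(outDir, "som_assignments.tsv"))
        .writeTSV(data.frame(node = rownames(som@codebooks), som@codebooks,
                             check.names = FALSE),
                  file.path(outDir, "som_codebooks.tsv"))
        if (isTRUE(config$mergeNodes)) {
            merged <- mergeSimilarNodes(som, somData,
                                        corThreshold = config$mergeCorThreshold)
            .writeTSV(data.frame(gene_id = names(merged$membership),
                                 subset = merged$membership),
                      file.path(outDir, "som_merged_subsets.tsv"))
        }
    }

    ## ---- concordance (optional)
    conc <- NULL
    if (!is.null(comparator)) {
        conc <- concordanceAnalysis(tc, comparator)
        rep <- lapply(conc@transitions, function(tr)
            list(r = tr$r, z = tr$z, p = tr$p, n = tr$n,
                 nAgreement = length(tr$agreement),
                 nDisagreement = length(tr$disagreement),
                 nZero = length(tr$zeros)))
        jsonlite::write_json(rep, file.path(outDir, "concordance.json"),
                             auto_unbox = TRUE, digits = NA)
        for (nm in names(conc@transitions)) {
            tr <- conc@transitions[[nm]]
            .writeTSV(data.frame(gene_id = tr$agreement),
                      file.path(outDir, paste0("agreement_", nm, ".tsv")))
            .writeTSV(data.frame(gene_id = tr$disagreement),
                      file.path(outDir, paste0("disagreement_", nm, ".tsv")))
        }
        manifest$counts$concordanceGenes <- conc@nGenes
    }

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(timecourse = tc, filtered = tcf, filterReport = filt$report,
                   pca = pca, clusters = km, de = deTables,
                   smoothness = scores, retained = retained, som = som,
                   concordance = conc, manifest = manifest))
}

#' Write the synthetic fixture datasets to disk
#'
#' Generates the default synthetic time course (all nine archetypes), its
#' stage-labelled comparator and the ground-truth ledger, and writes them as
#' TSV/JSON.
#'
#' @param outDir output directory.
#' @param config optional list with \code{archetypes} (as in
#'   \code{runPipeline}'s simulate block), \code{sharedSignFraction} and
#'   \code{seed}.
#' @return Invisibly, the file paths written.
#' @export
simulateFixture <- function(outDir, config = list()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    specs <- if (is.null(config$archetypes)) defaultArchetypeMix()
             else lapply(config$archetypes, function(s)
                 archetypeSpec(s$name, s$nGenes,
                               amplitude = if (is.null(s$amplitude)) 2
                                           else s$amplitude,
                               noiseSd = if (is.null(s$noiseSd)) 0.3
                                         else s$noiseSd))
    frac <- if (is.null(config$sharedSignFraction)) 1
            else config$sharedSignFraction
    tc <- simulateTimecourse(specs, seed = seed)
    ss <- simulateStageSeries(tc, sharedSignFraction = frac,
                              seed = seed + 1L)
    paths <- c(
        writeExpressionTSV(tc, file.path(outDir, "timecourse.tsv")),
        writeSampleMetaTSV(tc, file.path(outDir, "timecourse_metadata.tsv")),
        writeExpressionTSV(ss, file.path(outDir, "comparator.tsv")),
        writeSampleMetaTSV(ss, file.path(outDir, "comparator_metadata.tsv")),
        writeTruthJSON(tc, file.path(outDir, "truth.json")))
    invisible(paths)
}
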