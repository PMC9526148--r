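#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()]: a stage
#' list and one parameter block per stage. Analysis thresholds default to
#' the pipeline's standard values (5% expression gates, log2 fold-change
#' 0.5, 20-cell gene detection floor, 20% mitochondrial cap, 0.005 minimum
#' intra-set correlation, 15 neighbors, 2 dropped variance components,
#' 2000-cell subsampling cap); the bundled `simulate` block is a compact
#' panel so a full run stays interactive.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @param out_dir output directory.
#' @return a list of class `pipeline_config`.
#' @export
defaultPipelineConfig <- function(seed = 1, out_dir = tempfile("isletxmap_")) {
    structure(list(
        stages = c("simulate", "preprocess", "markers", "conserve",
                   "corr", "genesets", "score", "map"),
        seed = seed, out_dir = out_dir,
        simulate = list(species = c("human", "pig"),
                        cells_per_type = 150, n_genes = 800,
                        n_markers = 25, marker_log2fc = 2,
                        states = c(mature = 0.5, immature = 0.3,
                                   stress = 0.2)),
        preprocess = list(max_mito_fraction = 0.20, min_counts = 200,
                          min_genes = 50, min_cells_per_gene = 20,
                          max_fraction = 0.05),
        markers = list(frac_threshold = 0.05, fc_threshold = 0.5),
        conserve = list(expressed_threshold = 0.05),
        corr = list(n_pcs = 50, drop_top = 2, subsample_cap = 2000),
        genesets = list(n_variable = 300, n_clusters = 10,
                        min_corr = 0.005),
        score = list(n_bins = 25, background_size = 50),
        map = list(n_components = 5, k = 15)
    ), class = "pipeline_config")
}

.pipelineStageKeys <- list(
    simulate = c("species", "cells_per_type", "n_genes", "n_markers",
                 "marker_log2fc", "states"),
    preprocess = c("max_mito_fraction", "min_counts", "min_genes",
                   "min_cells_per_gene", "max_fraction"),
    markers = c("frac_threshold", "fc_threshold"),
    conserve = c("expressed_threshold"),
    corr = c("n_pcs", "drop_top", "subsample_cap"),
    genesets = c("n_variable", "n_clusters", "min_corr"),
    score = c("n_bins", "background_size"),
    map = c("n_components", "k"))

.validatePipelineConfig <- function(config) {
    known <- c("stages", "seed", "out_dir", names(.pipelineStageKeys))
    extra <- setdiff(names(config), known)
    if (length(extra))
        stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
    bad <- setdiff(config$stages, names(.pipelineStageKeys))
    if (length(bad))
        stop("unknown stage(s): ", paste(bad, collapse = ", "))
    for (st in intersect(names(config), names(.pipelineStageKeys))) {
        extra <- setdiff(names(config[[st]]), .pipelineStageKeys[[st]])
        if (length(extra))
            stop(sprintf("unknown key(s) in stage '%s': %s", st,
                         paste(extra, collapse = ", ")))
    }
    if (is.null(config$seed)) stop("a global seed is required")
    invisible(TRUE)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the same structure as
#'   [defaultPipelineConfig()]; missing stage blocks fall back to the
#'   defaults, unknown keys are rejected.
#' @return a `pipeline_config` list.
#' @export
readPipelineConfig <- function(path) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- defaultPipelineConfig()
    for (nm in names(user)) {
        if (nm %in% names(.pipelineStageKeys) && is.list(user[[nm]])) {
            for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
        } else cfg[[nm]] <- user[[nm]]
    }
    .validatePipelineConfig(cfg)
    cfg
}

#' Run the cross-species analysis pipeline
#'
#' Executes the configured stages in their declared order — `simulate`
#' (synthetic panel), `preprocess` (QC, normalization, zero-preserving
#' batch adjustment), `markers` (ortholog resolution, group profiles,
#' enriched markers), `conserve` (conservation calls + marker overlap),
#' `corr` (harmonic pattern correlations + PCA-space cell-type
#' correlation), `genesets` (variable genes + correlation clustering),
#' `score` (activation scores) and `map` (reference fit + query
#' projection + composition) — writing every output file under
#' `out_dir` and recording an md5 checksum for each. All randomness flows
#' from the global seed through per-stage derived seeds, so two runs with
#' the same configuration produce identical checksums.
#'
#' @param config a `pipeline_config` list ([defaultPipelineConfig()] or
#'   [readPipelineConfig()]).
#' @return the run report (list: `stages`, `outputs` with checksums,
#'   `warnings`), invisibly; also written as `report.json` in `out_dir`.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
    .validatePipelineConfig(config)
    out_dir <- config$out_dir
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    state <- new.env(parent = emptyenv())
    report <- list(stages = character(), outputs = list(),
                   warnings = character())
    stage_seed <- function(st)
        (config$seed + 1000L * match(st, names(.pipelineStageKeys))) %%
            .Machine$integer.max
    t0 <- Sys.time()
    for (st in config$stages) {
        message(sprintf("[isletXmap] stage %-10s ...", st))
        handler <- get(paste0(".stage_", st), mode = "function")
        files <- withCallingHandlers(
            handler(config, state, out_dir, stage_seed(st)),
            warning = function(w) {
                report$warnings <<- c(report$warnings,
                                      paste0(st, ": ", conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
        report$stages <- c(report$stages, st)
        for (f in files)
            report$outputs[[substring(f, nchar(out_dir) + 2)]] <-
                unname(tools::md5sum(f))
    }
    report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message(sprintf("[isletXmap] done: %d stage(s), %d file(s), %.1f s",
                    length(report$stages), length(report$outputs),
                    report$elapsed_sec))
    invisible(report)
}

.stage_simulate <- function(config, state, out_dir, seed) {
    p <- config$simulate
    types <- setNames(rep(p$cells_per_type, 4),
                      c("alpha", "beta", "delta", "pp"))
    states <- p$states
    if (!is.null(states)) states <- unlist(states)
    cfg <- simConfig(species = p$species, cell_types = types,
                     n_genes = p$n_genes, n_markers = p$n_markers,
                     marker_log2fc = p$marker_log2fc,
                     states = states, seed = seed)
    sim <- simulatePanel(cfg)
    state$sim <- sim
    files <- character()
    for (sp in names(sim$matrices)) {
        d <- file.path(out_dir, "sim", sp)
        writeCellMatrix(sim$matrices[[sp]], d)
        files <- c(files, list.files(d, full.names = TRUE))
    }
    f <- file.path(out_dir, "sim", "ortholog_table.tsv")
    writeOrthologTable(sim$ortholog, f)
    tr <- file.path(out_dir, "sim", "truth_markers.tsv")
    write.table(sim$truth$markers, tr, sep = "\t", quote = FALSE,
                row.names = FALSE)
    c(files, f, tr)
}

.stage_preprocess <- function(config, state, out_dir, seed) {
    if (is.null(state$sim)) stop("stage 'preprocess' requires 'simulate'")
    p <- config$preprocess
    cfg <- qcConfig(max_mito_fraction = p$max_mito_fraction,
                    min_counts = p$min_counts, min_genes = p$min_genes,
                    min_cells_per_gene = p$min_cells_per_gene)
    files <- character()
    state$norm <- lapply(state$sim$matrices, function(x) {
        x <- qcFilter(x, cfg)
        x <- normalizeLog(x, max_fraction = p$max_fraction)
        batchCorrectZeroPreserving(x)
    })
    for (sp in names(state$norm)) {
        d <- file.path(out_dir, "norm", sp)
        writeCellMatrix(state$norm[[sp]], d)
        files <- c(files, list.files(d, full.names = TRUE))
    }
    files
}

.stage_markers <- function(config, state, out_dir, seed) {
    if (is.null(state$norm)) stop("stage 'markers' requires 'preprocess'")
    p <- config$markers
    tab <- resolveOrthologs(state$sim$ortholog, state$norm)
    state$resolved <- tab
    state$mapped <- lapply(names(state$norm), function(sp)
        applyMapping(state$norm[[sp]], tab, species = sp))
    names(state$mapped) <- names(state$norm)
    state$profiles <- lapply(state$mapped, computeGroupProfile,
                             group_key = "cell_type")
    state$markers <- lapply(state$profiles, findEnrichedMarkers,
                            frac_threshold = p$frac_threshold,
                            fc_threshold = p$fc_threshold)
    files <- file.path(out_dir, "ortholog_resolved.tsv")
    writeOrthologTable(tab, files)
    for (sp in names(state$markers)) {
        f <- file.path(out_dir, sprintf("markers_%s.tsv", sp))
        write.table(state$markers[[sp]], f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, f)
        f <- file.path(out_dir, sprintf("profile_%s.tsv", sp))
        writeGroupProfile(state$profiles[[sp]], f)
        files <- c(files, f)
    }
    files
}

.stage_conserve <- function(config, state, out_dir, seed) {
    if (is.null(state$profiles)) stop("stage 'conserve' requires 'markers'")
    thr <- config$conserve$expressed_threshold
    ref <- names(state$profiles)[1]
    files <- character()
    calls <- list()
    for (sp in setdiff(names(state$profiles), ref)) {
        mk <- classifyMarkerConservation(state$markers[[ref]],
                                         state$markers[[sp]],
                                         state$profiles[[sp]],
                                         expressed_threshold = thr)
        ex <- classifyExpressionConservation(state$profiles[[ref]],
                                             state$profiles[[sp]],
                                             expressed_threshold = thr)
        mk$species <- sp; ex$species <- sp
        calls[[sp]] <- list(marker = mk, expression = ex)
        f1 <- file.path(out_dir, sprintf("conservation_marker_%s.tsv", sp))
        write.table(mk, f1, sep = "\t", quote = FALSE, row.names = FALSE)
        f2 <- file.path(out_dir,
                        sprintf("conservation_expression_%s.tsv", sp))
        write.table(ex, f2, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, f1, f2)
    }
    state$conservation <- calls
    ov <- markerOverlap(state$markers)
    f <- file.path(out_dir, "marker_overlap.tsv")
    write.table(ov, f, sep = "\t", quote = FALSE, row.names = FALSE)
    c(files, f)
}

.stage_corr <- function(config, state, out_dir, seed) {
    if (is.null(state$profiles)) stop("stage 'corr' requires 'markers'")
    p <- config$corr
    ref <- names(state$profiles)[1]
    genes <- Reduce(intersect,
                    lapply(state$profiles, function(x)
                        colnames(profileMean(x))))
    rows <- list()
    for (sp in setdiff(names(state$profiles), ref)) {
        ha <- harmonicProfile(state$profiles[[ref]], genes)
        hb <- harmonicProfile(state$profiles[[sp]], genes)
        rows[[sp]] <- data.frame(
            species_a = ref, species_b = sp,
            harmonic_r = patternCorrelation(ha, hb),
            mean_r = patternCorrelation(profileMean(state$profiles[[ref]]),
                                        profileMean(state$profiles[[sp]]),
                                        genes = genes), row.names = NULL)
    }
    f1 <- file.path(out_dir, "pattern_correlation.tsv")
    write.table(do.call(rbind, rows), f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    pg <- pcaGroupCorrelation(state$mapped, n_pcs = p$n_pcs,
                              drop_top = p$drop_top,
                              subsample_cap = p$subsample_cap, seed = seed)
    f2 <- file.path(out_dir, "pca_group_correlation.tsv")
    write.table(as.data.frame(pg$correlation), f2, sep = "\t",
                quote = FALSE)
    c(f1, f2)
}

.stage_genesets <- function(config, state, out_dir, seed) {
    if (is.null(state$mapped)) stop("stage 'genesets' requires 'markers'")
    p <- config$genesets
    ref <- names(state$mapped)[1]
    x <- state$mapped[[ref]]
    hv <- selectVariableGenes(x, n = p$n_variable)
    sets <- discoverGeneSets(x, hv, n_clusters = p$n_clusters,
                             min_corr = p$min_corr)
    state$sets <- sets
    f <- file.path(out_dir, "gene_sets.gmt")
    writeGMT(sets, f)
    f
}

.stage_score <- function(config, state, out_dir, seed) {
    if (is.null(state$sets)) stop("stage 'score' requires 'genesets'")
    p <- config$score
    ref <- names(state$mapped)[1]
    state$scores <- scoreGeneSets(state$mapped[[ref]], state$sets,
                                  n_bins = p$n_bins,
                                  background_size = p$background_size,
                                  seed = seed)
    f <- file.path(out_dir, "scores.tsv")
    df <- data.frame(cell_id = rownames(state$scores), state$scores,
                     row.names = NULL, check.names = FALSE)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
}

.stage_map <- function(config, state, out_dir, seed) {
    if (is.null(state$scores)) stop("stage 'map' requires 'score'")
    p <- config$map
    ref <- names(state$mapped)[1]
    cd <- SummarizedExperiment::colData(state$mapped[[ref]])
    labels <- if ("state" %in% colnames(cd) && !anyNA(cd$state))
        as.character(cd$state) else as.character(cd$cell_type)
    model <- fitReference(state$scores, labels, state$sets,
                          n_components = min(p$n_components,
                                             ncol(state$scores)),
                          k = p$k)
    files <- character()
    for (sp in setdiff(names(state$mapped), ref)) {
        res <- projectAndClassify(model, state$mapped[[sp]])
        f <- file.path(out_dir, sprintf("mapped_%s.tsv", sp))
        write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
        comp <- compositionSummary(res$label)
        f2 <- file.path(out_dir, sprintf("composition_%s.tsv", sp))
        write.table(comp, f2, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, f, f2)
    }
    files
}
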