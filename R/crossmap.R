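#' Fit a gene-set-space reference model
#'
#' Z-scales every gene-set score on the reference cells (sets with zero
#' variance are dropped with a warning), fits a PCA on the scaled score
#' matrix, and stores the loadings, reference coordinates, labels and kNN
#' settings. Queries projected with [projectAndClassify()] are always
#' scaled with these reference parameters, never re-fitted — the standard
#' reference-mapping contract.
#'
#' @param scores cells x sets score matrix (from [scoreGeneSets()];
#'   the `"score_config"` attribute, when present, is stored so queries
#'   are scored under the same contract).
#' @param labels character vector of reference state/cluster labels, one
#'   per cell.
#' @param sets the [GeneSetCollection-class] the scores were computed on.
#' @param n_components number of principal components to retain.
#' @param k neighbor count for label transfer (default 15).
#' @return a [ReferenceModel-class].
#' @export
fitReference <- function(scores, labels, sets, n_components, k = 15) {
    stopifnot(nrow(scores) >= k + 1, length(labels) == nrow(scores))
    if (length(unique(labels)) < 2)
        stop("at least two distinct labels are required")
    sdv <- apply(scores, 2, sd)
    if (all(sdv == 0)) stop("all gene sets have zero score variance")
    if (any(sdv == 0)) {
        warning("dropping zero-variance set(s): ",
                paste(colnames(scores)[sdv == 0], collapse = ", "))
        scores <- scores[, sdv > 0, drop = FALSE]
        sdv <- sdv[sdv > 0]
    }
    if (n_components > ncol(scores))
        stop(sprintf("n_components (%d) exceeds the number of usable sets (%d)",
                     n_components, ncol(scores)))
    mu <- colMeans(scores)
    z <- scale(scores, center = mu, scale = sdv)
    pc <- .canonicalSigns(
        prcomp(z, center = FALSE, scale. = FALSE, rank. = n_components))
    cfg <- attr(scores, "score_config")
    if (is.null(cfg)) cfg <- list(n_bins = 25, background_size = 50, seed = 1)
    keep_sets <- geneSets(sets)[colnames(scores)]
    new("ReferenceModel",
        geneSets = geneSetCollection(keep_sets,
                                     setCorrelations(sets)[colnames(scores)]),
        scalingMean = mu, scalingSd = sdv,
        loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
        refCoords = pc$x[, seq_len(n_components), drop = FALSE],
        refLabels = as.character(labels),
        k = as.integer(k), nComponents = as.integer(n_components),
        scoreConfig = cfg)
}

#' Project query cells onto a reference and transfer labels
#'
#' Scores query cells for the reference gene sets (members intersected
#' with the query's genes; expression bins computed on the query, same
#' binning/seed contract as [scoreGeneSets()]), scales the scores with the
#' reference scaling parameters, projects them with the reference PCA
#' loadings, and transfers labels by unweighted majority vote among the
#' `k` nearest reference cells in PC space (Euclidean; vote ties broken
#' toward the lexicographically smallest label).
#'
#' @param model a [ReferenceModel-class].
#' @param query a [CellExperiment-class] sharing the reference gene
#'   namespace (`geneIds()`).
#' @return `data.frame` with `cell_id`, `label`, `mean_neighbor_dist` and
#'   the PC coordinates as further columns.
#' @export
projectAndClassify <- function(model, query) {
    ids <- geneIds(query)
    sl <- geneSets(model@geneSets)
    inter <- lapply(sl, intersect, y = ids)
    lost <- lengths(inter) == 0
    if (all(lost)) stop("all gene sets lost every member in the query")
    if (any(lost))
        warning("set(s) with no member in the query dropped: ",
                paste(names(sl)[lost], collapse = ", "))
    usable <- geneSetCollection(inter[!lost],
                                setCorrelations(model@geneSets)[!lost])
    cfg <- model@scoreConfig
    qs <- scoreGeneSets(query, usable, n_bins = cfg$n_bins,
                        background_size = cfg$background_size,
                        seed = cfg$seed)
    # align to the model's set order; sets lost in the query contribute 0
    # after scaling (their reference-mean score), keeping the projection
    # defined on the remaining information
    z <- matrix(0, nrow = nrow(qs), ncol = length(model@scalingMean),
                dimnames = list(rownames(qs), names(model@scalingMean)))
    common <- colnames(qs)
    z[, common] <- scale(qs[, common, drop = FALSE],
                         center = model@scalingMean[common],
                         scale = model@scalingSd[common])
    coords <- z %*% model@loadings
    nn <- .knnClassify(model@refCoords, model@refLabels, coords, model@k)
    out <- data.frame(cell_id = rownames(coords), label = nn$label,
                      mean_neighbor_dist = nn$mean_dist, row.names = NULL)
    cbind(out, as.data.frame(coords))
}

# deterministic kNN majority vote; ties on the vote go to the
# lexicographically smallest label, ties on distance to the first
# reference cell in storage order
.knnClassify <- function(ref, labels, query, k) {
    k <- min(k, nrow(ref))
    ref2 <- rowSums(ref^2)
    lab <- character(nrow(query))
    md <- numeric(nrow(query))
    for (i in seq_len(nrow(query))) {
        d2 <- ref2 - 2 * drop(ref %*% query[i, ]) + sum(query[i, ]^2)
        idx <- order(d2)[seq_len(k)]
        votes <- table(labels[idx])
        top <- names(votes)[votes == max(votes)]
        lab[i] <- sort(top)[1]
        md[i] <- mean(sqrt(pmax(d2[idx], 0)))
    }
    list(label = lab, mean_dist = md)
}

#' Label composition summary
#'
#' Tabulates label fractions (and counts), optionally within strata such
#' as species or donor. Fractions sum to 1 within each stratum.
#'
#' @param labels character vector of per-cell labels.
#' @param stratify_by optional parallel vector of stratum tags.
#' @return `data.frame` with columns `stratum` (when stratified), `label`,
#'   `n`, `fraction`.
#' @export
compositionSummary <- function(labels, stratify_by = NULL) {
    stopifnot(length(labels) >= 1)
    if (is.null(stratify_by)) {
        tab <- table(labels)
        return(data.frame(label = names(tab), n = as.integer(tab),
                          fraction = as.numeric(tab) / sum(tab),
                          row.names = NULL))
    }
    stopifnot(length(stratify_by) == length(labels))
    out <- lapply(sort(unique(stratify_by)), function(s) {
        tab <- table(labels[stratify_by == s])
        data.frame(stratum = s, label = names(tab), n = as.integer(tab),
                   fraction = as.numeric(tab) / sum(tab), row.names = NULL)
    })
    do.call(rbind, out)
}
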