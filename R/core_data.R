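#' Quality-control configuration
#'
#' Thresholds for cell- and gene-level filtering. In practice these are
#' tuned per sample after inspecting count distributions; the defaults are
#' the values commonly applied to droplet-based islet data: cells with more
#' than 20% mitochondria-encoded counts, fewer than 200 total counts or
#' fewer than 200 detected genes are discarded, and genes detected in fewer
#' than 20 surviving cells are dropped.
#'
#' @param max_mito_fraction maximum tolerated fraction of counts from
#'   mitochondria-encoded genes, in `[0, 1]`.
#' @param min_counts minimum total UMI counts per cell.
#' @param min_genes minimum number of detected (count > 0) genes per cell.
#' @param min_cells_per_gene minimum number of surviving cells a gene must
#'   be detected in.
#' @param mito_genes character vector of `native_id`s of
#'   mitochondria-encoded genes (may be empty, in which case the mito
#'   criterion never fires).
#' @return a list of class `qc_config`.
#' @export
qcConfig <- function(max_mito_fraction = 0.20, min_counts = 200,
                     min_genes = 200, min_cells_per_gene = 20,
                     mito_genes = character()) {
    stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1,
              min_counts >= 0, min_genes >= 0, min_cells_per_gene >= 0)
    structure(list(max_mito_fraction = max_mito_fraction,
                   min_counts = min_counts, min_genes = min_genes,
                   min_cells_per_gene = min_cells_per_gene,
                   mito_genes = as.character(mito_genes)),
              class = "qc_config")
}

#' Filter low-quality cells and rarely detected genes
#'
#' Cells are kept when their mitochondrial count fraction is at most
#' `max_mito_fraction`, their total counts reach `min_counts`, and they
#' detect at least `min_genes` genes. Genes are then kept when detected
#' (count > 0) in at least `min_cells_per_gene` of the surviving cells.
#' The input ordering of surviving cells and genes is preserved.
#'
#' @param x a [CellExperiment-class] with a `"counts"` assay.
#' @param cfg a [qcConfig()] list.
#' @return the filtered [CellExperiment-class].
#' @export
qcFilter <- function(x, cfg = qcConfig()) {
    stopifnot(inherits(cfg, "qc_config"))
    cts <- SummarizedExperiment::assay(x, "counts")
    ids <- SummarizedExperiment::rowData(x)$native_id
    if (!all(cfg$mito_genes %in% ids))
        stop("mito_genes not found in the matrix: ",
             paste(setdiff(cfg$mito_genes, ids), collapse = ", "))
    totals <- Matrix::colSums(cts)
    mito <- if (length(cfg$mito_genes)) {
        Matrix::colSums(cts[ids %in% cfg$mito_genes, , drop = FALSE]) /
            pmax(totals, 1)
    } else rep(0, ncol(x))
    ngenes <- Matrix::colSums(cts > 0)

    keep <- mito <= cfg$max_mito_fraction
    if (!any(keep))
        stop("no cells survive the mitochondrial fraction criterion")
    keep <- keep & totals >= cfg$min_counts
    if (!any(keep)) stop("no cells survive the minimum total count criterion")
    keep <- keep & ngenes >= cfg$min_genes
    if (!any(keep)) stop("no cells survive the minimum gene count criterion")

    out <- x[, keep]
    detected <- Matrix::rowSums(
        SummarizedExperiment::assay(out, "counts") > 0)
    gkeep <- detected >= cfg$min_cells_per_gene
    if (!any(gkeep))
        stop("no genes survive the minimum cells-per-gene criterion")
    out[gkeep, ]
}

#' Total-count normalization with highly-expressed-gene exclusion
#'
#' A gene is flagged "highly expressed" when, in any single cell, it
#' accounts for more than `max_fraction` of that cell's total counts.
#' Per-cell size factors are (sum of counts over non-flagged genes) /
#' `target`, where `target` defaults to the median of those filtered sums.
#' All genes — including the flagged ones — are then normalized by the cell
#' size factor and transformed as `log(1 + x)`. Excluding dominant genes
#' (insulin and glucagon dwarf everything else in islet cells) keeps a
#' cell's size factor from being driven by one transcript.
#'
#' @param x a [CellExperiment-class] with a `"counts"` assay.
#' @param max_fraction per-cell count fraction above which a gene is
#'   excluded from size-factor computation (default 0.05).
#' @param target fixed normalization target; `NULL` (default) uses the
#'   median filtered sum.
#' @return `x` with a `"lognorm"` assay added; size factors stored in
#'   `colData(x)$size_factor` and the flag in `rowData(x)$highly_expressed`.
#' @export
normalizeLog <- function(x, max_fraction = 0.05, target = NULL) {
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    totals <- colSums(cts)
    if (any(totals == 0))
        stop("cells with zero total counts: ",
             paste(colnames(cts)[totals == 0], collapse = ", "))
    # flag genes exceeding max_fraction of the total in ANY cell
    frac <- sweep(cts, 2, totals, "/")
    flagged <- apply(frac > max_fraction, 1, any)
    filtered <- colSums(cts[!flagged, , drop = FALSE])
    if (any(filtered == 0))
        stop("zero counts outside highly-expressed genes for cells: ",
             paste(colnames(cts)[filtered == 0], collapse = ", "))
    if (is.null(target)) target <- median(filtered)
    sf <- filtered / target
    ln <- log1p(sweep(cts, 2, sf, "/"))
    SummarizedExperiment::assay(x, "lognorm") <- ln
    SummarizedExperiment::colData(x)$size_factor <- sf
    SummarizedExperiment::rowData(x)$highly_expressed <- flagged
    validObject(x)
    x
}

#' Zero-preserving empirical-Bayes batch adjustment
#'
#' Runs the ComBat parametric empirical-Bayes location/scale model (as
#' implemented in \pkg{sva}) on the `"lognorm"` assay with a batch-only
#' design, then resets every entry that was exactly zero before adjustment
#' back to exactly zero. Dropout zeros carry no batch signal, and shifting
#' them creates spurious sample-to-sample differences around zero, so they
#' are pinned. Non-zero entries are not clipped and may become negative.
#'
#' Genes with zero variance across all cells carry no batch-adjustable
#' signal and are passed through unchanged.
#'
#' @param x a [CellExperiment-class] with a `"lognorm"` assay.
#' @param batch_key `colData` column holding the batch tag (default
#'   `"batch"`).
#' @return `x` with the `"lognorm"` assay batch-adjusted.
#' @export
batchCorrectZeroPreserving <- function(x, batch_key = "batch") {
    cd <- SummarizedExperiment::colData(x)
    if (!batch_key %in% colnames(cd))
        stop("unknown batch key: ", batch_key)
    batch <- as.character(cd[[batch_key]])
    if (anyNA(batch)) stop("missing batch labels")
    tab <- table(batch)
    if (length(tab) == 1) return(x)
    if (any(tab < 2))
        stop("batches with a single cell: ",
             paste(names(tab)[tab < 2], collapse = ", "))
    ln <- lognorm(x)
    zero <- ln == 0
    v <- apply(ln, 1, var)
    adjustable <- v > 0
    adj <- ln
    if (any(adjustable)) {
        fixed <- suppressMessages(
            sva::ComBat(dat = ln[adjustable, , drop = FALSE], batch = batch,
                        par.prior = TRUE, prior.plots = FALSE))
        adj[adjustable, ] <- fixed
    }
    adj[zero] <- 0
    lognorm(x) <- adj
    validObject(x)
    x
}

#' Summarize expression per group
#'
#' Computes, on the `"lognorm"` assay, the mean expression and the fraction
#' of expressing (lognorm > 0) cells for every gene in every group, plus
#' group cell counts.
#'
#' @param x a [CellExperiment-class] with a `"lognorm"` assay.
#' @param group_key `colData` column defining the groups (e.g.
#'   `"cell_type"`, `"state"` or an interaction column).
#' @param genes optional character vector of `native_id`s (or `common_id`s
#'   if set) restricting the profile.
#' @return a [GroupProfile-class].
#' @export
computeGroupProfile <- function(x, group_key = "cell_type", genes = NULL) {
    cd <- SummarizedExperiment::colData(x)
    if (!group_key %in% colnames(cd))
        stop("unknown group key: ", group_key)
    grp <- as.character(cd[[group_key]])
    if (anyNA(grp)) stop("missing group labels under '", group_key, "'")
    ln <- lognorm(x)
    rownames(ln) <- geneIds(x)
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(ln))
        if (length(missing))
            stop("requested genes absent: ",
                 paste(head(missing, 5), collapse = ", "))
        ln <- ln[genes, , drop = FALSE]
    }
    groups <- sort(unique(grp))
    m <- t(vapply(groups, function(g)
        rowMeans(ln[, grp == g, drop = FALSE]), numeric(nrow(ln))))
    f <- t(vapply(groups, function(g)
        rowMeans(ln[, grp == g, drop = FALSE] > 0), numeric(nrow(ln))))
    n <- vapply(groups, function(g) sum(grp == g), numeric(1))
    dimnames(m) <- dimnames(f) <- list(groups, rownames(ln))
    new("GroupProfile", mean = m, frac = f, ncells = n)
}

#' Gene identifiers of a CellExperiment
#'
#' Returns `common_id` where present (after ortholog renaming) and
#' `native_id` otherwise.
#'
#' @param x a [CellExperiment-class].
#' @return character vector of gene ids.
#' @export
geneIds <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if ("common_id" %in% colnames(rd) && !anyNA(rd$common_id))
        as.character(rd$common_id)
    else as.character(rd$native_id)
}
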