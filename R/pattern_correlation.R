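#' Harmonic-average expression pattern profile
#'
#' Combines, per group and gene, the mean expression `m` and the
#' expressing-cell fraction `f` into a single statistic: the harmonic mean
#' `h = 2 m f' / (m + f')`, where `f' = f / mean_j(f)` is the fraction
#' normalized to the group's mean fraction over the gene subset under
#' comparison. The normalization makes `h` comparable across species and
#' platforms with different detection limits: multiplying all fractions of
#' a group by a constant leaves `f'` — and hence `h` — unchanged. `h` is 0
#' whenever `m + f' = 0`.
#'
#' @param profile a [GroupProfile-class].
#' @param genes character vector of gene ids defining the comparison
#'   subset; the normalization denominator is the mean fraction over
#'   exactly this subset (within each group).
#' @return a groups x genes matrix of harmonic pattern values.
#' @export
harmonicProfile <- function(profile, genes = colnames(profileMean(profile))) {
    stopifnot(length(genes) > 0)
    m <- profileMean(profile)[, genes, drop = FALSE]
    f <- profileFrac(profile)[, genes, drop = FALSE]
    denom <- rowMeans(f)
    if (any(denom == 0))
        stop("all-zero fractions over the subset in group(s): ",
             paste(rownames(f)[denom == 0], collapse = ", "))
    fp <- f / denom
    h <- 2 * m * fp / (m + fp)
    h[m + fp == 0] <- 0
    h
}

#' Pearson correlation of expression patterns across groups
#'
#' Flattens two (group x gene) grids — harmonic pattern profiles or plain
#' group-mean matrices — over the intersection of their genes and groups,
#' in identical order, and returns the Pearson correlation. Used to
#' compare e.g. transcription-factor or receptor expression patterns
#' between species across cell types or states.
#'
#' @param a,b groups x genes matrices (both [harmonicProfile()] outputs
#'   for harmonic mode, or both [profileMean()] matrices for mean mode),
#'   or [GroupProfile-class] objects (means are used).
#' @param genes,groups optional subsets; defaults to the intersection of
#'   the two grids.
#' @return the Pearson correlation coefficient.
#' @export
patternCorrelation <- function(a, b, genes = NULL, groups = NULL) {
    if (is(a, "GroupProfile")) a <- profileMean(a)
    if (is(b, "GroupProfile")) b <- profileMean(b)
    if (is.null(genes)) genes <- intersect(colnames(a), colnames(b))
    if (is.null(groups)) groups <- intersect(rownames(a), rownames(b))
    a <- a[groups, genes, drop = FALSE]
    b <- b[groups, genes, drop = FALSE]
    va <- as.vector(a); vb <- as.vector(b)
    if (length(va) < 3) stop("fewer than 3 grid points after intersection")
    if (sd(va) == 0 || sd(vb) == 0)
        stop("constant pattern vector: correlation undefined")
    cor(va, vb)
}

#' PCA-space cell-type correlation with species-component removal
#'
#' Measures global transcriptional similarity of cell types across
#' species. Cells are subsampled per (species, group) to balance
#' representation, the species matrices are concatenated, genes are
#' z-scored across the concatenated cells, and the result is reduced by
#' PCA. Because species mean differences survive gene-wise scaling of the
#' pooled data, the leading components are dominated by species identity
#' rather than cell-type biology; the top `drop_top` components are
#' therefore discarded. The remaining coordinates are averaged per
#' (species, group) and correlated pairwise. Hierarchical clustering
#' (average linkage on correlation distance) provides a display ordering.
#'
#' @param matrices named list (by species tag) of [CellExperiment-class]
#'   objects on a shared gene space (shared `geneIds()` order is
#'   intersected).
#' @param group_key `colData` column defining groups (default
#'   `"cell_type"`).
#' @param n_pcs number of principal components (default 50; capped at the
#'   data's rank).
#' @param drop_top number of leading components to discard (default 2).
#' @param subsample_cap per-(species, group) cell cap (default 2000).
#' @param seed integer seed for subsampling.
#' @return a list with `correlation` ((species, group) x (species, group)
#'   Pearson matrix), `order` (dendrogram label order) and `n_cells`
#'   (cells used per species-group).
#' @export
pcaGroupCorrelation <- function(matrices, group_key = "cell_type",
                                n_pcs = 50, drop_top = 2,
                                subsample_cap = 2000, seed = 1) {
    if (n_pcs <= drop_top) stop("n_pcs must exceed drop_top")
    genes <- Reduce(intersect, lapply(matrices, geneIds))
    if (!length(genes)) stop("no shared genes across species")
    rng <- .localSeed(seed)
    on.exit(rng(), add = TRUE)

    blocks <- list(); labels <- list()
    for (sp in names(matrices)) {
        x <- matrices[[sp]]
        ln <- lognorm(x)
        rownames(ln) <- geneIds(x)
        ln <- ln[genes, , drop = FALSE]
        grp <- as.character(
            SummarizedExperiment::colData(x)[[group_key]])
        take <- integer()
        for (g in sort(unique(grp))) {
            idx <- which(grp == g)
            if (length(idx) < 3) {
                warning(sprintf("group '%s' in species '%s' has <3 cells; excluded",
                                g, sp))
                next
            }
            if (length(idx) > subsample_cap)
                idx <- sort(sample(idx, subsample_cap))
            take <- c(take, idx)
        }
        blocks[[sp]] <- ln[, take, drop = FALSE]
        labels[[sp]] <- paste(sp, grp[take], sep = ":")
    }
    cells <- do.call(cbind, blocks)
    lab <- unlist(labels, use.names = FALSE)
    # z-score genes over the concatenated cells: species mean differences
    # survive and concentrate in the leading components
    mu <- rowMeans(cells)
    sdv <- apply(cells, 1, sd)
    cells <- (cells - mu) / ifelse(sdv > 0, sdv, 1)
    cells[sdv == 0, ] <- 0
    n_pcs <- min(n_pcs, nrow(cells) - 1, ncol(cells) - 1)
    if (n_pcs <= drop_top) stop("n_pcs must exceed drop_top")
    pc <- prcomp(t(cells), center = TRUE, scale. = FALSE, rank. = n_pcs)
    pc <- .canonicalSigns(pc)
    coords <- pc$x[, (drop_top + 1):n_pcs, drop = FALSE]
    centroid <- rowsum(coords, lab) / as.vector(table(lab)[sort(unique(lab))])
    cmat <- cor(t(centroid))
    ord <- if (nrow(cmat) > 2) {
        hc <- hclust(as.dist(1 - cmat), method = "average")
        rownames(cmat)[hc$order]
    } else rownames(cmat)
    list(correlation = cmat, order = ord,
         n_cells = table(lab))
}

# Orient every principal component so its largest-magnitude loading is
# positive; removes the SVD sign indeterminacy so results do not depend
# on storage order of the input.
.canonicalSigns <- function(pc) {
    flip <- apply(pc$rotation, 2, function(v)
        sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    pc$rotation <- sweep(pc$rotation, 2, flip, "*")
    pc$x <- sweep(pc$x, 2, flip, "*")
    pc
}

# Run code under a temporary RNG state; returns a restorer function.
.localSeed <- function(seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    function() {
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    }
}
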