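#' Select highly variable genes by binned normalized dispersion
#'
#' Genes detected in at least `min_cells` cells are ranked by normalized
#' dispersion: dispersion = variance / mean of the lognorm values, z-scored
#' within 20 equal-frequency mean-expression bins so that the ranking is
#' not confounded by the mean-variance relationship. The top `n` genes are
#' returned in rank order.
#'
#' @param x a [CellExperiment-class] with a `"lognorm"` assay.
#' @param n number of genes to return (default 3000).
#' @param min_cells minimum number of expressing cells (default 20).
#' @param n_bins number of mean-expression bins (default 20).
#' @return character vector of gene ids, most variable first.
#' @export
selectVariableGenes <- function(x, n = 3000, min_cells = 20, n_bins = 20) {
    ln <- lognorm(x)
    rownames(ln) <- geneIds(x)
    detected <- rowSums(ln > 0)
    ln <- ln[detected >= min_cells, , drop = FALSE]
    if (nrow(ln) < n)
        stop(sprintf("requested %d genes but only %d are detected in >= %d cells",
                     n, nrow(ln), min_cells))
    mu <- rowMeans(ln)
    v <- apply(ln, 1, var)
    disp <- ifelse(mu > 0, v / mu, 0)
    bins <- .equalFreqBins(mu, min(n_bins, length(mu)))
    z <- disp
    for (b in unique(bins)) {
        i <- bins == b
        s <- sd(disp[i])
        z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
    }
    ord <- order(-z, names(z))
    names(z)[ord][seq_len(n)]
}

# equal-frequency binning by rank; ties keep a deterministic assignment
.equalFreqBins <- function(values, n_bins) {
    r <- rank(values, ties.method = "first")
    as.integer(ceiling(r / (length(values) / n_bins)))
}

#' Discover gene sets by correlation clustering of variable genes
#'
#' Computes the gene-gene Pearson correlation matrix across cells,
#' represents each gene by its correlation row, and applies Ward
#' hierarchical clustering with Euclidean distance. The tree is cut into
#' `n_clusters` candidate sets; sets whose mean pairwise intra-set
#' correlation falls below `min_corr` (singletons count as 0) are dropped
#' as noise. Surviving sets are named `G1..Gk` in descending size.
#'
#' @param x a [CellExperiment-class] with a `"lognorm"` assay.
#' @param genes character vector of gene ids to cluster (typically from
#'   [selectVariableGenes()]).
#' @param n_clusters number of clusters to cut the tree into (default 20).
#' @param min_corr minimum mean intra-set correlation for retention
#'   (default 0.005).
#' @param h optional height threshold cutting the tree instead of
#'   `n_clusters`.
#' @return a [GeneSetCollection-class].
#' @export
discoverGeneSets <- function(x, genes, n_clusters = 20, min_corr = 0.005,
                             h = NULL) {
    stopifnot(length(genes) >= 2)
    ln <- lognorm(x)
    rownames(ln) <- geneIds(x)
    expr <- t(ln[genes, , drop = FALSE])
    sdv <- apply(expr, 2, sd)
    if (any(sdv == 0))
        stop("constant gene(s) among inputs: ",
             paste(head(genes[sdv == 0], 5), collapse = ", "))
    cmat <- cor(expr)
    hc <- hclust(dist(cmat), method = "ward.D2")
    cl <- if (is.null(h)) cutree(hc, k = min(n_clusters, length(genes)))
          else cutree(hc, h = h)
    members <- split(genes, cl)
    intra <- vapply(members, function(g) {
        if (length(g) < 2) return(0)
        sub <- cmat[g, g]
        mean(sub[upper.tri(sub)])
    }, numeric(1))
    keep <- intra >= min_corr
    members <- members[keep]; intra <- intra[keep]
    ord <- order(-lengths(members), vapply(members, min, character(1)))
    members <- members[ord]; intra <- intra[ord]
    nm <- sprintf("G%d", seq_along(members))
    geneSetCollection(setNames(members, nm), setNames(intra, nm),
                      provenance = list(n_variable_genes = length(genes),
                                        n_clusters_requested = n_clusters,
                                        min_corr = min_corr))
}

#' Gene-set activation scores with expression-matched background
#'
#' The activation score of a cell for a gene set is the mean lognorm
#' expression of the set's members minus the mean expression of an
#' expression-matched background. Genes are binned by overall mean
#' expression into `n_bins` equal-frequency bins; for each member,
#' `background_size` genes are sampled (seeded, without replacement) from
#' the member's bin excluding all set members. When a bin's eligible pool
#' has at most `background_size` genes the whole pool is used, which makes
#' small fixtures deterministic. The background is the union of the
#' per-member draws.
#'
#' @param x a [CellExperiment-class] with a `"lognorm"` assay.
#' @param sets a [GeneSetCollection-class].
#' @param n_bins number of expression bins (default 25).
#' @param background_size background genes per member (default 50).
#' @param seed integer seed for background sampling.
#' @return cells x sets score matrix with the scoring configuration in
#'   attribute `"score_config"`.
#' @export
scoreGeneSets <- function(x, sets, n_bins = 25, background_size = 50,
                          seed = 1) {
    ln <- lognorm(x)
    rownames(ln) <- geneIds(x)
    sl <- geneSets(sets)
    missing <- setdiff(unlist(sl, use.names = FALSE), rownames(ln))
    if (length(missing))
        stop("set members absent from the matrix: ",
             paste(head(missing, 5), collapse = ", "))
    mu <- rowMeans(ln)
    bins <- .equalFreqBins(mu, min(n_bins, length(mu)))
    names(bins) <- rownames(ln)
    rng <- .localSeed(seed)
    on.exit(rng(), add = TRUE)
    scores <- matrix(0, nrow = ncol(ln), ncol = length(sl),
                     dimnames = list(colnames(ln), names(sl)))
    for (s in names(sl)) {
        members <- sl[[s]]
        bg <- character()
        for (g in members) {
            pool <- names(bins)[bins == bins[[g]]]
            pool <- setdiff(pool, members)
            if (!length(pool)) next
            bg <- c(bg, if (length(pool) <= background_size) pool
                    else sample(pool, background_size))
        }
        bg <- unique(bg)
        if (!length(bg))
            stop("empty background pool for every member of set ", s)
        mem_mean <- colMeans(ln[members, , drop = FALSE])
        bg_mean <- colMeans(ln[bg, , drop = FALSE])
        scores[, s] <- mem_mean - bg_mean
    }
    attr(scores, "score_config") <- list(n_bins = n_bins,
                                         background_size = background_size,
                                         seed = seed)
    scores
}

#' Rank genes by Welch's t-statistic between two groups
#'
#' Computes Welch's unequal-variance t-statistic per gene on the lognorm
#' layer, with per-group variances floored at `var_floor` to keep the
#' statistic finite for near-constant genes, and returns the `top_n` genes
#' by descending t (ties broken by gene id). Used to build
#' disease/condition signatures (e.g. a T1D score from the top 50 genes).
#'
#' @param x a [CellExperiment-class] with a `"lognorm"` assay.
#' @param group_key `colData` column holding the group tags.
#' @param group_a,group_b the two group tags to contrast (t > 0 means
#'   higher in `group_a`).
#' @param top_n number of genes to return (default 50).
#' @param var_floor variance floor (default 1e-9).
#' @return `data.frame` with columns `gene`, `t`, `mean_a`, `mean_b`,
#'   ordered by descending t.
#' @export
rankGenesWelch <- function(x, group_key, group_a, group_b, top_n = 50,
                           var_floor = 1e-9) {
    grp <- as.character(SummarizedExperiment::colData(x)[[group_key]])
    ln <- lognorm(x)
    rownames(ln) <- geneIds(x)
    ia <- which(grp == group_a); ib <- which(grp == group_b)
    if (length(ia) < 2 || length(ib) < 2)
        stop("each group needs at least 2 cells")
    a <- ln[, ia, drop = FALSE]; b <- ln[, ib, drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- pmax(apply(a, 1, var), var_floor)
    vb <- pmax(apply(b, 1, var), var_floor)
    tstat <- (ma - mb) / sqrt(va / length(ia) + vb / length(ib))
    ord <- order(-tstat, rownames(ln))
    res <- data.frame(gene = rownames(ln)[ord], t = tstat[ord],
                      mean_a = ma[ord], mean_b = mb[ord], row.names = NULL)
    head(res, top_n)
}
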