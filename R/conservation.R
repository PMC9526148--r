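#' Detect cell-type-enriched marker genes
#'
#' For every cell type `c` and gene `j`, compares the mean log-normalized
#' expression in `c` against the cell-count-weighted mean over all other
#' cells: `log2fc = log2((E_c + eps) / (E_rest + eps))`. A gene is an
#' enriched marker of `c` when it is expressed in at least `frac_threshold`
#' of the cells of `c` (5% by default) and `log2fc` exceeds `fc_threshold`
#' (0.5 by default, i.e. at least a 1.4-fold increase over the rest).
#'
#' @param profile a [GroupProfile-class] over cell types (>= 2 groups).
#' @param frac_threshold minimum expressing-cell fraction within the type
#'   (default 0.05).
#' @param fc_threshold log2 fold-change threshold, exclusive (default 0.5).
#' @param epsilon pseudocount guarding zero denominators (default 1e-9).
#' @param frac_strict use a strict `>` comparison for the fraction gate
#'   instead of the default inclusive `>=`.
#' @return a `data.frame` ("marker table") with columns `cell_type`,
#'   `gene`, `log2fc`, `frac_in_type`, `is_enriched`.
#' @export
findEnrichedMarkers <- function(profile, frac_threshold = 0.05,
                                fc_threshold = 0.5, epsilon = 1e-9,
                                frac_strict = FALSE) {
    m <- profileMean(profile)
    f <- profileFrac(profile)
    n <- profileCells(profile)
    if (nrow(m) < 2) stop("at least two groups are required")
    total <- colSums(m * n)        # per gene, sum over groups of n_g * m_gj
    out <- lapply(rownames(m), function(g) {
        e_c <- m[g, ]
        e_rest <- (total - n[g] * e_c) / (sum(n) - n[g])
        lfc <- log2((e_c + epsilon) / (e_rest + epsilon))
        pass_frac <- if (frac_strict) f[g, ] > frac_threshold
                     else f[g, ] >= frac_threshold
        data.frame(cell_type = g, gene = colnames(m), log2fc = lfc,
                   frac_in_type = f[g, ],
                   is_enriched = pass_frac & lfc > fc_threshold,
                   row.names = NULL)
    })
    do.call(rbind, out)
}

#' Classify expression-level conservation against a reference species
#'
#' For every gene and cell type where the reference species passes the
#' expression criterion (expressed in more than `expressed_threshold` of
#' the type's cells), the target species is classified as: `conserved`
#' (passes in the same cell type), `loss` (fails there but passes in at
#' least one other cell type), or `absent` (passes nowhere). Additionally,
#' `gain` is called when the reference fails the criterion in a cell type
#' but the target passes it there.
#'
#' @param ref,target [GroupProfile-class] objects on a shared gene space
#'   and cell-type vocabulary (intersections are taken).
#' @param expressed_threshold expressing-cell fraction defining
#'   "expressed" (strict `>`, default 0.05).
#' @return a `data.frame` ("conservation calls") with columns `gene`,
#'   `cell_type`, `category`.
#' @export
classifyExpressionConservation <- function(ref, target,
                                           expressed_threshold = 0.05) {
    genes <- intersect(colnames(profileFrac(ref)),
                       colnames(profileFrac(target)))
    if (!length(genes)) stop("no shared genes between profiles")
    types <- intersect(rownames(profileFrac(ref)),
                       rownames(profileFrac(target)))
    fr <- profileFrac(ref)[types, genes, drop = FALSE] > expressed_threshold
    ft <- profileFrac(target)[types, genes, drop = FALSE] >
        expressed_threshold
    calls <- list()
    for (ct in types) {
        other_pass <- colSums(ft[setdiff(types, ct), , drop = FALSE]) > 0
        ref_pass <- fr[ct, ]
        tgt_pass <- ft[ct, ]
        category <- rep(NA_character_, length(genes))
        category[ref_pass & tgt_pass] <- "conserved"
        category[ref_pass & !tgt_pass & other_pass] <- "loss"
        category[ref_pass & !tgt_pass & !other_pass] <- "absent"
        category[!ref_pass & tgt_pass] <- "gain"
        keep <- !is.na(category)
        calls[[ct]] <- data.frame(gene = genes[keep], cell_type = ct,
                                  category = category[keep],
                                  row.names = NULL)
    }
    do.call(rbind, calls)
}

#' Classify marker-level conservation against a reference species
#'
#' For every reference-enriched (gene, cell type) pair the target species
#' is classified as: `conserved` (enriched marker of the same cell type —
#' same-type matches take precedence over any other enrichment), `switch`
#' (enriched marker of a different cell type), `loss` (not enriched
#' anywhere but expressed in more than `expressed_threshold` of the cells
#' of at least one target cell type), or `absent` (neither).
#'
#' @param ref_markers,tgt_markers marker tables from
#'   [findEnrichedMarkers()] on a shared gene space and vocabulary.
#' @param tgt_profile the target [GroupProfile-class] (for the expressed
#'   test behind `loss`).
#' @param expressed_threshold expressing-cell fraction defining
#'   "expressed" (strict `>`, default 0.05).
#' @return a `data.frame` with columns `gene`, `cell_type`, `category`.
#' @export
classifyMarkerConservation <- function(ref_markers, tgt_markers,
                                       tgt_profile,
                                       expressed_threshold = 0.05) {
    enr_ref <- ref_markers[ref_markers$is_enriched, , drop = FALSE]
    if (!nrow(enr_ref))
        return(data.frame(gene = character(), cell_type = character(),
                          category = character()))
    ft <- profileFrac(tgt_profile)
    shared <- intersect(unique(ref_markers$gene), unique(tgt_markers$gene))
    if (!length(shared)) stop("no shared genes between marker tables")
    enr_ref <- enr_ref[enr_ref$gene %in% shared, , drop = FALSE]
    enr_tgt <- tgt_markers[tgt_markers$is_enriched, , drop = FALSE]
    tgt_types <- split(enr_tgt$cell_type, enr_tgt$gene)
    expressed_any <- colnames(ft)[colSums(ft > expressed_threshold) > 0]
    category <- character(nrow(enr_ref))
    for (i in seq_len(nrow(enr_ref))) {
        g <- enr_ref$gene[i]; ct <- enr_ref$cell_type[i]
        tt <- tgt_types[[g]]
        category[i] <- if (!is.null(tt) && ct %in% tt) "conserved"
            else if (!is.null(tt) && length(tt)) "switch"
            else if (g %in% expressed_any) "loss"
            else "absent"
    }
    data.frame(gene = enr_ref$gene, cell_type = enr_ref$cell_type,
               category = category, row.names = NULL)
}

#' Per-cell-type Venn counts of marker sets across species
#'
#' Partitions, for every cell type, the union of enriched marker genes
#' into the exclusive Venn regions of the species' marker sets and counts
#' genes per region.
#'
#' @param markers_by_species named list (by species tag) of marker tables
#'   from [findEnrichedMarkers()].
#' @return a `data.frame` with columns `cell_type`, `region` (species tags
#'   joined by `&`), `n_genes`.
#' @export
markerOverlap <- function(markers_by_species) {
    stopifnot(length(markers_by_species) >= 2)
    species <- names(markers_by_species)
    types <- sort(unique(unlist(lapply(markers_by_species,
                                       function(m) m$cell_type))))
    out <- list()
    for (ct in types) {
        sets <- lapply(markers_by_species, function(m)
            m$gene[m$is_enriched & m$cell_type == ct])
        univ <- unique(unlist(sets))
        if (!length(univ)) next
        membership <- vapply(sets, function(s) univ %in% s,
                             logical(length(univ)))
        membership <- matrix(membership, nrow = length(univ),
                             dimnames = list(univ, species))
        region <- apply(membership, 1, function(b)
            paste(species[b], collapse = "&"))
        tab <- table(region[region != ""])
        out[[ct]] <- data.frame(cell_type = ct, region = names(tab),
                                n_genes = as.integer(tab), row.names = NULL)
    }
    if (!length(out))
        return(data.frame(cell_type = character(), region = character(),
                          n_genes = integer()))
    do.call(rbind, out)
}
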