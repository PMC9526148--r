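#' Resolve an ortholog table to a one-to-one gene space
#'
#' Drops records whose genes are undetected in any species, then resolves
#' one-to-many mappings: whenever a gene of species `s` occurs in several
#' records with distinct partners in species `t`, only the record whose
#' `t`-partner has the highest overall mean log-normalized expression in
#' the `t` data survives. Ties are broken toward the lexicographically
#' smallest partner id, so resolution is deterministic and invariant to
#' record order. With three or more species the contest is applied to
#' every ordered species pair and a record must win all of its contests.
#'
#' @param table an unresolved [OrthologTable-class].
#' @param expr_by_species named list (by species tag) of
#'   [CellExperiment-class] (with `"lognorm"`) or [GroupProfile-class]
#'   objects providing expression for that species' genes.
#' @return the resolved [OrthologTable-class]; `orthoRecords(., kept_only
#'   = TRUE)` gives the surviving one-to-one records, and the full record
#'   table gains `cardinality` and `kept` columns.
#' @export
resolveOrthologs <- function(table, expr_by_species) {
    stopifnot(is(table, "OrthologTable"))
    if (!all(table@species %in% names(expr_by_species)))
        stop("expression missing for species: ",
             paste(setdiff(table@species, names(expr_by_species)),
                   collapse = ", "))
    rec <- unique(table@records)
    rownames(rec) <- NULL
    sp <- table@species
    expr <- lapply(expr_by_species[sp], .meanExprVector)

    # detection: a gene is detected when expression data exists for it
    detected <- rep(TRUE, nrow(rec))
    for (s in sp) detected <- detected & rec[[s]] %in% names(expr[[s]])
    cardinality <- rep("one_to_one", nrow(rec))
    kept <- detected

    idx_det <- which(detected)
    for (s in sp) {
        for (t in setdiff(sp, s)) {
            ids_s <- rec[[s]][idx_det]
            dup <- unique(ids_s[duplicated(ids_s)])
            for (g in dup) {
                rows <- idx_det[ids_s == g]
                partners <- rec[[t]][rows]
                if (length(unique(partners)) == 1) next
                cardinality[rows] <- "ambiguous"
                e <- expr[[t]][partners]
                if (anyNA(e))
                    stop("expression missing for ambiguous candidate: ",
                         paste(partners[is.na(e)], collapse = ", "))
                # max expression, ties to lexicographically smallest id
                ord <- order(-e, partners)
                kept[rows[ord[-1]]] <- FALSE
            }
        }
    }
    rec$cardinality <- cardinality
    rec$kept <- kept
    new("OrthologTable", records = rec, species = sp, resolved = TRUE)
}

.meanExprVector <- function(obj) {
    if (is(obj, "GroupProfile")) {
        w <- profileCells(obj)
        m <- colSums(profileMean(obj) * w) / sum(w)
        m
    } else if (is(obj, "CellExperiment")) {
        ln <- lognorm(obj)
        setNames(rowMeans(ln), SummarizedExperiment::rowData(obj)$native_id)
    } else stop("unsupported expression carrier of class ", class(obj)[1])
}

#' Rename a matrix into a resolved cross-species gene space
#'
#' Subsets a matrix to the genes covered by a resolved ortholog table and
#' sets `common_id` to the identifier of the chosen namespace species.
#' Output gene order follows the table's record order.
#'
#' @param x a [CellExperiment-class].
#' @param table a resolved [OrthologTable-class].
#' @param species the species tag whose ids `x` currently carries.
#' @param namespace the species tag whose ids become `common_id` (default:
#'   first species of the table, conventionally human).
#' @return the renamed, subset [CellExperiment-class].
#' @export
applyMapping <- function(x, table, species, namespace = table@species[1]) {
    if (!isResolved(table)) stop("ortholog table is not resolved")
    stopifnot(species %in% table@species, namespace %in% table@species)
    rec <- orthoRecords(table, kept_only = TRUE)
    ids <- SummarizedExperiment::rowData(x)$native_id
    hit <- rec[[species]] %in% ids
    rec <- rec[hit, , drop = FALSE]
    if (!nrow(rec)) stop("no mappable genes")
    out <- x[match(rec[[species]], ids), ]
    SummarizedExperiment::rowData(out)$common_id <- rec[[namespace]]
    out
}

#' Fraction of total expression variance retained by a gene subset
#'
#' The ratio of summed per-gene lognorm variances over the subset to the
#' sum over all genes. Used to quantify how much of a species' expression
#' variation the cross-species mappable gene space retains.
#'
#' @param x a [CellExperiment-class] with a `"lognorm"` assay.
#' @param gene_subset character vector of gene ids (native, or common if
#'   set), a subset of the matrix's genes.
#' @return a proportion in `[0, 1]`.
#' @export
explainedVarianceFraction <- function(x, gene_subset) {
    ln <- lognorm(x)
    rownames(ln) <- geneIds(x)
    missing <- setdiff(gene_subset, rownames(ln))
    if (length(missing))
        stop("genes absent from the matrix: ",
             paste(head(missing, 5), collapse = ", "))
    v <- apply(ln, 1, var)
    total <- sum(v)
    if (total == 0) stop("total variance is zero")
    sum(v[rownames(ln) %in% gene_subset]) / total
}
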