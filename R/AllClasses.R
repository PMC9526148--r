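#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom stats cor dist hclust cutree median prcomp quantile rnbinom
#'   rnorm runif rbinom sd var as.dist setNames plogis
#' @importFrom utils read.delim write.table head
NULL

#' Cell-level expression container for cross-species islet data
#'
#' `CellExperiment` extends
#' [SingleCellExperiment::SingleCellExperiment] with the column and row
#' annotations the cross-species pipeline relies on. Genes are rows, cells
#' are columns. The `"counts"` assay holds raw UMI counts; the `"lognorm"`
#' assay, once computed by [normalizeLog()], holds `log(1 + count/sizefactor)`
#' values. Column metadata must carry `species`, `batch` and `cell_type`
#' tags (plus an optional `state` tag); row metadata must carry a unique
#' `native_id` per gene and may carry a `common_id` once genes have been
#' renamed into a cross-species namespace by [applyMapping()].
#'
#' The validity method enforces: presence of the required metadata columns,
#' uniqueness of `native_id`, finite `lognorm` values, and the
#' zero-preservation contract that every zero count is a zero in `lognorm`
#' (batch adjustment never invents expression where none was observed).
#'
#' @slot int_colData,int_elementMetadata,colData,assays inherited from
#'   `SingleCellExperiment`.
#' @seealso [cellExperiment()] for the user-facing constructor.
#' @export
setClass("CellExperiment", contains = "SingleCellExperiment")

.validCellExperiment <- function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("species", "batch", "cell_type")) {
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!"native_id" %in% colnames(rd)) {
        msg <- c(msg, "rowData column 'native_id' is required")
    } else if (anyDuplicated(rd$native_id)) {
        msg <- c(msg, "gene native_id values must be unique")
    }
    if ("lognorm" %in% SummarizedExperiment::assayNames(object)) {
        ln <- SummarizedExperiment::assay(object, "lognorm")
        if (any(!is.finite(as.matrix(ln))))
            msg <- c(msg, "lognorm contains non-finite values")
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(as.matrix(ln)[as.matrix(cts) == 0] != 0))
            msg <- c(msg, "lognorm must be zero wherever counts are zero")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("CellExperiment", .validCellExperiment)

#' Construct a CellExperiment
#'
#' @param counts gene x cell matrix (base or [Matrix::Matrix]) of
#'   non-negative integer UMI counts.
#' @param cell_meta `data.frame` with one row per cell and columns
#'   `species`, `batch`, `cell_type` and optionally `state`. Row names (or a
#'   `cell_id` column) become cell identifiers.
#' @param gene_meta `data.frame` with one row per gene and column
#'   `native_id` (unique) and optionally `common_id`.
#' @param lognorm optional gene x cell matrix of log-normalized expression.
#' @return a [CellExperiment-class] object.
#' @examples
#' counts <- matrix(rpois(20, 2), nrow = 5,
#'                  dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
#' ce <- cellExperiment(counts,
#'     cell_meta = data.frame(species = "human", batch = "b1",
#'                            cell_type = rep(c("alpha", "beta"), 2),
#'                            row.names = colnames(counts)),
#'     gene_meta = data.frame(native_id = rownames(counts)))
#' ce
#' @export
cellExperiment <- function(counts, cell_meta, gene_meta, lognorm = NULL) {
    if (!is.null(cell_meta$cell_id)) {
        rownames(cell_meta) <- cell_meta$cell_id
        cell_meta$cell_id <- NULL
    }
    if (is.null(colnames(counts))) colnames(counts) <- rownames(cell_meta)
    if (is.null(rownames(counts))) rownames(counts) <- gene_meta$native_id
    assays <- list(counts = counts)
    if (!is.null(lognorm)) {
        dimnames(lognorm) <- dimnames(counts)
        assays$lognorm <- lognorm
    }
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(cell_meta),
        rowData = S4Vectors::DataFrame(gene_meta))
    new("CellExperiment", sce)
}

#' Access the log-normalized assay
#'
#' @param x a [CellExperiment-class].
#' @return the `"lognorm"` assay as a base matrix.
#' @export
lognorm <- function(x) {
    if (!"lognorm" %in% SummarizedExperiment::assayNames(x))
        stop("no 'lognorm' assay; run normalizeLog() first")
    as.matrix(SummarizedExperiment::assay(x, "lognorm"))
}

#' @describeIn lognorm replace the log-normalized assay.
#' @param value replacement matrix.
#' @export
`lognorm<-` <- function(x, value) {
    SummarizedExperiment::assay(x, "lognorm") <- value
    x
}

setMethod("show", "CellExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("CellExperiment: %d genes x %d cells\n",
                nrow(object), ncol(object)))
    cat("  species:", paste(unique(cd$species), collapse = ", "), "\n")
    cat("  cell types:", paste(unique(cd$cell_type), collapse = ", "), "\n")
    cat("  assays:",
        paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

#' Per-group expression summary
#'
#' For every (group, gene) pair, a `GroupProfile` stores the mean
#' log-normalized expression, the fraction of the group's cells with
#' non-zero expression, and the group's cell count. It is the common input
#' to marker detection, conservation classification and pattern
#' correlation.
#'
#' @slot mean groups x genes matrix of mean lognorm expression.
#' @slot frac groups x genes matrix of expressing-cell fractions.
#' @slot ncells named integer vector of group sizes.
#' @seealso [computeGroupProfile()]
#' @export
setClass("GroupProfile",
    representation(mean = "matrix", frac = "matrix", ncells = "numeric"))

setValidity("GroupProfile", function(object) {
    msg <- NULL
    if (!identical(dim(object@mean), dim(object@frac)))
        msg <- c(msg, "mean and frac must have identical dimensions")
    if (!identical(rownames(object@mean), names(object@ncells)))
        msg <- c(msg, "group names of mean and ncells must match")
    if (any(object@frac < 0 | object@frac > 1))
        msg <- c(msg, "frac must lie in [0, 1]")
    if (any(object@ncells < 1))
        msg <- c(msg, "every group must contain at least one cell")
    if (any(!is.finite(object@mean)))
        msg <- c(msg, "mean must be finite")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn GroupProfile group x gene matrix of mean expression.
#' @param object,x a `GroupProfile`.
#' @export
profileMean <- function(x) x@mean

#' @describeIn GroupProfile group x gene matrix of expressing fractions.
#' @export
profileFrac <- function(x) x@frac

#' @describeIn GroupProfile named vector of group cell counts.
#' @export
profileCells <- function(x) x@ncells

setMethod("show", "GroupProfile", function(object) {
    cat(sprintf("GroupProfile: %d groups x %d genes\n",
                nrow(object@mean), ncol(object@mean)))
    cat("  groups:", paste(rownames(object@mean), collapse = ", "), "\n")
})

#' Cross-species ortholog table
#'
#' One row per candidate ortholog tuple; one column of gene identifiers per
#' species. Before resolution a gene may occur in several rows (one-to-many
#' mappings from duplications or annotation gaps). [resolveOrthologs()]
#' reduces the table to at most one use of every gene per species by
#' keeping, within each ambiguity group, the row whose candidate partner is
#' most highly expressed in the partner's own data.
#'
#' @slot records data.frame with one `<species>` column per species plus,
#'   after resolution, logical `kept` and character `cardinality` columns.
#' @slot species character vector of species tags (column names).
#' @slot resolved logical flag.
#' @export
setClass("OrthologTable",
    representation(records = "data.frame", species = "character",
                   resolved = "logical"))

setValidity("OrthologTable", function(object) {
    msg <- NULL
    if (!all(object@species %in% colnames(object@records)))
        msg <- c(msg, "records must contain one column per species")
    if (object@resolved) {
        kept <- object@records[isTRUE(object@resolved) &
                               object@records$kept, , drop = FALSE]
        for (sp in object@species) {
            if (anyDuplicated(kept[[sp]]))
                msg <- c(msg, sprintf(
                    "resolved table reuses a %s gene in several records", sp))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn OrthologTable construct an (unresolved) ortholog table.
#' @param records data.frame of id tuples, one column per species.
#' @param species character vector naming the id columns; defaults to all
#'   columns of `records`.
#' @export
orthologTable <- function(records, species = colnames(records)) {
    records <- as.data.frame(records)
    for (sp in species) records[[sp]] <- as.character(records[[sp]])
    new("OrthologTable", records = records, species = species,
        resolved = FALSE)
}

#' @describeIn OrthologTable the record data.frame (kept rows only when
#'   `kept_only = TRUE` on a resolved table).
#' @param kept_only drop discarded records of a resolved table.
#' @export
orthoRecords <- function(x, kept_only = FALSE) {
    rec <- x@records
    if (kept_only) {
        if (!x@resolved) stop("table is not resolved")
        rec <- rec[rec$kept, , drop = FALSE]
        rownames(rec) <- NULL
    }
    rec
}

#' @describeIn OrthologTable TRUE once the table has been resolved.
#' @export
isResolved <- function(x) x@resolved

setMethod("show", "OrthologTable", function(object) {
    cat(sprintf("OrthologTable: %d records across %s (%s)\n",
                nrow(object@records),
                paste(object@species, collapse = "/"),
                if (object@resolved) "resolved" else "unresolved"))
})

#' Named gene sets discovered by correlation clustering
#'
#' @slot sets named list of character vectors (gene ids), each of length
#'   >= 1; retained sets have mean intra-set Pearson correlation at or above
#'   the discovery threshold.
#' @slot meanIntraCor named numeric, mean pairwise intra-set correlation
#'   (singletons are assigned 0).
#' @slot provenance list with the discovery parameters
#'   (`n_variable_genes`, `n_clusters_requested`, `min_corr`).
#' @seealso [discoverGeneSets()], [readGMT()], [writeGMT()]
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", meanIntraCor = "numeric",
                   provenance = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- NULL
    if (!identical(names(object@sets), names(object@meanIntraCor)))
        msg <- c(msg, "sets and meanIntraCor must share names")
    all_genes <- unlist(object@sets, use.names = FALSE)
    if (anyDuplicated(all_genes))
        msg <- c(msg, "gene sets must be disjoint")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn GeneSetCollection construct a collection.
#' @param sets named list of character vectors.
#' @param meanIntraCor named numeric of mean intra-set correlations.
#' @param provenance list of discovery parameters.
#' @export
geneSetCollection <- function(sets, meanIntraCor = NULL, provenance = list()) {
    if (is.null(meanIntraCor))
        meanIntraCor <- setNames(rep(NA_real_, length(sets)), names(sets))
    new("GeneSetCollection", sets = sets, meanIntraCor = meanIntraCor,
        provenance = provenance)
}

#' @describeIn GeneSetCollection the named list of member genes.
#' @param object,x a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection mean intra-set correlations.
#' @export
setCorrelations <- function(x) x@meanIntraCor

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets, %d genes\n",
                length(object@sets),
                length(unlist(object@sets, use.names = FALSE))))
    if (length(object@sets)) {
        sizes <- lengths(object@sets)
        cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                              collapse = ", "), "\n")
    }
})

#' Fitted gene-set-space reference for query projection
#'
#' Stores everything needed to project query cells onto a reference state
#' map: the gene sets, the per-set z-scaling fitted on reference activation
#' scores, the principal-component loadings of the scaled reference score
#' matrix, the reference cell coordinates and labels, and the kNN settings
#' for label transfer.
#'
#' @slot geneSets the [GeneSetCollection-class] the reference was scored on.
#' @slot scalingMean,scalingSd named per-set scaling parameters (reference
#'   fit; queries are always scaled with these, never re-fitted).
#' @slot loadings sets x components orthonormal loading matrix.
#' @slot refCoords reference cells x components coordinate matrix.
#' @slot refLabels character labels, one per reference cell.
#' @slot k neighbor count for label transfer.
#' @slot nComponents number of retained components.
#' @slot scoreConfig list of scoring parameters (`n_bins`,
#'   `background_size`, `seed`) reused when scoring queries.
#' @seealso [fitReference()], [projectAndClassify()]
#' @export
setClass("ReferenceModel",
    representation(geneSets = "GeneSetCollection",
                   scalingMean = "numeric", scalingSd = "numeric",
                   loadings = "matrix", refCoords = "matrix",
                   refLabels = "character", k = "integer",
                   nComponents = "integer", scoreConfig = "list"))

setValidity("ReferenceModel", function(object) {
    msg <- NULL
    if (any(object@scalingSd <= 0))
        msg <- c(msg, "scaling sd must be positive for every retained set")
    if (object@k < 1) msg <- c(msg, "k must be >= 1")
    if (length(object@refLabels) != nrow(object@refCoords))
        msg <- c(msg, "labels must cover all reference cells")
    ortho <- crossprod(object@loadings)
    if (max(abs(ortho - diag(ncol(object@loadings)))) > 1e-6)
        msg <- c(msg, "loadings must be orthonormal")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ReferenceModel", function(object) {
    cat(sprintf(
        "ReferenceModel: %d sets -> %d PCs, %d reference cells, k = %d\n",
        nrow(object@loadings), object@nComponents,
        nrow(object@refCoords), object@k))
    cat("  labels:", paste(unique(object@refLabels), collapse = ", "), "\n")
})

#' @describeIn ReferenceModel reference cell labels.
#' @param object,x a `ReferenceModel`.
#' @export
refLabels <- function(x) x@refLabels

#' @describeIn ReferenceModel reference coordinates in PC space.
#' @export
refCoords <- function(x) x@refCoords
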