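#' Read a cell matrix from Matrix Market + TSV annotations
#'
#' Expects the conventional trio `matrix.mtx` (genes x cells counts),
#' `genes.tsv` (`native_id` and optional `common_id`, no header),
#' `barcodes.tsv` (one cell id per line), plus `cell_meta.tsv` (TSV with
#' header: `cell_id`, `species`, `batch`, `cell_type`, optional `state`).
#' When `lognorm.mtx` is present it is loaded as the `"lognorm"` assay.
#'
#' @param dir directory containing the files.
#' @return a [CellExperiment-class].
#' @export
readCellMatrix <- function(dir) {
    counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
    genes <- read.delim(file.path(dir, "genes.tsv"), header = FALSE)
    colnames(genes) <- c("native_id", "common_id")[seq_len(ncol(genes))]
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    meta <- read.delim(file.path(dir, "cell_meta.tsv"))
    meta <- meta[match(barcodes, meta$cell_id), , drop = FALSE]
    dimnames(counts) <- list(genes$native_id, barcodes)
    ln <- NULL
    lnp <- file.path(dir, "lognorm.mtx")
    if (file.exists(lnp)) {
        ln <- as.matrix(Matrix::readMM(lnp))
        dimnames(ln) <- dimnames(counts)
    }
    cellExperiment(counts, meta, genes, lognorm = ln)
}

#' Write a cell matrix as Matrix Market + TSV annotations
#'
#' Inverse of [readCellMatrix()]; writes `matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`, `cell_meta.tsv` and, when present, `lognorm.mtx`.
#'
#' @param x a [CellExperiment-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCellMatrix <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cts <- SummarizedExperiment::assay(x, "counts")
    Matrix::writeMM(as(as(cts, "dMatrix"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    keep <- intersect(c("native_id", "common_id"), colnames(rd))
    write.table(rd[, keep, drop = FALSE], file.path(dir, "genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- cbind(cell_id = colnames(x), cd)
    write.table(cd, file.path(dir, "cell_meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if ("lognorm" %in% SummarizedExperiment::assayNames(x)) {
        Matrix::writeMM(as(Matrix::Matrix(lognorm(x), sparse = TRUE),
                           "CsparseMatrix"),
                        file.path(dir, "lognorm.mtx"))
    }
    invisible(dir)
}

#' Read / write ortholog tables as TSV
#'
#' The TSV carries one id column per species (header = species tags); a
#' resolved table additionally carries `cardinality` and `kept`.
#'
#' @param path TSV file path.
#' @return an [OrthologTable-class].
#' @export
readOrthologTable <- function(path) {
    df <- read.delim(path)
    sp <- setdiff(colnames(df), c("cardinality", "kept"))
    tab <- orthologTable(df[, sp, drop = FALSE], species = sp)
    if (all(c("cardinality", "kept") %in% colnames(df))) {
        tab@records$cardinality <- df$cardinality
        tab@records$kept <- as.logical(df$kept)
        tab@resolved <- TRUE
    }
    tab
}

#' @rdname readOrthologTable
#' @param table an [OrthologTable-class].
#' @export
writeOrthologTable <- function(table, path) {
    write.table(table@records, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write a group profile as TSV
#'
#' Long format: `group`, `gene`, `mean_expr`, `frac_expr`, `n_cells`.
#'
#' @param profile a [GroupProfile-class].
#' @param path output TSV path.
#' @export
writeGroupProfile <- function(profile, path) {
    m <- profileMean(profile); f <- profileFrac(profile)
    n <- profileCells(profile)
    df <- data.frame(
        group = rep(rownames(m), each = ncol(m)),
        gene = rep(colnames(m), times = nrow(m)),
        mean_expr = as.vector(t(m)), frac_expr = as.vector(t(f)),
        n_cells = rep(n, each = ncol(m)), row.names = NULL)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description (the mean intra-set correlation),
#' then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, character(1), 1)
    cors <- suppressWarnings(
        as.numeric(vapply(parts, `[`, character(1), 2)))
    geneSetCollection(sets, setNames(cors, names(sets)))
}

#' @rdname readGMT
#' @param sets a [GeneSetCollection-class].
#' @export
writeGMT <- function(sets, path) {
    sl <- geneSets(sets); cors <- setCorrelations(sets)
    lines <- vapply(names(sl), function(nm)
        paste(c(nm, format(cors[[nm]], digits = 10), sl[[nm]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
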