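# small in-code fixtures shared across test files

# CellExperiment from an explicit lognorm layer; counts are the expression
# indicator so the zero-consistency invariant holds by construction
ceFromLognorm <- function(ln, cell_type = "beta", batch = "b1",
                          species = "human", state = NULL) {
    if (is.null(dimnames(ln)))
        dimnames(ln) <- list(sprintf("g%03d", seq_len(nrow(ln))),
                             sprintf("c%03d", seq_len(ncol(ln))))
    cm <- data.frame(species = species, batch = batch,
                     cell_type = rep_len(cell_type, ncol(ln)),
                     row.names = colnames(ln))
    if (!is.null(state)) cm$state <- rep_len(state, ncol(ln))
    cellExperiment((ln > 0) * 1, cm,
                   data.frame(native_id = rownames(ln)), lognorm = ln)
}

ceFromCounts <- function(counts, cell_type = "beta", batch = "b1",
                         species = "human") {
    if (is.null(dimnames(counts)))
        dimnames(counts) <- list(sprintf("g%03d", seq_len(nrow(counts))),
                                 sprintf("c%03d", seq_len(ncol(counts))))
    cellExperiment(counts,
                   data.frame(species = species, batch = batch,
                              cell_type = rep_len(cell_type, ncol(counts)),
                              row.names = colnames(counts)),
                   data.frame(native_id = rownames(counts)))
}

# GroupProfile built directly from matrices
profileFromMatrices <- function(m, f, n) {
    new("GroupProfile", mean = m, frac = f,
        ncells = setNames(as.numeric(n), rownames(m)))
}

randomProfile <- function(n_genes, n_types, seed) {
    set.seed(seed)
    genes <- sprintf("g%02d", seq_len(n_genes))
    types <- paste0("t", seq_len(n_types))
    f <- matrix(runif(n_types * n_genes), n_types,
                dimnames = list(types, genes))
    # sprinkle exact zeros and values straddling the 5% threshold
    f[runif(length(f)) < 0.3] <- 0
    near <- runif(length(f)) < 0.2
    f[near] <- runif(sum(near), 0.02, 0.08)
    m <- matrix(runif(n_types * n_genes, 0, 3), n_types,
                dimnames = list(types, genes))
    m[f == 0] <- 0
    profileFromMatrices(m, f, sample(5:50, n_types, replace = TRUE))
}
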