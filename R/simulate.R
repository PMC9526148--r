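#' Configuration for the synthetic multi-species panel generator
#'
#' Describes a multi-species single-cell count panel with planted ground
#' truth: cell types with marker effects, per-target-species conservation
#' categories for those markers, correlated gene modules driven by rank-1
#' latent factors (optionally coupled to cell states), per-batch
#' expression shifts, and negative-binomial counts with mean-dependent
#' dropout. The first species is the reference.
#'
#' @param species character vector of species tags; the first is the
#'   reference.
#' @param cell_types named integer vector: cells per cell type (applies to
#'   every species).
#' @param n_genes total genes in the reference species.
#' @param n_markers planted enriched markers per cell type.
#' @param marker_log2fc planted marker effect on the count scale (log2).
#' @param conservation_spec named proportions over
#'   `conserved`/`loss`/`switch`/`absent`/`gain` governing how each
#'   reference marker behaves in each non-reference species (`gain` genes
#'   are near-silent in the reference and activated only in targets).
#' @param module_spec list of `list(n_genes =, latent_sd =)` correlated
#'   blocks (rank-1 Gaussian factor per block, log2 scale).
#' @param states optional named numeric vector of state proportions
#'   (applied within every cell type); state `i` additionally up-shifts
#'   the genes of module `i` by `state_log2fc`.
#' @param state_log2fc state activation effect on module genes (log2).
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param dropout `NULL` to disable, or `list(midpoint =, slope =)`:
#'   per-gene dropout probability `plogis(-slope * (log(mean) -
#'   midpoint))`, a logistic detection limit in the gene's mean.
#' @param n_batches batches per species (cells assigned at random).
#' @param batch_sd per-batch, per-gene log2 shift standard deviation.
#' @param depth mean counts per cell.
#' @param ambig_fraction fraction of mapped genes given an additional
#'   decoy ortholog record (one-to-many mapping with known, lower-expressed
#'   decoy partner).
#' @param seed integer seed; a fixed seed gives bit-identical panels.
#' @return a list of class `sim_config`.
#' @export
simConfig <- function(species = c("human", "pig"),
                      cell_types = c(alpha = 500, beta = 500,
                                     delta = 500, pp = 500),
                      n_genes = 2000,
                      n_markers = 40, marker_log2fc = 2,
                      conservation_spec = c(conserved = 0.4, loss = 0.25,
                                            switch = 0.2, absent = 0.1,
                                            gain = 0.05),
                      module_spec = list(list(n_genes = 40, latent_sd = 0.5),
                                         list(n_genes = 40, latent_sd = 0.5)),
                      states = NULL, state_log2fc = 1.5,
                      nb_dispersion = 0.3,
                      dropout = list(midpoint = -2, slope = 1),
                      n_batches = 2, batch_sd = 0.15,
                      depth = 2000, ambig_fraction = 0.05, seed = 1) {
    stopifnot(length(species) >= 1, all(cell_types > 0), n_genes > 0,
              abs(sum(conservation_spec) - 1) < 1e-9,
              all(conservation_spec >= 0), seed == floor(seed))
    if (n_markers * length(cell_types) +
        sum(vapply(module_spec, `[[`, numeric(1), "n_genes")) > n_genes)
        stop("more marker/module genes requested than n_genes")
    if (length(cell_types) < 2 && conservation_spec[["switch"]] > 0)
        stop("'switch' requires at least two cell types")
    if (!is.null(states)) {
        stopifnot(abs(sum(states) - 1) < 1e-9, length(module_spec) >= 1)
    }
    structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-species single-cell panel with planted ground truth
#'
#' Generates, for each species, a [CellExperiment-class] of
#' negative-binomial UMI counts realizing the structure described by the
#' [simConfig()]: per-type marker effects, conservation edits in the
#' non-reference species, rank-1 correlated gene modules (optionally
#' state-activated), per-batch log-shifts, mean-dependent dropout. An
#' ortholog table with planted one-to-many records and a ground-truth
#' object accompany the matrices.
#'
#' @param cfg a [simConfig()].
#' @return list with elements `matrices` (named list of
#'   [CellExperiment-class], counts only), `ortholog` (unresolved
#'   [OrthologTable-class]) and `truth` (list: `markers`, `conservation`,
#'   `modules`, `ambiguous`, `gene_rate`, per-cell annotations live in the
#'   matrices' `colData`).
#' @export
simulatePanel <- function(cfg) {
    stopifnot(inherits(cfg, "sim_config"))
    rng <- .localSeed(cfg$seed)
    on.exit(rng(), add = TRUE)

    n_genes <- cfg$n_genes
    types <- names(cfg$cell_types)
    ref <- cfg$species[1]
    targets <- setdiff(cfg$species, ref)

    # base relative expression rates (shared across species)
    rate <- exp(rnorm(n_genes, mean = 0, sd = 1.2))
    gene_idx <- seq_len(n_genes)
    ids_ref <- sprintf("%s_g%04d", ref, gene_idx)

    # reserve decoy genes (no ortholog of their own) from the
    # low-expression stratum so planted ambiguity argmax is unambiguous
    n_mapped <- n_genes
    n_decoy <- ceiling(cfg$ambig_fraction * n_genes)
    low <- order(rate)[seq_len(max(n_decoy * 2, n_decoy))]
    decoy <- sort(low[seq_len(n_decoy)])
    mapped <- setdiff(gene_idx, decoy)

    # markers and modules drawn from moderately-to-highly expressed,
    # non-decoy genes (detectability of the planted effects)
    q <- quantile(rate[mapped], c(0.4, 0.9))
    eligible <- mapped[rate[mapped] >= q[1] & rate[mapped] <= q[2]]
    eligible <- sample(eligible)
    pick <- function(n) {
        stopifnot(length(eligible) >= n)
        out <- eligible[seq_len(n)]
        eligible <<- eligible[-seq_len(n)]
        out
    }
    module_id <- integer(n_genes)
    for (m in seq_along(cfg$module_spec))
        module_id[pick(cfg$module_spec[[m]]$n_genes)] <- m

    marker_of <- character(n_genes)      # "" = not a marker candidate
    is_gain <- logical(n_genes)
    for (ct in types) {
        cand <- pick(cfg$n_markers)
        p_gain <- cfg$conservation_spec[["gain"]]
        gain_flag <- runif(length(cand)) < p_gain
        marker_of[cand] <- ct
        is_gain[cand] <- gain_flag
    }
    # per-target conservation categories for true (non-gain) markers
    cats <- c("conserved", "loss", "switch", "absent")
    p4 <- cfg$conservation_spec[cats] / sum(cfg$conservation_spec[cats])
    conservation <- list()
    for (sp in targets) {
        idx <- which(marker_of != "" & !is_gain)
        cat_draw <- sample(cats, length(idx), replace = TRUE, prob = p4)
        gi <- which(is_gain)
        conservation[[sp]] <- data.frame(
            species = rep(sp, length(idx) + length(gi)),
            gene = ids_ref[c(idx, gi)],
            cell_type = marker_of[c(idx, gi)],
            category = c(cat_draw, rep("gain", length(gi))),
            row.names = NULL)
    }

    # per-species cell annotations (shared layout)
    n_cells <- sum(cfg$cell_types)
    cell_type <- rep(types, times = cfg$cell_types)
    state <- if (!is.null(cfg$states)) {
        unlist(lapply(types, function(ct) sample(
            names(cfg$states), cfg$cell_types[[ct]], replace = TRUE,
            prob = cfg$states)), use.names = FALSE)
    } else rep(NA_character_, n_cells)

    next_type <- setNames(types[c(seq_along(types)[-1], 1)], types)
    matrices <- list()
    for (sp in cfg$species) {
        present <- if (sp == ref) gene_idx else mapped
        # log2 effect of cell type on each (present) gene
        eff <- matrix(0, n_genes, length(types),
                      dimnames = list(NULL, types))
        rate_sp <- rate
        for (g in which(marker_of != "")) {
            ct <- marker_of[g]
            if (is_gain[g]) {
                if (sp == ref) rate_sp[g] <- rate[g] * 0.02
                else eff[g, ct] <- cfg$marker_log2fc
                next
            }
            if (sp == ref) { eff[g, ct] <- cfg$marker_log2fc; next }
            cc <- conservation[[sp]]
            category <- cc$category[cc$gene == ids_ref[g] &
                                    cc$cell_type == ct][1]
            if (category == "conserved") eff[g, ct] <- cfg$marker_log2fc
            else if (category == "switch")
                eff[g, next_type[[ct]]] <- cfg$marker_log2fc
            else if (category == "absent") rate_sp[g] <- 0
            # loss: base expression, no enrichment
        }
        # state activation of module genes
        seff <- NULL
        if (!is.null(cfg$states)) {
            sn <- names(cfg$states)
            seff <- matrix(0, n_genes, length(sn),
                           dimnames = list(NULL, sn))
            for (si in seq_along(sn)) {
                m <- ((si - 1) %% length(cfg$module_spec)) + 1
                seff[module_id == m, si] <- cfg$state_log2fc
            }
        }
        batch <- paste0(sp, "_b",
                        sample(seq_len(cfg$n_batches), n_cells,
                               replace = TRUE))
        bshift <- matrix(rnorm(n_genes * cfg$n_batches, 0, cfg$batch_sd),
                         n_genes, cfg$n_batches,
                         dimnames = list(NULL, paste0(sp, "_b",
                                                      seq_len(cfg$n_batches))))
        # per-cell module latent factors
        zmod <- matrix(rnorm(length(cfg$module_spec) * n_cells),
                       length(cfg$module_spec), n_cells)
        lsd <- vapply(cfg$module_spec, `[[`, numeric(1), "latent_sd")

        log2mu <- eff[, cell_type, drop = FALSE] + bshift[, batch]
        if (!is.null(seff)) log2mu <- log2mu + seff[, state, drop = FALSE]
        for (m in seq_along(cfg$module_spec)) {
            sel <- module_id == m
            log2mu[sel, ] <- log2mu[sel, ] +
                matrix(lsd[m] * zmod[m, ], sum(sel), n_cells, byrow = TRUE)
        }
        mu <- rate_sp * 2^log2mu
        depth_cell <- cfg$depth * exp(rnorm(n_cells, 0, 0.25))
        mu <- sweep(mu, 2, depth_cell / pmax(colSums(mu), 1e-12), "*")
        counts <- matrix(rnbinom(length(mu), mu = mu,
                                 size = 1 / cfg$nb_dispersion),
                         n_genes, n_cells)
        if (!is.null(cfg$dropout)) {
            gm <- rowMeans(mu)
            p_drop <- stats::plogis(-cfg$dropout$slope *
                                    (log(pmax(gm, 1e-12)) -
                                     cfg$dropout$midpoint))
            keep <- matrix(rbinom(length(counts), 1,
                                  rep(1 - p_drop, n_cells)),
                           n_genes, n_cells)
            counts <- counts * keep
        }
        counts <- counts[present, , drop = FALSE]
        ids_sp <- if (sp == ref) ids_ref
                  else sprintf("%s_g%04d", sp, present)
        dimnames(counts) <- list(ids_sp,
                                 sprintf("%s_c%05d", sp, seq_len(n_cells)))
        cm <- data.frame(species = sp, batch = batch,
                         cell_type = cell_type, state = state,
                         row.names = colnames(counts))
        matrices[[sp]] <- cellExperiment(
            counts, cm, data.frame(native_id = ids_sp))
    }

    # ortholog table: one record per mapped gene, plus decoy records for a
    # planted subset of target genes (ambiguous one-to-many mappings)
    rec <- data.frame(ids_ref[mapped])
    colnames(rec) <- ref
    for (sp in targets) rec[[sp]] <- sprintf("%s_g%04d", sp, mapped)
    ambiguous <- data.frame()
    if (length(targets) && n_decoy > 0) {
        # true partners of planted ambiguities: well expressed and free of
        # category edits, so the higher-expressed record is unambiguous
        hi <- mapped[rate[mapped] >= median(rate[mapped]) &
                     marker_of[mapped] == ""]
        amb <- sample(hi, min(n_decoy, length(hi)))
        extra <- rec[match(sprintf("%s_g%04d", ref, amb), rec[[ref]]), ,
                     drop = FALSE]
        extra[[ref]] <- ids_ref[decoy[seq_along(amb)]]
        rec <- rbind(rec, extra)
        ambiguous <- data.frame(
            target_gene = sprintf("%s_g%04d", targets[1], amb),
            true_ref = ids_ref[amb],
            decoy_ref = ids_ref[decoy[seq_along(amb)]], row.names = NULL)
    }
    tab <- orthologTable(rec, species = cfg$species)

    truth <- list(
        markers = data.frame(gene = ids_ref[marker_of != "" & !is_gain],
                             cell_type = marker_of[marker_of != "" &
                                                   !is_gain],
                             row.names = NULL),
        conservation = if (length(conservation))
            do.call(rbind, conservation) else NULL,
        modules = data.frame(gene = ids_ref[module_id > 0],
                             module = module_id[module_id > 0],
                             row.names = NULL),
        ambiguous = ambiguous,
        gene_rate = setNames(rate, ids_ref))
    list(matrices = matrices, ortholog = tab, truth = truth)
}
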