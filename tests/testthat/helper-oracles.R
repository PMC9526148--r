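# independent brute-force oracles, written as literal enumerations of the
# classification rule tables and textbook formulas; they never call the
# package functions they are used to check

# expression-level conservation: explicit per-(gene, type) enumeration
oracleExpressionConservation <- function(f_ref, f_tgt, thr = 0.05) {
    types <- intersect(rownames(f_ref), rownames(f_tgt))
    genes <- intersect(colnames(f_ref), colnames(f_tgt))
    out <- data.frame()
    for (ct in types) for (g in genes) {
        ref_pass <- f_ref[ct, g] > thr
        tgt_pass <- f_tgt[ct, g] > thr
        elsewhere <- FALSE
        for (other in setdiff(types, ct))
            if (f_tgt[other, g] > thr) elsewhere <- TRUE
        category <- if (ref_pass && tgt_pass) "conserved"
            else if (ref_pass && !tgt_pass && elsewhere) "loss"
            else if (ref_pass && !tgt_pass && !elsewhere) "absent"
            else if (!ref_pass && tgt_pass) "gain"
            else NA_character_
        if (!is.na(category))
            out <- rbind(out, data.frame(gene = g, cell_type = ct,
                                         category = category))
    }
    out
}

# marker-level conservation: enumeration over reference-enriched pairs
oracleMarkerConservation <- function(ref_markers, tgt_markers, f_tgt,
                                     thr = 0.05) {
    enr <- ref_markers[ref_markers$is_enriched, , drop = FALSE]
    out <- data.frame()
    for (i in seq_len(nrow(enr))) {
        g <- enr$gene[i]; ct <- enr$cell_type[i]
        tgt_enr_types <- tgt_markers$cell_type[tgt_markers$gene == g &
                                               tgt_markers$is_enriched]
        expressed_somewhere <- any(f_tgt[, g] > thr)
        category <- if (ct %in% tgt_enr_types) "conserved"
            else if (length(tgt_enr_types) > 0) "switch"
            else if (expressed_somewhere) "loss"
            else "absent"
        out <- rbind(out, data.frame(gene = g, cell_type = ct,
                                     category = category))
    }
    out
}

# Pearson correlation from the raw definition
oraclePearson <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Welch's t from the raw definition (with variance floor)
oracleWelch <- function(a, b, floor = 1e-9) {
    va <- max(sum((a - mean(a))^2) / (length(a) - 1), floor)
    vb <- max(sum((b - mean(b))^2) / (length(b) - 1), floor)
    (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
}

# ortholog resolution by exhaustive per-record contest enumeration:
# a record survives iff, for every ordered species pair (s, t), its
# t-partner attains the maximal mean expression among all records sharing
# its s-gene (ties to the lexicographically smallest partner id)
oracleResolve <- function(records, species, expr) {
    detected <- rep(TRUE, nrow(records))
    for (sp in species)
        detected <- detected & records[[sp]] %in% names(expr[[sp]])
    kept <- detected
    for (i in which(detected)) {
        for (s in species) for (t in setdiff(species, s)) {
            rivals <- which(detected & records[[s]] == records[[s]][i])
            partners <- records[[t]][rivals]
            e <- expr[[t]][partners]
            best <- partners[order(-e, partners)][1]
            if (records[[t]][i] != best) kept[i] <- FALSE
        }
    }
    kept
}

# comparison helper: category calls as a canonical sorted key string
callKey <- function(df) {
    df <- df[order(df$gene, df$cell_type), ]
    paste(df$gene, df$cell_type, df$category, collapse = ";")
}
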