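test_that("qcFilter retains exactly the cells passing every criterion", {
    # 5 cells with mito fractions 0.10/0.25/0.05/0.30/0.00, totals 100
    mito <- c(10, 25, 5, 30, 0)
    counts <- rbind(mt = mito, g1 = 50 - mito, g2 = rep(50, 5))
    ce <- ceFromCounts(counts)
    out <- qcFilter(ce, qcConfig(max_mito_fraction = 0.20, min_counts = 0,
                                 min_genes = 0, min_cells_per_gene = 0,
                                 mito_genes = "mt"))
    expect_identical(colnames(out), colnames(ce)[c(1, 3, 5)])

    # all thresholds passing: identity
    all_pass <- qcFilter(ce, qcConfig(max_mito_fraction = 1, min_counts = 0,
                                      min_genes = 0, min_cells_per_gene = 0))
    expect_identical(dim(all_pass), dim(ce))
    expect_identical(SummarizedExperiment::assay(all_pass, "counts"),
                     SummarizedExperiment::assay(ce, "counts"))

    # degenerate threshold names the exhausted criterion
    expect_error(qcFilter(ce, qcConfig(min_counts = 1e6)),
                 "no cells survive.*total count")
    expect_error(qcFilter(ce, qcConfig(min_counts = 0, min_genes = 100)),
                 "no cells survive.*gene count")
})

test_that("qcFilter is idempotent on generated data", {
    set.seed(42)
    counts <- matrix(rpois(300 * 80, 0.8), 300, 80)
    ce <- ceFromCounts(counts)
    cfg <- qcConfig(min_counts = 150, min_genes = 80,
                    min_cells_per_gene = 10)
    once <- qcFilter(ce, cfg)
    twice <- qcFilter(once, cfg)
    expect_identical(dim(once), dim(twice))
    expect_identical(SummarizedExperiment::assay(once, "counts"),
                     SummarizedExperiment::assay(twice, "counts"))
})

test_that("normalizeLog reproduces the two-cell size-factor arithmetic", {
    counts <- matrix(c(10, 90, 50, 50), nrow = 2,
                     dimnames = list(c("g1", "g2"), c("A", "B")))
    ce <- ceFromCounts(counts)
    # gene2 has 90/100 of cell A's counts -> flagged at a 0.5 cap;
    # filtered sums [10, 50], target median 30, size factors [1/3, 5/3]
    out <- normalizeLog(ce, max_fraction = 0.5)
    expect_equal(SummarizedExperiment::colData(out)$size_factor,
                 c(1 / 3, 5 / 3), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(SummarizedExperiment::rowData(out)$highly_expressed),
                 c(FALSE, TRUE))
    expect_equal(unname(lognorm(out)),
                 log1p(matrix(c(30, 270, 30, 30), nrow = 2)),
                 tolerance = 1e-12)
})

test_that("normalizeLog equals plain median normalization when no gene is flagged", {
    set.seed(1)
    counts <- matrix(rpois(40 * 20, 5), 40, 20)   # no gene dominates a cell
    ce <- ceFromCounts(counts)
    out <- normalizeLog(ce, max_fraction = 0.99)
    sf <- colSums(counts) / median(colSums(counts))
    expect_equal(unname(lognorm(out)),
                 unname(log1p(sweep(counts, 2, sf, "/"))),
                 tolerance = 1e-12)
    # all-zero gene maps to all-zero lognorm
    counts[3, ] <- 0
    out0 <- normalizeLog(ceFromCounts(counts))
    expect_true(all(lognorm(out0)[3, ] == 0))
})

test_that("normalizeLog invariant: filtered sums hit the target", {
    set.seed(2)
    counts <- matrix(rnbinom(100 * 30, mu = 2, size = 1), 100, 30)
    counts[1, ] <- counts[1, ] + 200   # a dominating gene
    ce <- ceFromCounts(counts)
    out <- normalizeLog(ce, max_fraction = 0.05)
    flagged <- SummarizedExperiment::rowData(out)$highly_expressed
    sf <- SummarizedExperiment::colData(out)$size_factor
    target <- median(colSums(counts[!flagged, ]))
    norm_sums <- colSums(sweep(counts[!flagged, , drop = FALSE], 2, sf, "/"))
    expect_true(all(abs(norm_sums - target) < 1e-9))
})

test_that("batch adjustment preserves the zero mask and is a no-op for one batch", {
    set.seed(5)
    ln <- matrix(rexp(60 * 40), 60, 40)
    ln[runif(length(ln)) < 0.4] <- 0
    ce <- ceFromLognorm(ln, batch = rep(c("a", "b"), each = 20))
    out <- batchCorrectZeroPreserving(ce)
    expect_identical(unname(lognorm(out) == 0), unname(ln) == 0)

    one <- ceFromLognorm(ln, batch = "a")
    expect_equal(lognorm(batchCorrectZeroPreserving(one)), lognorm(one),
                 tolerance = 1e-9)

    expect_error(batchCorrectZeroPreserving(
        ceFromLognorm(ln, batch = c("a", rep("b", 39)))), "single cell")
    expect_error(batchCorrectZeroPreserving(ce, batch_key = "nope"),
                 "unknown batch key")
})

test_that("batch adjustment removes a planted constant offset", {
    # genes share the value multiset (equal moments), so the EB shrinkage
    # target coincides with every gene's own estimate and the location
    # adjustment is exact
    set.seed(7)
    vals <- rexp(60) + 0.5
    b1 <- t(vapply(1:50, function(i) sample(vals), numeric(60)))
    ln <- cbind(b1, b1 + 1.0)
    ce <- ceFromLognorm(ln, batch = rep(c("a", "b"), each = 60))
    out <- lognorm(batchCorrectZeroPreserving(ce))
    d <- rowMeans(out[, 1:60]) - rowMeans(out[, 61:120])
    expect_true(max(abs(d)) < 1e-6)
})

test_that("batch adjustment is equivariant under cell permutation", {
    set.seed(8)
    ln <- matrix(rexp(40 * 50), 40, 50)
    ln[runif(length(ln)) < 0.3] <- 0
    batch <- rep(c("a", "b"), 25)
    ce <- ceFromLognorm(ln, batch = batch)
    perm <- sample(50)
    cep <- ceFromLognorm(ln[, perm], batch = batch[perm])
    out <- lognorm(batchCorrectZeroPreserving(ce))
    outp <- lognorm(batchCorrectZeroPreserving(cep))
    expect_equal(unname(out[, perm]), unname(outp), tolerance = 1e-9)
})

test_that("batch adjustment does not increase between-batch mean differences", {
    set.seed(9)
    ln <- matrix(rexp(50 * 200), 50, 200)
    ln[runif(length(ln)) < 0.3] <- 0
    batch <- rep(c("a", "b"), each = 100)   # i.i.d. batches
    ce <- ceFromLognorm(ln, batch = batch)
    out <- lognorm(batchCorrectZeroPreserving(ce))
    gap <- function(m) mean(abs(rowMeans(m[, batch == "a"]) -
                                rowMeans(m[, batch == "b"])))
    expect_lte(gap(out), gap(ln))
})

test_that("computeGroupProfile summarizes means, fractions and counts", {
    ln <- cbind(c(0, 1), c(0, 2), c(2, 0), c(4, 5))
    rownames(ln) <- c("gA", "gB")
    ce <- ceFromLognorm(ln, cell_type = c("x", "x", "x", "x"))
    p <- computeGroupProfile(ce)
    expect_equal(unname(profileMean(p)["x", ]), c(1.5, 2))
    expect_equal(unname(profileFrac(p)["x", ]), c(0.5, 0.75))

    # singleton group: mean is the cell itself, frac the 0/1 indicator
    ce2 <- ceFromLognorm(ln, cell_type = c("a", "b", "b", "b"))
    p2 <- computeGroupProfile(ce2)
    expect_equal(unname(profileMean(p2)["a", ]), ln[, 1], ignore_attr = TRUE)
    expect_equal(unname(profileFrac(p2)["a", ]), as.numeric(ln[, 1] > 0))
    expect_equal(sum(profileCells(p2)), 4)
    # frac * n is an integer count
    expect_true(all(abs(profileFrac(p2) * profileCells(p2) -
                        round(profileFrac(p2) * profileCells(p2))) < 1e-9))
    expect_error(computeGroupProfile(ce, group_key = "donor"),
                 "unknown group key")
    expect_error(computeGroupProfile(ce, genes = "nope"), "absent")
})
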