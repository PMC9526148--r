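test_that("harmonicProfile matches the hand-computed worked values", {
    # m = 2, f = 0.5, group mean fraction over the subset = 0.25
    m <- rbind(A = c(2.0, 1.0))
    f <- rbind(A = c(0.5, 0.0))
    colnames(m) <- colnames(f) <- c("g1", "g2")
    p <- profileFromMatrices(m, f, c(A = 10))
    h <- harmonicProfile(p)
    expect_equal(h["A", "g1"], 2 * 2 * 2 / (2 + 2), tolerance = 1e-12)
    # m > 0 but f = 0: f' = 0 and h = 0
    expect_equal(h["A", "g2"], 0)

    # equal fractions in a group: f' = 1, h = 2m/(m+1)
    m2 <- rbind(A = c(3, 0.5)); f2 <- rbind(A = c(0.4, 0.4))
    colnames(m2) <- colnames(f2) <- c("g1", "g2")
    h2 <- harmonicProfile(profileFromMatrices(m2, f2, c(A = 5)))
    expect_equal(unname(h2["A", ]), 2 * c(3, 0.5) / (c(3, 0.5) + 1),
                 tolerance = 1e-12)

    # zero annihilation: m = 0 gives h = 0 regardless of f
    m3 <- rbind(A = c(0, 1)); f3 <- rbind(A = c(0.9, 0.3))
    colnames(m3) <- colnames(f3) <- c("g1", "g2")
    expect_equal(harmonicProfile(profileFromMatrices(m3, f3, 5))["A", "g1"],
                 0)
    # all-zero fractions in a group over the subset is an error
    mz <- rbind(A = c(g1 = 1, g2 = 1)); fz <- rbind(A = c(g1 = 0, g2 = 0))
    expect_error(harmonicProfile(profileFromMatrices(mz, fz, 5)),
                 "all-zero")
})

test_that("harmonic values stay within their analytic envelope", {
    set.seed(12)
    for (i in 1:20) {
        p <- randomProfile(10, 4, 100 + i)
        ok <- rowMeans(profileFrac(p)) > 0
        p <- profileFromMatrices(profileMean(p)[ok, , drop = FALSE],
                                 profileFrac(p)[ok, , drop = FALSE],
                                 profileCells(p)[ok])
        h <- harmonicProfile(p)
        fp <- profileFrac(p) / rowMeans(profileFrac(p))
        expect_true(all(h >= 0))
        expect_true(all(h <= 2 * pmin(profileMean(p), fp) + 1e-12))
        expect_true(all(is.finite(h)))
    }
})

test_that("patternCorrelation reproduces the direct Pearson formula", {
    a <- rbind(g1 = c(1, 0), g2 = c(2, 3))
    b <- rbind(g1 = c(1, 1), g2 = c(2, 2))
    colnames(a) <- colnames(b) <- c("t1", "t2")
    # 2 genes x 2 groups flattened: direct formula gives 2/sqrt(5)
    expect_equal(patternCorrelation(t(a), t(b)),
                 oraclePearson(as.vector(t(a)), as.vector(t(b))),
                 tolerance = 1e-9)
    expect_equal(patternCorrelation(t(a), t(b)), 2 / sqrt(5),
                 tolerance = 1e-9)
    expect_equal(patternCorrelation(t(a), t(a)), 1)
    expect_error(patternCorrelation(t(a), t(b) * 0 + 1), "constant")
})

test_that("harmonic-mode correlation is invariant to per-group fraction rescaling", {
    set.seed(31)
    m <- matrix(runif(4 * 12, 0.1, 3), 4,
                dimnames = list(paste0("t", 1:4), paste0("g", 1:12)))
    f <- matrix(runif(4 * 12, 0.05, 1), 4, dimnames = dimnames(m))
    p1 <- profileFromMatrices(m, f, rep(10, 4))
    # same profile with one group's fractions multiplied by a constant;
    # the group-mean normalization cancels the factor
    f2 <- f; f2[2, ] <- pmin(f2[2, ] * 0.35, 1)
    p2 <- profileFromMatrices(m, f2, rep(10, 4))
    set.seed(32)
    other <- profileFromMatrices(matrix(runif(4 * 12, 0.1, 3), 4,
                                        dimnames = dimnames(m)),
                                 matrix(runif(4 * 12, 0.05, 1), 4,
                                        dimnames = dimnames(m)),
                                 rep(10, 4))
    ho <- harmonicProfile(other)
    expect_equal(patternCorrelation(harmonicProfile(p1), ho),
                 patternCorrelation(harmonicProfile(p2), ho),
                 tolerance = 1e-9)
})

test_that("patternCorrelation is symmetric and permutation invariant", {
    set.seed(33)
    a <- matrix(runif(3 * 8), 3, dimnames = list(paste0("t", 1:3),
                                                 paste0("g", 1:8)))
    b <- matrix(runif(3 * 8), 3, dimnames = dimnames(a))
    expect_equal(patternCorrelation(a, b), patternCorrelation(b, a))
    pg <- sample(8); pt <- sample(3)
    expect_equal(patternCorrelation(a[pt, pg], b[pt, pg]),
                 patternCorrelation(a, b), tolerance = 1e-12)
})

test_that("pcaGroupCorrelation drops the species components", {
    set.seed(44)
    n_genes <- 60; n <- 120
    type <- rep(c("alpha", "beta"), each = n / 2)
    sig <- matrix(0, n_genes, n)
    sig[1:10, type == "alpha"] <- 2          # shared cell-type signal
    sig[11:20, type == "beta"] <- 2
    mk <- function(sp, offset) {
        ln <- pmax(sig + offset + matrix(rnorm(n_genes * n, 0, 0.5),
                                         n_genes, n), 0)
        dimnames(ln) <- list(sprintf("g%03d", 1:n_genes),
                             sprintf("%s_c%03d", sp, 1:n))
        ceFromLognorm(ln, cell_type = type, species = sp)
    }
    # two species-driven variance directions carry the most variance: a
    # constant cross-species offset and a strong pig-only technical factor
    offs <- matrix(rnorm(n_genes, 0, 2), n_genes, n)
    tech <- outer(rnorm(n_genes, 0, 1.5), rnorm(n, 0, 1))
    mats <- list(human = mk("human", 0), pig = mk("pig", offs + tech))
    cross_r <- function(drop_top) {
        res <- pcaGroupCorrelation(mats, n_pcs = 20, drop_top = drop_top,
                                   subsample_cap = 2000, seed = 9)
        mean(c(res$correlation["human:alpha", "pig:alpha"],
               res$correlation["human:beta", "pig:beta"]))
    }
    expect_gt(cross_r(2), cross_r(0))

    # same seed, permuted cells: identical output
    res1 <- pcaGroupCorrelation(mats, n_pcs = 10, drop_top = 2, seed = 5)
    perm <- sample(n)
    mats_p <- mats
    cd <- SummarizedExperiment::colData(mats_p$human)
    mats_p$human <- mats_p$human[, perm]
    res2 <- pcaGroupCorrelation(mats_p, n_pcs = 10, drop_top = 2, seed = 5)
    expect_equal(res1$correlation, res2$correlation, tolerance = 1e-6)

    expect_error(pcaGroupCorrelation(mats, n_pcs = 2, drop_top = 2),
                 "exceed")
})

test_that("pcaGroupCorrelation handles single species and small groups", {
    set.seed(46)
    ln <- matrix(rexp(40 * 30), 40, 30)
    ce <- ceFromLognorm(ln, cell_type = rep(c("a", "b"), 15))
    res <- pcaGroupCorrelation(list(human = ce), n_pcs = 8, drop_top = 2,
                               subsample_cap = 5, seed = 1)
    cm <- res$correlation
    expect_equal(dim(cm), c(2, 2))
    expect_equal(unname(diag(cm)), c(1, 1))
    expect_equal(cm[1, 2], cm[2, 1])
    # a group with fewer cells than the cap uses all its cells
    res_all <- pcaGroupCorrelation(list(human = ce), n_pcs = 8,
                                   drop_top = 2, subsample_cap = 1000,
                                   seed = 1)
    expect_equal(sum(res_all$n_cells), 30)
})
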