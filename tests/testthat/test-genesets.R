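test_that("selectVariableGenes ranks by binned normalized dispersion", {
    set.seed(51)
    n <- 60
    # all background genes share one value multiset (identical mean and
    # dispersion); gene 5 has far higher variance at a comparable mean
    v <- rexp(n, 1) + 0.2
    ln <- t(vapply(1:30, function(i) sample(v), numeric(n)))
    ln[5, ] <- rep(c(0.1, 2 * mean(v) - 0.1), length.out = n)
    ln[6, ] <- mean(v)                           # constant, same mean
    ce <- ceFromLognorm(ln)
    ids <- geneIds(ce)
    top <- selectVariableGenes(ce, n = 10, min_cells = 5, n_bins = 5)
    expect_identical(top[1], ids[5])
    expect_false(ids[6] %in% top)

    # n = number of eligible genes returns them all
    all_g <- selectVariableGenes(ce, n = 30, min_cells = 5)
    expect_setequal(all_g, ids)
    expect_error(selectVariableGenes(ce, n = 31, min_cells = 5),
                 "only 30")
})

test_that("discoverGeneSets recovers planted correlation blocks", {
    set.seed(52)
    n_cells <- 400
    z1 <- rnorm(n_cells); z2 <- rnorm(n_cells)
    mk_block <- function(z, k) t(vapply(seq_len(k), function(i)
        3 * z + rnorm(n_cells), numeric(n_cells)))
    ln <- rbind(mk_block(z1, 15), mk_block(z2, 15),
                matrix(rnorm(20 * n_cells), 20, n_cells))
    ln <- ln - min(ln) + 0.01
    ce <- ceFromLognorm(ln)
    ids <- geneIds(ce)
    sets <- discoverGeneSets(ce, ids, n_clusters = 3, min_corr = 0.005)
    sl <- geneSets(sets)
    # the two blocks are recovered; the noise cluster is filtered out
    expect_equal(length(sl), 2)
    expect_setequal(sl$G1, ids[1:15])
    expect_setequal(sl$G2, ids[16:30])
    expect_true(all(setCorrelations(sets) > 0.5))
})

test_that("discoverGeneSets conventions: duplicates, singletons, order", {
    set.seed(53)
    ln <- matrix(rnorm(10 * 100), 10, 100)
    ln[2, ] <- ln[1, ]                     # duplicated gene column pair
    ln <- ln - min(ln) + 0.01
    ce <- ceFromLognorm(ln)
    ids <- geneIds(ce)
    sets <- discoverGeneSets(ce, ids, n_clusters = 5, min_corr = 0.9)
    dup_set <- Filter(function(s) ids[1] %in% s, geneSets(sets))
    expect_equal(length(dup_set), 1)
    expect_true(ids[2] %in% dup_set[[1]])

    # every cluster a singleton: all dropped (singleton correlation is 0)
    none <- discoverGeneSets(ce, ids[3:8], n_clusters = 6, min_corr = 0.005)
    expect_equal(length(geneSets(none)), 0)

    # gene order only permutes naming, not membership
    s1 <- discoverGeneSets(ce, ids, n_clusters = 4, min_corr = -1)
    s2 <- discoverGeneSets(ce, rev(ids), n_clusters = 4, min_corr = -1)
    canon <- function(s) sort(vapply(geneSets(s), function(g)
        paste(sort(g), collapse = ","), character(1)))
    expect_identical(unname(canon(s1)), unname(canon(s2)))

    ln[3, ] <- 1
    expect_error(discoverGeneSets(ceFromLognorm(ln), ids, n_clusters = 3),
                 "constant")
})

test_that("scoreGeneSets whole-pool fixture matches hand arithmetic", {
    # one-gene set, one bin: background = all other genes, deterministic
    ln <- rbind(g = c(2.0, 1.0), o1 = c(0.5, 0.2), o2 = c(0.5, 0.4))
    colnames(ln) <- c("c1", "c2")
    ce <- ceFromLognorm(ln)
    sets <- geneSetCollection(list(S = "g"))
    sc <- scoreGeneSets(ce, sets, n_bins = 1, background_size = 50,
                        seed = 1)
    expect_equal(unname(sc[, "S"]), c(2.0 - 0.5, 1.0 - 0.3),
                 tolerance = 1e-12)

    # all-zero set and pool: score 0 (use a two-gene zero stratum)
    ln0 <- rbind(a = c(0, 0), b = c(0, 0), hi = c(3, 4), hi2 = c(2, 5))
    colnames(ln0) <- c("c1", "c2")
    sc0 <- scoreGeneSets(ceFromLognorm(ln0), geneSetCollection(list(Z = "a")),
                         n_bins = 2, background_size = 50, seed = 1)
    expect_equal(unname(sc0[, "Z"]), c(0, 0))
})

test_that("scoreGeneSets is seed-reproducible and shift invariant", {
    set.seed(55)
    ln <- matrix(rexp(200 * 40), 200, 40)
    ce <- ceFromLognorm(ln)
    ids <- geneIds(ce)
    sets <- geneSetCollection(list(S1 = ids[1:10], S2 = ids[21:25]))
    a <- scoreGeneSets(ce, sets, seed = 99)
    b <- scoreGeneSets(ce, sets, seed = 99)
    expect_identical(a, b)
    # adding a constant to every entry leaves scores unchanged
    shifted <- ceFromLognorm(ln + 2)
    # same bins are guaranteed because ranks are unchanged
    d <- scoreGeneSets(shifted, sets, seed = 99)
    expect_equal(unname(a), unname(d), tolerance = 1e-9)
})

test_that("a set drawn from its own background pool scores near zero", {
    set.seed(56)
    ln <- matrix(rexp(300 * 60), 300, 60)
    ce <- ceFromLognorm(ln)
    ids <- geneIds(ce)
    mu <- rowMeans(ln)
    bin <- cut(rank(mu), 25)
    pool <- ids[as.integer(bin) == 12]
    null_set <- geneSetCollection(list(N = sample(pool,
                                                  min(8, length(pool)))))
    sc <- scoreGeneSets(ce, null_set, n_bins = 25, background_size = 50,
                        seed = 7)
    expect_lt(abs(mean(sc[, "N"])), 0.05)
})

test_that("rankGenesWelch matches the Welch formula and its conventions", {
    set.seed(57)
    ln <- matrix(rexp(30 * 20), 30, 20)
    grp <- rep(c("a", "b"), each = 10)
    ce <- ceFromLognorm(ln, cell_type = grp)
    res <- rankGenesWelch(ce, "cell_type", "a", "b", top_n = 30)
    ids <- geneIds(ce)
    for (g in ids[c(1, 7, 13)]) {
        expect_equal(res$t[res$gene == g],
                     oracleWelch(ln[match(g, ids), grp == "a"],
                                 ln[match(g, ids), grp == "b"]),
                     tolerance = 1e-9)
    }
    # antisymmetry
    rev_res <- rankGenesWelch(ce, "cell_type", "b", "a", top_n = 30)
    expect_equal(res$t[order(res$gene)], -rev_res$t[order(rev_res$gene)],
                 tolerance = 1e-12)

    # identical groups: all t zero, ranking lexicographic
    ln2 <- cbind(ln[, 1:10], ln[, 1:10])
    ce2 <- ceFromLognorm(ln2, cell_type = rep(c("a", "b"), each = 10))
    res2 <- rankGenesWelch(ce2, "cell_type", "a", "b", top_n = 30)
    expect_true(all(res2$t == 0))
    expect_identical(res2$gene, sort(ids))

    # variance floor engages for constant groups
    ln3 <- rbind(matrix(rexp(10 * 8), 10, 8),
                 rep(c(2, 0), each = 4))
    ce3 <- ceFromLognorm(ln3, cell_type = rep(c("a", "b"), each = 4))
    res3 <- rankGenesWelch(ce3, "cell_type", "a", "b", top_n = 1)
    expect_identical(res3$gene, geneIds(ce3)[11])
    expect_gt(res3$t, 1e3)
    expect_error(rankGenesWelch(ce3, "cell_type", "a", "missing"),
                 "at least 2 cells")
})

test_that("planted shift genes dominate the Welch ranking", {
    set.seed(58)
    n <- 50
    ln <- matrix(rexp(205 * 2 * n, 1), 205, 2 * n)
    planted <- 1:5
    ln[planted, 1:n] <- ln[planted, 1:n] + 2.0
    ce <- ceFromLognorm(ln, cell_type = rep(c("a", "b"), each = n))
    res <- rankGenesWelch(ce, "cell_type", "a", "b", top_n = 50)
    expect_true(all(geneIds(ce)[planted] %in% res$gene))
})
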