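test_that("module score is exactly zero on homogeneous data", {
    # every gene has the identical expression vector -> control mean
    # equals target mean whatever the draw
    cts <- matrix(rep(c(2, 5, 1, 8), times = 12), nrow = 12, byrow = TRUE)
    ds <- logNormalize(makeToyData(cts))
    sc <- suppressWarnings(
        moduleScore(ds, rownames(ds)[c(2, 5)], n_bins = 3, n_ctrl = 2,
                    seed = 1))
    expect_equal(unname(as.numeric(sc)), rep(0, 4))
})

test_that("module score reduces to set mean minus global mean with one bin", {
    # 6-gene x 4-cell fixture; n_bins = 1, n_ctrl = G draws every gene
    # without replacement: score = mean(set) - mean(all genes)
    set.seed(4)
    cts <- matrix(rpois(24, 6) + 1, nrow = 6)
    ds <- logNormalize(makeToyData(cts))
    ln <- as.matrix(SingleCellExperiment::logcounts(ds))
    target <- rownames(ds)[c(1, 4)]
    expected <- colMeans(ln[target, ]) - colMeans(ln)
    sc <- moduleScore(ds, target, n_bins = 1, n_ctrl = 6, seed = 7)
    expect_equal(unname(as.numeric(sc)), unname(expected))
})

test_that("module score is shift-invariant and monotone in target expression", {
    set.seed(5)
    cts <- matrix(rpois(40 * 30, 5) + 1, nrow = 40,
                  dimnames = list(sprintf("g%02d", 1:40),
                                  sprintf("c%03d", 1:30)))
    ds <- logNormalize(makeToyData(cts))
    target <- sprintf("g%02d", 1:5)
    base <- moduleScore(ds, target, n_bins = 4, n_ctrl = 5, seed = 3)

    # add a constant to one cell's log-normalized profile
    shifted <- ds
    ln <- as.matrix(SingleCellExperiment::logcounts(shifted))
    ln[, 7] <- ln[, 7] + 1.3
    SingleCellExperiment::logcounts(shifted) <-
        Matrix::Matrix(ln, sparse = TRUE)
    sc_shift <- moduleScore(shifted, target, n_bins = 4, n_ctrl = 5,
                            seed = 3)
    expect_equal(sc_shift[[7]], base[[7]], tolerance = 1e-12)

    # scaling target genes up in a cell subset raises their scores
    boosted <- ds
    ln2 <- as.matrix(SingleCellExperiment::logcounts(boosted))
    ln2[target, 1:10] <- ln2[target, 1:10] * 1.8
    SingleCellExperiment::logcounts(boosted) <-
        Matrix::Matrix(ln2, sparse = TRUE)
    sc_boost <- moduleScore(boosted, target, n_bins = 4, n_ctrl = 5,
                            seed = 3)
    # boosted cells gain score relative to unaltered cells (bins, and
    # hence control draws, legitimately shift with the dataset average)
    gap_before <- mean(base[1:10]) - mean(base[11:30])
    gap_after <- mean(sc_boost[1:10]) - mean(sc_boost[11:30])
    expect_gt(gap_after, gap_before)
})

test_that("module score is seed-deterministic and seed-unbiased on null data", {
    set.seed(6)
    cts <- matrix(rpois(60 * 50, 5), nrow = 60)
    ds <- logNormalize(makeToyData(cts))
    target <- rownames(ds)[1:8]
    a <- moduleScore(ds, target, n_bins = 6, n_ctrl = 8, seed = 11)
    b <- moduleScore(ds, target, n_bins = 6, n_ctrl = 8, seed = 11)
    expect_identical(as.numeric(a), as.numeric(b))
    diffs <- vapply(1:20, function(s)
        mean(moduleScore(ds, target, n_bins = 6, n_ctrl = 8, seed = s) - a),
        numeric(1))
    expect_lt(abs(mean(diffs)), 0.05)
})

test_that("score battery emits per-set columns plus the aggregate ECM score", {
    spec <- syntheticSpec("ecm", seed = 21)
    sim <- generateDataset(spec)
    ds <- logNormalize(sim$data)
    gs <- defaultGeneSets(spec)
    battery <- suppressWarnings(scoreBattery(ds, gs, seed = 2))
    expect_setequal(colnames(battery),
                    c(names(geneSets(gs)), "ECM"))

    # a set with no overlap degrades gracefully: column absent, warning
    gs2 <- GeneSetCollection(c(geneSets(gs),
                               list(GeneSet("ghost", c("nopeA", "nopeB"),
                                            "custom"))))
    w <- capture_warnings(b2 <- scoreBattery(ds, gs2, seed = 2))
    expect_true(any(grepl("ghost", w)))
    expect_false("ghost" %in% colnames(b2))
    expect_true(all(names(geneSets(gs)) %in% colnames(b2)))

    # only fibrillar collagens amplified -> fibrillar score exceeds the
    # network score in the amplified cells
    fib <- geneSets(gs)$fibrillar@genes
    ln <- as.matrix(SingleCellExperiment::logcounts(ds))
    ln[fib, 1:500] <- ln[fib, 1:500] * 2
    ds_amp <- ds
    SingleCellExperiment::logcounts(ds_amp) <-
        Matrix::Matrix(ln, sparse = TRUE)
    b3 <- suppressWarnings(scoreBattery(ds_amp, gs, seed = 2))
    expect_true(mean(b3$fibrillar[1:500] > b3$network[1:500]) > 0.9)
})

test_that("cell-cycle calls follow the argmax rule and recover cycling cells", {
    spec <- syntheticSpec("ecm", seed = 8)
    sim <- generateDataset(spec)
    ds <- logNormalize(sim$data)
    gs <- defaultGeneSets(spec)
    g2m_genes <- geneSets(gs)$g2m_phase@genes
    # plant cycling cells: G2M signature tripled in cells 1..200
    ln <- as.matrix(SingleCellExperiment::logcounts(ds))
    ln[g2m_genes, 1:200] <- ln[g2m_genes, 1:200] * 3
    SingleCellExperiment::logcounts(ds) <- Matrix::Matrix(ln, sparse = TRUE)
    calls <- suppressWarnings(
        cellCyclePhase(ds, geneSets(gs)$s_phase, geneSets(gs)$g2m_phase,
                       seed = 4))
    expect_gte(mean(calls$phase[1:200] == "G2M"), 0.9)
    # argmax / both-negative rule on the emitted scores
    both_neg <- calls$s_score <= 0 & calls$g2m_score <= 0
    expect_true(all(calls$phase[both_neg] == "G1"))
    s_wins <- calls$s_score > 0 & calls$s_score >= calls$g2m_score
    expect_true(all(calls$phase[s_wins] == "S"))
})
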