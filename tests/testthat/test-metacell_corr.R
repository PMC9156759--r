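test_that("meta-cells on two separated blobs match nearest-centroid assignment", {
    blobs <- makeBlobData(n1 = 50, n2 = 50, seed = 9)
    mc <- buildMetaCells(blobs$data, resolution = 0.1, n_var_genes = 60,
                         seed = 1)
    expect_equal(length(mcSizes(mc)), 2L)
    oracle <- nearestCentroid(blobs$data, blobs$blob)
    asg <- mcAssignment(mc)
    # identical partition up to label names
    expect_equal(length(unique(paste(asg, oracle))), 2L)
    expect_equal(sort(unname(mcSizes(mc))), c(50L, 50L))
})

test_that("undersized meta-cells are dropped and their cells excluded", {
    # two well-populated blobs plus a 3-cell outlier group expressing
    # its own block of the null genes
    set.seed(12)
    g_block <- 15; G <- 3 * g_block; n <- c(40, 40, 3)
    mu <- matrix(2, G, sum(n))
    mu[seq_len(g_block), 1:40] <- 40
    mu[g_block + seq_len(g_block), 41:80] <- 40
    mu[2 * g_block + seq_len(g_block), 81:83] <- 40
    cts <- matrix(rpois(length(mu), mu), G, sum(n),
                  dimnames = list(sprintf("g%02d", seq_len(G)),
                                  sprintf("c%03d", seq_len(sum(n)))))
    ds <- logNormalize(makeToyData(cts))
    mc <- suppressWarnings(
        buildMetaCells(ds, resolution = 0.5, n_var_genes = G,
                       min_size = 5, k_neighbors = 3, seed = 1))
    asg <- mcAssignment(mc)
    expect_true(anyNA(asg))                      # dropped cells marked
    expect_true(all(mcSizes(mc) >= 5))
    expect_equal(sum(mcSizes(mc)), sum(!is.na(asg)))
    expect_error(buildMetaCells(ds[, 1:8], min_size = 5),
                 "too few cells")
})

test_that("score-gene correlation ranks a self-identical gene first and honours exclusions", {
    profiles <- matrix(rnorm(20 * 8), nrow = 8,
                       dimnames = list(paste0("mc", 1:8),
                                       sprintf("g%02d", 1:20)))
    score <- profiles[, "g05"]
    profiles[, "g11"] <- 3              # constant profile
    mc <- new("MetaCellTable",
              assignment = stats::setNames(rep(1:8, 2), paste0("c", 1:16)),
              profiles = profiles,
              scoreMeans = matrix(score, ncol = 1,
                                  dimnames = list(paste0("mc", 1:8), "S")),
              sizes = rep(2L, 8),
              parameters = list())
    res <- suppressWarnings(scoreGeneCorrelation(mc, "S", top_n = Inf))
    expect_identical(res$gene[1], "g05")
    expect_equal(res$r[1], 1)
    # constant gene sits at r = 0 by convention
    expect_equal(res$r[res$gene == "g11"], 0)
    # exclusion removes the gene from the output entirely
    res2 <- suppressWarnings(
        scoreGeneCorrelation(mc, "S", exclude_genes = c("g05"),
                             top_n = Inf))
    expect_false("g05" %in% res2$gene)
    expect_length(intersect(res2$gene, "g05"), 0)
    # permuting meta-cell order leaves correlations unchanged
    perm <- sample(8)
    mc2 <- mc
    mc2@profiles <- profiles[perm, ]
    mc2@scoreMeans <- mc@scoreMeans[perm, , drop = FALSE]
    res3 <- suppressWarnings(scoreGeneCorrelation(mc2, "S", top_n = Inf))
    expect_equal(res3[order(res3$gene), ], res[order(res$gene), ],
                 ignore_attr = TRUE)
    expect_error(scoreGeneCorrelation(mc, "nope"), "not found")
})

test_that("regulon activity reduces to signed z-profiles for single targets", {
    profiles <- matrix(rnorm(5 * 6), nrow = 6,
                       dimnames = list(paste0("mc", 1:6),
                                       paste0("g", 1:5)))
    mc <- new("MetaCellTable",
              assignment = stats::setNames(rep(1:6, 2), paste0("c", 1:12)),
              profiles = profiles,
              scoreMeans = matrix(numeric(6), ncol = 1,
                                  dimnames = list(paste0("mc", 1:6), "S")),
              sizes = rep(2L, 6), parameters = list())
    reg <- data.frame(tf = c("TFplus", "TFminus"),
                      target = c("g2", "g2"),
                      mode = c(1, -1), weight = c(1, 1))
    act <- regulonActivity(mc, reg)
    z <- (profiles[, "g2"] - mean(profiles[, "g2"])) / sd(profiles[, "g2"])
    expect_equal(unname(act[, "TFplus"]), unname(z))
    expect_equal(unname(act[, "TFminus"]), unname(-z))
    # a regulon with no present target is excluded with a warning
    reg2 <- rbind(reg, data.frame(tf = "TFghost", target = "absent",
                                  mode = 1, weight = 1))
    expect_warning(act2 <- regulonActivity(mc, reg2), "no present target")
    expect_false("TFghost" %in% colnames(act2))
})

test_that("score-TF correlation finds a planted program-linked TF", {
    spec <- syntheticSpec("ecm", seed = 31)
    sim <- generateDataset(spec)
    ds <- logNormalize(sim$data)
    sc <- suppressWarnings(
        moduleScore(ds, sim$truth$ecm_targets, seed = 1,
                    score_name = "ECM"))
    mc <- buildMetaCells(ds, scores = data.frame(ECM = as.numeric(sc)),
                         resolution = 10, seed = 2)
    reg <- generateRegulonTable(spec, n_null = 50, seed = 3)
    act <- suppressWarnings(regulonActivity(mc, reg))
    # planted TF activity tracks the program activity at meta-cell level
    asg <- mcAssignment(mc)
    keep <- !is.na(asg)
    a_mc <- tapply(sim$truth$activity[keep], asg[keep], mean)
    expect_gt(cor(act[, "Tf_prog"], as.numeric(a_mc)), 0.9)
    top <- scoreScoreCorrelation(mc, act, "ECM", top_n = 10)
    expect_true("Tf_prog" %in% top$tf)
    expect_identical(top$tf[1], "Tf_prog")
})

test_that("meta-cell averaging strengthens driver-score correlations", {
    spec <- syntheticSpec("ecm", seed = 41)
    sim <- generateDataset(spec)
    ds <- logNormalize(sim$data)
    sc <- suppressWarnings(
        moduleScore(ds, sim$truth$ecm_targets, seed = 1,
                    score_name = "ECM"))
    mc <- buildMetaCells(ds, scores = data.frame(ECM = as.numeric(sc)),
                         resolution = 10, seed = 2)
    ln <- as.matrix(SingleCellExperiment::logcounts(ds))
    drv <- sim$truth$drivers
    r_cell <- abs(cor(as.numeric(sc), t(ln[drv, ])))
    prof <- mcProfiles(mc)
    r_mc <- abs(cor(mcScoreMeans(mc)[, "ECM"], prof[, drv]))
    expect_gt(median(r_mc), median(r_cell))
})
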