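test_that("consensus database is exact set arithmetic over sources", {
    srcs <- list(A = data.frame(ligand = c("L1", "L2"),
                                receptor = c("R1", "R2")),
                 B = data.frame(ligand = "L1", receptor = "R1"),
                 C = data.frame(ligand = c("L1", "L3"),
                                receptor = c("R1", "R3")))
    db <- buildConsensusDB(srcs, min_sources = 2)
    tab <- interactions(db)
    expect_equal(nrow(tab), 1)
    expect_equal(tab$ligand, "L1")
    expect_equal(tab$sources, "A,B,C")
    # min_sources = 1 is the plain union of the 3 distinct pairs
    db1 <- buildConsensusDB(srcs, min_sources = 1)
    expect_equal(nrow(interactions(db1)), 3)
    expect_error(buildConsensusDB(stats::setNames(srcs, c("A", "A", "C"))),
                 "duplicate source names")
})

test_that("consensus filter equals brute force and is monotone in min_sources", {
    fx <- generateLRFixture(n_sources = 5, n_pairs = 40, seed = 13)
    prev <- NULL
    for (k in 1:5) {
        db <- buildConsensusDB(fx$sources, min_sources = k)
        got <- interactions(db)[, c("ligand", "receptor")]
        want <- fx$truth[fx$truth$n_sources >= k, c("ligand", "receptor")]
        want <- want[order(want$ligand, want$receptor), ]
        expect_equal(got, want, ignore_attr = TRUE)
        # per-pair source counts agree with the key
        expect_equal(interactions(db)$n_sources,
                     fx$truth$n_sources[fx$truth$n_sources >= k])
        if (!is.null(prev)) {
            key <- paste(got$ligand, got$receptor)
            expect_true(all(key %in% prev))    # retained(k) subset of k-1
        }
        prev <- paste(got$ligand, got$receptor)
    }
})

test_that("ortholog mapping translates complete pairs and drops the rest", {
    db <- buildConsensusDB(list(
        A = data.frame(ligand = c("l1", "l2", "l3"),
                       receptor = c("r1", "r2", "r3")),
        B = data.frame(ligand = c("l1", "l2", "l3"),
                       receptor = c("r1", "r2", "r3"))))
    idmap <- data.frame(from = c("l1", "l2", "l3", "r1", "r2", "r3"),
                        to = c("l1", "l2", "l3", "r1", "r2", "r3"))
    same <- mapOrthologs(db, idmap)
    expect_equal(interactions(same)[, 1:2], interactions(db)[, 1:2])
    # unmapped ligand drops its pair and is counted
    part <- idmap[idmap$from != "l2", ]
    out <- mapOrthologs(db, part)
    expect_equal(nrow(interactions(out)), 2)
    expect_equal(attr(interactions(out), "n_dropped"), 1)
    expect_error(mapOrthologs(db, data.frame(from = c("l1", "l1"),
                                             to = c("A", "B"))),
                 "one-to-many")
})

test_that("interaction scores use the mean-expression definition with a detection gate", {
    # two clusters, deterministic expression
    cts <- matrix(0, nrow = 3, ncol = 8,
                  dimnames = list(c("L1", "R1", "Gx"),
                                  sprintf("c%03d", 1:8)))
    cts["L1", 1:4] <- c(4, 4, 4, 4); cts["Gx", ] <- 10
    cts["R1", 5:8] <- c(6, 6, 6, 6)
    ds <- logNormalize(makeToyData(cts, cluster = rep(c("A", "B"),
                                                      each = 4)))
    db <- buildConsensusDB(list(s1 = data.frame(ligand = "L1",
                                                receptor = "R1"),
                                s2 = data.frame(ligand = "L1",
                                                receptor = "R1")))
    res <- interactionTest(ds, db, n_perm = 100, seed = 1)
    ln <- as.matrix(SingleCellExperiment::logcounts(ds))
    want <- (mean(ln["L1", 1:4]) + mean(ln["R1", 5:8])) / 2
    got <- res[res$sender == "A" & res$receiver == "B", ]
    expect_equal(got$mean_lr, want)
    expect_equal(got$expressed_fraction_l, 1)
    # reverse direction fails the detection gate (L1 absent in B)
    rev <- res[res$sender == "B" & res$receiver == "A", ]
    expect_false(rev$expressed)
    expect_true(is.na(rev$p_perm))
    expect_true(all(res$p_perm >= 1 / 101, na.rm = TRUE))

    # a database gene absent from the universe is skipped with a warning
    db2 <- buildConsensusDB(list(s1 = data.frame(ligand = c("L1", "Lmiss"),
                                                 receptor = c("R1", "R1")),
                                 s2 = data.frame(ligand = c("L1", "Lmiss"),
                                                 receptor = c("R1", "R1"))))
    expect_warning(res2 <- interactionTest(ds, db2, n_perm = 100, seed = 1),
                   "absent from the dataset")
    expect_false("Lmiss" %in% res2$ligand)
})

test_that("planted directional interaction is significant only in its direction", {
    sim <- generateDataset(syntheticSpec("crosstalk", seed = 23))
    ds <- logNormalize(sim$data)
    pl <- sim$truth$planted_lr
    db <- buildConsensusDB(list(
        a = pl[, c("ligand", "receptor")],
        b = pl[, c("ligand", "receptor")]))
    res <- interactionTest(ds, db, n_perm = 500, seed = 3)
    fwd <- res[res$sender == pl$sender & res$receiver == pl$receiver, ]
    rev <- res[res$sender == pl$receiver & res$receiver == pl$sender, ]
    expect_lt(fwd$p_perm, 0.05)
    expect_gt(rev$p_perm, 0.05)
})

test_that("differential network is antisymmetric with clean up/down splits", {
    mk <- function(mean_lr, sig) data.frame(
        sender = c("A", "A", "B"), receiver = c("B", "B", "A"),
        ligand = c("L1", "L2", "L2"), receptor = c("R1", "R2", "R2"),
        expressed = TRUE, mean_lr = mean_lr,
        p_perm = ifelse(sig, 0.01, 0.5), significant = sig)
    sham <- mk(c(1.0, 0.5, 0.2), c(TRUE, TRUE, FALSE))
    tac <- mk(c(2.2, 0.1, 0.9), c(TRUE, FALSE, TRUE))
    dn <- differentialNetwork(sham, tac)
    # identical inputs: all zero, sets empty
    id <- differentialNetwork(sham, sham)
    expect_true(all(id$edges$delta_weight == 0))
    expect_true(all(lengths(id$gene_sets) == 0))
    # single-edge arithmetic: B->A significant only in TAC at 0.9
    eb <- dn$edges[dn$edges$sender == "B", ]
    expect_equal(eb$delta_weight, 0.9)
    expect_true("L2" %in% dn$gene_sets$ligand_up ||
                    !"L2" %in% unlist(dn$gene_sets))
    # antisymmetry: swapping conditions negates weights, swaps sets
    dn_rev <- differentialNetwork(tac, sham)
    expect_equal(dn_rev$edges$delta_weight, -dn$edges$delta_weight)
    expect_identical(dn_rev$gene_sets$ligand_up, dn$gene_sets$ligand_down)
    expect_identical(dn_rev$gene_sets$receptor_down,
                     dn$gene_sets$receptor_up)
    # vocabulary mismatch errors
    bad <- mk(c(1, 1, 1), c(TRUE, TRUE, TRUE))
    bad$sender <- c("A", "A", "Z")
    expect_error(differentialNetwork(sham, bad), "vocabulary mismatch")
})

test_that("genes moving both up and down are disregarded from both sets", {
    res_a <- data.frame(sender = c("A", "B"), receiver = c("B", "A"),
                        ligand = c("L1", "L1"), receptor = c("R1", "R2"),
                        expressed = TRUE, mean_lr = c(1, 1),
                        p_perm = 0.01, significant = TRUE)
    res_b <- res_a
    res_b$mean_lr <- c(2, 0.5)    # L1 up in one pair, down in the other
    dn <- differentialNetwork(res_a, res_b)
    expect_false("L1" %in% dn$gene_sets$ligand_up)
    expect_false("L1" %in% dn$gene_sets$ligand_down)
})
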