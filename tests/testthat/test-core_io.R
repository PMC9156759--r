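test_that("triplet round-trip preserves counts, flags and metadata", {
    cts <- matrix(c(0, 3, 1, 0, 0, 5), nrow = 3,
                  dimnames = list(c("GeneA", "mt-Nd1", "tdTomato"),
                                  c("bc1", "bc2")))
    ds <- makeToyData(cts)
    expect_equal(sum(SummarizedExperiment::assay(ds, "counts")), 9)
    expect_true(SummarizedExperiment::rowData(ds)["mt-Nd1", "is_mito"])
    expect_false(SummarizedExperiment::rowData(ds)["GeneA", "is_mito"])
    expect_true(SummarizedExperiment::rowData(ds)["tdTomato", "is_reporter"])

    dir <- withr::local_tempdir()
    writeCounts(ds, dir)
    ds2 <- readCounts(file.path(dir, "matrix.mtx"),
                      file.path(dir, "features.tsv"),
                      file.path(dir, "barcodes.tsv"),
                      file.path(dir, "meta.tsv"))
    expect_identical(as.matrix(SummarizedExperiment::assay(ds2, "counts")),
                     as.matrix(SummarizedExperiment::assay(ds, "counts")))
    expect_identical(rownames(ds2), rownames(ds))
    expect_identical(colnames(ds2), colnames(ds))
})

test_that("reader rejects inconsistent or incomplete companion files", {
    cts <- matrix(1:6, nrow = 3,
                  dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
    ds <- makeToyData(cts)
    dir <- withr::local_tempdir()
    writeCounts(ds, dir)
    # barcode missing from the metadata table
    meta <- read.delim(file.path(dir, "meta.tsv"))
    write.table(meta[1, , drop = FALSE], file.path(dir, "meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCounts(file.path(dir, "matrix.mtx"),
                            file.path(dir, "features.tsv"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "meta.tsv")),
                 "missing from cell metadata.*c2")
    # feature file with the wrong number of rows
    writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
    expect_error(readCounts(file.path(dir, "matrix.mtx"),
                            file.path(dir, "features.tsv"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "meta.tsv")),
                 "features.tsv")
    # duplicate symbols
    writeLines(c("g1", "g1", "g3"), file.path(dir, "features.tsv"))
    expect_error(readCounts(file.path(dir, "matrix.mtx"),
                            file.path(dir, "features.tsv"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "meta.tsv")),
                 "duplicate gene symbols.*g1")
})

test_that("log-normalization matches the closed form and is column-local", {
    # a single count of 1: entry = ln(1 + 1e4)
    cts <- matrix(c(1, 0, 0, 2, 2, 0), nrow = 3)
    ds <- logNormalize(makeToyData(cts))
    ln <- as.matrix(SingleCellExperiment::logcounts(ds))
    expect_equal(ln[1, 1], log(1 + 1e4))
    # cell with counts (2,2): both entries ln(1 + 5000)
    expect_equal(unname(ln[1:2, 2]), rep(log(1 + 5000), 2))
    # all-zero gene stays all-zero
    expect_equal(unname(ln[3, ]), c(0, 0))
    # counts unchanged
    expect_equal(as.matrix(SummarizedExperiment::assay(ds, "counts")),
                 cts, ignore_attr = TRUE)

    # column-locality: permuting cells permutes lognorm columns identically
    set.seed(1)
    cts2 <- matrix(rpois(60, 5) + 1, nrow = 6)
    ds_a <- logNormalize(makeToyData(cts2))
    perm <- sample(ncol(cts2))
    ds_b <- logNormalize(makeToyData(cts2[, perm]))
    expect_equal(unname(as.matrix(SingleCellExperiment::logcounts(ds_b))),
                 unname(as.matrix(
                     SingleCellExperiment::logcounts(ds_a))[, perm]))

    expect_error(logNormalize(makeToyData(matrix(c(1, 0), nrow = 1))),
                 "zero total counts")
})

test_that("variable-gene selection ranks true variance and is order-invariant", {
    # one bimodal gene among constants is ranked first
    n <- 20
    cts <- rbind(bimodal = rep(c(0, 10), each = n / 2),
                 matrix(3, nrow = 5, ncol = n,
                        dimnames = list(paste0("const", 1:5), NULL)))
    colnames(cts) <- sprintf("c%03d", seq_len(n))
    ds <- logNormalize(makeToyData(cts))
    expect_identical(selectVariableGenes(ds, 1), "bimodal")
    # n = gene count returns every gene
    expect_setequal(selectVariableGenes(ds, nrow(cts)), rownames(cts))
    expect_error(selectVariableGenes(ds, nrow(cts) + 1), "exceeds")

    # identical profiles rank together (oracle: direct variance), and the
    # ranking is invariant to permuting the gene order
    set.seed(2)
    cts2 <- matrix(rpois(30 * 40, 5), nrow = 30,
                   dimnames = list(sprintf("g%02d", 1:30), NULL))
    cts2 <- rbind(cts2, twinA = cts2[1, ], twinB = cts2[1, ])
    colnames(cts2) <- sprintf("c%03d", 1:40)
    ds2 <- logNormalize(makeToyData(cts2))
    ranked <- selectVariableGenes(ds2, nrow(cts2))
    pos <- match(c("g01", "twinA", "twinB"), ranked)
    expect_equal(diff(sort(pos)), c(1, 1))  # identical profiles adjacent
    expect_identical(ranked[sort(pos)], c("g01", "twinA", "twinB"))

    perm <- sample(nrow(cts2))
    ds3 <- logNormalize(makeToyData(cts2[perm, ]))
    expect_identical(selectVariableGenes(ds3, 10),
                     selectVariableGenes(ds2, 10))
})
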