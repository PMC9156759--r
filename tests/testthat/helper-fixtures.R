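# Fixtures built in code and independent oracles used across test files.

# small NicheData from a dense count matrix; default metadata single
# sample/condition
makeToyData <- function(counts, sample = "s1", condition = "sham",
                        cluster = NULL, ...) {
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
    meta <- data.frame(cell_id = colnames(counts),
                       sample = rep_len(sample, ncol(counts)),
                       condition = rep_len(condition, ncol(counts)),
                       stringsAsFactors = FALSE)
    if (!is.null(cluster)) meta$cluster <- cluster
    NicheData(Matrix::Matrix(counts, sparse = TRUE), meta, ...)
}

# Poisson two-blob dataset: cells 1..n1 high in the first gene block,
# the rest high in the second block
makeBlobData <- function(n1 = 50, n2 = 50, g_block = 20, g_null = 20,
                         hi = 40, lo = 2, seed = 9) {
    set.seed(seed)
    G <- 2 * g_block + g_null
    n <- n1 + n2
    mu <- matrix(lo, G, n)
    mu[seq_len(g_block), seq_len(n1)] <- hi
    mu[g_block + seq_len(g_block), n1 + seq_len(n2)] <- hi
    cts <- matrix(rpois(G * n, mu), G, n,
                  dimnames = list(sprintf("g%02d", seq_len(G)),
                                  sprintf("c%03d", seq_len(n))))
    list(data = logNormalize(makeToyData(cts)),
         blob = rep(1:2, c(n1, n2)))
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

# exact two-sided rank-sum p-value by full enumeration of group
# assignments (tie-free data only)
exactRankSumP <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    ranks <- rank(c(x, y))
    w_obs <- sum(ranks[seq_len(n1)])
    combos <- utils::combn(n1 + n2, n1)
    w_null <- apply(combos, 2L, function(idx) sum(ranks[idx]))
    pl <- mean(w_null <= w_obs)
    pg <- mean(w_null >= w_obs)
    min(1, 2 * min(pl, pg))
}

# nearest-centroid assignment oracle in log-normalized expression space
nearestCentroid <- function(ds, groups) {
    ln <- as.matrix(SummarizedExperiment::assay(ds, "logcounts"))
    cents <- sapply(sort(unique(groups)), function(g)
        rowMeans(ln[, groups == g, drop = FALSE]))
    apply(ln, 2L, function(v) which.min(colSums((cents - v)^2)))
}

# cell indices of a dataset generated by generateDataset, by true type
truthIndex <- function(sim, type) which(sim$truth$type == type)
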